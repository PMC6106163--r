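test_that("single-species community is forced to unit relative metrics", {
  surv <- two_species_survey()[1, ]
  m <- relative_metrics(surv)
  expect_equal(m$RD, 1)
  expect_equal(m$RF, 1)
  expect_equal(m$RG_or_RC, 1)
  expect_equal(m$IV, 1)
})

test_that("two-species hand-derived example matches arithmetic", {
  m <- relative_metrics(two_species_survey()) |> dplyr::arrange(species)
  expect_equal(m$RD, c(0.75, 0.25))
  expect_equal(m$RF, c(0.5, 0.5))
  expect_equal(m$RG_or_RC, c(0.5, 0.5))
  expect_equal(m$IV, c((0.75 + 0.5 + 0.5) / 3, (0.25 + 0.5 + 0.5) / 3))
})

test_that("IV is the arithmetic mean of its three components", {
  m <- relative_metrics(demo_survey())
  expect_equal(m$IV, (m$RD + m$RF + m$RG_or_RC) / 3)
  # components sum to 1 within each community x stratum
  sums <- m |>
    dplyr::group_by(community_type) |>
    dplyr::summarise(dplyr::across(c(RD, RF, RG_or_RC), sum))
  expect_true(all(abs(sums$RD - 1) < 1e-9))
  expect_true(all(abs(sums$RF - 1) < 1e-9))
  expect_true(all(abs(sums$RG_or_RC - 1) < 1e-9))
})

test_that("total importance weights IVs by area ratio", {
  # single community, AR = 1: TIV equals IV
  m1 <- relative_metrics(two_species_survey())
  areas1 <- tibble::tibble(community_type = "c1", area_ratio = 1)
  d1 <- total_importance(m1, areas1)
  expect_equal(d1$TIV[match(m1$species, d1$species)], m1$IV)

  # two communities, AR {0.5, 0.5}: weighted mean, absent species counts 0
  m2 <- dplyr::bind_rows(
    tibble::tibble(community_type = "a", species = "x", RD = 1, RF = 1,
                   RG_or_RC = 1, IV = 0.6, stratum = "herb"),
    tibble::tibble(community_type = "b", species = "x", RD = 1, RF = 1,
                   RG_or_RC = 1, IV = 0.2, stratum = "herb"))
  areas2 <- tibble::tibble(community_type = c("a", "b"),
                           area_ratio = c(0.5, 0.5))
  expect_equal(total_importance(m2, areas2)$TIV, 0.4)

  # RTIV always sums to 100
  d <- total_importance(relative_metrics(demo_survey()), demo_areas())
  expect_equal(sum(d$RTIV), 100, tolerance = 1e-9)

  # bad area ratios are rejected, reporting the sum
  expect_error(
    total_importance(m1, tibble::tibble(community_type = "c1",
                                        area_ratio = 0.9)),
    "0.9", class = "apparency_validation_error")
})

test_that("zero-count and empty communities are errors", {
  z <- two_species_survey(); z$count <- 0L
  expect_error(relative_metrics(z), "zero total count",
               class = "apparency_validation_error")
  expect_error(relative_metrics(demo_survey(), community = "bog"),
               "bog", class = "apparency_validation_error")
})

test_that("group importance conserves TIV and normalizes RGIV", {
  dom <- total_importance(relative_metrics(demo_survey()), demo_areas())
  # one group holding everything
  all_in <- group_importance(dom, setNames(rep("all", nrow(dom)), dom$species))
  expect_equal(all_in$RGIV, 100)
  # explicit 3:1 split
  g <- group_importance(
    tibble::tibble(species = c("a", "b"), TIV = c(3, 1), RTIV = c(75, 25)),
    c(a = "g1", b = "g2"))
  expect_equal(g$RGIV[g$group == "g1"], 75)
  expect_equal(g$RGIV[g$group == "g2"], 25)
  # conservation under any partition
  set.seed(7)
  for (rep in 1:10) {
    part <- setNames(sample(letters[1:3], nrow(dom), TRUE), dom$species)
    gi <- group_importance(dom, part)
    expect_equal(sum(gi$GIV), sum(dom$TIV), tolerance = 1e-12)
    expect_equal(sum(gi$RGIV), 100, tolerance = 1e-9)
  }
  expect_error(group_importance(dom, character()), "empty",
               class = "apparency_validation_error")
})

test_that("RD is invariant to rescaling all counts in one community", {
  surv <- demo_survey()
  scaled <- surv |>
    dplyr::mutate(count = ifelse(community_type == "steppe",
                                 count * 7L, count))
  m0 <- relative_metrics(surv) |> dplyr::arrange(community_type, species)
  m1 <- relative_metrics(scaled) |> dplyr::arrange(community_type, species)
  expect_equal(m0$RD, m1$RD, tolerance = 1e-12)
})

test_that("merging equal-IV communities with summed ARs preserves TIV", {
  m <- relative_metrics(two_species_survey())
  dup <- dplyr::bind_rows(m, dplyr::mutate(m, community_type = "c2"))
  areas_split <- tibble::tibble(community_type = c("c1", "c2"),
                                area_ratio = c(0.3, 0.7))
  areas_merged <- tibble::tibble(community_type = "c1", area_ratio = 1)
  split <- total_importance(dup, areas_split) |> dplyr::arrange(species)
  merged <- total_importance(m, areas_merged) |> dplyr::arrange(species)
  expect_equal(split$TIV, merged$TIV, tolerance = 1e-12)
})

test_that("a species in two strata keeps the stratum with larger IV", {
  surv <- dplyr::bind_rows(
    demo_survey()[1:4, ],
    tibble::tibble(community_type = "forest", plot_id = "p1",
                   subplot_id = "s1", species = "Quercus mongolica",
                   stratum = "herb", count = 1L, size = 0.05),
    tibble::tibble(community_type = "forest", plot_id = "p1",
                   subplot_id = c("s1", "s2"), species = "Carex duriuscula",
                   stratum = "herb", count = c(30L, 25L), size = c(0.6, 0.5)))
  m <- relative_metrics(surv)
  oak <- m[m$species == "Quercus mongolica", ]
  expect_equal(nrow(oak), 1)          # never counted twice
  expect_equal(oak$stratum, "tree")   # tree-layer IV dominates the seedling
})
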