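test_that("logistic fit matches symmetry, closed forms and a brute-force
           likelihood maximizer", {
  # symmetric design: slope exactly 0
  sym <- tibble::tibble(taxon = letters[1:4], mined = c(0, 1, 0, 1),
                        tiv = c(1, 1, 2, 2))
  expect_lt(abs(fit_glm_binary(sym)$B), 1e-10)

  # intercept-only data: logit of the mean
  flat <- tibble::tibble(taxon = letters[1:8],
                         mined = c(1, rep(0, 3), 1, rep(0, 3)), tiv = 0)
  expect_equal(fit_glm_binary(flat)$intercept, log(1 / 3), tolerance = 1e-8)

  # 6-point dataset against direct likelihood optimization
  d6 <- tibble::tibble(taxon = letters[1:6],
                       mined = c(0, 0, 1, 0, 1, 1),
                       tiv = c(-1.2, 0.4, 0.9, 1.3, 2.0, 3.1))
  f <- fit_glm_binary(d6)
  oracle <- brute_logistic(d6$tiv, d6$mined)
  expect_equal(f$intercept, oracle[1], tolerance = 1e-6)
  expect_equal(f$B, oracle[2], tolerance = 1e-6)
  expect_equal(f$AIC, 2 * 2 + 2 * brute_nll(oracle, d6$tiv, d6$mined),
               tolerance = 1e-6)

  # perfect separation raises a dedicated error
  sep <- tibble::tibble(taxon = letters[1:8], mined = rep(c(0, 1), each = 4),
                        tiv = c(1:4, 11:14))
  expect_error(fit_glm_binary(sep), class = "apparency_separation_error")
})

test_that("PGLMM collapses to the ordinary logistic fit without signal", {
  set.seed(21)
  n <- 150
  tr <- random_dated_tree(n, seed = 21)
  tiv <- skewed_tiv(n)[sample(n)]
  y <- rbinom(n, 1, plogis(-1 + 0.003 * tiv))
  d <- tibble::tibble(taxon = tr$tip.label, mined = y, tiv = tiv)
  fg <- fit_glm_binary(d)

  # star phylogeny (V = identity): same coefficients within 1e-3
  fi <- fit_binary_pglmm(d, diag(n))
  expect_equal(fi$B, fg$B, tolerance = 1e-3)
  expect_equal(fi$intercept, fg$intercept, tolerance = 1e-3)

  # s2 fixed at 0: identical to 1e-6 whatever V
  V <- tip_covariance(tr, standardize = TRUE)
  f0 <- fit_binary_pglmm(d, V, s2_fixed = 0)
  expect_equal(f0$B, fg$B, tolerance = 1e-6)
  expect_equal(f0$intercept, fg$intercept, tolerance = 1e-6)
})

test_that("PGLMM agrees with an independent PQL implementation", {
  tr <- random_dated_tree(120, seed = 42)
  V <- tip_covariance(tr, standardize = TRUE)
  tiv <- seq(0, 1000, length.out = 120)
  pres <- gen_presence(sim_config(seed = 5, s2_true = 0.4),
                       tibble::tibble(species = tr$tip.label, tiv = tiv), tr)
  d <- tibble::tibble(taxon = pres$taxon, mined = pres$mined,
                      tiv = tiv[match(pres$taxon, tr$tip.label)])
  mine <- fit_binary_pglmm(d, V)
  ref <- suppressWarnings(
    ape::binaryPGLMM(mined ~ tiv, data = as.data.frame(d), phy = tr))
  expect_equal(mine$B, unname(ref$B[2]), tolerance = 1e-4)
  expect_equal(mine$intercept, unname(ref$B[1]), tolerance = 1e-4)
  expect_equal(mine$signal, ref$s2, tolerance = 1e-3)
  expect_equal(mine$p_B, unname(ref$B.pvalue[2]), tolerance = 1e-4)
})

test_that("PGLMM input contracts are enforced", {
  d <- tibble::tibble(taxon = c("a", "b", "c"), mined = c(1, 1, 1),
                      tiv = 1:3)
  expect_error(fit_binary_pglmm(d, diag(3)), "constant",
               class = "apparency_validation_error")
  d2 <- tibble::tibble(taxon = c("a", "b", "c"), mined = c(0, 1, 1),
                       tiv = 1:3)
  notpsd <- matrix(c(1, 0, 0, 0, 1, 2, 0, 2, 1), 3, 3)
  expect_error(fit_binary_pglmm(d2, notpsd), "semi-definite",
               class = "apparency_validation_error")
})

test_that("phyloglm matches the plain fit in the no-correlation limit and
           stays finite under saturation", {
  set.seed(31)
  n <- 400
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- sprintf("s%03d", seq_len(n))
  tiv <- 1000 * runif(n)^2
  y <- rbinom(n, 1, plogis(0.004 * tiv))
  d <- tibble::tibble(taxon = star$tip.label, mined = y, tiv = tiv)
  fg <- fit_glm_binary(d)
  fp <- fit_phyloglm(d, star)
  expect_lt(abs(fp$B - fg$B), 1e-2)
  expect_lt(abs(fp$intercept - fg$intercept), 1e-2)
  expect_true(is.finite(fp$AIC))

  # two tips, y = (0, 1): the penalty keeps the estimates finite
  tt <- ape::read.tree(text = "(A:1,B:1);")
  f2 <- fit_phyloglm(tibble::tibble(taxon = c("A", "B"), mined = c(0, 1),
                                    tiv = c(0, 1)), tt)
  expect_true(all(is.finite(c(f2$B, f2$intercept))))
  expect_lt(abs(f2$B), 10)

  # mismatched tips are reported by name
  expect_error(fit_phyloglm(dplyr::mutate(d[1:10, ], taxon = letters[1:10]),
                            star),
               class = "apparency_validation_error")
})

test_that("phyloglm recovers strong phylogenetic signal in alpha", {
  hits <- purrr::map_lgl(1:25, function(s) {
    set.seed(s)
    n <- 200
    tr <- random_dated_tree(n, seed = 800 + s)
    V <- tip_covariance(tr, standardize = TRUE)
    Dm <- outer(diag(V), diag(V), "+") - 2 * V
    L <- t(chol(exp(-1 * Dm) + 1e-10 * diag(n))) # OU rate 1: strong signal
    y <- rbinom(n, 1, plogis(2 * drop(L %*% rnorm(n))))
    if (length(unique(y)) < 2) return(NA)
    d <- tibble::tibble(taxon = tr$tip.label, mined = y,
                        tiv = runif(n, 0, 1000))
    fit_phyloglm(d, tr)$signal < 10
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})

test_that("slope rescales inversely with the covariate in all models", {
  tr <- random_dated_tree(100, seed = 9)
  tiv <- skewed_tiv(100)
  pres <- gen_presence(sim_config(seed = 9, s2_true = 0.3),
                       tibble::tibble(species = tr$tip.label, tiv = tiv), tr)
  d <- tibble::tibble(taxon = pres$taxon, mined = pres$mined,
                      tiv = tiv[match(pres$taxon, tr$tip.label)])
  d10 <- dplyr::mutate(d, tiv = tiv / 10)
  V <- tip_covariance(tr, standardize = TRUE)
  for (pair in list(list(fit_glm_binary(d), fit_glm_binary(d10)),
                    list(fit_binary_pglmm(d, V), fit_binary_pglmm(d10, V)),
                    list(fit_phyloglm(d, tr, n_grid = 21),
                         fit_phyloglm(d10, tr, n_grid = 21)))) {
    expect_equal(pair[[2]]$B, 10 * pair[[1]]$B, tolerance = 1e-3)
    expect_equal(pair[[2]]$intercept, pair[[1]]$intercept, tolerance = 1e-3)
  }
})

test_that("p-values are valid and invariant to tip reordering", {
  tr <- random_dated_tree(80, seed = 13)
  tiv <- skewed_tiv(80)
  pres <- gen_presence(sim_config(seed = 13, s2_true = 0.4),
                       tibble::tibble(species = tr$tip.label, tiv = tiv), tr)
  d <- tibble::tibble(taxon = pres$taxon, mined = pres$mined,
                      tiv = tiv[match(pres$taxon, tr$tip.label)])
  V <- tip_covariance(tr, standardize = TRUE)
  f <- fit_binary_pglmm(d, V)
  for (p in c(f$p_B, f$p_intercept, f$p_signal)) {
    expect_gt(p, 0); expect_lte(p, 1)
  }
  perm <- sample(nrow(d))
  f2 <- fit_binary_pglmm(d[perm, ], V[perm, perm])
  expect_equal(f2$p_B, f$p_B, tolerance = 1e-6)
  expect_equal(f2$B, f$B, tolerance = 1e-8)
})

test_that("incidence curves are logistic in the fitted coefficients", {
  f <- structure(list(intercept = 0, B = 0), class = "mine_fit")
  expect_equal(incidence_curve(f, c(-5, 0, 7))$p, rep(0.5, 3))
  f2 <- structure(list(intercept = -2, B = 0.004), class = "mine_fit")
  expect_equal(incidence_curve(f2, 500)$p, 0.5) # x = -intercept/B
  curve <- incidence_curve(f2, seq(0, 1000, 50))
  expect_true(all(diff(curve$p) > 0)) # monotone increasing iff B > 0
})

test_that("model summaries expose broom-style tidy and glance", {
  d <- tibble::tibble(taxon = letters[1:10],
                      mined = rep(c(0, 1), 5), tiv = 1:10 * 10)
  f <- fit_glm_binary(d)
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "tiv"))
  expect_equal(td$estimate, c(f$intercept, f$B))
  gl <- glance(f)
  expect_equal(gl$model, "glm")
  expect_equal(gl$nobs, 10L)
})

test_that("dominance slope is recovered as positive and significant under
           the printed-regime emulation", {
  hits <- purrr::map_lgl(1:20, function(s) {
    cfg <- sim_config(seed = 4000 + s, n_species = 444)
    phy <- gen_phylogeny(cfg)
    set.seed(4000 + s)
    dom <- tibble::tibble(species = phy$tree$tip.label,
                          tiv = 1000 * runif(444)^3)
    pres <- gen_presence(cfg, dom, phy$tree)
    d <- tibble::tibble(taxon = pres$taxon, mined = pres$mined,
                        tiv = dom$tiv[match(pres$taxon, dom$species)])
    f <- tryCatch(fit_glm_binary(d), error = function(e) NULL)
    !is.null(f) && f$B > 0 && f$p_B < 0.05
  })
  expect_gte(mean(hits), 0.9)
})
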