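#' Per-community relative dominance metrics and importance values
#'
#' For one community type, computes each species' relative density (RD),
#' relative frequency (RF) and relative size — summed GBH for the tree
#' stratum (RG) or summed coverage for the shrub/herb strata (RC) — and
#' the importance value IV = (RD + RF + RG-or-RC) / 3.
#'
#' Normalization is within stratum: RD is a species' total count over the
#' stratum's total count, RF its occupied-subplot fraction over the sum
#' of all such fractions in the stratum, and the size component its
#' summed GBH (trees) or coverage (shrubs/herbs) over the stratum total.
#' A species recorded in more than one stratum of the community (e.g.
#' tree layer plus seedling layer) keeps the stratum where its IV is
#' larger, so it is never scored against two denominators at once.
#'
#' @param surveys Survey record tibble (see [read_surveys()]).
#' @param community Community type identifier to compute metrics for;
#'   `NULL` (default) computes all communities present.
#' @return A tibble with columns `community_type`, `species`, `stratum`,
#'   `RD`, `RF`, `RG_or_RC`, `IV`. Within each community and stratum,
#'   RD, RF and RG_or_RC each sum to 1.
#' @export
relative_metrics <- function(surveys, community = NULL) {
  validate_surveys(surveys)
  if (!is.null(community)) {
    unknown <- setdiff(community, surveys$community_type)
    if (length(unknown) > 0) {
      abort(sprintf("no records for community type(s): %s",
                    paste(unknown, collapse = ", ")),
            class = "apparency_validation_error")
    }
    surveys <- filter(surveys, .data$community_type %in% community)
  }
  if (nrow(surveys) == 0) {
    abort("no survey records to compute metrics from",
          class = "apparency_validation_error")
  }

  per_stratum <- surveys |>
    group_by(.data$community_type, .data$stratum) |>
    dplyr::group_modify(~ stratum_metrics(.x, .y)) |>
    ungroup()

  # a species present in several strata keeps its best stratum
  per_stratum |>
    group_by(.data$community_type, .data$species) |>
    arrange(desc(.data$IV), .data$stratum, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$community_type, desc(.data$IV), .data$species)
}

stratum_metrics <- function(records, key) {
  total_count <- sum(records$count)
  if (total_count == 0) {
    abort(sprintf("community %s (%s stratum) has zero total count",
                  key$community_type, key$stratum),
          class = "apparency_validation_error")
  }
  total_size <- sum(records$size)
  if (total_size == 0) {
    abort(sprintf("community %s (%s stratum) has zero total size measure",
                  key$community_type, key$stratum),
          class = "apparency_validation_error")
  }
  n_subplots <- dplyr::n_distinct(paste(records$plot_id, records$subplot_id))
  per_sp <- records |>
    group_by(.data$species) |>
    summarise(
      count = sum(.data$count),
      freq = dplyr::n_distinct(paste(.data$plot_id, .data$subplot_id)) / n_subplots,
      size = sum(.data$size),
      .groups = "drop"
    )
  per_sp |>
    mutate(
      RD = .data$count / sum(.data$count),
      RF = .data$freq / sum(.data$freq),
      RG_or_RC = .data$size / sum(.data$size),
      IV = (.data$RD + .data$RF + .data$RG_or_RC) / 3
    ) |>
    select("species", "RD", "RF", "RG_or_RC", "IV")
}

#' Area-weighted total importance values (TIV and RTIV)
#'
#' The total importance value of species j is the sum over community
#' types of its importance value there times the community type's area
#' ratio: TIV_j = sum_i IV_ij x AR_i, with IV = 0 where the species is
#' absent. RTIV_j rescales TIV to a percentage of the sum over species.
#'
#' @param metrics Output of [relative_metrics()] over all communities
#'   (columns `community_type`, `species`, `IV`).
#' @param areas Tibble with `community_type` and `area_ratio` summing
#'   to 1.
#' @param species_pool Optional character vector of all species in the
#'   flora; pool members absent from every surveyed community receive
#'   TIV = 0.
#' @return A tibble with `species`, `TIV`, `RTIV` (percent), sorted by
#'   decreasing TIV.
#' @export
total_importance <- function(metrics, areas, species_pool = NULL) {
  check_area_ratios(areas$area_ratio)
  missing <- setdiff(unique(metrics$community_type), areas$community_type)
  if (length(missing) > 0) {
    abort(sprintf("no area ratio for community type(s): %s",
                  paste(missing, collapse = ", ")),
          class = "apparency_validation_error")
  }
  out <- metrics |>
    left_join(select(areas, "community_type", "area_ratio"),
              by = "community_type") |>
    group_by(.data$species) |>
    summarise(TIV = sum(.data$IV * .data$area_ratio), .groups = "drop") |>
    mutate(RTIV = .data$TIV / sum(.data$TIV) * 100) |>
    arrange(desc(.data$TIV), .data$species)
  if (!is.null(species_pool)) {
    absent <- setdiff(species_pool, out$species)
    out <- bind_rows(out, tibble(species = absent, TIV = 0, RTIV = 0))
  }
  out
}

#' Group importance values (GIV and RGIV)
#'
#' The group importance value of a group (a family, genus, life form,
#' water ecotype, phytogeographic type, or rank bin) is the sum of its
#' member species' TIVs; RGIV expresses it as a percentage of the total.
#'
#' @param dominance Tibble with `species` and `TIV` (see
#'   [total_importance()]).
#' @param partition Named character vector or two-column data frame
#'   (`species`, `group`) assigning species to groups. Species with
#'   TIV > 0 not covered by the partition are collected into an
#'   `"unassigned"` group.
#' @return A tibble with `group`, `GIV`, `RGIV` (percent), `n_species`,
#'   sorted by decreasing GIV.
#' @export
group_importance <- function(dominance, partition) {
  if (is.data.frame(partition)) {
    stopifnot(all(c("species", "group") %in% names(partition)))
    partition <- setNames(as.character(partition$group),
                          as.character(partition$species))
  }
  if (length(partition) == 0) {
    abort("empty partition", class = "apparency_validation_error")
  }
  grp <- unname(partition[dominance$species])
  grp[is.na(grp)] <- "unassigned"
  dominance |>
    mutate(group = grp) |>
    group_by(.data$group) |>
    summarise(GIV = sum(.data$TIV), n_species = dplyr::n(), .groups = "drop") |>
    mutate(RGIV = .data$GIV / sum(.data$GIV) * 100) |>
    select("group", "GIV", "RGIV", "n_species") |>
    arrange(desc(.data$GIV), .data$group)
}
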