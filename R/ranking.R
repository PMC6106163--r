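#' Rank taxa by TIV and bin into equal-size dominance groups
#'
#' Taxa with TIV > 0 are ranked in decreasing TIV order (ties broken by
#' taxon name) and cut into `n_groups` contiguous groups of exactly
#' `floor(n / n_groups)` taxa; the remainder taxa with the smallest
#' nonzero TIVs are omitted, as is done when the taxon count is not
#' precisely divisible by the group count.
#'
#' @param dominance Tibble with a taxon column (`species` or `taxon`) and
#'   `TIV`.
#' @param n_groups Number of equal-size groups (rank 1 = most dominant).
#' @param level Taxonomic level label carried through to reports.
#' @return A tibble of binned taxa (`taxon`, `TIV`, `rank`) of class
#'   `ranked_groups`, with attributes `level`, `n_groups`, `group_size`
#'   and `omitted` (character vector of dropped taxa).
#' @export
rank_and_bin <- function(dominance, n_groups, level = "species") {
  if (!"taxon" %in% names(dominance) && "species" %in% names(dominance)) {
    dominance <- rename(dominance, taxon = "species")
  }
  stopifnot(n_groups >= 1)
  nonzero <- dominance |>
    filter(.data$TIV > 0) |>
    arrange(desc(.data$TIV), .data$taxon)
  n <- nrow(nonzero)
  if (n < n_groups) {
    abort(sprintf("only %d taxa with TIV > 0 but %d groups requested",
                  n, n_groups),
          class = "apparency_validation_error")
  }
  group_size <- n %/% n_groups
  n_omit <- n %% n_groups
  omitted <- if (n_omit > 0) tail(nonzero$taxon, n_omit) else character()
  binned <- head(nonzero, n - n_omit) |>
    mutate(rank = rep(seq_len(n_groups), each = group_size)) |>
    select("taxon", "TIV", "rank")
  structure(binned,
            class = c("ranked_groups", class(binned)),
            level = level,
            n_groups = as.integer(n_groups),
            group_size = as.integer(group_size),
            omitted = omitted,
            tiv_total = sum(nonzero$TIV))
}

#' @export
print.ranked_groups <- function(x, ...) {
  cat(sprintf("Ranked dominance groups (%s level): %d groups of %d taxa, %d omitted\n",
              attr(x, "level"), attr(x, "n_groups"), attr(x, "group_size"),
              length(attr(x, "omitted"))))
  NextMethod()
}

#' Host counts and host ratios per dominance rank group
#'
#' Joins binary leaf-mine presence onto the binned taxa and summarises
#' each rank group: its relative group importance value (RGIV), its host
#' count and its host ratio (hosts over group size). Taxa missing from
#' the presence table are treated as non-hosts and reported via a
#' message.
#'
#' @param groups A `ranked_groups` object from [rank_and_bin()].
#' @param presence Presence tibble (`taxon`, `mined`) at the same level.
#' @param quiet Suppress the missing-taxa message.
#' @return A tibble with one row per rank group: `rank`, `RGIV`,
#'   `n_taxa`, `host_count`, `host_ratio`; class `host_ratio_table`.
#' @export
host_ratio_table <- function(groups, presence, quiet = FALSE) {
  stopifnot(inherits(groups, "ranked_groups"))
  validate_presence(presence)
  missing <- setdiff(groups$taxon, presence$taxon)
  if (!quiet && length(missing) > 0) {
    inform(sprintf("%d binned taxa absent from presence table, scored 0: %s%s",
                   length(missing), paste(head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) ", ..." else ""))
  }
  tiv_total <- attr(groups, "tiv_total")
  out <- groups |>
    left_join(presence, by = "taxon") |>
    mutate(mined = tidyr::replace_na(.data$mined, 0)) |>
    group_by(.data$rank) |>
    summarise(
      RGIV = sum(.data$TIV) / tiv_total * 100,
      n_taxa = dplyr::n(),
      host_count = sum(.data$mined),
      host_ratio = sum(.data$mined) / dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$rank)
  structure(out,
            class = c("host_ratio_table", class(out)),
            level = attr(groups, "level"),
            group_size = attr(groups, "group_size"),
            omitted = attr(groups, "omitted"))
}

#' Dominance and host status summarised by a plant attribute
#'
#' Summarises RGIV, species counts, host counts and host ratios per
#' category of a plant attribute (life form, water ecotype, or
#' phytogeographic distribution type). Species lacking the attribute are
#' collected under an `"unknown"` category. Species absent from the
#' dominance table contribute zero TIV but still count toward category
#' sizes and host counts.
#'
#' @param dominance Tibble with `species` and `TIV`.
#' @param attrs Taxon attribute tibble (see [read_attributes()]).
#' @param presence Species-level presence tibble (`taxon`, `mined`).
#' @param attribute One of `"life_form"`, `"water_ecotype"`,
#'   `"phytogeo_type"`.
#' @return A tibble with one row per category, sorted by decreasing
#'   RGIV: `category`, `RGIV`, `n_species`, `host_count`, `host_ratio`.
#' @export
attribute_summary <- function(dominance, attrs, presence,
                              attribute = c("life_form", "water_ecotype",
                                            "phytogeo_type")) {
  attribute <- match.arg(attribute)
  validate_presence(presence)
  tab <- attrs |>
    select("species", category = dplyr::all_of(attribute)) |>
    mutate(category = ifelse(is.na(.data$category) | .data$category == "",
                             "unknown", .data$category)) |>
    left_join(select(dominance, "species", "TIV"), by = "species") |>
    left_join(presence, by = c(species = "taxon")) |>
    mutate(TIV = tidyr::replace_na(.data$TIV, 0),
           mined = tidyr::replace_na(.data$mined, 0))
  tab |>
    group_by(.data$category) |>
    summarise(
      RGIV = sum(.data$TIV), # rescaled below
      n_species = dplyr::n(),
      host_count = sum(.data$mined),
      host_ratio = sum(.data$mined) / dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(RGIV = .data$RGIV / sum(.data$RGIV) * 100) |>
    arrange(desc(.data$RGIV), .data$category)
}

#' Round report columns the way the printed tables do
#'
#' Ratios to 3 decimals and RGIV to 2, half-up; full precision is kept
#' everywhere else in the pipeline.
#'
#' @param x A `host_ratio_table` or attribute summary tibble.
#' @return The tibble with rounded display columns.
#' @export
format_report <- function(x) {
  if ("host_ratio" %in% names(x)) x$host_ratio <- round_half_up(x$host_ratio, 3)
  if ("RGIV" %in% names(x)) x$RGIV <- round_half_up(x$RGIV, 2)
  x
}
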