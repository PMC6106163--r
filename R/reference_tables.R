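#' Published Saihanwula dominance-group and attribute summary counts
#'
#' Loads the published summary tables for the Saihanwula National
#' Nature Reserve leafminer-host survey that ship with the package:
#' per-rank-group relative group importance values and host counts at
#' the species (12 groups of 37), genus (12 groups of 21, 2 omitted)
#' and family (7 groups of 10, 1 omitted) levels, and per-category
#' counts for life forms, water ecotypes and phytogeographic types.
#' These are the printed group-level counts only, not the underlying
#' plot records.
#'
#' @param which One of `"species_groups"`, `"genus_groups"`,
#'   `"family_groups"`, `"life_forms"`, `"water_ecotypes"`,
#'   `"phytogeo_types"`.
#' @return A tibble.
#' @export
saihanwula_counts <- function(which = c("species_groups", "genus_groups",
                                        "family_groups", "life_forms",
                                        "water_ecotypes", "phytogeo_types")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("saihanwula_", which, ".csv"),
                      package = "apparency", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Expand published group counts into a taxon-level table
#'
#' Reconstructs a taxon-level dominance and presence table consistent
#' with a published rank-group summary: each rank group of
#' `group_size` taxa receives strictly decreasing synthetic TIVs
#' proportional to its RGIV (floored at a small positive value so
#' every binned taxon has TIV > 0), and its first `host_count` members
#' are scored as hosts. `n_omitted` extra tail taxa with still smaller
#' nonzero TIVs reproduce the omission of remainder taxa when the
#' taxon count is not divisible by the group count. Re-running
#' [rank_and_bin()] and [host_ratio_table()] on the expansion
#' reproduces the published group sizes, omission counts and host
#' ratios.
#'
#' @param counts Tibble with `rank`, `RGIV`, `host_count` (see
#'   [saihanwula_counts()]).
#' @param group_size Taxa per rank group.
#' @param n_omitted Remainder taxa omitted in the published ranking.
#' @return A list: `dominance` (tibble `taxon`, `TIV`) and `presence`
#'   (tibble `taxon`, `mined`).
#' @export
expand_group_counts <- function(counts, group_size, n_omitted = 0) {
  stopifnot(all(c("rank", "RGIV", "host_count") %in% names(counts)),
            all(counts$host_count <= group_size))
  n <- nrow(counts) * group_size
  tiv <- rep(pmax(counts$RGIV, 0.005), each = group_size)
  tiv <- tiv - seq_len(n) * 1e-7 # strictly decreasing, stays positive
  mined <- unlist(lapply(counts$host_count, function(h) {
    c(rep(1L, h), rep(0L, group_size - h))
  }))
  taxon <- sprintf("t%04d", seq_len(n + n_omitted))
  if (n_omitted > 0) {
    tiv <- c(tiv, min(tiv) * rev(seq_len(n_omitted)) / (2 * n_omitted))
    mined <- c(mined, rep(0L, n_omitted))
  }
  list(dominance = tibble(taxon = taxon, TIV = tiv),
       presence = tibble(taxon = taxon, mined = mined))
}
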