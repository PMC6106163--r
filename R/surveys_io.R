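#' Read and validate community survey records
#'
#' Reads a delimited table of plot-survey observations and validates it.
#' One row is one observation of a species in a subplot of a community
#' type: its individual count and its size measure (girth at breast
#' height, GBH, in cm for the tree stratum; coverage as a fraction of the
#' subplot for the shrub and herb strata).
#'
#' @param path Path to a delimited text file with a header naming the six
#'   required columns: `community_type`, `plot_id`, `subplot_id`,
#'   `species`, `stratum`, `count`, `size`.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A tibble of validated survey records.
#' @seealso [validate_surveys()] for the checks applied.
#' @export
read_surveys <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  required <- c("community_type", "plot_id", "subplot_id", "species",
                "stratum", "count", "size")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("survey file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "apparency_schema_error")
  }
  for (col in c("count", "size")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(num) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s at data row(s) %s (file line %s)",
                    col, paste(bad, collapse = ", "),
                    paste(bad + 1L, collapse = ", ")),
            class = "apparency_parse_error")
    }
    df[[col]] <- num
  }
  df$count <- as.integer(df$count)
  validate_surveys(as_tibble(df))
}

#' Validate survey records
#'
#' Checks the invariants of a survey table: non-negative counts and
#' sizes, a closed stratum vocabulary, and coverage at most 1 for
#' non-tree strata (whose `size` is a subplot coverage fraction).
#'
#' @param surveys A data frame of survey records (see [read_surveys()]).
#' @return The input, invisibly unchanged, as a tibble.
#' @export
validate_surveys <- function(surveys) {
  surveys <- as_tibble(surveys)
  ok_strata <- c("tree", "shrub", "herb")
  bad <- which(!surveys$stratum %in% ok_strata)
  if (length(bad) > 0) {
    abort(sprintf("unknown stratum %s at row(s) %s (must be one of %s)",
                  paste(unique(surveys$stratum[bad]), collapse = ", "),
                  paste(head(bad, 5), collapse = ", "),
                  paste(ok_strata, collapse = "/")),
          class = "apparency_validation_error")
  }
  bad <- which(is.na(surveys$count) | surveys$count < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or missing count at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "apparency_validation_error")
  }
  bad <- which(is.na(surveys$size) | surveys$size < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or missing size at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "apparency_validation_error")
  }
  bad <- which(surveys$stratum != "tree" & surveys$size > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "coverage > 1 for non-tree stratum at row(s) %s; coverage is a fraction",
      paste(head(bad, 5), collapse = ", ")),
      class = "apparency_validation_error")
  }
  invisible(surveys)
}

#' Read a community-type area table
#'
#' @param path CSV with columns `community_type` and `area_ratio`.
#'   Area ratios (area of the community type over the total area) must
#'   sum to 1.
#' @param delim Field delimiter.
#' @return A tibble with one row per community type.
#' @export
read_areas <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  missing <- setdiff(c("community_type", "area_ratio"), names(df))
  if (length(missing) > 0) {
    abort(paste0("area file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "apparency_schema_error")
  }
  check_area_ratios(df$area_ratio)
  as_tibble(df)
}

check_area_ratios <- function(ar) {
  if (any(ar < 0 | ar > 1)) {
    abort("area ratios must lie in [0, 1]", class = "apparency_validation_error")
  }
  s <- sum(ar)
  if (abs(s - 1) > 1e-9) {
    abort(sprintf("area ratios must sum to 1 (got %.12g)", s),
          class = "apparency_validation_error")
  }
  invisible(ar)
}

#' Read a plant attribute table
#'
#' @param path CSV with columns `species`, `genus`, `family`,
#'   `life_form`, `water_ecotype`, `phytogeo_type`.
#' @param delim Field delimiter.
#' @return A tibble of taxon attributes.
#' @export
read_attributes <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  required <- c("species", "genus", "family", "life_form", "water_ecotype",
                "phytogeo_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("attribute file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "apparency_schema_error")
  }
  bad <- which(is.na(df$genus) | df$genus == "" |
                 is.na(df$family) | df$family == "")
  if (length(bad) > 0) {
    abort(sprintf("species with empty genus/family at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "apparency_validation_error")
  }
  as_tibble(df)
}

#' Read a binary leaf-mine presence table
#'
#' @param path CSV with columns `taxon` and `mined` (0/1).
#' @param level Taxonomic level the table is stated at
#'   (`"species"`, `"genus"` or `"family"`); stored as an attribute.
#' @param delim Field delimiter.
#' @return A tibble with one row per taxon and a `level` attribute.
#' @export
read_presence <- function(path, level = "species", delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  missing <- setdiff(c("taxon", "mined"), names(df))
  if (length(missing) > 0) {
    abort(paste0("presence file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "apparency_schema_error")
  }
  validate_presence(as_tibble(df), level = level)
}

validate_presence <- function(presence, level = attr(presence, "level") %||% "species") {
  if (!all(presence$mined %in% c(0, 1))) {
    bad <- which(!presence$mined %in% c(0, 1))
    abort(sprintf("presence values must be 0/1; offending row(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "apparency_validation_error")
  }
  if (anyDuplicated(presence$taxon)) {
    abort(sprintf("duplicated taxa in presence table: %s",
                  paste(unique(presence$taxon[duplicated(presence$taxon)]),
                        collapse = ", ")),
          class = "apparency_validation_error")
  }
  attr(presence, "level") <- match.arg(level, c("species", "genus", "family"))
  presence
}

#' Apply an offline synonym map to survey species names
#'
#' Replaces raw species names by their accepted names using a static
#' lookup (an offline stand-in for online name-resolution services).
#' Unmapped names pass through unchanged; every effective replacement is
#' reported via a message.
#'
#' @param surveys A survey tibble (see [read_surveys()]).
#' @param synonym_map Named character vector (`names` = raw name,
#'   values = accepted name), or a two-column data frame
#'   (`raw`, `accepted`). May be empty.
#' @param quiet Suppress the per-name replacement messages.
#' @return The survey tibble with `species` rewritten.
#' @export
resolve_names <- function(surveys, synonym_map, quiet = FALSE) {
  map <- as_synonym_map(synonym_map)
  if (length(map) == 0) return(surveys)
  # a raw name whose accepted name is itself mapped back is a cycle
  cyc <- names(map)[!is.na(map[map]) & map[map] == names(map) & map != names(map)]
  if (length(cyc) > 0) {
    abort(sprintf("cyclic synonym map entries: %s",
                  paste(unique(sort(cyc)), collapse = ", ")),
          class = "apparency_config_error")
  }
  hit <- surveys$species %in% names(map)
  new <- surveys$species
  new[hit] <- unname(map[surveys$species[hit]])
  changed <- unique(surveys$species[hit][new[hit] != surveys$species[hit]])
  if (!quiet && length(changed) > 0) {
    inform(sprintf("resolved %d name(s): %s", length(changed),
                   paste(changed, "->", unname(map[changed]), collapse = "; ")))
  }
  surveys$species <- new
  surveys
}

as_synonym_map <- function(synonym_map) {
  if (is.data.frame(synonym_map)) {
    stopifnot(all(c("raw", "accepted") %in% names(synonym_map)))
    synonym_map <- setNames(as.character(synonym_map$accepted),
                            as.character(synonym_map$raw))
  }
  if (length(synonym_map) > 0 && is.null(names(synonym_map))) {
    abort("synonym map must be named (raw -> accepted)",
          class = "apparency_config_error")
  }
  synonym_map
}

#' Aggregate species-level presence to genus or family level
#'
#' A genus (or family) is scored as a leafminer host iff at least one of
#' its member species bears leaf mines.
#'
#' @param presence Species-level presence tibble (`taxon`, `mined`).
#' @param attrs Taxon attribute tibble mapping species to genus/family.
#' @param level `"genus"` or `"family"`.
#' @return A presence tibble at the requested level.
#' @export
aggregate_presence <- function(presence, attrs, level = c("genus", "family")) {
  level <- match.arg(level)
  validate_presence(presence)
  orphans <- setdiff(presence$taxon, attrs$species)
  if (length(orphans) > 0) {
    abort(sprintf("species absent from the attribute table: %s",
                  paste(sort(orphans), collapse = ", ")),
          class = "apparency_validation_error")
  }
  out <- presence |>
    inner_join(attrs |> select("species", group = dplyr::all_of(level)),
               by = c(taxon = "species")) |>
    group_by(taxon = .data$group) |>
    summarise(mined = as.integer(any(.data$mined == 1)), .groups = "drop") |>
    arrange(.data$taxon)
  attr(out, "level") <- level
  out
}

#' Write a result table to CSV
#'
#' Thin wrapper over [readr::write_csv()] so that write-then-read
#' round-trips reproduce tables field for field.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
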