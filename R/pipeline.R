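#' Build a pipeline run configuration
#'
#' Assembles, with defaults, the configuration consumed by
#' [run_pipeline()]: either paths to survey/area/attribute/presence
#' tables plus a megatree and age file, or `simulate = TRUE` to run on
#' data from the synthetic generator.
#'
#' @param out_dir Output directory for all stage results.
#' @param simulate Generate inputs with the synthetic module.
#' @param sim Optional [sim_config()] (defaults to `sim_config(seed =
#'   seed)`).
#' @param paths Named list of input paths (`surveys`, `areas`,
#'   `attributes`, `presence`, `megatree`, `ages`) when
#'   `simulate = FALSE`.
#' @param levels Taxonomic levels to analyse.
#' @param n_groups Named integer vector of rank-group counts per level.
#' @param models Models to fit per level.
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = TRUE, sim = NULL, paths = list(),
                       levels = c("species", "genus", "family"),
                       n_groups = c(species = 12L, genus = 12L, family = 7L),
                       models = c("glm", "pglmm", "phyloglm"),
                       seed = 1L) {
  levels <- match.arg(levels, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  if (length(levels) == 0) {
    abort("at least one level must be analysed", class = "apparency_config_error")
  }
  if (!simulate) {
    need <- c("surveys", "areas", "attributes", "presence", "megatree", "ages")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0) {
      abort(paste0("paths missing for: ", paste(missing, collapse = ", ")),
            class = "apparency_config_error")
    }
    gone <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(gone) > 0) {
      abort(paste0("input file(s) not found: ", paste(gone, collapse = ", ")),
            class = "apparency_config_error")
    }
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 sim = sim %||% sim_config(seed = seed), paths = paths,
                 levels = levels, n_groups = n_groups, models = models,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments
#'   (`sim` may be a mapping of [sim_config()] fields).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(sim_config, raw$sim) else NULL
  run_config(out_dir = raw$out_dir,
             simulate = raw$simulate %||% TRUE,
             sim = sim,
             paths = raw$paths %||% list(),
             levels = raw$levels %||% c("species", "genus", "family"),
             n_groups = unlist(raw$n_groups %||%
                                 c(species = 12L, genus = 12L, family = 7L)),
             models = raw$models %||% c("glm", "pglmm", "phyloglm"),
             seed = raw$seed %||% 1L)
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "apparency_pipeline_error", stage = stage, parent = e)
  })
}

#' Run the dominance-to-incidence pipeline end to end
#'
#' Executes the five analysis stages — surveys, dominance, ranking,
#' phylogeny, fits — writing versioned CSV/Newick outputs under
#' `cfg$out_dir` plus a JSON manifest with input checksums, a config
#' echo, per-stage row counts and model convergence flags. A stage
#' error aborts with the stage name attached. Identical configuration
#' and inputs give byte-identical outputs.
#'
#' @param cfg A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  for (d in c("inputs", "dominance", "ranking", "phylogeny", "fits")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- list(config = config_echo(cfg), stages = list())

  # -- stage 1: surveys ------------------------------------------------------
  dat <- stage_run("surveys", {
    if (cfg$simulate) {
      phy <- gen_phylogeny(cfg$sim)
      attrs <- gen_taxon_attributes(cfg$sim, phy$taxonomy)
      com <- gen_communities(cfg$sim, attrs)
      validate_surveys(com$surveys)
      list(surveys = com$surveys, areas = com$areas, attrs = attrs,
           tree = phy$tree, presence = NULL)
    } else {
      p <- cfg$paths
      list(surveys = read_surveys(p$surveys),
           areas = read_areas(p$areas),
           attrs = read_attributes(p$attributes),
           tree = NULL,
           presence = read_presence(p$presence))
    }
  })
  write_table(dat$surveys, file.path(out, "inputs", "surveys.csv"))
  write_table(dat$areas, file.path(out, "inputs", "areas.csv"))
  write_table(dat$attrs, file.path(out, "inputs", "attributes.csv"))
  manifest$stages$surveys <- list(rows = nrow(dat$surveys),
                                  species = length(unique(dat$surveys$species)))

  # -- stage 2: dominance ----------------------------------------------------
  dom <- stage_run("dominance", {
    metrics <- relative_metrics(dat$surveys)
    sp <- total_importance(metrics, dat$areas,
                           species_pool = dat$attrs$species) |>
      mutate(tiv_pm = .data$TIV * 1000) # per-mille regression scale
    list(metrics = metrics, species = sp)
  })
  write_table(dom$species, file.path(out, "dominance", "species_dominance.csv"))
  manifest$stages$dominance <- list(rows = nrow(dom$species),
                                    nonzero = sum(dom$species$TIV > 0))

  # presence: simulated only after dominance exists (incidence depends on TIV)
  presence_sp <- stage_run("surveys", {
    if (cfg$simulate) {
      gen_presence(cfg$sim,
                   dom$species |> select("species", tiv = "tiv_pm"),
                   dat$tree)
    } else {
      dat$presence
    }
  })
  write_table(presence_sp, file.path(out, "inputs", "presence.csv"))

  # level-wise dominance and presence tables
  level_dom <- list(species = dom$species |> select(taxon = "species", "TIV"))
  level_pres <- list(species = presence_sp)
  for (lv in c("genus", "family")) {
    if (!lv %in% cfg$levels) next
    part <- dat$attrs |> select("species", group = dplyr::all_of(lv))
    gd <- group_importance(dom$species, part)
    level_dom[[lv]] <- gd |> select(taxon = "group", TIV = "GIV")
    level_pres[[lv]] <- aggregate_presence(presence_sp, dat$attrs, lv)
    write_table(gd, file.path(out, "dominance",
                              paste0("group_dominance_", lv, ".csv")))
  }

  # -- stage 3: ranking ------------------------------------------------------
  ranking <- stage_run("ranking", {
    lapply(setNames(cfg$levels, cfg$levels), function(lv) {
      rg <- rank_and_bin(level_dom[[lv]], cfg$n_groups[[lv]], level = lv)
      hr <- host_ratio_table(rg, level_pres[[lv]], quiet = TRUE)
      write_table(rg, file.path(out, "ranking", paste0("ranked_", lv, ".csv")))
      write_table(hr, file.path(out, "ranking",
                                paste0("host_ratio_", lv, ".csv")))
      hr
    })
  })
  if ("species" %in% cfg$levels) {
    for (attr_name in c("life_form", "water_ecotype", "phytogeo_type")) {
      asum <- attribute_summary(dom$species, dat$attrs, presence_sp, attr_name)
      write_table(asum, file.path(out, "ranking",
                                  paste0("attribute_", attr_name, ".csv")))
    }
  }
  manifest$stages$ranking <- lapply(ranking, nrow)

  # -- stage 4: phylogeny ----------------------------------------------------
  trees <- stage_run("phylogeny", {
    sp_tree <- if (cfg$simulate) {
      dat$tree
    } else {
      mega <- read_newick(cfg$paths$megatree)
      ages <- readr::read_csv(cfg$paths$ages, show_col_types = FALSE)
      taxa <- dat$attrs |> select("family", "genus", "species")
      bladj_date(graft_taxa(mega, taxa), ages)
    }
    out_trees <- list(species = sp_tree)
    for (lv in c("genus", "family")) {
      if (!lv %in% cfg$levels) next
      out_trees[[lv]] <- representative_tree(sp_tree, dat$attrs, lv)
    }
    out_trees
  })
  for (lv in names(trees)) {
    write_newick(trees[[lv]], file.path(out, "phylogeny",
                                        paste0("tree_", lv, ".nwk")))
  }
  manifest$stages$phylogeny <- lapply(trees, function(t) length(t$tip.label))

  # -- stage 5: fits ---------------------------------------------------------
  fits <- stage_run("fits", {
    res <- list()
    for (lv in cfg$levels) {
      dset <- level_dom[[lv]] |>
        mutate(tiv = .data$TIV * 1000) |>
        inner_join(level_pres[[lv]], by = "taxon") |>
        select("taxon", "mined", "tiv")
      tr <- ape::keep.tip(trees[[lv]],
                          intersect(trees[[lv]]$tip.label, dset$taxon))
      dset <- filter(dset, .data$taxon %in% tr$tip.label)
      V <- tip_covariance(tr, standardize = TRUE)
      for (m in cfg$models) {
        fit <- switch(m,
                      glm = fit_glm_binary(dset),
                      pglmm = fit_binary_pglmm(dset, V),
                      phyloglm = fit_phyloglm(dset, tr))
        res[[paste(lv, m, sep = "_")]] <- fit
        write_table(glance(fit) |> mutate(level = lv, .before = 1),
                    file.path(out, "fits", paste0("fit_", lv, "_", m, ".csv")))
      }
    }
    res
  })
  manifest$stages$fits <- lapply(fits, function(f) f$converged)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(files)) |>
    setNames(sub(paste0("^", out, "/?"), "", files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_echo <- function(cfg) {
  list(simulate = cfg$simulate, levels = cfg$levels,
       n_groups = as.list(cfg$n_groups), models = cfg$models,
       seed = cfg$seed, sim = unclass(cfg$sim),
       paths = cfg$paths)
}

# prune the species tree to one (alphabetically first) member per group
# and relabel tips by the group name
representative_tree <- function(sp_tree, attrs, level) {
  reps <- attrs |>
    select("species", group = dplyr::all_of(level)) |>
    filter(.data$species %in% sp_tree$tip.label) |>
    arrange(.data$group, .data$species) |>
    distinct(.data$group, .keep_all = TRUE)
  tr <- ape::keep.tip(sp_tree, reps$species)
  tr$tip.label <- reps$group[match(tr$tip.label, reps$species)]
  tr
}

#' Produce report tables from a completed pipeline run
#'
#' Assembles, under `run_dir/reports`: a model-statistics table with
#' one row per level and a column block per model; the rank-group
#' host-ratio tables and attribute summaries with report rounding
#' (ratios to 3 decimals, RGIV to 2); and fitted incidence-curve data
#' (TIV grid and p per model and level).
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param n_curve Number of grid points per incidence curve.
#' @return Invisibly, a list of the report tibbles.
#' @export
make_reports <- function(run_dir, n_curve = 101) {
  need <- c("dominance/species_dominance.csv", "manifest.json")
  gone <- need[!file.exists(file.path(run_dir, need))]
  if (length(gone) > 0) {
    abort(paste0("incomplete run; missing: ", paste(gone, collapse = ", ")),
          class = "apparency_pipeline_error")
  }
  dir.create(file.path(run_dir, "reports"), showWarnings = FALSE)
  fit_files <- list.files(file.path(run_dir, "fits"), full.names = TRUE)
  if (length(fit_files) == 0) {
    abort("incomplete run; missing stage: fits",
          class = "apparency_pipeline_error")
  }
  fits <- purrr::map_dfr(fit_files, ~ readr::read_csv(.x, show_col_types = FALSE))
  table1 <- fits |>
    select("level", "model", "B", "p_B", "intercept", "p_intercept",
           "signal", "p_signal", "AIC") |>
    tidyr::pivot_wider(names_from = "model",
                       values_from = c("B", "p_B", "intercept", "p_intercept",
                                       "signal", "p_signal", "AIC"))
  write_table(table1, file.path(run_dir, "reports", "model_statistics.csv"))

  rank_files <- list.files(file.path(run_dir, "ranking"),
                           pattern = "^host_ratio_", full.names = TRUE)
  ranks <- lapply(rank_files, function(f) {
    tab <- readr::read_csv(f, show_col_types = FALSE) |> format_report()
    write_table(tab, file.path(run_dir, "reports", basename(f)))
    tab
  })
  attr_files <- list.files(file.path(run_dir, "ranking"),
                           pattern = "^attribute_", full.names = TRUE)
  for (f in attr_files) {
    write_table(readr::read_csv(f, show_col_types = FALSE) |> format_report(),
                file.path(run_dir, "reports", basename(f)))
  }

  dom <- readr::read_csv(file.path(run_dir, "dominance", "species_dominance.csv"),
                         show_col_types = FALSE)
  grid <- seq(0, max(dom$tiv_pm), length.out = n_curve)
  curves <- fits |>
    dplyr::rowwise() |>
    dplyr::reframe(level = .data$level, model = .data$model,
                   incidence_curve(list(intercept = .data$intercept,
                                        B = .data$B) |>
                                     structure(class = "mine_fit"),
                                   grid))
  write_table(curves, file.path(run_dir, "reports", "incidence_curves.csv"))
  invisible(list(model_statistics = table1, host_ratios = ranks,
                 curves = curves))
}
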