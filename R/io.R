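# Readers, writers, validation and the end-to-end pipeline runner.
#
# All tabular artifacts are plain CSV; statistical results are JSON. Every
# written artifact carries the run seed and a config hash so that reruns can
# be verified bit-identical.

.record_columns <- c("taxon_id", "group", "rank", "species_count", "stage",
                     "category", "weight", "predominance",
                     "exclusively_nectivorous", "aquatic_flag", "fish_pct")

#' Validate a taxon diet record data frame
#'
#' Checks the record table against the input contract: required columns,
#' known group and stage labels, positive species counts, categories valid
#' for each row's group, and habitat flags present. Row-level problems are
#' collected and reported together with row numbers.
#'
#' @param records Data frame in the record dialect (see
#'   [read_taxon_records()]).
#' @return The validated (type-normalized) data frame, invisibly usable
#'   downstream.
#' @export
validate_taxon_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("taxon records must be a non-empty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(.record_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("taxon records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records$taxon_id <- as.character(records$taxon_id)
  records$group <- as.character(records$group)
  records$stage <- as.character(records$stage)
  records$category <- as.character(records$category)
  records$predominance <- as.character(records$predominance)
  records$predominance[records$predominance %in% c("", "none")] <- NA
  records$exclusively_nectivorous <-
    .as_flag(records$exclusively_nectivorous)
  records$aquatic_flag <- .as_flag(records$aquatic_flag)
  errs <- character(0)
  add <- function(rows, msg) {
    errs <<- c(errs, paste0("row(s) ", paste(rows, collapse = ","), ": ", msg))
  }
  bad <- which(!records$group %in% taxon_groups())
  if (length(bad)) add(bad, paste0("unknown group; valid groups: ",
                                   paste(taxon_groups(), collapse = ", ")))
  bad <- which(!records$stage %in% c("single", "larva", "adult"))
  if (length(bad)) add(bad, "stage must be single, larva or adult")
  bad <- which(is.na(records$species_count) | records$species_count <= 0)
  if (length(bad)) add(bad, "species_count must be > 0")
  bad <- which(is.na(records$aquatic_flag))
  if (length(bad)) add(bad, "aquatic_flag is required (TRUE/FALSE)")
  ok_group <- records$group %in% taxon_groups()
  bad <- which(ok_group & !mapply(function(ct, g) {
    ct %in% names(.category_rules[[g]])
  }, records$category, records$group))
  if (length(bad)) {
    for (r in bad) {
      add(r, paste0("unknown category '", records$category[r],
                    "' for group '", records$group[r], "'; valid: ",
                    paste(diet_categories(records$group[r]), collapse = ", ")))
    }
  }
  bad <- which(!is.na(records$predominance) &
                 records$predominance != "most")
  if (length(bad)) add(bad, "predominance must be empty or 'most'")
  if (length(errs) > 0) {
    stop("invalid taxon records:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  records
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[tolower(as.character(x)) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(as.character(x)) %in% c("false", "f", "0", "no", "")] <- FALSE
  out[is.na(x)] <- FALSE
  out
}

#' Read taxon diet records from CSV
#'
#' One row per (taxon, stage, diet component); columns `taxon_id`, `group`,
#' `rank`, `species_count`, `stage`, `category`, `weight`, `predominance`,
#' `exclusively_nectivorous`, `aquatic_flag`, `fish_pct`. UTF-8 with header.
#' A stage's rows either all carry weights (a within-species diet
#' composition, summing to 100 or 1) or none (an across-species assignment).
#'
#' @param path CSV file path.
#' @return Validated record data frame.
#' @export
read_taxon_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0) {
    stop("record file '", path, "' contains no rows", call. = FALSE)
  }
  validate_taxon_records(df)
}

#' Read an uncertainty configuration from YAML
#'
#' Any field of [uncertainty_config()] may be overridden; unspecified fields
#' keep their defaults. A `seed` entry is required so that runs driven by a
#' config file are reproducible.
#'
#' @param path YAML file path.
#' @return An `"uncertainty_config"`.
#' @export
read_uncertainty_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(uncertainty_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(vals$seed)) {
    stop("config file must set a seed for reproducible runs", call. = FALSE)
  }
  do.call(uncertainty_config, vals)
}

#' Read a species-by-pixel presence table
#'
#' Accepts either a long-format CSV (`species_id`, `pixel_id`) or a wide 0/1
#' matrix CSV whose first column is `species_id` and remaining columns are
#' pixel ids.
#'
#' @param path CSV file path.
#' @return Long-format data frame (`species_id`, `pixel_id`).
#' @export
read_presence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("species_id", "pixel_id") %in% names(df))) {
    return(df[c("species_id", "pixel_id")])
  }
  if (names(df)[1] != "species_id") {
    stop("presence table must be long (species_id, pixel_id) or wide with ",
         "a leading species_id column", call. = FALSE)
  }
  mat <- as.matrix(df[-1])
  hits <- which(mat != 0, arr.ind = TRUE)
  data.frame(species_id = df$species_id[hits[, 1]],
             pixel_id = colnames(mat)[hits[, 2]],
             stringsAsFactors = FALSE)
}

.hash_config <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", .string_hash(as.character(s)))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates filter -> classify -> pyramid -> grid -> stats and writes
#' every artifact to `out_dir`: replicate-level and summary pyramid CSVs
#' (pooled and per group), per-pixel composition and aggregated-diet CSVs,
#' per-structure averages, and a `stats.json` with the discriminant and
#' ANOVA results. All outputs embed the seed and a config hash; rerunning
#' with the same inputs and config is bit-identical.
#'
#' @param records Taxon diet record data frame (or path to its CSV).
#' @param grid Optional list with `presence`, `pixels`, `diet` (data frames
#'   or CSV paths) as produced by [generate_grid()]; `NULL` disables the
#'   grid and stats stages.
#' @param cfg An [uncertainty_config()] with a non-`NULL` seed.
#' @param out_dir Output directory, created if needed.
#' @param run_pyramid Toggle the Monte Carlo pyramid stage.
#' @param validation,baseline_mode Passed to [discriminate_structures()].
#' @return Invisibly, a list of the in-memory results and artifact paths.
#' @export
run_pipeline <- function(records, grid = NULL, cfg = uncertainty_config(seed = 1),
                         out_dir = "trophicstrat-run", run_pyramid = TRUE,
                         validation = "resubstitution",
                         baseline_mode = "proportional") {
  if (is.null(cfg$seed)) {
    stop("run_pipeline requires a seeded config", call. = FALSE)
  }
  if (is.character(records)) records <- read_taxon_records(records)
  records <- validate_taxon_records(records)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(seed = cfg$seed, config_hash = .hash_config(unclass(cfg)))
  artifacts <- list()
  results <- list(config = cfg, stamp = stamp)

  # stage 1: exclusion filter + deterministic classification
  keep <- tryCatch(filter_species(records, cfg), error = function(e) {
    stop("[filter] ", conditionMessage(e), call. = FALSE)
  })
  retained <- records[records$taxon_id %in% names(keep)[keep], , drop = FALSE]
  if (nrow(retained) == 0) stop("[filter] no taxa retained", call. = FALSE)
  profiles <- tryCatch(
    species_primary_fraction(retained, cfg),
    error = function(e) stop("[classify] ", conditionMessage(e), call. = FALSE))
  results$profiles <- profiles
  artifacts$profiles <- .write_csv(
    cbind(profiles, seed = stamp$seed, config_hash = stamp$config_hash),
    file.path(out_dir, "species_profiles.csv"))

  # stage 2: Monte Carlo pyramids, pooled and per group
  if (run_pyramid) {
    pooled <- tryCatch(build_pyramid(retained, cfg), error = function(e) {
      stop("[pyramid] ", conditionMessage(e), call. = FALSE)
    })
    by_group <- pyramid_by_group(retained, cfg)
    results$pyramid <- pooled
    results$pyramid_by_group <- by_group
    reps <- do.call(rbind, lapply(c(list(pooled), by_group), function(py) {
      data.frame(group = py$group,
                 replicate = rep(seq_len(py$n_replicates), 3),
                 level = rep(.levels, each = py$n_replicates),
                 percent = as.numeric(py$replicates))
    }))
    artifacts$pyramid_replicates <- .write_csv(
      reps, file.path(out_dir, "pyramid_replicates.csv"))
    summaries <- do.call(rbind, lapply(c(list(pooled), by_group),
                                       summarize_pyramid))
    artifacts$pyramid_summary <- .write_csv(
      cbind(summaries, seed = stamp$seed, config_hash = stamp$config_hash),
      file.path(out_dir, "pyramid_summary.csv"))
    results$pyramid_summary <- summaries
  }

  # stage 3 + 4: gridded communities and structure statistics
  if (!is.null(grid)) {
    presence <- if (is.character(grid$presence)) read_presence(grid$presence)
      else grid$presence
    pixels <- if (is.character(grid$pixels))
      utils::read.csv(grid$pixels, stringsAsFactors = FALSE) else grid$pixels
    grid_profiles <- grid$profiles
    if (is.null(grid_profiles)) {
      # fall back to the classification stage's own units
      grid_profiles <- stats::setNames(profiles[c("unit_id", "p")],
                                       c("species_id", "p"))
    }
    comp <- tryCatch(
      assemble_pixels(presence, profiles = grid_profiles, pixels = pixels),
      error = function(e) stop("[grid] ", conditionMessage(e), call. = FALSE))
    results$compositions <- comp
    artifacts$pixel_composition <- .write_csv(
      comp, file.path(out_dir, "pixel_composition.csv"))
    artifacts$structure_averages <- .write_csv(
      per_structure_averages(comp),
      file.path(out_dir, "structure_averages.csv"))
    disc <- tryCatch(
      discriminate_structures(comp, validation = validation,
                              baseline_mode = baseline_mode),
      error = function(e) stop("[stats] ", conditionMessage(e), call. = FALSE))
    results$discrimination <- disc
    stats_out <- list(
      seed = stamp$seed, config_hash = stamp$config_hash,
      discriminant = list(
        accuracy = disc$accuracy, chance_baseline = disc$chance_baseline,
        improvement = disc$improvement, validation = disc$validation,
        baseline_mode = disc$baseline_mode,
        confusion = as.data.frame.matrix(unclass(disc$confusion))),
      pooled_levels = pooled_level_summary(comp))
    if (!is.null(grid$diet)) {
      diet <- if (is.character(grid$diet))
        utils::read.csv(grid$diet, stringsAsFactors = FALSE,
                        check.names = FALSE) else grid$diet
      agg <- tryCatch(aggregate_community_diet(presence, diet),
                      error = function(e) stop("[stats] ",
                                               conditionMessage(e),
                                               call. = FALSE))
      results$aggregated_diet <- agg
      artifacts$aggregated_diet <- .write_csv(
        agg, file.path(out_dir, "aggregated_diet.csv"))
      av <- anova_r2(
        agg$primary_consumption_pct[match(comp$pixel_id, agg$pixel_id)],
        comp$structure_class)
      results$anova <- av
      stats_out$anova <- list(
        r_squared = av$r_squared, f_statistic = av$f_statistic,
        df = as.list(av$df), p_value = av$p_value,
        ss_between = av$ss_between, ss_within = av$ss_within,
        ss_total = av$ss_total,
        group_means = as.list(av$group_means))
    }
    artifacts$stats <- file.path(out_dir, "stats.json")
    jsonlite::write_json(stats_out, artifacts$stats, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  results$artifacts <- artifacts
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
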