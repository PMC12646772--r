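# Monte Carlo trophic pyramids of species richness.
#
# Each replicate redraws every uncertain rule quantity (predominance shares,
# interval-category fractions, adult stage weights), reclassifies all
# species-equivalent units, and records the percentage of species at each
# trophic level. Replicates are driven by per-replicate child seeds combined
# with a per-taxon hash, so pooled and per-group runs of the same records
# produce identical draws for every taxon.

.levels <- c("primary", "mixed", "higher")

#' Classify a primary-consumption fraction into a trophic level
#'
#' A species is a primary consumer when more than 2/3 of its diet is primary
#' consumption, a higher-level consumer when less than 1/3 is, and a mixed
#' consumer on the closed band in between (ties at exactly 1/3 or 2/3 are
#' mixed).
#'
#' @param p Numeric vector of primary fractions in \[0, 1\].
#' @param band Length-2 mixed band, default `c(1/3, 2/3)`.
#' @return Factor with levels `primary`, `mixed`, `higher`.
#' @export
#' @examples
#' classify_level(c(1, 0.5, 2/3, 0.2))
classify_level <- function(p, band = c(1 / 3, 2 / 3)) {
  if (any(!is.finite(p)) || any(p < -1e-9 | p > 1 + 1e-9)) {
    stop("primary fractions must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(p > band[2], "primary", ifelse(p < band[1], "higher", "mixed"))
  factor(out, levels = .levels)
}

# replicate-level percentages from a profile table
.level_percentages <- function(weight, level) {
  tot <- sum(weight)
  pct <- vapply(.levels, function(l) sum(weight[level == l]), numeric(1))
  100 * pct / tot
}

# Child seeds for the replicate substreams, derived once from the master seed.
.replicate_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483629L, n)
}

#' Build a Monte Carlo trophic pyramid
#'
#' Resolves and classifies every taxon afresh in each replicate and records
#' the percentage of species-equivalents at each trophic level. Records
#' should already have passed [filter_species()]; see [run_pipeline()] for
#' the orchestrated path.
#'
#' @param records Taxon diet record data frame (validated, filtered).
#' @param cfg An [uncertainty_config()]; `cfg$seed` drives all draws and
#'   `cfg$n_replicates` sets the replicate count.
#' @param group Label attached to the pyramid (default `"all"`).
#' @return An object of class `"trophic_pyramid"`: a list with `replicates`
#'   (n_replicates x 3 matrix of level percentages), `group`,
#'   `n_replicates`, `seed` and `cfg`.
#' @export
#' @examples
#' rec <- data.frame(taxon_id = "t1", group = "arthropod", rank = "family",
#'                   species_count = 10, stage = "single",
#'                   category = "phytophagy", weight = NA, predominance = NA,
#'                   exclusively_nectivorous = FALSE, aquatic_flag = FALSE,
#'                   fish_pct = NA)
#' pyr <- build_pyramid(rec, uncertainty_config(seed = 1, n_replicates = 10))
#' summarize_pyramid(pyr)
build_pyramid <- function(records, cfg = uncertainty_config(),
                          group = "all") {
  compiled <- .compile_records(records, cfg)
  if (length(compiled) == 0) {
    stop("no taxon records to build a pyramid from", call. = FALSE)
  }
  n <- cfg$n_replicates
  child <- .replicate_seeds(cfg$seed, n)
  reps <- matrix(NA_real_, nrow = n, ncol = 3,
                 dimnames = list(NULL, .levels))
  for (r in seq_len(n)) {
    weight <- numeric(0)
    p <- numeric(0)
    for (ct in compiled) {
      set.seed(as.integer((as.numeric(child[r]) + ct$hash) %% 2147483629))
      blocks <- .resolve_taxon(ct, cfg, .taxon_draws(ct, cfg, "random"))
      weight <- c(weight, blocks$weight)
      p <- c(p, blocks$p)
    }
    level <- classify_level(pmin(pmax(p, 0), 1), cfg$mixed_band)
    reps[r, ] <- .level_percentages(weight, level)
  }
  structure(
    list(replicates = reps, group = group, n_replicates = n,
         seed = cfg$seed, cfg = cfg),
    class = "trophic_pyramid"
  )
}

#' Summarize a trophic pyramid
#'
#' Per-level mean percentage across replicates with a 95% confidence
#' interval: the 2.5--97.5 percentile interval of replicate values by
#' default, or a normal approximation (mean +/- 1.96 sd) when the pyramid
#' was built with `ci_method = "normal"`.
#'
#' @param pyramid A `"trophic_pyramid"`.
#' @param ci_method Override the pyramid's CI method.
#' @return Data frame with columns `group`, `level`, `mean`, `ci_lo`,
#'   `ci_hi`, `half_width` and `n_replicates`. With a single replicate the
#'   CI columns are `NA` and `half_width` is `NA`.
#' @export
summarize_pyramid <- function(pyramid, ci_method = pyramid$cfg$ci_method) {
  stopifnot(inherits(pyramid, "trophic_pyramid"))
  reps <- pyramid$replicates
  m <- colMeans(reps)
  if (nrow(reps) < 2) {
    lo <- hi <- rep(NA_real_, 3)
  } else if (ci_method == "percentile") {
    qs <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    lo <- qs[1, ]
    hi <- qs[2, ]
  } else {
    s <- apply(reps, 2, stats::sd)
    lo <- m - 1.96 * s
    hi <- m + 1.96 * s
  }
  data.frame(
    group = pyramid$group,
    level = factor(.levels, levels = .levels),
    mean = as.numeric(m),
    ci_lo = as.numeric(lo),
    ci_hi = as.numeric(hi),
    half_width = as.numeric(hi - lo) / 2,
    n_replicates = nrow(reps),
    row.names = NULL
  )
}

#' @export
print.trophic_pyramid <- function(x, ...) {
  cat("Trophic pyramid (", x$group, "): ", x$n_replicates,
      " replicates\n", sep = "")
  print(summarize_pyramid(x), digits = 4)
  invisible(x)
}

#' Per-species trophic-level frequencies across Monte Carlo replicates
#'
#' Runs the same replicate scheme as [build_pyramid()] but tracks, for each
#' species-equivalent unit, how often it classifies to each trophic level.
#' The majority level across replicates is the recommended fixed
#' classification for downstream grid analyses; the frequency columns allow
#' propagating classification uncertainty instead (see
#' [assemble_pixels()]'s `propagate` argument).
#'
#' @param records Taxon diet record data frame (validated, filtered).
#' @param cfg An [uncertainty_config()].
#' @return Data frame with `species_id` (the unit id), `taxon_id`, `group`,
#'   `f_primary`, `f_mixed`, `f_higher` (replicate frequencies summing to
#'   1) and `level` (majority level, ties broken toward mixed).
#' @export
species_level_frequencies <- function(records, cfg = uncertainty_config()) {
  compiled <- .compile_records(records, cfg)
  if (length(compiled) == 0) stop("no taxon records", call. = FALSE)
  n <- cfg$n_replicates
  child <- .replicate_seeds(cfg$seed, n)
  counts <- NULL
  ids <- NULL
  for (r in seq_len(n)) {
    p <- numeric(0)
    if (r == 1) meta <- list()
    for (ct in compiled) {
      set.seed(as.integer((as.numeric(child[r]) + ct$hash) %% 2147483629))
      blocks <- .resolve_taxon(ct, cfg, .taxon_draws(ct, cfg, "random"))
      p <- c(p, blocks$p)
      if (r == 1) meta[[length(meta) + 1]] <- blocks[c("unit_id", "taxon_id",
                                                       "group")]
    }
    lv <- as.integer(classify_level(pmin(pmax(p, 0), 1), cfg$mixed_band))
    if (is.null(counts)) counts <- matrix(0, length(p), 3)
    counts[cbind(seq_along(lv), lv)] <- counts[cbind(seq_along(lv), lv)] + 1
  }
  meta <- do.call(rbind, meta)
  freq <- counts / n
  # majority with ties toward mixed (the uncertain middle)
  maj <- apply(freq[, c(2, 1, 3), drop = FALSE], 1, which.max)
  level <- factor(c("mixed", "primary", "higher")[maj], levels = .levels)
  data.frame(species_id = meta$unit_id, taxon_id = meta$taxon_id,
             group = meta$group, f_primary = freq[, 1], f_mixed = freq[, 2],
             f_higher = freq[, 3], level = level, stringsAsFactors = FALSE)
}

#' Plot a trophic pyramid
#'
#' Horizontal bar chart of mean level percentages with 95% CI whiskers,
#' stacked primary (bottom) to higher-level (top) in the conventional
#' pyramid orientation.
#'
#' @param x A `"trophic_pyramid"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.trophic_pyramid <- function(x, ...) {
  s <- summarize_pyramid(x)
  s <- s[rev(seq_len(nrow(s))), ]     # primary at the bottom
  mid <- graphics::barplot(s$mean, names.arg = as.character(s$level),
                           horiz = TRUE, xlab = "% of species",
                           main = paste("Trophic pyramid:", x$group),
                           xlim = c(0, max(s$ci_hi, s$mean, na.rm = TRUE) * 1.1),
                           ...)
  ok <- !is.na(s$ci_lo) & s$half_width > 0
  if (any(ok)) {
    graphics::arrows(s$ci_lo[ok], mid[ok], s$ci_hi[ok], mid[ok],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(x)
}

#' Build one pyramid per taxon group
#'
#' Partitions records by a grouping column and builds a pyramid per
#' partition. All partitions share the master seed's replicate substreams
#' and per-taxon draw streams, so each group's pyramid is identical to what
#' the same taxa produce inside a pooled run: replicate by replicate, the
#' weighted average of the group pyramids equals the pooled pyramid.
#'
#' @param records Taxon diet record data frame.
#' @param cfg An [uncertainty_config()].
#' @param grouping Column of `records` to partition by (default `"group"`).
#' @return Named list of `"trophic_pyramid"` objects.
#' @export
pyramid_by_group <- function(records, cfg = uncertainty_config(),
                             grouping = "group") {
  records <- validate_taxon_records(records)
  if (!grouping %in% names(records)) {
    stop("unknown grouping column '", grouping, "'", call. = FALSE)
  }
  labels <- unique(records[[grouping]])
  out <- lapply(labels, function(g) {
    build_pyramid(records[records[[grouping]] == g, , drop = FALSE],
                  cfg, group = g)
  })
  stats::setNames(out, labels)
}
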