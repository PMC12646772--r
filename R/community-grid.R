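# Per-pixel community composition on a one-degree grid.
#
# Communities are species sets present in one-degree grid cells, each cell
# carrying one of six community trophic structure labels ("trophic biomes").
# For every cell we compute the proportion of primary, mixed and higher-level
# consumer species and, for birds and mammals, an aggregated community diet.

#' Community trophic structure labels
#' @return Character vector of the six structure class labels, ordered from
#'   least to most productive.
#' @export
structure_classes <- function() {
  c("depauperate", "boreal", "temperate", "semi-arid",
    "seasonal tropical", "humid tropical")
}

#' Variance-stabilizing arcsine square-root transform
#'
#' Maps a proportion x in \[0, 1\] to `asin(sqrt(x))` in \[0, pi/2\]
#' (radians). Values outside \[0, 1\] by at most 1e-12 are clamped; larger
#' excursions are an error.
#'
#' @param x Numeric vector of proportions.
#' @return Transformed values in \[0, pi/2\].
#' @export
#' @examples
#' arcsine_sqrt(c(0, 0.25, 1))   # 0, pi/6, pi/2
arcsine_sqrt <- function(x) {
  if (any(!is.finite(x)) || any(x < -1e-12 | x > 1 + 1e-12)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(pmin(pmax(x, 0), 1)))
}

.check_presence <- function(presence) {
  need <- c("species_id", "pixel_id")
  if (!all(need %in% names(presence))) {
    stop("presence table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  presence$species_id <- as.character(presence$species_id)
  presence$pixel_id <- as.character(presence$pixel_id)
  unique(presence[need])
}

#' Assemble per-pixel trophic-level compositions
#'
#' Joins a species-by-pixel presence table with per-species trophic levels
#' and per-pixel structure labels, and computes the proportion of primary,
#' mixed and higher-level species in every cell, together with their
#' arcsine-square-root transforms. Pixels with no species are dropped (their
#' count is reported in a message).
#'
#' @param presence Long-format data frame with columns `species_id`,
#'   `pixel_id`.
#' @param profiles Data frame with `species_id` and either a `level` column
#'   (`primary`/`mixed`/`higher`) or a primary fraction `p` from which levels
#'   are derived via [classify_level()].
#' @param pixels Data frame with `pixel_id`, `structure_class` and optionally
#'   `lat`, `lon`.
#' @param propagate If `TRUE` and `profiles` carries replicate level
#'   frequencies (`f_primary`, `f_mixed`, `f_higher`, from
#'   [species_level_frequencies()]), pixel proportions are the mean of the
#'   species' level probabilities instead of hard counts, propagating
#'   classification uncertainty into the composition.
#' @return Data frame, one row per non-empty pixel: `pixel_id`,
#'   `structure_class`, `lat`/`lon` if supplied, `richness`, proportions
#'   `p_primary`, `p_mixed`, `p_higher`, and transforms `t_primary`,
#'   `t_mixed`, `t_higher`.
#' @export
assemble_pixels <- function(presence, profiles, pixels, propagate = FALSE) {
  if (propagate) {
    fcols <- c("f_primary", "f_mixed", "f_higher")
    if (!all(fcols %in% names(profiles))) {
      stop("propagate = TRUE needs level-frequency columns ",
           paste(fcols, collapse = ", "),
           " (see species_level_frequencies)", call. = FALSE)
    }
  }
  presence <- .check_presence(presence)
  profiles$species_id <- as.character(profiles$species_id)
  if (!"level" %in% names(profiles)) {
    if (!"p" %in% names(profiles)) {
      stop("profiles need a 'level' or 'p' column", call. = FALSE)
    }
    profiles$level <- classify_level(profiles$p)
  }
  missing_sp <- setdiff(presence$species_id, profiles$species_id)
  if (length(missing_sp) > 0) {
    stop("species without a trophic profile: ",
         paste(utils::head(missing_sp, 10), collapse = ", "),
         if (length(missing_sp) > 10) sprintf(" (and %d more)",
                                              length(missing_sp) - 10),
         call. = FALSE)
  }
  pixels$pixel_id <- as.character(pixels$pixel_id)
  unlabeled <- setdiff(presence$pixel_id, pixels$pixel_id)
  if (length(unlabeled) > 0) {
    stop("pixels without a structure label: ",
         paste(utils::head(unlabeled, 10), collapse = ", "), call. = FALSE)
  }
  idx <- match(presence$species_id, profiles$species_id)
  if (propagate) {
    fmat <- as.matrix(profiles[idx, c("f_primary", "f_mixed", "f_higher")])
    tab <- rowsum(fmat, group = presence$pixel_id)
    colnames(tab) <- .levels
  } else {
    lev <- profiles$level[idx]
    tab <- table(pixel_id = presence$pixel_id,
                 level = factor(lev, levels = .levels))
  }
  n_empty <- sum(!pixels$pixel_id %in% rownames(tab))
  if (n_empty > 0) {
    message(n_empty, " pixel(s) with no species dropped")
  }
  richness <- tapply(rep(1L, nrow(presence)), presence$pixel_id, sum)
  richness <- richness[rownames(tab)]
  props <- tab / rowSums(tab)
  out <- data.frame(
    pixel_id = rownames(tab),
    richness = as.integer(richness),
    p_primary = as.numeric(props[, "primary"]),
    p_mixed = as.numeric(props[, "mixed"]),
    p_higher = as.numeric(props[, "higher"]),
    stringsAsFactors = FALSE
  )
  meta_cols <- intersect(c("structure_class", "lat", "lon"), names(pixels))
  out <- cbind(out,
               pixels[match(out$pixel_id, pixels$pixel_id), meta_cols,
                      drop = FALSE])
  out$t_primary <- arcsine_sqrt(out$p_primary)
  out$t_mixed <- arcsine_sqrt(out$p_mixed)
  out$t_higher <- arcsine_sqrt(out$p_higher)
  rownames(out) <- NULL
  out[order(out$pixel_id), ]
}

#' Aggregate species diet items into a per-pixel community diet
#'
#' Sums the diet-item percentages (plants, seeds, fruit, nectar,
#' invertebrates, vertebrate endotherms, vertebrate ectotherms, fish,
#' carrion, unknown vertebrates) of every species present in a pixel, and
#' splits the aggregated diet into primary (plant-based) versus higher-level
#' (animal-based) consumption. Fish and unknown vertebrates count as
#' animal-based.
#'
#' @param presence Long-format presence data frame (`species_id`,
#'   `pixel_id`).
#' @param diet Data frame with `species_id` and the ten diet-item columns of
#'   [diet_item_names()], each species' items summing to 100 (or 1).
#' @return Data frame, one row per pixel: the summed item percentages and
#'   `primary_consumption_pct` in \[0, 100\].
#' @export
aggregate_community_diet <- function(presence, diet) {
  presence <- .check_presence(presence)
  items <- diet_item_names()
  if (!all(items %in% names(diet))) {
    stop("diet table missing item columns: ",
         paste(setdiff(items, names(diet)), collapse = ", "), call. = FALSE)
  }
  diet$species_id <- as.character(diet$species_id)
  mat <- as.matrix(diet[items])
  sums <- rowSums(mat)
  scale01 <- abs(sums - 1) < 1e-6
  mat[scale01, ] <- mat[scale01, , drop = FALSE] * 100
  sums[scale01] <- sums[scale01] * 100
  bad <- abs(sums - 100) > 1e-6 * 100
  if (any(bad)) {
    stop("diet items do not sum to 100 for species: ",
         paste(utils::head(diet$species_id[bad], 10), collapse = ", "),
         call. = FALSE)
  }
  missing_sp <- setdiff(presence$species_id, diet$species_id)
  if (length(missing_sp) > 0) {
    stop("species without diet items: ",
         paste(utils::head(missing_sp, 10), collapse = ", "), call. = FALSE)
  }
  idx <- match(presence$species_id, diet$species_id)
  agg <- rowsum(mat[idx, , drop = FALSE], group = presence$pixel_id)
  total <- rowSums(agg)
  plant <- rowSums(agg[, .plant_items, drop = FALSE])
  out <- data.frame(pixel_id = rownames(agg), agg,
                    primary_consumption_pct = 100 * plant / total,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$pixel_id), ]
}

#' Per-structure averages of trophic-level proportions
#'
#' Class-wise mean of each trophic-level proportion together with boxplot
#' statistics (quartiles and Tukey whiskers) across the pixels of each
#' community trophic structure. Empty classes are omitted with a warning.
#'
#' @param compositions Output of [assemble_pixels()].
#' @param classes Optional subset/order of structure classes to report.
#' @return Tidy data frame: `structure_class`, `level`, `n_pixels`, `mean`,
#'   `q1`, `median`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
per_structure_averages <- function(compositions,
                                   classes = unique(compositions$structure_class)) {
  empty <- setdiff(classes, compositions$structure_class)
  if (length(empty) > 0) {
    warning("structure class(es) with no pixels omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
    classes <- setdiff(classes, empty)
  }
  rows <- lapply(classes, function(cl) {
    sub <- compositions[compositions$structure_class == cl, , drop = FALSE]
    do.call(rbind, lapply(.levels, function(l) {
      x <- sub[[paste0("p_", l)]]
      bs <- grDevices::boxplot.stats(x)$stats
      data.frame(structure_class = cl, level = l, n_pixels = nrow(sub),
                 mean = mean(x), q1 = bs[2], median = bs[3], q3 = bs[4],
                 whisker_lo = bs[1], whisker_hi = bs[5],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = .levels)
  rownames(out) <- NULL
  out
}
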