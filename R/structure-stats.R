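# Tests of trophic-structure uniformity across community classes:
# linear discriminant analysis of transformed level proportions, chance
# baselines, one-way ANOVA variance decomposition, and pooled summaries.

#' Chance baseline for classification accuracy
#'
#' @param labels Vector of class labels.
#' @param mode `"proportional"` (default): the proportional chance criterion
#'   `sum(p_k^2)`, the expected accuracy of prior-proportional random
#'   assignment, appropriate for unbalanced classes; `"uniform"`: `1/K`;
#'   `"majority"`: `max(p_k)`.
#' @return Baseline accuracy in \[0, 1\].
#' @export
#' @examples
#' chance_baseline(rep(letters[1:6], each = 10))        # 1/6
chance_baseline <- function(labels,
                            mode = c("proportional", "uniform", "majority")) {
  mode <- match.arg(mode)
  if (length(labels) == 0) stop("labels must be non-empty", call. = FALSE)
  p <- as.numeric(table(labels)) / length(labels)
  switch(mode,
         proportional = sum(p^2),
         uniform = 1 / length(p),
         majority = max(p))
}

#' Discriminant analysis of community trophic compositions
#'
#' Fits a linear discriminant analysis predicting each pixel's community
#' trophic structure from its arcsine-square-root transformed trophic-level
#' proportions, and reports classification accuracy as an improvement over a
#' chance baseline. Because the three raw proportions sum to one, only the
#' transformed primary and mixed proportions enter by default (full-rank
#' predictors); `keep_all = TRUE` retains all three.
#'
#' @param compositions Output of [assemble_pixels()] (needs `t_primary`,
#'   `t_mixed`, `t_higher` and `structure_class`).
#' @param validation `"resubstitution"` (accuracy on the training pixels,
#'   default) or `"loo"` (leave-one-out cross-validation).
#' @param baseline_mode Passed to [chance_baseline()].
#' @param keep_all Keep all three transformed proportions as predictors.
#' @return An object of class `"structure_discrimination"`: list with
#'   `confusion` (K x K matrix, rows = true class), `accuracy`,
#'   `chance_baseline`, `improvement` (accuracy minus baseline),
#'   `validation`, `baseline_mode`, `n_pixels` and the fitted `lda` object
#'   (resubstitution only).
#' @export
discriminate_structures <- function(compositions,
                                    validation = c("resubstitution", "loo"),
                                    baseline_mode = "proportional",
                                    keep_all = FALSE) {
  validation <- match.arg(validation)
  labels <- factor(compositions$structure_class)
  if (nlevels(labels) < 2) {
    stop("need at least two structure classes", call. = FALSE)
  }
  if (any(table(labels) < 2)) {
    stop("every structure class needs at least two pixels", call. = FALSE)
  }
  predictors <- if (keep_all) c("t_primary", "t_mixed", "t_higher") else
    c("t_primary", "t_mixed")
  x <- as.matrix(compositions[predictors])
  # Degenerate predictors (no within-class variation) defeat LDA; fall back
  # to the majority-class constant classifier rather than erroring.
  degenerate <- all(apply(x, 2, function(col) {
    all(abs(col - col[1]) < 1e-12)
  }))
  if (degenerate) {
    pred <- factor(rep(names(which.max(table(labels))), length(labels)),
                   levels = levels(labels))
    fit <- NULL
  } else {
    fit <- tryCatch(
      MASS::lda(x, grouping = labels, CV = (validation == "loo")),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      if (grepl("constant within groups", conditionMessage(fit))) {
        # zero within-class covariance (perfectly concentrated classes):
        # classify by nearest class centroid, the limiting LDA rule
        centroids <- apply(x, 2, tapply, labels, mean)
        d2 <- outer(rowSums(x^2), rowSums(centroids^2), `+`) -
          2 * x %*% t(centroids)
        pred <- factor(levels(labels)[apply(d2, 1, which.min)],
                       levels = levels(labels))
        fit <- NULL
      } else {
        stop("discriminant fit failed (", conditionMessage(fit),
             "); predictors may be collinear or constant within classes -- ",
             "try keep_all = FALSE or fewer predictors", call. = FALSE)
      }
    } else {
      pred <- if (validation == "loo") fit$class else
        stats::predict(fit, x)$class
    }
  }
  confusion <- table(truth = labels, predicted = pred)
  accuracy <- mean(pred == labels)
  base <- chance_baseline(labels, baseline_mode)
  structure(
    list(confusion = confusion,
         accuracy = accuracy,
         chance_baseline = base,
         improvement = accuracy - base,
         validation = validation,
         baseline_mode = baseline_mode,
         n_pixels = length(labels),
         predictors = predictors,
         fit = if (validation == "resubstitution") fit else NULL),
    class = "structure_discrimination"
  )
}

#' @export
print.structure_discrimination <- function(x, ...) {
  cat("Discriminant analysis of trophic composition (", x$validation,
      ")\n", sep = "")
  cat(sprintf("  accuracy: %.4f  chance (%s): %.4f  improvement: %.4f\n",
              x$accuracy, x$baseline_mode, x$chance_baseline, x$improvement))
  cat("  pixels:", x$n_pixels, " predictors:",
      paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' One-way ANOVA with variance explained
#'
#' Standard one-way decomposition of a per-pixel response (typically the
#' percentage of primary consumption in the aggregated community diet)
#' across structure classes, reporting `R^2 = SS_between / SS_total` as the
#' explanatory power of class membership. Groups with no observations are
#' dropped with a warning; when all values are equal, `R^2` is defined as 0.
#'
#' @param values Numeric response per pixel.
#' @param groups Class label per pixel.
#' @return An object of class `"anova_r2"`: list with `ss_between`,
#'   `ss_within`, `ss_total`, `r_squared`, `r_squared_adj` (the
#'   degrees-of-freedom-adjusted R-squared, centred on 0 when class
#'   membership explains nothing), `f_statistic`, `df`, `p_value`
#'   and `group_means`.
#' @export
#' @examples
#' anova_r2(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))  # R^2 = 3/11
anova_r2 <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups)[keep]
  dropped <- levels(groups)[table(groups) == 0]
  if (length(dropped) > 0) {
    warning("empty group(s) dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    groups <- droplevels(groups)
  }
  if (nlevels(groups) < 2) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  if (length(values) - 1 < 2) {
    stop("need at least two total degrees of freedom", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ssb <- tab["groups", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  sst <- ssb + ssw
  # a constant response carries no variance to decompose
  if (sst <= 1e-10 * (abs(mean(values)) + 1)^2) sst <- 0
  gm <- tapply(values, groups, mean)
  structure(
    list(ss_between = ssb,
         ss_within = ssw,
         ss_total = sst,
         r_squared = if (sst > 0) ssb / sst else 0,
         # unbiased under the null hypothesis (raw R^2 has expectation
         # (k-1)/(n-1) even for identical groups)
         r_squared_adj = if (sst > 0) {
           1 - (ssw / tab["Residuals", "Df"]) / (sst / (length(values) - 1))
         } else 0,
         f_statistic = tab["groups", "F value"],
         df = c(between = tab["groups", "Df"],
                within = tab["Residuals", "Df"]),
         p_value = tab["groups", "Pr(>F)"],
         group_means = stats::setNames(as.numeric(gm), names(gm))),
    class = "anova_r2"
  )
}

#' @export
print.anova_r2 <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: R^2 = %.4f  F(%d, %d) = %.3f  p = %.3g\n",
    x$r_squared, x$df["between"], x$df["within"],
    x$f_statistic, x$p_value))
  invisible(x)
}

#' Pooled trophic-level summary across pixels
#'
#' Mean percentage of species at each trophic level across all pixels, with
#' a normal-theory 95% confidence interval (mean +/- 1.96 standard errors).
#'
#' @param compositions Output of [assemble_pixels()].
#' @return Data frame with `level`, `mean_pct`, `ci_lo`, `ci_hi`,
#'   `half_width`, `n_pixels`.
#' @export
pooled_level_summary <- function(compositions) {
  n <- nrow(compositions)
  if (n < 2) stop("need at least two pixels", call. = FALSE)
  do.call(rbind, lapply(.levels, function(l) {
    x <- 100 * compositions[[paste0("p_", l)]]
    se <- stats::sd(x) / sqrt(n)
    data.frame(level = factor(l, levels = .levels),
               mean_pct = mean(x),
               ci_lo = mean(x) - 1.96 * se,
               ci_hi = mean(x) + 1.96 * se,
               half_width = 1.96 * se,
               n_pixels = n)
  }))
}
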