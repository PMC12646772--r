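test_that("trophic-level classification honours the closed mixed band", {
  expect_equal(as.character(classify_level(c(1, 0.5, 2 / 3, 1 / 3, 0.2, 0))),
               c("primary", "mixed", "mixed", "mixed", "higher", "higher"))
  expect_error(classify_level(1.2), "\\[0, 1\\]")
  expect_error(classify_level(-0.1), "\\[0, 1\\]")
})

test_that("pyramids with no stochastic rules are exact in every replicate", {
  cfg <- uncertainty_config(seed = 7, n_replicates = 25)
  # 10 species all phytophagy -> (100, 0, 0) always
  pyr <- build_pyramid(record_rows("t1", category = "phytophagy"), cfg)
  expect_equal(dim(pyr$replicates), c(25, 3))
  expect_true(all(pyr$replicates[, "primary"] == 100))
  expect_true(all(pyr$replicates[, c("mixed", "higher")] == 0))
  # one species 50/50 plant/animal -> always mixed
  mixed <- record_rows("t2", species_count = 1,
                       category = c("phytophagy", "predation"),
                       weight = c(50, 50))
  pyr <- build_pyramid(mixed, cfg)
  expect_true(all(pyr$replicates[, "mixed"] == 100))
  expect_error(build_pyramid(record_rows("t", )[0, ], cfg), "non-empty")
})

test_that("pyramid matches an exhaustive hand count on a mixed fixture", {
  # hand count: 10 primary (phytophagy) + 100 higher (carnivory) +
  # 5 mixed (50/50 within-species) = 115 species
  recs <- rbind(
    record_rows("a", species_count = 10, category = "phytophagy"),
    record_rows("b", group = "reptile", rank = "order", species_count = 100,
                category = "carnivory"),
    record_rows("c", species_count = 5,
                category = c("phytophagy", "predation"), weight = c(50, 50))
  )
  pyr <- build_pyramid(recs, uncertainty_config(seed = 3, n_replicates = 10))
  expect_equal(unname(pyr$replicates[1, ]),
               100 * c(10, 5, 100) / 115, tolerance = 1e-12)
  expect_true(all(apply(pyr$replicates, 1, function(r)
    isTRUE(all.equal(unname(r), 100 * c(10, 5, 100) / 115)))))
})

test_that("plant-detritivore share converges to the analytic 2/3 primary", {
  # p ~ U(0.5, 1): P(primary) = P(p > 2/3) = (1/3) / (1/2) = 2/3, the rest
  # mixed; with 4 one-species taxa each replicate share is an average of
  # independent Bernoulli(2/3) indicators.
  recs <- do.call(rbind, lapply(1:4, function(i) {
    record_rows(paste0("d", i), species_count = 1,
                category = "plant_detritivory")
  }))
  cfg <- uncertainty_config(seed = 5, n_replicates = 1000)
  pyr <- build_pyramid(recs, cfg)
  expect_true(all(pyr$replicates[, "higher"] == 0))
  expect_true(all(pyr$replicates[, "primary"] %in% (100 * 0:4 / 4)))
  m <- mean(pyr$replicates[, "primary"])
  se <- sd(pyr$replicates[, "primary"]) / sqrt(1000)
  expect_lt(abs(m - 200 / 3), 3 * se)
})

test_that("summaries report percentile intervals as mean +/- half-width", {
  cfg <- uncertainty_config(seed = 1, n_replicates = 4)
  pyr <- build_pyramid(record_rows("t", category = "phytophagy"), cfg)
  # identical replicates -> zero half-width
  s <- summarize_pyramid(pyr)
  expect_equal(s$half_width, c(0, 0, 0))
  expect_equal(s$mean, c(100, 0, 0))
  # frozen percentile oracle: uniform grid 40..60 of 1000 values has
  # type-7 percentiles 40.5 and 59.5 exactly
  grid <- seq(40, 60, length.out = 1000)
  pyr$replicates <- cbind(primary = grid, mixed = rep(0, 1000),
                          higher = 60 - grid + 40 - 40)
  pyr$replicates[, "higher"] <- 100 - rowSums(pyr$replicates[, 1:2])
  s <- summarize_pyramid(pyr)
  expect_equal(s$mean[1], 50)
  expect_equal(s$ci_lo[1], 40.5)
  expect_equal(s$ci_hi[1], 59.5)
  # degenerate two-replicate input {0, 100}
  pyr$replicates <- cbind(primary = c(0, 100), mixed = c(0, 0),
                          higher = c(100, 0))
  expect_equal(summarize_pyramid(pyr)$mean[1], 50)
  # single replicate: mean only, CI undefined
  pyr$replicates <- cbind(primary = 100, mixed = 0, higher = 0)
  s1 <- summarize_pyramid(pyr)
  expect_equal(s1$mean[1], 100)
  expect_true(all(is.na(s1$ci_lo)))
  # normal method runs and brackets the mean
  pyr$replicates <- cbind(primary = grid, mixed = 0 * grid,
                          higher = 100 - grid)
  sn <- summarize_pyramid(pyr, ci_method = "normal")
  expect_true(sn$ci_lo[1] < 50 && sn$ci_hi[1] > 50)
})

test_that("replicate percentages sum to 100 and reruns are bit-identical", {
  g <- generate_taxon_records(synthetic_spec(n_taxa = 20, seed = 9,
                                             frac_aquatic = 0,
                                             frac_fishy = 0))
  cfg <- uncertainty_config(seed = 123, n_replicates = 50)
  pyr1 <- build_pyramid(g$records, cfg)
  expect_equal(rowSums(pyr1$replicates), rep(100, 50), tolerance = 1e-9)
  pyr2 <- build_pyramid(g$records, cfg)
  expect_identical(pyr1$replicates, pyr2$replicates)
  # different seed, different draws (the fixture has stochastic rules)
  pyr3 <- build_pyramid(g$records, uncertainty_config(seed = 124,
                                                      n_replicates = 50))
  expect_false(identical(pyr1$replicates, pyr3$replicates))
})

test_that("group pyramids share draw streams with the pooled run", {
  g <- generate_taxon_records(synthetic_spec(n_taxa = 24, seed = 15,
                                             frac_aquatic = 0,
                                             frac_fishy = 0))
  cfg <- uncertainty_config(seed = 77, n_replicates = 30)
  pooled <- build_pyramid(g$records, cfg)
  parts <- pyramid_by_group(g$records, cfg)
  expect_true(length(parts) > 1)
  # weighted average of group pyramids reproduces the pooled pyramid
  # replicate by replicate (conservation under the shared seed stream)
  w <- vapply(names(parts), function(gl) {
    sum(tapply(g$records$species_count[g$records$group == gl],
               g$records$taxon_id[g$records$group == gl], max))
  }, numeric(1))
  combo <- Reduce(`+`, Map(function(py, wt) py$replicates * wt,
                           parts, w)) / sum(w)
  expect_equal(combo, pooled$replicates, tolerance = 1e-9)
  # single group: identical to build_pyramid on the subset
  one <- g$records[g$records$group == names(parts)[1], ]
  solo <- build_pyramid(one, cfg, group = names(parts)[1])
  expect_identical(parts[[1]]$replicates, solo$replicates)
  expect_error(pyramid_by_group(g$records, cfg, grouping = "nope"),
               "grouping")
})

test_that("CI half-width shrinks roughly as 1/sqrt(n_replicates)", {
  recs <- do.call(rbind, lapply(1:6, function(i) {
    record_rows(paste0("d", i), species_count = 1,
                category = "plant_detritivory")
  }))
  hw <- vapply(c(100, 1600), function(n) {
    pyr <- build_pyramid(recs, uncertainty_config(seed = 2, n_replicates = n))
    m <- mean(pyr$replicates[, "primary"])
    1.96 * sd(pyr$replicates[, "primary"]) / sqrt(n)   # SE of the MC mean
  }, numeric(1))
  # 16x the replicates -> ~4x smaller standard error (allow 25% slack)
  expect_lt(hw[2], hw[1] / 4 * 1.25)
  expect_gt(hw[2], hw[1] / 4 * 0.75)
})
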