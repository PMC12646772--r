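test_that("exclusion filter drops aquatic taxa and fish-heavy birds/mammals", {
  recs <- rbind(
    record_rows("fishy_bird", group = "bird", rank = "species",
                species_count = 1, category = "fish", fish_pct = 40),
    record_rows("boundary_bird", group = "bird", rank = "species",
                species_count = 1, category = "invertebrates", fish_pct = 30),
    record_rows("aq_amph", group = "amphibian", rank = "order",
                category = "carnivory", aquatic_flag = TRUE),
    record_rows("dry_moth", category = "phytophagy")
  )
  keep <- filter_species(recs)
  expect_false(keep[["fishy_bird"]])       # > 30% fish, strictly more
  expect_true(keep[["boundary_bird"]])     # exactly 30% is retained
  expect_false(keep[["aq_amph"]])          # aquatic at some life stage
  expect_true(keep[["dry_moth"]])
})

test_that("category fractions: constants ignore u, intervals map linearly", {
  cfg <- uncertainty_config()
  expect_equal(primary_fraction_of_component("phytophagy", "arthropod", u = 0), 1)
  expect_equal(primary_fraction_of_component("phytophagy", "arthropod", u = 1), 1)
  expect_equal(primary_fraction_of_component("fungivory", "arthropod", u = 0.9), 0)
  expect_equal(primary_fraction_of_component("scavenging", "arthropod"), 0)
  expect_equal(primary_fraction_of_component("plant_detritivory", "arthropod",
                                             u = 0), 0.5)
  expect_equal(primary_fraction_of_component("plant_detritivory", "arthropod",
                                             u = 1), 1.0)
  expect_equal(primary_fraction_of_component("generalist_saprophagy",
                                             "arthropod", u = 0.25), 0.25)
  expect_equal(primary_fraction_of_component("detritivory", "reptile",
                                             u = 0.25), 0.25)
  # all constant categories hit their documented poles
  for (g in taxon_groups()) {
    p <- primary_fraction_of_component(diet_categories(g), g, u = 0.5,
                                       cfg = cfg)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(primary_fraction_of_component("herbivory", "arthropod"),
               "valid categories")
})

test_that("predominance allocation conserves species counts", {
  a <- resolve_predominance(c("predation", "phytophagy"), "predation",
                            100, q = 0.80)
  expect_equal(a, c(predation = 80, phytophagy = 20))
  # no descriptor: even split, fractional allowed
  expect_equal(unname(resolve_predominance(c("a_cat", "b_cat"), NA, 10)),
               c(5, 5))
  expect_equal(unname(resolve_predominance(c("x", "y", "z"), NA, 10)),
               rep(10 / 3, 3))
  # predominance with zero alternatives: predominant gets everything
  expect_equal(unname(resolve_predominance("predation", "predation", 7)), 7)
  # conservation across random draws
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    n <- runif(1, 1, 1e4)
    q <- runif(1, 0.65, 0.95)
    cats <- paste0("cat", seq_len(k))
    expect_equal(sum(resolve_predominance(cats, cats[1], n, q)), n)
  }
})

test_that("stage averaging weights nectivorous adults within 10-50%", {
  expect_equal(stage_average(0, 1, TRUE, w = 0.2), 0.2)
  expect_equal(stage_average(1, 1, TRUE, w = 0.37), 1.0)
  # non-nectivorous adults weigh equally regardless of w
  expect_equal(stage_average(0.2, 0.8, FALSE), 0.5)
  expect_error(stage_average(0, 1, TRUE, w = 0.7), "outside configured range")
})

test_that("species_primary_fraction matches hand-computed weighted sums", {
  # within-species mix: p = 0.6 * 1 + 0.4 * 0
  mix <- record_rows("t1", category = c("phytophagy", "predation"),
                     weight = c(60, 40))
  prof <- species_primary_fraction(mix)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$p, 0.6)
  expect_equal(as.character(prof$level), "mixed")

  # order-level record, all carnivory: single block at p = 0
  carn <- record_rows("t2", group = "reptile", rank = "order",
                      species_count = 100, category = "carnivory")
  prof <- species_primary_fraction(carn)
  expect_equal(prof$weight, 100)
  expect_equal(prof$p, 0)
  expect_equal(as.character(prof$level), "higher")

  # interval category at midpoint: plant_detritivory -> 0.75
  det <- record_rows("t3", category = "plant_detritivory")
  expect_equal(species_primary_fraction(det)$p, 0.75)

  # weights on a 0-1 scale are accepted too
  mix01 <- record_rows("t4", category = c("phytophagy", "predation"),
                       weight = c(0.6, 0.4))
  expect_equal(species_primary_fraction(mix01)$p, 0.6)

  # three components: direct hand-computed weighted sum
  tri <- record_rows("t5", category = c("phytophagy", "nectivory", "predation"),
                     weight = c(20, 30, 50))
  expect_equal(species_primary_fraction(tri)$p, 0.5)
})

test_that("two-stage taxa combine larval allocation with the adult fraction", {
  rec <- rbind(
    record_rows("moth", species_count = 12, stage = "larva",
                category = "phytophagy"),
    record_rows("moth", species_count = 12, stage = "adult",
                category = "nectivory", exclusively_nectivorous = TRUE)
  )
  prof <- species_primary_fraction(rec)        # both stages primary
  expect_equal(prof$p, 1)
  expect_equal(prof$weight, 12)

  rec2 <- rbind(
    record_rows("wasp", species_count = 10, stage = "larva",
                category = "predation"),
    record_rows("wasp", species_count = 10, stage = "adult",
                category = "nectivory", exclusively_nectivorous = TRUE)
  )
  # midpoint adult weight 0.3: p = 0.7 * 0 + 0.3 * 1
  expect_equal(species_primary_fraction(rec2)$p, 0.3)
})

test_that("malformed records are rejected with informative errors", {
  bad_sum <- record_rows("t1", category = c("phytophagy", "predation"),
                         weight = c(60, 20))
  expect_error(species_primary_fraction(bad_sum), "sum to")
  bad_cat <- record_rows("t1", category = "herbivory")  # reptile term
  expect_error(validate_taxon_records(bad_cat), "unknown category")
  bad_stage <- record_rows("t1", stage = "pupa")
  expect_error(validate_taxon_records(bad_stage), "stage")
  expect_error(validate_taxon_records(record_rows("t1", species_count = 0)),
               "species_count")
  expect_error(validate_taxon_records(data.frame()), "non-empty")
  # a lone adult stage is not a valid record shape
  lone_adult <- record_rows("t1", stage = "adult", category = "nectivory")
  expect_error(species_primary_fraction(lone_adult), "larva")
})

test_that("fractions stay in [0,1] and counts are conserved on random records", {
  set.seed(42)
  cfg <- uncertainty_config()
  for (i in 1:40) {
    g <- generate_taxon_records(synthetic_spec(n_taxa = 8, seed = i,
                                               frac_aquatic = 0,
                                               frac_fishy = 0))
    for (mode in c("midpoint", "random")) {
      prof <- species_primary_fraction(g$records, cfg, draws = mode)
      expect_true(all(prof$p >= 0 & prof$p <= 1))
      counts <- tapply(prof$weight, prof$taxon_id, sum)
      expected <- tapply(g$records$species_count, g$records$taxon_id, max)
      expect_equal(counts[names(expected)], expected, tolerance = 1e-12)
    }
  }
})

test_that("midpoint resolution is deterministic and monotone in plant weight", {
  rec <- record_rows("t1", category = c("phytophagy", "predation"),
                     weight = c(50, 50))
  p1 <- species_primary_fraction(rec)$p
  p2 <- species_primary_fraction(rec)$p
  expect_identical(p1, p2)
  # increasing the constant-1 component weight never decreases p
  ps <- vapply(seq(0, 100, by = 10), function(w) {
    r <- record_rows("t1", category = c("phytophagy", "predation"),
                     weight = c(w, 100 - w))
    species_primary_fraction(r)$p
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))
})
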