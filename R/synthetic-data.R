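# Synthetic-data generation for the full pipeline.
#
# Two generators: taxon diet records with a ground-truth trophic pyramid
# under midpoint draws, and gridded assemblages drawn from six parameterized
# community structure archetypes with controllable separability. Every rule
# branch of the classification engine (predominance descriptors,
# within-species mixes, stage splits, interval categories, aquatic flags,
# fish thresholds) is reachable from a spec toggle.

# Default class archetypes: deliberately similar trophic-level ratios
# (anchored near the pooled tetrapod stratification of roughly 21% primary,
# 10% mixed, 69% higher-level) but class-specific diet-item mixes. These are
# synthetic defaults, not fitted values.
.default_archetypes <- list(
  "depauperate"       = c(primary = 0.20, mixed = 0.10, higher = 0.70),
  "boreal"            = c(primary = 0.22, mixed = 0.10, higher = 0.68),
  "temperate"         = c(primary = 0.21, mixed = 0.11, higher = 0.68),
  "semi-arid"         = c(primary = 0.23, mixed = 0.09, higher = 0.68),
  "seasonal tropical" = c(primary = 0.21, mixed = 0.10, higher = 0.69),
  "humid tropical"    = c(primary = 0.22, mixed = 0.11, higher = 0.67)
)

# Class-specific diet-item mixes (rows sum to 1 within plant and animal
# blocks). Cold/dry classes leaning on seeds and endotherm prey; tropical
# classes on fruit, nectar and invertebrates.
.default_diet_profiles <- list(
  "depauperate"       = list(plant = c(plants = 0.55, seeds = 0.35, fruit = 0.05, nectar = 0.05),
                             animal = c(invertebrates = 0.35, vertebrate_endotherms = 0.40,
                                        vertebrate_ectotherms = 0.05, fish = 0.05,
                                        carrion = 0.10, unknown_vertebrates = 0.05)),
  "boreal"            = list(plant = c(plants = 0.45, seeds = 0.40, fruit = 0.10, nectar = 0.05),
                             animal = c(invertebrates = 0.45, vertebrate_endotherms = 0.30,
                                        vertebrate_ectotherms = 0.05, fish = 0.05,
                                        carrion = 0.10, unknown_vertebrates = 0.05)),
  "temperate"         = list(plant = c(plants = 0.35, seeds = 0.30, fruit = 0.25, nectar = 0.10),
                             animal = c(invertebrates = 0.55, vertebrate_endotherms = 0.20,
                                        vertebrate_ectotherms = 0.10, fish = 0.05,
                                        carrion = 0.05, unknown_vertebrates = 0.05)),
  "semi-arid"         = list(plant = c(plants = 0.40, seeds = 0.40, fruit = 0.10, nectar = 0.10),
                             animal = c(invertebrates = 0.55, vertebrate_endotherms = 0.15,
                                        vertebrate_ectotherms = 0.20, fish = 0.00,
                                        carrion = 0.05, unknown_vertebrates = 0.05)),
  "seasonal tropical" = list(plant = c(plants = 0.25, seeds = 0.20, fruit = 0.40, nectar = 0.15),
                             animal = c(invertebrates = 0.60, vertebrate_endotherms = 0.10,
                                        vertebrate_ectotherms = 0.15, fish = 0.05,
                                        carrion = 0.05, unknown_vertebrates = 0.05)),
  "humid tropical"    = list(plant = c(plants = 0.15, seeds = 0.15, fruit = 0.45, nectar = 0.25),
                             animal = c(invertebrates = 0.65, vertebrate_endotherms = 0.10,
                                        vertebrate_ectotherms = 0.15, fish = 0.05,
                                        carrion = 0.00, unknown_vertebrates = 0.05))
)

#' Specification of a synthetic data set
#'
#' Collects every knob of the synthetic generators. Defaults emulate the
#' structure of real inputs: taxa with species counts spanning orders of
#' magnitude (log-uniform), a share of taxa described only as "most species
#' are X", holometabolous taxa with exclusively nectivorous adults, and a
#' one-degree grid whose six community structure classes share very similar
#' trophic-level archetypes while differing in diet-item mixes.
#'
#' @param n_taxa Number of taxon records to generate.
#' @param species_count_range Bounds of the log-uniform species-count
#'   distribution.
#' @param group_probs Named sampling probabilities over [taxon_groups()].
#' @param frac_most Fraction of multi-diet taxa carrying a "most" descriptor.
#' @param frac_within Fraction of multi-diet taxa whose diets are
#'   within-species compositions rather than across-species splits.
#' @param frac_two_stage Fraction of arthropod taxa with a larva+adult pair
#'   whose adult is exclusively nectivorous.
#' @param frac_multi Fraction of taxa with more than one diet.
#' @param frac_aquatic Fraction of taxa flagged aquatic (excluded upstream).
#' @param frac_fishy Fraction of bird/mammal taxa with fish_pct above the
#'   exclusion threshold.
#' @param interval_categories If `FALSE`, only constant-fraction categories
#'   are sampled, making the midpoint ground truth exact for every draw.
#' @param pixels_per_class Named or scalar pixel count per structure class.
#' @param richness Species per pixel.
#' @param archetypes Named list (class -> length-3 mean composition,
#'   `primary`/`mixed`/`higher`, summing to 1).
#' @param concentration Dirichlet concentration of pixel compositions around
#'   the class archetype; `Inf` gives point-mass compositions.
#' @param diet_profiles Named list (class -> list(plant=, animal=)) of
#'   item mixes used to draw species diet tables.
#' @param diet_concentration Dirichlet concentration of species item vectors
#'   around the class profile.
#' @param pool_size Species pool size per (class, level); compositions
#'   demanding more species of a level than the pool holds are an error.
#'   Default equals `richness`, which is always attainable.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_taxa = 60,
                           species_count_range = c(2, 500),
                           group_probs = c(mammal = 0.15, bird = 0.15,
                                           reptile = 0.1, amphibian = 0.1,
                                           arthropod = 0.5),
                           frac_most = 0.25,
                           frac_within = 0.25,
                           frac_two_stage = 0.25,
                           frac_multi = 0.5,
                           frac_aquatic = 0.05,
                           frac_fishy = 0.1,
                           interval_categories = TRUE,
                           pixels_per_class = 40,
                           richness = 50,
                           archetypes = .default_archetypes,
                           concentration = 60,
                           diet_profiles = .default_diet_profiles,
                           diet_concentration = 100,
                           pool_size = richness,
                           seed = 1L) {
  if (n_taxa < 1) stop("n_taxa must be >= 1", call. = FALSE)
  for (a in archetypes) {
    if (abs(sum(a) - 1) > 1e-9) {
      stop("archetype means must sum to 1", call. = FALSE)
    }
  }
  if (any(pixels_per_class < 1)) {
    stop("pixels_per_class must be >= 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

.log_uniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

# midpoint primary fraction of a category (independent bookkeeping used for
# the generator's ground truth)
.midpoint_p <- c(
  fungivory = 0, phytophagy = 1, nectivory = 1, predation = 0,
  parasitism = 0, ectoparasitism = 0, scavenging = 0,
  plant_detritivory = 0.75, generalist_saprophagy = 0.5,
  herbivory = 1, carnivory = 0, detritivory = 0.5,
  plants = 1, seeds = 1, fruit = 1, nectar = 1, invertebrates = 0,
  vertebrate_endotherms = 0, vertebrate_ectotherms = 0, fish = 0,
  carrion = 0, unknown_vertebrates = 0
)

#' Generate synthetic taxon diet records with known ground truth
#'
#' Emits a record table exercising the classification rule branches enabled
#' in the spec, together with the expected trophic pyramid under midpoint
#' draws (interval categories at midpoints, predominance at 0.80, adult
#' weight at the range midpoint), computed by direct arithmetic independent
#' of the rule engine. Excluded taxa (aquatic, fish-heavy) do not count
#' toward the truth.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (data frame in the input CSV dialect) and
#'   `truth` (data frame `level`, `expected_pct` under midpoint draws).
#' @export
generate_taxon_records <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rows <- list()
  truth <- c(primary = 0, mixed = 0, higher = 0)
  classify_mid <- function(p) {
    if (p > 2 / 3) "primary" else if (p < 1 / 3) "higher" else "mixed"
  }
  cats_for <- function(group) {
    cats <- diet_categories(group)
    if (!spec$interval_categories) {
      cats <- setdiff(cats, c("plant_detritivory", "generalist_saprophagy",
                              "detritivory"))
    }
    cats
  }
  for (i in seq_len(spec$n_taxa)) {
    id <- sprintf("tax%04d", i)
    group <- sample(names(spec$group_probs), 1, prob = spec$group_probs)
    n_sp <- round(.log_uniform(1, spec$species_count_range))
    n_sp <- max(n_sp, 1)
    rank <- switch(group, mammal = "species", bird = "species",
                   arthropod = "family", "order")
    if (group %in% c("mammal", "bird")) n_sp <- 1
    aquatic <- stats::runif(1) < spec$frac_aquatic
    fish_pct <- NA_real_
    if (group %in% c("mammal", "bird")) {
      fish_pct <- if (stats::runif(1) < spec$frac_fishy)
        stats::runif(1, 35, 90) else stats::runif(1, 0, 25)
    }
    excluded <- aquatic ||
      (!is.na(fish_pct) && fish_pct > 30)
    two_stage <- group == "arthropod" && stats::runif(1) < spec$frac_two_stage
    multi <- stats::runif(1) < spec$frac_multi
    cats <- cats_for(group)
    k <- if (multi) sample(2:min(3, length(cats)), 1) else 1
    chosen <- sample(cats, k)
    within <- multi && stats::runif(1) < spec$frac_within
    most <- multi && !within && stats::runif(1) < spec$frac_most
    stage <- if (two_stage) "larva" else "single"
    if (within) {
      w <- as.numeric(stats::rmultinom(1, 100, rep(1, k)))
      # avoid zero-weight components
      while (any(w == 0)) w <- as.numeric(stats::rmultinom(1, 100, rep(1, k)))
    } else {
      w <- rep(NA_real_, k)
    }
    pred <- rep(NA_character_, k)
    if (most) pred[1] <- "most"
    rows[[length(rows) + 1]] <- data.frame(
      taxon_id = id, group = group, rank = rank, species_count = n_sp,
      stage = stage, category = chosen, weight = w, predominance = pred,
      exclusively_nectivorous = FALSE, aquatic_flag = aquatic,
      fish_pct = fish_pct, stringsAsFactors = FALSE
    )
    if (two_stage) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = id, group = group, rank = rank, species_count = n_sp,
        stage = "adult", category = "nectivory", weight = NA_real_,
        predominance = NA_character_, exclusively_nectivorous = TRUE,
        aquatic_flag = aquatic, fish_pct = fish_pct,
        stringsAsFactors = FALSE
      )
    }
    if (excluded) next
    # ground truth under midpoint draws, by direct arithmetic
    p_cat <- .midpoint_p[chosen]
    if (two_stage) p_cat <- 0.7 * p_cat + 0.3 * 1   # w = mid(0.1, 0.5)
    if (within) {
      p <- sum(w / 100 * p_cat)
      truth[classify_mid(p)] <- truth[classify_mid(p)] + n_sp
    } else if (k == 1) {
      truth[classify_mid(p_cat)] <- truth[classify_mid(p_cat)] + n_sp
    } else {
      share <- if (most) {
        s <- rep(0.2 / (k - 1), k); s[1] <- 0.8; s
      } else rep(1 / k, k)
      for (j in seq_len(k)) {
        lv <- classify_mid(p_cat[j])
        truth[lv] <- truth[lv] + share[j] * n_sp
      }
    }
  }
  records <- do.call(rbind, rows)
  if (sum(truth) == 0) {
    stop("spec produced no retained taxa; increase n_taxa or lower ",
         "exclusion fractions", call. = FALSE)
  }
  list(
    records = records,
    truth = data.frame(level = factor(names(truth), levels = .levels),
                       expected_pct = 100 * as.numeric(truth) / sum(truth))
  )
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Dirichlet draw around a mean with concentration conc; conc = Inf is the
# point mass at the mean.
.rdirichlet_mean <- function(mean, conc) {
  if (!is.finite(conc)) return(mean / sum(mean))
  .rdirichlet(conc * mean)
}

# largest-remainder rounding of richness * props to integer counts
.integer_counts <- function(props, total) {
  raw <- props * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1
  }
  counts
}

#' Generate a synthetic gridded assemblage data set
#'
#' Builds, per structure class, a regional species pool at each trophic
#' level, then draws each pixel's level composition from the class Dirichlet
#' archetype and fills the pixel with species sampled from the pools.
#' Species diet-item vectors are drawn consistently with their trophic
#' level: primary species eat the class's plant-item mix, higher-level
#' species its animal-item mix, and mixed species a 50/50 blend.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `presence` (species_id, pixel_id), `pixels` (pixel_id,
#'   lat, lon, structure_class), `profiles` (species_id, level, p), `diet`
#'   (species_id plus the ten item columns) and `true_means` (the class
#'   archetypes used).
#' @export
generate_grid <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  classes <- names(spec$archetypes)
  npix <- spec$pixels_per_class
  if (length(npix) == 1) {
    npix <- stats::setNames(rep(npix, length(classes)), classes)
  }
  p_bands <- list(primary = c(0.70, 1), mixed = c(0.35, 0.65),
                  higher = c(0, 0.30))
  presence <- list()
  pixels <- list()
  profiles <- list()
  diets <- list()
  pixel_counter <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    mean_c <- spec$archetypes[[cl]][.levels]
    prof_c <- spec$diet_profiles[[cl]]
    pools <- list()
    for (lv in .levels) {
      n_pool <- spec$pool_size
      ids <- sprintf("c%d_%s_%03d", ci, substr(lv, 1, 3), seq_len(n_pool))
      p <- stats::runif(n_pool, p_bands[[lv]][1], p_bands[[lv]][2])
      pools[[lv]] <- ids
      profiles[[length(profiles) + 1]] <- data.frame(
        species_id = ids, level = lv, p = p, stringsAsFactors = FALSE)
      # item vectors consistent with level
      items <- t(vapply(seq_len(n_pool), function(i) {
        pl <- .rdirichlet_mean(prof_c$plant, spec$diet_concentration)
        an <- .rdirichlet_mean(prof_c$animal, spec$diet_concentration)
        share_plant <- switch(lv, primary = 1, higher = 0, mixed = 0.5)
        100 * c(share_plant * pl, (1 - share_plant) * an)
      }, numeric(10)))
      colnames(items) <- c(names(prof_c$plant), names(prof_c$animal))
      diets[[length(diets) + 1]] <- data.frame(
        species_id = ids, items[, diet_item_names(), drop = FALSE],
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    for (px in seq_len(npix[[cl]])) {
      pixel_counter <- pixel_counter + 1L
      pid <- sprintf("px%05d", pixel_counter)
      lon <- -179.5 + ((pixel_counter - 1L) %% 360)
      lat <- -89.5 + ((pixel_counter - 1L) %/% 360)
      comp <- .rdirichlet_mean(mean_c, spec$concentration)
      counts <- .integer_counts(comp, spec$richness)
      names(counts) <- .levels
      for (lv in .levels) {
        if (counts[lv] > length(pools[[lv]])) {
          stop("pixel composition demands ", counts[lv], " ", lv,
               " species but the '", cl, "' pool holds only ",
               length(pools[[lv]]),
               "; increase pool_size or reduce richness", call. = FALSE)
        }
        if (counts[lv] > 0) {
          sp <- sample(pools[[lv]], counts[lv])
          presence[[length(presence) + 1]] <- data.frame(
            species_id = sp, pixel_id = pid, stringsAsFactors = FALSE)
        }
      }
      pixels[[length(pixels) + 1]] <- data.frame(
        pixel_id = pid, lat = lat, lon = lon, structure_class = cl,
        stringsAsFactors = FALSE)
    }
  }
  list(
    presence = do.call(rbind, presence),
    pixels = do.call(rbind, pixels),
    profiles = do.call(rbind, profiles),
    diet = do.call(rbind, diets),
    true_means = spec$archetypes
  )
}
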