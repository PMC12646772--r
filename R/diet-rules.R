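# Diet-category rule tables and the per-species primary-consumption engine.
#
# Every consumer species is scored by the fraction p of its diet drawn from
# autotroph (plant) material. Categories map to p = 1 (plant-based), p = 0
# (animal- or fungus-based) or to an uncertainty interval when the energy
# source of the diet is ambiguous (detritivory, saprophagy).

#' Valid diet categories per taxonomic group
#'
#' Returns the closed vocabulary of diet categories accepted for a taxonomic
#' group. Arthropods use functional feeding categories; reptiles and
#' amphibians use a coarse three-way scheme; birds and mammals use diet-item
#' labels from standard foraging-attribute compilations.
#'
#' @param group One of `"mammal"`, `"bird"`, `"reptile"`, `"amphibian"`,
#'   `"arthropod"`.
#' @return Character vector of category names.
#' @export
#' @examples
#' diet_categories("arthropod")
diet_categories <- function(group) {
  group <- match.arg(group, names(.category_rules))
  names(.category_rules[[group]])
}

# Rule table: each entry is either a constant in {0, 1} or the name of the
# config range that parameterizes its uniform interval.
.herptile_rules <- list(
  herbivory   = 1,
  carnivory   = 0,
  detritivory = "saprophagy_range"
)
.category_rules <- list(
  arthropod = list(
    fungivory            = 0,
    phytophagy           = 1,
    nectivory            = 1,
    predation            = 0,
    parasitism           = 0,
    ectoparasitism       = 0,
    scavenging           = 0,
    plant_detritivory    = "plant_detritivory_range",
    generalist_saprophagy = "saprophagy_range"
  ),
  reptile   = .herptile_rules,
  amphibian = .herptile_rules,
  bird = as.list(c(
    plants = 1, seeds = 1, fruit = 1, nectar = 1,
    invertebrates = 0, vertebrate_endotherms = 0, vertebrate_ectotherms = 0,
    fish = 0, carrion = 0, unknown_vertebrates = 0
  )),
  mammal = NULL
)
.category_rules$mammal <- .category_rules$bird

#' Tetrapod and arthropod group labels
#' @return Character vector of the five recognized taxonomic groups.
#' @export
taxon_groups <- function() names(.category_rules)

#' Bird/mammal diet-item labels
#' @return Character vector of the ten diet-item column names used in
#'   species-level diet tables for birds and mammals.
#' @export
diet_item_names <- function() names(.category_rules$bird)

# Items counted as plant-based when splitting an aggregated community diet.
.plant_items <- c("plants", "seeds", "fruit", "nectar")

#' Uncertainty configuration for the classification rules
#'
#' Bundles every tunable range of the rule engine together with the Monte
#' Carlo settings. All ranges are sub-intervals of \[0, 1\] and are sampled
#' uniformly.
#'
#' @param predominance_range Share of a taxon's species assumed to follow a
#'   diet described verbally as what "most" species eat. Default
#'   `c(0.65, 0.95)`.
#' @param plant_detritivory_range Primary-consumption fraction of plant
#'   detritivory (dead wood/leaves); the balance is fungal. Default
#'   `c(0.5, 1)`.
#' @param saprophagy_range Primary-consumption fraction of generalist
#'   saprophagy and herptile detritivory, where the energy source is fully
#'   unknown. Default `c(0, 1)`.
#' @param adult_weight_range Energetic weight of the adult stage when
#'   averaging larval and adult diets of taxa whose adults are exclusively
#'   nectivorous. Default `c(0.10, 0.50)`.
#' @param fish_exclusion_threshold Percent of fish in a bird or mammal diet
#'   above which the species is excluded as predominantly aquatic. Default 30.
#' @param mixed_band Closed interval of p classified as mixed consumption.
#'   Default `c(1/3, 2/3)`.
#' @param n_replicates Number of Monte Carlo pyramid replicates. Default 1000.
#' @param seed Integer seed driving every random draw. `NULL` leaves the RNG
#'   state untouched (not reproducible).
#' @param ci_method `"percentile"` (2.5--97.5 percentile across replicates)
#'   or `"normal"` (mean +/- 1.96 sd).
#' @return A list of class `"uncertainty_config"`.
#' @export
#' @examples
#' cfg <- uncertainty_config(seed = 42, n_replicates = 200)
uncertainty_config <- function(predominance_range = c(0.65, 0.95),
                               plant_detritivory_range = c(0.5, 1),
                               saprophagy_range = c(0, 1),
                               adult_weight_range = c(0.10, 0.50),
                               fish_exclusion_threshold = 30,
                               mixed_band = c(1 / 3, 2 / 3),
                               n_replicates = 1000,
                               seed = NULL,
                               ci_method = c("percentile", "normal")) {
  ci_method <- match.arg(ci_method)
  cfg <- list(
    predominance_range = as.numeric(predominance_range),
    plant_detritivory_range = as.numeric(plant_detritivory_range),
    saprophagy_range = as.numeric(saprophagy_range),
    adult_weight_range = as.numeric(adult_weight_range),
    fish_exclusion_threshold = as.numeric(fish_exclusion_threshold),
    mixed_band = as.numeric(mixed_band),
    n_replicates = as.integer(n_replicates),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    ci_method = ci_method
  )
  for (nm in c("predominance_range", "plant_detritivory_range",
               "saprophagy_range", "adult_weight_range", "mixed_band")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < 0 || r[2] > 1) {
      stop(nm, " must be an ordered pair within [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  class(cfg) <- "uncertainty_config"
  cfg
}

#' Primary-consumption fraction of one diet category
#'
#' Constant categories (e.g. phytophagy -> 1, predation -> 0) ignore the
#' uniform draw; interval categories map `u` linearly onto their configured
#' range, `lo + u * (hi - lo)`.
#'
#' @param category Diet category name, valid for `group`.
#' @param group Taxonomic group the category belongs to.
#' @param u Uniform draw in \[0, 1\]; defaults to the interval midpoint.
#' @param cfg An [uncertainty_config()].
#' @return Fraction in \[0, 1\]. Vectorized over `category` and `u`.
#' @export
#' @examples
#' primary_fraction_of_component("phytophagy", "arthropod")        # 1
#' primary_fraction_of_component("plant_detritivory", "arthropod",
#'                               u = 0)                            # 0.5
primary_fraction_of_component <- function(category, group, u = 0.5,
                                          cfg = uncertainty_config()) {
  group <- match.arg(group, taxon_groups())
  rules <- .category_rules[[group]]
  bad <- setdiff(unique(category), names(rules))
  if (length(bad) > 0) {
    stop("unknown diet categor", if (length(bad) > 1) "ies " else "y ",
         paste(sQuote(bad), collapse = ", "), " for group '", group,
         "'; valid categories are: ", paste(names(rules), collapse = ", "),
         call. = FALSE)
  }
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]", call. = FALSE)
  u <- rep_len(u, length(category))
  vapply(seq_along(category), function(i) {
    rule <- rules[[category[i]]]
    if (is.numeric(rule)) return(rule)
    r <- cfg[[rule]]
    r[1] + u[i] * (r[2] - r[1])
  }, numeric(1))
}

#' Exclusion filter for predominantly aquatic species
#'
#' Drops taxa with marine or aquatic habits at any life stage, and birds or
#' mammals whose diets consist of more than the configured percentage of fish
#' (strictly more; the default threshold of 30% separates opportunistic
#' fish-eaters from predominantly aquatic feeders).
#'
#' @param records A taxon diet record data frame (see [read_taxon_records()]).
#' @param cfg An [uncertainty_config()].
#' @return Logical vector, one element per taxon (in order of first
#'   appearance), `TRUE` when the taxon is retained. Names are taxon ids.
#' @export
filter_species <- function(records, cfg = uncertainty_config()) {
  records <- validate_taxon_records(records)
  ids <- unique(records$taxon_id)
  vapply(ids, function(id) {
    rows <- records[records$taxon_id == id, , drop = FALSE]
    if (any(rows$aquatic_flag)) return(FALSE)
    if (rows$group[1] %in% c("bird", "mammal")) {
      fp <- rows$fish_pct[!is.na(rows$fish_pct)]
      if (length(fp) > 0 && max(fp) > cfg$fish_exclusion_threshold) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = TRUE)
}

#' Allocate a taxon's species across diets under a predominance descriptor
#'
#' When a taxon's diets are described across species ("most species are X"),
#' the predominant diet receives a share `q` of the species and the remainder
#' is split evenly among the alternatives. Without a descriptor all diets
#' receive an even share. Fractional allocations are retained so that counts
#' are conserved exactly.
#'
#' @param categories Character vector of diet categories (across species).
#' @param predominant Name of the predominant category, or `NA` for none.
#' @param species_count Positive number of species in the taxon.
#' @param q Predominant share in \[0, 1\] (drawn from
#'   `predominance_range` in Monte Carlo runs).
#' @return Named numeric vector of species allocations summing to
#'   `species_count`.
#' @export
#' @examples
#' resolve_predominance(c("predation", "phytophagy"), "predation", 100, 0.8)
resolve_predominance <- function(categories, predominant = NA,
                                 species_count, q = 0.80) {
  k <- length(categories)
  if (k == 0) stop("at least one diet category required", call. = FALSE)
  if (species_count <= 0) stop("species_count must be > 0", call. = FALSE)
  if (is.na(predominant) || k == 1) {
    # no descriptor (or nothing to predominate over): even split
    if (!is.na(predominant) && k == 1) {
      return(stats::setNames(species_count, categories))
    }
    return(stats::setNames(rep(species_count / k, k), categories))
  }
  if (!predominant %in% categories) {
    stop("predominant category '", predominant,
         "' not among the taxon's diets", call. = FALSE)
  }
  if (q < 0 || q > 1) stop("q must lie in [0, 1]", call. = FALSE)
  alloc <- rep((1 - q) * species_count / (k - 1), k)
  alloc[categories == predominant] <- q * species_count
  stats::setNames(alloc, categories)
}

#' Average larval and adult primary fractions
#'
#' Taxa with complete metamorphosis are scored by averaging the two stages.
#' When the adult is exclusively nectivorous its diet is a minor energetic
#' contribution, so its weight `w` is limited to the configured
#' `adult_weight_range`; otherwise the stages weigh equally.
#'
#' @param p_larva,p_adult Stage primary fractions in \[0, 1\].
#' @param exclusively_nectivorous_adult Logical.
#' @param w Adult weight draw; used only for exclusively nectivorous adults.
#' @param cfg An [uncertainty_config()].
#' @return Combined primary fraction `(1 - w) * p_larva + w * p_adult`.
#' @export
stage_average <- function(p_larva, p_adult,
                          exclusively_nectivorous_adult = FALSE,
                          w = mean(cfg$adult_weight_range),
                          cfg = uncertainty_config()) {
  if (exclusively_nectivorous_adult) {
    r <- cfg$adult_weight_range
    if (any(w < r[1] | w > r[2])) {
      stop("adult weight w outside configured range [", r[1], ", ", r[2], "]",
           call. = FALSE)
    }
  } else {
    w <- 0.5
  }
  (1 - w) * p_larva + w * p_adult
}

# ---- internal: compile records into per-taxon resolution plans -------------

# A compiled taxon is a list with everything needed to resolve it quickly in
# the replicate loop: per-stage category/weight vectors, which components are
# interval-valued, whether a predominance draw or an adult-weight draw is
# needed, and a stable per-taxon hash for seed derivation.
.compile_taxon <- function(rows, cfg) {
  id <- rows$taxon_id[1]
  group <- rows$group[1]
  stages <- lapply(split(rows, rows$stage, drop = TRUE), function(st) {
    st <- st[order(st$category), , drop = FALSE]
    within <- !all(is.na(st$weight))
    if (within && any(is.na(st$weight))) {
      stop("taxon '", id, "': mixed given and missing diet weights within ",
           "one stage; a stage is either a within-species composition ",
           "(all weights given) or an across-species assignment (none)",
           call. = FALSE)
    }
    w <- NULL
    if (within) {
      w <- st$weight
      total <- sum(w)
      # accept 0-100 or 0-1 scales, validate the sum
      if (abs(total - 100) < 1e-6 * 100) {
        w <- w / 100
      } else if (abs(total - 1) >= 1e-6) {
        stop("taxon '", id, "': diet weights sum to ", total,
             ", expected 100 (or 1)", call. = FALSE)
      }
    }
    rule_names <- vapply(st$category, function(ct) {
      rule <- .category_rules[[group]][[ct]]
      if (is.numeric(rule)) "" else rule
    }, character(1))
    pred <- st$category[!is.na(st$predominance) & st$predominance == "most"]
    if (length(pred) > 1) {
      stop("taxon '", id, "': more than one predominant diet", call. = FALSE)
    }
    list(
      stage = st$stage[1],
      categories = st$category,
      const_p = primary_fraction_of_component(st$category, group,
                                              u = 0.5, cfg = cfg),
      interval_rule = rule_names,       # "" for constant categories
      within = within,
      weights = w,
      predominant = if (length(pred) == 1 && !within) pred else NA_character_,
      nectivorous_adult = isTRUE(any(st$exclusively_nectivorous))
    )
  })
  stage_names <- unname(vapply(stages, `[[`, character(1), "stage"))
  if (anyDuplicated(stage_names) > 0) {
    stop("taxon '", id, "': duplicated stage", call. = FALSE)
  }
  if (!(identical(sort(stage_names), "single") ||
        identical(sort(stage_names), c("adult", "larva")))) {
    stop("taxon '", id, "': stages must be 'single' or a larva+adult pair; ",
         "got ", paste(stage_names, collapse = ", "), call. = FALSE)
  }
  two_stage <- length(stages) == 2
  adult <- if (two_stage) stages[[match("adult", stage_names)]] else NULL
  if (!is.null(adult) && adult$nectivorous_adult) {
    ok <- identical(adult$categories, "nectivory")
    if (!ok) {
      stop("taxon '", id, "': exclusively_nectivorous adult must have the ",
           "single diet 'nectivory'", call. = FALSE)
    }
  }
  list(
    taxon_id = id,
    group = group,
    species_count = rows$species_count[1],
    two_stage = two_stage,
    larva = if (two_stage) stages[[match("larva", stage_names)]] else NULL,
    adult = adult,
    single = if (!two_stage) stages[[1]] else NULL,
    hash = .string_hash(id)
  )
}

.string_hash <- function(s) {
  codes <- utf8ToInt(as.character(s))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483629
  as.integer(h)
}

.compile_records <- function(records, cfg) {
  records <- validate_taxon_records(records)
  ids <- unique(records$taxon_id)
  lapply(ids, function(id) {
    .compile_taxon(records[records$taxon_id == id, , drop = FALSE], cfg)
  })
}

# Draws for one taxon: q per stage needing predominance, u per component,
# w for the nectivorous-adult average. mode "midpoint" pins u = 0.5,
# q = 0.80, w = mid(adult_weight_range); mode "random" samples uniformly
# from the current RNG stream.
.taxon_draws <- function(ct, cfg, mode = c("midpoint", "random")) {
  mode <- match.arg(mode)
  stages <- if (ct$two_stage) list(ct$larva, ct$adult) else list(ct$single)
  draws <- lapply(stages, function(st) {
    n <- length(st$categories)
    if (mode == "midpoint") {
      list(u = rep(0.5, n), q = 0.80)
    } else {
      pr <- cfg$predominance_range
      list(u = stats::runif(n),
           q = stats::runif(1, pr[1], pr[2]))
    }
  })
  names(draws) <- vapply(stages, `[[`, character(1), "stage")
  aw <- cfg$adult_weight_range
  draws$w <- if (mode == "midpoint") mean(aw) else stats::runif(1, aw[1], aw[2])
  draws
}

# Resolve one stage to blocks: data frame (share, p) with share summing to 1.
.resolve_stage <- function(st, cfg, u, q) {
  p <- st$const_p
  iv <- st$interval_rule != ""
  if (any(iv)) {
    for (i in which(iv)) {
      r <- cfg[[st$interval_rule[i]]]
      p[i] <- r[1] + u[i] * (r[2] - r[1])
    }
  }
  if (st$within) {
    data.frame(share = 1, p = sum(st$weights * p))
  } else if (length(st$categories) == 1) {
    data.frame(share = 1, p = p)
  } else {
    alloc <- resolve_predominance(st$categories, st$predominant, 1, q)
    data.frame(share = as.numeric(alloc), p = p)
  }
}

# Resolve a compiled taxon into species-equivalent blocks (unit_id, weight, p).
.resolve_taxon <- function(ct, cfg, draws) {
  if (ct$two_stage) {
    larva <- .resolve_stage(ct$larva, cfg, draws$larva$u, draws$larva$q)
    adult <- .resolve_stage(ct$adult, cfg, draws$adult$u, draws$adult$q)
    p_adult <- sum(adult$share * adult$p)   # adult stage as one fraction
    p <- stage_average(larva$p, p_adult,
                       exclusively_nectivorous_adult = ct$adult$nectivorous_adult,
                       w = draws$w, cfg = cfg)
    blocks <- data.frame(share = larva$share, p = p)
  } else {
    blocks <- .resolve_stage(ct$single, cfg, draws$single$u, draws$single$q)
  }
  data.frame(
    unit_id = if (nrow(blocks) == 1) ct$taxon_id else
      paste0(ct$taxon_id, "#", seq_len(nrow(blocks))),
    taxon_id = ct$taxon_id,
    group = ct$group,
    weight = blocks$share * ct$species_count,
    p = blocks$p,
    stringsAsFactors = FALSE
  )
}

#' Resolve taxon records into per-species primary-consumption profiles
#'
#' Applies the full rule set to each retained taxon: within-species diet
#' compositions are weight-averaged into one profile; across-species diet
#' assignments allocate the taxon's species count across diets (with the
#' predominance rule when a "most species are" descriptor is present);
#' two-stage taxa average larval and adult fractions. With the default
#' midpoint draws the mapping is deterministic (interval categories at their
#' midpoints, predominance at 0.80, adult weight at the range midpoint).
#'
#' @param records Taxon diet record data frame.
#' @param cfg An [uncertainty_config()].
#' @param draws `"midpoint"` for the deterministic point-estimate resolution,
#'   or `"random"` to sample every uncertain quantity from the current RNG
#'   stream.
#' @return Data frame of species trophic profiles with columns `unit_id`,
#'   `taxon_id`, `group`, `weight` (species-equivalents, possibly
#'   fractional), `p` (primary fraction) and `level`.
#' @export
#' @examples
#' rec <- data.frame(taxon_id = "t1", group = "arthropod", rank = "family",
#'                   species_count = 10, stage = "single",
#'                   category = c("phytophagy", "predation"),
#'                   weight = c(60, 40), predominance = NA,
#'                   exclusively_nectivorous = FALSE, aquatic_flag = FALSE,
#'                   fish_pct = NA)
#' species_primary_fraction(rec)  # one profile with p = 0.6 (mixed)
species_primary_fraction <- function(records, cfg = uncertainty_config(),
                                     draws = c("midpoint", "random")) {
  draws <- match.arg(draws)
  compiled <- .compile_records(records, cfg)
  out <- do.call(rbind, lapply(compiled, function(ct) {
    .resolve_taxon(ct, cfg, .taxon_draws(ct, cfg, mode = draws))
  }))
  stopifnot(all(out$p >= -1e-12 & out$p <= 1 + 1e-12))
  out$p <- pmin(pmax(out$p, 0), 1)
  out$level <- classify_level(out$p, cfg$mixed_band)
  rownames(out) <- NULL
  out
}
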