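# Fixture builders shared across test files. All fixtures are constructed in
# code; none are read from disk.

# One record row (or a block of rows for multi-component assignments) in the
# input dialect, with sensible defaults.
record_rows <- function(taxon_id, group = "arthropod", rank = "family",
                        species_count = 10, stage = "single",
                        category = "phytophagy", weight = NA_real_,
                        predominance = NA_character_,
                        exclusively_nectivorous = FALSE,
                        aquatic_flag = FALSE, fish_pct = NA_real_) {
  data.frame(taxon_id = taxon_id, group = group, rank = rank,
             species_count = species_count, stage = stage,
             category = category, weight = weight,
             predominance = predominance,
             exclusively_nectivorous = exclusively_nectivorous,
             aquatic_flag = aquatic_flag, fish_pct = fish_pct,
             stringsAsFactors = FALSE)
}

# A tiny grid: two structure classes, hand-placed species, for exact checks.
tiny_grid <- function() {
  profiles <- data.frame(
    species_id = c("sp1", "sp2", "sp3", "sp4", "sp5"),
    level = c("primary", "primary", "primary", "higher", "mixed"),
    stringsAsFactors = FALSE
  )
  presence <- data.frame(
    species_id = c("sp1", "sp2", "sp3", "sp4",   # pixel a: 3 primary, 1 higher
                   "sp5"),                        # pixel b: 1 mixed
    pixel_id = c("a", "a", "a", "a", "b"),
    stringsAsFactors = FALSE
  )
  pixels <- data.frame(
    pixel_id = c("a", "b"),
    lat = c(0.5, 0.5), lon = c(0.5, 1.5),
    structure_class = c("temperate", "boreal"),
    stringsAsFactors = FALSE
  )
  list(profiles = profiles, presence = presence, pixels = pixels)
}

# Compositions with controllable class separation for discriminant tests:
# n pixels per class, class means given as a list of (primary, mixed, higher).
make_compositions <- function(means, n_per_class, sd = 0.02) {
  rows <- lapply(seq_along(means), function(i) {
    m <- means[[i]]
    props <- t(vapply(seq_len(n_per_class), function(j) {
      x <- pmax(m + stats::rnorm(3, 0, sd), 1e-6)
      x / sum(x)
    }, numeric(3)))
    data.frame(pixel_id = sprintf("c%d_%d", i, seq_len(n_per_class)),
               structure_class = names(means)[i] %||% paste0("class", i),
               p_primary = props[, 1], p_mixed = props[, 2],
               p_higher = props[, 3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$t_primary <- arcsine_sqrt(out$p_primary)
  out$t_mixed <- arcsine_sqrt(out$p_mixed)
  out$t_higher <- arcsine_sqrt(out$p_higher)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
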