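#' Specification of a synthetic deep-pelagic community
#'
#' Collects the generator settings emulating the structure of the study
#' system: ~42 species x 26 mixed-type traits, 3-39 measured individuals per
#' species, four depth layers spanning 20-2000 m with a richness gradient,
#' log-skewed biomass, sparse non-random missingness, and a per-layer
#' assembly mechanism — `"neutral"` (uniform draws from the pool),
#' `"filtered"` (species selected near a layer trait optimum, with the
#' selection kernel's SD shrunk by `filter_strength`) or `"divergent"`
#' (greedy max-min spacing in trait space). The default assembly pattern
#' places filtering in the epipelagic layer and divergence in the
#' bathypelagic layer, the configuration the pipeline is designed to detect.
#'
#' @param n_species Pool size (default 42).
#' @param n_individuals Range (min, max) of measured individuals per species.
#' @param layers Depth-layer table ([pelagic_layers()]).
#' @param richness Species richness per layer (default `c(13, 28, 32, 42)`).
#' @param n_hauls Trawl hauls per layer (default `c(7, 27, 16, 18)`).
#' @param assembly Assembly mode per layer.
#' @param filter_strength SD-shrink factor of the filtering kernel (> 1).
#' @param missing_rate Fraction of raw measurement cells removed, missing at
#'   random conditional on standard length (default 0.01).
#' @param noise_sd Multiplicative (lognormal sdlog) intraspecific measurement
#'   noise.
#' @param sl_noise_sd Multiplicative spread of individual standard length
#'   around the species mean.
#' @param biomass_meanlog,biomass_sdlog Lognormal parameters of a species'
#'   biomass (kg) in a layer.
#' @param seed Master seed; stage seeds are derived as `seed + 1, 2, 3`
#'   (pool, individuals, assemblages).
#' @return Object of class `"community_spec"`.
#' @export
community_spec <- function(n_species = 42, n_individuals = c(3, 39),
                           layers = pelagic_layers(),
                           richness = c(13, 28, 32, 42),
                           n_hauls = c(7, 27, 16, 18),
                           assembly = c("filtered", "neutral", "neutral",
                                        "divergent"),
                           filter_strength = 4, missing_rate = 0.01,
                           noise_sd = 0.07, sl_noise_sd = 0.12,
                           biomass_meanlog = log(0.2), biomass_sdlog = 1.2,
                           seed = 1) {
  stopifnot(n_species >= 1, all(n_individuals >= 1),
            length(richness) == nrow(layers),
            length(n_hauls) == nrow(layers),
            all(assembly %in% c("neutral", "filtered", "divergent")),
            missing_rate >= 0, missing_rate < 1,
            filter_strength > 1, all(n_hauls >= 1))
  if (any(richness > n_species)) stop("layer richness cannot exceed pool size")
  structure(list(
    n_species = n_species, n_individuals = n_individuals, layers = layers,
    richness = richness, n_hauls = n_hauls, assembly = assembly,
    filter_strength = filter_strength, missing_rate = missing_rate,
    noise_sd = noise_sd, sl_noise_sd = sl_noise_sd,
    biomass_meanlog = biomass_meanlog, biomass_sdlog = biomass_sdlog,
    seed = seed
  ), class = "community_spec")
}

#' Generate a species pool of trait archetypes
#'
#' Draws, per species, a mean standard length (lognormal, clipped to the
#' 3-55 cm span of the measured community), a preferred depth with an
#' occupied depth range, raw-morphology archetypes expressed as fractions of
#' standard length (uniform/lognormal families spanning plausible fish body
#' proportions), and categorical traits with depth-trending probabilities
#' (large/fang teeth more likely at depth; small teeth, ventral photophores
#' and well-developed gill rakers more likely in shallow species). Archetype
#' trait values are the [derive_traits()] image of the archetype morphology.
#'
#' Uses the current RNG state; see [simulate_community()] for seeded runs.
#'
#' @param spec A `"community_spec"`.
#' @return List with `archetypes` (data frame of species-level parameters)
#'   and `traits` (species x 26 archetype trait matrix).
#' @export
generate_pool <- function(spec) {
  n <- spec$n_species
  sp <- sprintf("species_%02d", seq_len(n))
  pref <- runif(n, min(spec$layers$depth_min), max(spec$layers$depth_max))
  z <- (pref - min(spec$layers$depth_min)) /
    diff(range(c(spec$layers$depth_min, spec$layers$depth_max)))
  hw <- runif(n, 150, 900)
  a <- data.frame(
    species = sp,
    sl_mean = pmin(pmax(rlnorm(n, log(9), 0.55), 3), 55),
    pref_depth = pref,
    depth_min = pmax(min(spec$layers$depth_min), pref - hw),
    depth_max = pmin(max(spec$layers$depth_max), pref + hw),
    stringsAsFactors = FALSE
  )
  a$frac_body_depth <- exp(runif(n, log(0.12), log(0.35)))
  a$frac_body_width <- a$frac_body_depth * runif(n, 0.35, 0.9)
  a$frac_head_length <- runif(n, 0.18, 0.38)
  a$frac_head_depth <- runif(n, 0.10, 0.28)
  a$frac_eye_diameter <- a$frac_head_depth *
    pmin(runif(n, 0.2, 0.7) * (1.25 - 0.5 * z), 0.95)
  a$frac_eye_height <- a$frac_head_depth * runif(n, 0.25, 0.75)
  a$frac_lower_jaw_length <- runif(n, 0.08, 0.30) * (0.85 + 0.3 * z)
  a$frac_mouth_width <- runif(n, 0.05, 0.18) * (0.8 + 0.5 * z)
  a$frac_mouth_depth <- runif(n, 0.05, 0.22) * (0.8 + 0.5 * z)
  a$frac_operculum_width <- runif(n, 0.03, 0.12)
  a$frac_operculum_depth <- a$frac_operculum_width * runif(n, 0.6, 1.6)
  a$frac_predorsal_length <- runif(n, 0.35, 0.62)
  a$frac_prepectoral_length <- runif(n, 0.20, 0.40)
  a$frac_caudal_peduncle_depth <- runif(n, 0.015, 0.08)
  a$frac_upjaw_bottom_head <- a$frac_head_depth * runif(n, 0.3, 0.95)
  a$frac_pectoral_bottom_body <- a$frac_body_depth * runif(n, 0.2, 0.8)
  a$frac_body_depth_pectoral <- a$frac_body_depth * runif(n, 0.75, 1.1)

  a$chin_barbel <- rbinom(n, 1, 0.15)
  a$fang_teeth <- rbinom(n, 1, plogis(-2.2 + 2.5 * z))
  a$gland_head <- rbinom(n, 1, plogis(-2.5 + 1.5 * z))
  a$internal_teeth <- rbinom(n, 1, 0.3)
  a$large_teeth <- rbinom(n, 1, plogis(-1.8 + 3 * z))
  a$ventral_photophores <- rbinom(n, 1, plogis(1.8 - 2 * z))
  a$retractable_teeth <- rbinom(n, 1, 0.12)
  a$small_teeth <- rbinom(n, 1, plogis(1.2 - 2.5 * z))
  a$gill_raker_type <- vapply(z, function(zi) {
    p_well <- 0.65 - 0.45 * zi
    p_abs <- 0.10 + 0.45 * zi
    sample.int(3, 1, prob = c(p_abs, 1 - p_abs - p_well, p_well))
  }, integer(1))
  a$oral_gape_axis <- vapply(z, function(zi) {
    p <- exp(-(1:5 - (2.6 + 0.8 * zi))^2 / 2)
    sample.int(5, 1, prob = p / sum(p))
  }, integer(1))

  raw <- archetype_raw(a)
  traits <- derive_traits(raw)
  mat <- as.matrix(traits[names(trait_kinds())])
  rownames(mat) <- traits$species
  attr(mat, "kinds") <- trait_kinds()
  list(archetypes = a, traits = mat)
}

# materialize the raw morphometric record implied by archetype fractions
archetype_raw <- function(a, sl = a$sl_mean) {
  frac_cols <- grep("^frac_", names(a), value = TRUE)
  raw <- data.frame(
    individual_id = a$species, species = a$species,
    capture_depth = a$pref_depth, standard_length = sl,
    stringsAsFactors = FALSE
  )
  for (fc in frac_cols) raw[[sub("^frac_", "", fc)]] <- a[[fc]] * sl
  kinds <- trait_kinds()
  for (tr in names(kinds)[kinds != "continuous"]) raw[[tr]] <- a[[tr]]
  raw
}

#' Generate individual-level morphometric records
#'
#' Draws, per species, a number of individuals within the configured range,
#' individual standard lengths around the species mean, raw measurements as
#' archetype fraction x standard length x multiplicative lognormal noise
#' (so [derive_traits()] recovers the archetype means), and capture depths
#' within the species depth range. Missing cells are then injected at
#' exactly `round(missing_rate * n_cells)` raw-measurement cells, sampled
#' with probability inversely proportional to standard length (small fish
#' lose measurements more often — missing at random conditional on size).
#'
#' @param pool Output of [generate_pool()].
#' @param spec The `"community_spec"`.
#' @return Data frame of raw morphometric records, one row per individual.
#' @export
generate_individuals <- function(pool, spec) {
  a <- pool$archetypes
  counts <- sample(seq(spec$n_individuals[1], spec$n_individuals[2]),
                   nrow(a), replace = TRUE)
  rows <- lapply(seq_len(nrow(a)), function(i) {
    k <- counts[i]
    ai <- a[rep(i, k), , drop = FALSE]
    sl <- a$sl_mean[i] * rlnorm(k, 0, spec$sl_noise_sd)
    raw <- archetype_raw(ai, sl = sl)
    meas <- raw_measurements()
    noise <- matrix(rlnorm(k * length(meas), 0, spec$noise_sd), k)
    raw[meas] <- raw[meas] * noise
    raw$capture_depth <- runif(k, a$depth_min[i], a$depth_max[i])
    raw$individual_id <- sprintf("%s_ind%02d", a$species[i], seq_len(k))
    raw
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_remove <- round(spec$missing_rate * nrow(out) * length(raw_measurements()))
  if (n_remove > 0) {
    cells <- expand.grid(row = seq_len(nrow(out)), col = raw_measurements(),
                         stringsAsFactors = FALSE)
    wcell <- 1 / out$standard_length[cells$row]
    take <- sample.int(nrow(cells), n_remove, prob = wcell)
    for (i in take) out[cells$row[i], cells$col[i]] <- NA
  }
  out
}

# greedy max-min selection of s rows from a dissimilarity matrix
maxmin_select <- function(dm, s) {
  n <- nrow(dm)
  start <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  sel <- as.integer(start)
  while (length(sel) < s) {
    cand <- setdiff(seq_len(n), sel)
    mind <- apply(dm[cand, sel, drop = FALSE], 1, min)
    sel <- c(sel, cand[which.max(mind)])
  }
  sort(sel)
}

#' Generate layer assemblages, trawl hauls and catches
#'
#' Chooses each layer's member species from the pool according to its
#' assembly mode (neutral: uniform; filtered: Gaussian kernel on Gower
#' distance to a randomly chosen layer-optimum species, kernel SD = pool
#' dissimilarity SD / `filter_strength`; divergent: greedy max-min Gower
#' spacing), draws lognormal species biomasses per layer, and scatters them
#' over the layer's trawl hauls (standard gear: 24 m x 58 m mouth, 7408 m
#' towed). Every member species is caught in at least one haul.
#'
#' @inheritParams generate_individuals
#' @return List: `membership` (list of species per layer), `biomass`
#'   (layer x species kg matrix), `hauls`, `catches` (CSV-ready data frames),
#'   `occurrences` (species x depth records from the catches) and `truth`
#'   (assembly modes and filtering optima per layer).
#' @export
generate_assemblages <- function(pool, spec) {
  gd <- gower_dist(pool$traits)
  sigma <- sd(gd[lower.tri(gd)]) / spec$filter_strength
  layers <- spec$layers
  membership <- list()
  optima <- list()
  biomass <- matrix(0, nrow(layers), nrow(pool$traits),
                    dimnames = list(layers$layer, rownames(pool$traits)))
  hauls <- list()
  catches <- list()
  for (l in seq_len(nrow(layers))) {
    s_l <- spec$richness[l]
    mode <- spec$assembly[l]
    members <- select_members(gd, s_l, mode, spec$filter_strength)
    opt <- attr(members, "optimum")
    optima[[layers$layer[l]]] <- if (is.null(opt)) NA_character_ else
      rownames(gd)[opt]
    sp <- rownames(gd)[members]
    b <- rlnorm(s_l, spec$biomass_meanlog, spec$biomass_sdlog)
    biomass[l, sp] <- b
    st <- sprintf("st_%s_%02d", substr(layers$layer[l], 1, 3),
                  seq_len(spec$n_hauls[l]))
    hauls[[l]] <- data.frame(
      station_id = st,
      immersion_depth = runif(spec$n_hauls[l], layers$depth_min[l],
                              layers$depth_max[l]),
      vertical_opening = 24, horizontal_opening = 58,
      distance_trawled = 1852 * 4, stringsAsFactors = FALSE
    )
    for (k in seq_along(sp)) {
      occ <- which(runif(spec$n_hauls[l]) < 0.6)
      if (!length(occ)) occ <- sample.int(spec$n_hauls[l], 1)
      prop <- rexp(length(occ))
      catches[[length(catches) + 1]] <- data.frame(
        station_id = st[occ], species = sp[k],
        mass_kg = b[k] * prop / sum(prop), stringsAsFactors = FALSE
      )
    }
    membership[[layers$layer[l]]] <- sp
  }
  hauls <- do.call(rbind, hauls)
  catches <- do.call(rbind, catches)
  occ <- merge(catches, hauls[c("station_id", "immersion_depth")],
               by = "station_id")
  occurrences <- data.frame(species = occ$species,
                            depth = occ$immersion_depth,
                            station_id = occ$station_id,
                            stringsAsFactors = FALSE)
  list(membership = membership, biomass = biomass, hauls = hauls,
       catches = catches, occurrences = occurrences,
       truth = list(assembly = setNames(spec$assembly, layers$layer),
                    optima = optima, filter_sigma = sigma))
}

#' Simulate a full synthetic community data set
#'
#' End-to-end seeded generation: species pool, individual morphometric
#' records (with injected missingness) and layer assemblages with trawl hauls
#' and catches, in the CSV dialects the ingest and traits modules read.
#' Deterministic under the spec's master seed (stage seeds `seed + 1, 2, 3`).
#'
#' @param spec A `"community_spec"` (default settings emulate the study
#'   system).
#' @return List: `spec`, `pool`, `individuals`, `hauls`, `catches`,
#'   `membership`, `biomass`, `occurrences`, `truth`.
#' @export
simulate_community <- function(spec = community_spec()) {
  set.seed(spec$seed + 1)
  pool <- generate_pool(spec)
  set.seed(spec$seed + 2)
  individuals <- generate_individuals(pool, spec)
  set.seed(spec$seed + 3)
  asm <- generate_assemblages(pool, spec)
  c(list(spec = spec, pool = pool, individuals = individuals), asm)
}
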