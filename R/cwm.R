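#' Community-weighted mean of a trait
#'
#' Biomass-weighted mean `sum_i w_i t_i` over the species present. For binary
#' traits this is the biomass-weighted proportion of species showing the
#' trait. The two nominal-use ordinal traits (gill raker type, oral gape
#' axis) are excluded when a full trait matrix is supplied.
#'
#' @param traits Either a numeric vector (one trait value per species) or a
#'   species x trait matrix; rows/elements must align with `w` (matched by
#'   name when both are named).
#' @param w Biomass weights (normalized internally).
#' @return A weighted mean (or a named vector over the non-ordinal traits).
#' @export
cwm_point <- function(traits, w) {
  w <- normalize_weights(w)
  if (is.matrix(traits) || is.data.frame(traits)) {
    traits <- as.matrix(traits)
    if (!is.null(rownames(traits)) && !is.null(names(w))) {
      traits <- traits[names(w), , drop = FALSE]
    }
    kinds <- trait_kinds()[colnames(traits)]
    keep <- is.na(kinds) | kinds != "ordinal"
    return(colSums(traits[, keep, drop = FALSE] * w))
  }
  if (!is.null(names(traits)) && !is.null(names(w))) {
    traits <- traits[names(w)]
  }
  sum(traits * w)
}

#' Bootstrapped community-weighted trait means
#'
#' Nonparametric bootstrap of the CWM at one sampling depth using
#' individual-level trait values: each of `n_boot` draws resamples
#' `sample_size` individuals with replacement, with selection probability
#' proportional to the species' biomass at that depth (spread uniformly over
#' the species' available individuals), and takes the mean trait value.
#' Species with biomass but no measured individuals are excluded from the
#' depth with a warning.
#'
#' @param individuals Data frame of individual trait values with a `species`
#'   column (e.g. from [derive_traits()] after imputation); supply
#'   depth-specific individuals when available, the species-wide pool
#'   otherwise.
#' @param biomass Named biomass vector (one entry per species present at the
#'   depth).
#' @param traits Trait columns to bootstrap (default: all non-ordinal traits
#'   present in `individuals`).
#' @param n_boot Number of bootstrap draws (default 999).
#' @param sample_size Individuals resampled per draw (default 200).
#' @param seed Integer seed.
#' @return Object of class `"cwm_distribution"`: list with `boot` (n_boot x
#'   traits matrix of bootstrap means), `summary` (data frame: trait, mean,
#'   ci_low, ci_high), `n_boot`, `sample_size`, `species_used`.
#' @export
cwm_bootstrap <- function(individuals, biomass, traits = NULL, n_boot = 999,
                          sample_size = 200, seed = 1) {
  if (is.null(traits)) {
    kinds <- trait_kinds()
    traits <- intersect(names(kinds)[kinds != "ordinal"], names(individuals))
  }
  sp <- names(biomass)
  have <- sp[sp %in% individuals$species]
  if (length(have) < length(sp)) {
    warning("no measured individuals for: ",
            paste(setdiff(sp, have), collapse = ", "),
            "; excluded from this depth")
  }
  if (!length(have)) stop("no species with measured individuals")
  pool <- individuals[individuals$species %in% have, , drop = FALSE]
  wsp <- normalize_weights(biomass[have])
  n_ind <- table(pool$species)[pool$species]
  p <- as.numeric(wsp[pool$species] / n_ind)
  x <- as.matrix(pool[traits])
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(traits),
                 dimnames = list(NULL, traits))
  for (b in seq_len(n_boot)) {
    take <- sample.int(nrow(x), sample_size, replace = TRUE, prob = p)
    boot[b, ] <- colMeans(x[take, , drop = FALSE])
  }
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), type = 7)
  structure(list(
    boot = boot,
    summary = data.frame(trait = traits, mean = colMeans(boot),
                         ci_low = ci[1, ], ci_high = ci[2, ],
                         row.names = NULL, stringsAsFactors = FALSE),
    n_boot = n_boot, sample_size = sample_size, species_used = have
  ), class = "cwm_distribution")
}

#' @export
print.cwm_distribution <- function(x, ...) {
  cat(sprintf("Bootstrapped CWM: %d draws of %d individuals, %d species\n",
              x$n_boot, x$sample_size, length(x$species_used)))
  print(cbind(x$summary[1], round(x$summary[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' PCA of depth-layer median CWM profiles
#'
#' Principal component analysis of the layer x trait matrix of median CWM
#' values (columns centred and scaled to unit variance), identifying the
#' dominant community trait profiles along the depth gradient. Constant trait
#' columns are dropped with a warning; with L layers at most L - 1 components
#' are non-null.
#'
#' @param x Layer x trait numeric matrix of median CWM values (no missing
#'   cells).
#' @return List with `loadings` (trait x component), `scores` (layer x
#'   component) and `pct_var` (percent variance per component, summing to 100
#'   over non-null components).
#' @export
cwm_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 layers and 2 traits")
  if (anyNA(x)) stop("median CWM matrix must be complete")
  constant <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(constant)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
  }
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  varc <- fit$sdev^2
  keep <- varc > 1e-12 * sum(varc)
  list(loadings = fit$rotation[, keep, drop = FALSE],
       scores = fit$x[, keep, drop = FALSE],
       pct_var = 100 * varc[keep] / sum(varc))
}

#' Functional uniqueness
#'
#' `U_i = min_{j != i} d_ij`: the smallest trait dissimilarity between a
#' species and any other community member. Species carrying a trait
#' combination no other species approaches score high.
#'
#' @param d Square dissimilarity matrix (>= 2 species).
#' @return Named numeric vector of uniqueness values.
#' @export
uniqueness <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 2) stop("need at least 2 species")
  diag(dm) <- Inf
  apply(dm, 1, min)
}

#' Depth-range restrictedness
#'
#' `R_i = 1 - (species depth extent) / (total sampled extent)`, clipped to
#' \[0, 1\]. A species spanning the whole sampled column scores 0; a species
#' seen at a single depth scores 1 (flagged). An occupied-stations variant
#' (`method = "stations"`) uses 1 minus the fraction of sampled stations
#' occupied instead.
#'
#' @param occurrences Data frame with `species` and `depth` columns (one row
#'   per occurrence), plus `station_id` when `method = "stations"`.
#' @param extent Total sampled depth range, m (default `c(20, 2000)`).
#' @param method `"extent"` (depth range, default) or `"stations"`.
#' @param n_stations Total number of sampled stations (required for the
#'   stations variant).
#' @return Data frame: `species`, `restrictedness`, `flag` (`"single_depth"`
#'   where the extent is zero).
#' @export
restrictedness <- function(occurrences, extent = c(20, 2000),
                           method = c("extent", "stations"),
                           n_stations = NULL) {
  method <- match.arg(method)
  spl <- split(occurrences, occurrences$species)
  total <- diff(range(extent))
  out <- do.call(rbind, lapply(names(spl), function(s) {
    o <- spl[[s]]
    if (method == "extent") {
      ext <- max(o$depth) - min(o$depth)
      r <- min(max(1 - ext / total, 0), 1)
      flag <- if (ext == 0) "single_depth" else NA_character_
    } else {
      if (is.null(n_stations)) stop("n_stations required for stations variant")
      r <- 1 - length(unique(o$station_id)) / n_stations
      flag <- NA_character_
    }
    data.frame(species = s, restrictedness = r, flag = flag,
               stringsAsFactors = FALSE)
  }))
  out[order(out$species), , drop = FALSE]
}

#' Functional rarity: uniqueness versus restrictedness
#'
#' Combines [uniqueness()] and [restrictedness()] and flags, for each
#' species, whether it lies above the community median of each index — the
#' most functionally rare species combine high uniqueness with high
#' restrictedness.
#'
#' @param d Species dissimilarity matrix.
#' @param occurrences Occurrence table (see [restrictedness()]).
#' @param extent Total sampled depth range.
#' @return Data frame: `species`, `uniqueness`, `restrictedness`,
#'   `above_median_uniqueness`, `above_median_restrictedness`, `flag`.
#' @export
functional_rarity <- function(d, occurrences, extent = c(20, 2000)) {
  u <- uniqueness(d)
  r <- restrictedness(occurrences, extent)
  out <- merge(data.frame(species = names(u), uniqueness = unname(u),
                          stringsAsFactors = FALSE), r, by = "species")
  out$above_median_uniqueness <- out$uniqueness > median(out$uniqueness)
  out$above_median_restrictedness <-
    out$restrictedness > median(out$restrictedness)
  out[order(out$species),
      c("species", "uniqueness", "restrictedness",
        "above_median_uniqueness", "above_median_restrictedness", "flag")]
}
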