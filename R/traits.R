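#' The 26-trait registry
#'
#' Names and measurement kinds of the 26 foraging-related traits: 16
#' continuous (mostly size-standardized ratios; caudal throttle width and gill
#' outflow are absolute measures in cm), 2 ordinal and 8 binary
#' (presence/absence). Ordinal traits are encoded as integer ranks:
#' `gill_raker_type` 1 = absent/rudimentary, 2 = low-developed,
#' 3 = well-developed; `oral_gape_axis` 1 = superior, 2 = supraterminal,
#' 3 = terminal, 4 = subterminal, 5 = inferior.
#'
#' @return Named character vector mapping trait name to
#'   `"continuous"`, `"ordinal"` or `"binary"`.
#' @export
trait_kinds <- function() {
  c(
    body_depth = "continuous", caudal_throttle_width = "continuous",
    dorsal_fin_insertion = "continuous", eye_position = "continuous",
    eye_size = "continuous", gill_outflow = "continuous",
    head_length = "continuous", lower_jaw_length = "continuous",
    operculum_volume = "continuous", oral_gape_position = "continuous",
    oral_gape_shape = "continuous", oral_gape_surface = "continuous",
    orbital_length = "continuous", pectoral_fin_insertion = "continuous",
    pectoral_fin_position = "continuous", transversal_shape = "continuous",
    gill_raker_type = "ordinal", oral_gape_axis = "ordinal",
    chin_barbel = "binary", fang_teeth = "binary", gland_head = "binary",
    internal_teeth = "binary", large_teeth = "binary",
    ventral_photophores = "binary", retractable_teeth = "binary",
    small_teeth = "binary"
  )
}

# raw linear measurement columns a morphometric record may carry (cm)
raw_measurements <- function() {
  c("body_depth", "body_width", "head_length", "head_depth", "eye_diameter",
    "eye_height", "lower_jaw_length", "mouth_width", "mouth_depth",
    "operculum_width", "operculum_depth", "predorsal_length",
    "prepectoral_length", "caudal_peduncle_depth", "upjaw_bottom_head",
    "pectoral_bottom_body", "body_depth_pectoral")
}

ordinal_levels <- function() {
  list(
    gill_raker_type = c("absent_rudimentary", "low_developed",
                        "well_developed"),
    oral_gape_axis = c("superior", "supraterminal", "terminal", "subterminal",
                       "inferior")
  )
}

safe_ratio <- function(num, den, what) {
  bad <- !is.na(den) & den == 0
  if (any(bad)) {
    warning(sprintf("zero denominator in %s for %d record(s); emitted missing",
                    what, sum(bad)))
    den[bad] <- NA
  }
  num / den
}

#' Derive the 26 foraging traits from raw morphometric measurements
#'
#' Computes, per individual, the 16 continuous traits from raw linear
#' measurements (ratios standardized by standard length, head depth, body
#' dimensions, etc.; caudal throttle width and gill outflow are carried over
#' as absolute measures), recodes the two ordinal traits as integer ranks and
#' passes the 8 binary observations through. A trait whose inputs are missing
#' is emitted missing; a zero denominator yields a missing cell with a logged
#' anomaly.
#'
#' @param records Data frame with columns `individual_id`, `species`,
#'   `capture_depth`, `standard_length` (cm, required for every individual),
#'   the raw linear measurements (cm; see Details) and the categorical /
#'   binary observation columns named as in [trait_kinds()].
#' @details Raw measurement columns: `body_depth`, `body_width`,
#'   `head_length`, `head_depth`, `eye_diameter`, `eye_height`,
#'   `lower_jaw_length`, `mouth_width`, `mouth_depth`, `operculum_width`,
#'   `operculum_depth`, `predorsal_length`, `prepectoral_length`,
#'   `caudal_peduncle_depth`, `upjaw_bottom_head` (upper jaw to bottom of
#'   head), `pectoral_bottom_body` (pectoral insertion to bottom of body) and
#'   `body_depth_pectoral` (body depth at the pectoral insertion). Ordinal
#'   columns may hold either level labels or integer ranks.
#' @return Data frame with `individual_id`, `species`, `capture_depth`,
#'   `standard_length` and the 26 trait columns (ordinals as integer ranks,
#'   binaries as 0/1).
#' @export
derive_traits <- function(records) {
  if (is.null(records$standard_length) || anyNA(records$standard_length)) {
    stop("standard_length must be present for every individual")
  }
  r <- records
  out <- data.frame(
    individual_id = r$individual_id, species = r$species,
    capture_depth = r$capture_depth, standard_length = r$standard_length,
    stringsAsFactors = FALSE
  )
  sl <- r$standard_length
  out$body_depth <- r$body_depth / sl
  out$caudal_throttle_width <- r$caudal_peduncle_depth
  out$dorsal_fin_insertion <- r$predorsal_length / sl
  out$eye_position <- safe_ratio(r$eye_height, r$head_depth, "eye_position")
  out$eye_size <- safe_ratio(r$eye_diameter, r$head_depth, "eye_size")
  out$gill_outflow <- r$operculum_width
  out$head_length <- r$head_length / sl
  out$lower_jaw_length <- r$lower_jaw_length / sl
  out$operculum_volume <- safe_ratio(r$operculum_depth, r$operculum_width,
                                     "operculum_volume")
  out$oral_gape_position <- safe_ratio(r$upjaw_bottom_head, r$head_depth,
                                       "oral_gape_position")
  out$oral_gape_shape <- safe_ratio(r$mouth_depth, r$mouth_width,
                                    "oral_gape_shape")
  out$oral_gape_surface <- safe_ratio(r$mouth_width * r$mouth_depth,
                                      r$body_width * r$body_depth,
                                      "oral_gape_surface")
  out$orbital_length <- r$eye_diameter / sl
  out$pectoral_fin_insertion <- r$prepectoral_length / sl
  out$pectoral_fin_position <- safe_ratio(r$pectoral_bottom_body,
                                          r$body_depth_pectoral,
                                          "pectoral_fin_position")
  out$transversal_shape <- safe_ratio(r$body_depth, r$body_width,
                                      "transversal_shape")
  for (tr in names(ordinal_levels())) {
    v <- r[[tr]]
    if (is.numeric(v)) {
      out[[tr]] <- as.integer(v)
    } else {
      out[[tr]] <- as.integer(factor(as.character(v),
                                     levels = ordinal_levels()[[tr]]))
    }
  }
  kinds <- trait_kinds()
  for (tr in names(kinds)[kinds == "binary"]) {
    v <- r[[tr]]
    if (is.character(v) || is.logical(v)) v <- as.integer(v %in% c("P", "1", TRUE))
    out[[tr]] <- as.integer(v)
  }
  out
}

#' Exclude species with too many wholly unmeasured traits
#'
#' A trait counts as missing for a species when no individual of that species
#' has an observed value for it. Species whose fraction of missing traits
#' exceeds `threshold` are dropped (e.g. 7 of 26 traits, 26.9%, exceeds the
#' default 25%).
#'
#' @param traits Individual trait table from [derive_traits()].
#' @param threshold Exclusion threshold as a fraction in (0, 1).
#' @return List with `traits` (retained rows) and `excluded` (data frame of
#'   species and their missing-trait fractions).
#' @export
exclude_sparse_species <- function(traits, threshold = 0.25) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)")
  }
  tn <- names(trait_kinds())
  frac <- vapply(split(traits[tn], traits$species), function(tt) {
    mean(vapply(tt, function(col) all(is.na(col)), logical(1)))
  }, numeric(1))
  drop <- names(frac)[frac > threshold]
  list(
    traits = traits[!traits$species %in% drop, , drop = FALSE],
    excluded = data.frame(species = drop,
                          missing_fraction = unname(frac[drop]),
                          stringsAsFactors = FALSE)
  )
}

# one chained-equation sweep over the incomplete columns of `x`
# x: numeric matrix (ordinals as ranks, binaries 0/1); miss: logical matrix of
# originally-missing cells; k: donor pool size
pmm_sweep <- function(x, miss, k, binary_cols) {
  for (j in which(colSums(miss) > 0)) {
    obs <- !miss[, j]
    df <- as.data.frame(x[, -j, drop = FALSE])
    fit <- suppressWarnings(lm(x[obs, j] ~ ., data = df[obs, , drop = FALSE]))
    pred <- suppressWarnings(predict(fit, newdata = df))
    p_obs <- pred[obs]
    y_obs <- x[obs, j]
    for (i in which(miss[, j])) {
      d <- abs(p_obs - pred[i])
      donors <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
      if (j %in% binary_cols) {
        # nearest-donor class: majority among the k nearest donors
        x[i, j] <- as.numeric(mean(y_obs[donors]) >= 0.5)
      } else {
        x[i, j] <- y_obs[donors[sample.int(length(donors), 1)]]
      }
    }
  }
  x
}

#' Impute missing trait cells by chained equations
#'
#' Multivariate imputation by chained equations with predictive mean matching
#' (PMM): in each of `iterations` sweeps, every incomplete column is regressed
#' on all other trait columns and each missing cell is filled from the
#' observed value of a donor drawn among the `k` nearest predictions
#' (continuous/ordinal: one donor sampled; binary: majority class of the `k`
#' nearest donors). `m` independent chains are run and pooled: mean across
#' chains for continuous traits, majority vote (median rank) for ordinal and
#' binary traits. Observed cells are never altered.
#'
#' @param traits Individual trait table from [derive_traits()].
#' @param m Number of chains (default 5).
#' @param iterations Sweeps per chain (default 50).
#' @param k PMM donor pool size (default 5).
#' @param seed Integer master seed; chain `c` is seeded `seed + c`.
#' @return The completed trait table, with an `"imputation_log"` attribute
#'   listing each imputed cell (row, trait) and the per-chain values.
#' @export
impute_missing <- function(traits, m = 5, iterations = 50, k = 5, seed = 1) {
  tn <- names(trait_kinds())
  x0 <- as.matrix(traits[tn])
  storage.mode(x0) <- "double"
  miss <- is.na(x0)
  if (!any(miss)) return(traits)
  empty <- colnames(x0)[colSums(!miss) == 0]
  if (length(empty)) {
    stop("cannot impute column(s) with no observed values: ",
         paste(empty, collapse = ", "))
  }
  if (any(colMeans(miss) >= 0.5)) {
    stop("per-column missingness must stay below 50%")
  }
  kinds <- trait_kinds()[tn]
  binary_cols <- which(kinds == "binary")
  categorical <- kinds != "continuous"

  chains <- vector("list", m)
  for (ch in seq_len(m)) {
    set.seed(seed + ch)
    x <- x0
    for (j in which(colSums(miss) > 0)) {  # initialize from observed margins
      x[miss[, j], j] <- sample(x[!miss[, j], j], sum(miss[, j]),
                                replace = TRUE)
    }
    for (it in seq_len(iterations)) x <- pmm_sweep(x, miss, k, binary_cols)
    chains[[ch]] <- x
  }

  cells <- which(miss, arr.ind = TRUE)
  vals <- sapply(chains, function(x) x[cells])
  if (nrow(cells) == 1) vals <- matrix(vals, nrow = 1)
  pooled <- vapply(seq_len(nrow(cells)), function(r) {
    if (categorical[cells[r, 2]]) round(median(vals[r, ])) else
      mean(vals[r, ])
  }, numeric(1))
  res <- traits
  for (r in seq_len(nrow(cells))) {
    j <- tn[cells[r, 2]]
    v <- pooled[r]
    res[[j]][cells[r, 1]] <- if (is.integer(res[[j]])) as.integer(v) else v
  }
  log <- data.frame(row = cells[, 1], trait = tn[cells[, 2]],
                    pooled = pooled, stringsAsFactors = FALSE)
  log <- cbind(log, as.data.frame(vals))
  names(log)[-(1:3)] <- paste0("chain", seq_len(m))
  attr(res, "imputation_log") <- log
  res
}

#' Summarise individual traits to a species x trait matrix
#'
#' Continuous traits are averaged over a species' individuals; ordinal traits
#' take the median rank; binary traits are aggregated by majority vote.
#' Standard-length mean and SD and the individual count are recorded per
#' species as the `"meta"` attribute.
#'
#' @param traits Complete individual trait table (post-imputation).
#' @return Numeric species x 26 matrix (rownames: species, sorted) with
#'   attributes `"meta"` (data frame: species, n_individuals, sl_mean, sl_sd)
#'   and `"kinds"` (the [trait_kinds()] vector).
#' @export
summarise_species <- function(traits) {
  tn <- names(trait_kinds())
  if (anyNA(traits[tn])) stop("trait table must be complete; impute first")
  kinds <- trait_kinds()
  sp <- sort(unique(traits$species))
  rows <- lapply(sp, function(s) {
    tt <- traits[traits$species == s, tn, drop = FALSE]
    vapply(tn, function(j) {
      switch(kinds[[j]],
        continuous = mean(tt[[j]]),
        ordinal = round(median(tt[[j]])),
        binary = as.numeric(mean(tt[[j]]) >= 0.5)
      )
    }, numeric(1))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- sp
  meta <- do.call(rbind, lapply(sp, function(s) {
    sl <- traits$standard_length[traits$species == s]
    data.frame(species = s, n_individuals = length(sl), sl_mean = mean(sl),
               sl_sd = if (length(sl) > 1) sd(sl) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(mat, "meta") <- meta
  attr(mat, "kinds") <- kinds
  mat
}
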