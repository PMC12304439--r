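#' Trait-randomization null draws
#'
#' Draws, for each of `n_sim` null assemblages, `s` whole trait vectors
#' (functional-space coordinate rows) with replacement from the full species
#' pool, simulating a null in which species traits are independent of their
#' ecological (depth) distribution. Observed biomass weights stay attached to
#' the assemblage slots in order. Alternatively, `per_trait = TRUE` shuffles
#' each trait axis independently, breaking trait covariance.
#'
#' Uses the current RNG state; seed upstream (e.g. [fd_ses()]'s `seed`) for
#' reproducibility.
#'
#' @param pool_size Number of species in the randomization pool.
#' @param s Assemblage richness (number of slots to fill).
#' @param n_sim Number of null draws (default 999).
#' @param per_trait If `TRUE`, return an array of independently shuffled
#'   indices per axis instead of whole-row draws.
#' @param n_axes Number of axes, required when `per_trait = TRUE`.
#' @return An `s x n_sim` integer matrix of pool row indices (or an
#'   `s x n_sim x n_axes` array when `per_trait = TRUE`).
#' @export
randomize_traits <- function(pool_size, s, n_sim = 999, per_trait = FALSE,
                             n_axes = NULL) {
  if (pool_size < 1) stop("empty species pool")
  if (!per_trait) {
    return(matrix(sample.int(pool_size, s * n_sim, replace = TRUE), s, n_sim))
  }
  if (is.null(n_axes)) stop("n_axes required for per-trait shuffling")
  array(sample.int(pool_size, s * n_sim * n_axes, replace = TRUE),
        dim = c(s, n_sim, n_axes))
}

#' Standardized effect size
#'
#' `SES = (observed - mean(simulated)) / sd(simulated)` with the n-1
#' denominator in the SD. Negative values indicate the observed index is
#' lower than the null expectation (trait convergence / environmental
#' filtering); positive values indicate divergence (limiting similarity).
#'
#' @param observed Observed index value.
#' @param simulated Numeric vector of null index values (>= 2, non-zero
#'   spread).
#' @return The SES (dimensionless).
#' @export
ses <- function(observed, simulated) {
  simulated <- simulated[is.finite(simulated)]
  if (length(simulated) < 2) stop("need at least 2 simulated values")
  s <- sd(simulated)
  if (s == 0) stop("degenerate null: simulated values have zero spread")
  (observed - mean(simulated)) / s
}

#' Normality and symmetry assessment of a null distribution
#'
#' Shapiro-Wilk test at level `alpha`; if rejected and all values are
#' positive, the values are log-transformed and retested. The adjusted
#' Fisher-Pearson skewness is reported on the working scale (the scale that
#' passed normality, or the last scale tried), with `|skewness| > 1` flagged
#' as largely asymmetric.
#'
#' @param simulated Null index values (n >= 3).
#' @param alpha Significance level for the Shapiro-Wilk test.
#' @return List: `normal` (logical), `transform` (`"none"` or `"log"`),
#'   `shapiro_p` (on the working scale), `skewness`, `asymmetric`.
#' @export
assess_distribution <- function(simulated, alpha = 0.05) {
  x <- simulated[is.finite(simulated)]
  if (length(x) < 3) stop("need at least 3 simulated values")
  p_raw <- shapiro.test(x)$p.value
  if (p_raw >= alpha) {
    sk <- e1071::skewness(x, type = 2)
    return(list(normal = TRUE, transform = "none", shapiro_p = p_raw,
                skewness = sk, asymmetric = abs(sk) > 1))
  }
  if (all(x > 0)) {
    lx <- log(x)
    p_log <- shapiro.test(lx)$p.value
    sk <- e1071::skewness(lx, type = 2)
    return(list(normal = p_log >= alpha, transform = "log",
                shapiro_p = p_log, skewness = sk, asymmetric = abs(sk) > 1))
  }
  sk <- e1071::skewness(x, type = 2)
  list(normal = FALSE, transform = "none", shapiro_p = p_raw, skewness = sk,
       asymmetric = abs(sk) > 1)
}

#' Significance decision for an observed index against its null
#'
#' Gaussian pathway when the (possibly log-transformed) null values pass
#' normality: significant iff `|SES| > threshold` (SES computed on the
#' working scale). Otherwise the percentile pathway: significant iff the
#' observed value falls outside the central percentile interval of the null
#' values (linear-interpolation quantiles).
#'
#' @param observed Observed index value.
#' @param simulated Null index values.
#' @param assessment Result of [assess_distribution()] (recomputed when
#'   omitted).
#' @param threshold Gaussian SES cutoff (default 1.96).
#' @param probs Percentile bounds (default 2.5% and 97.5%).
#' @return List: `ses` (working scale), `pathway`
#'   (`"gaussian"`/`"percentile"`), `significant`, `lower`, `upper`
#'   (percentile bounds on the raw scale), plus the assessment fields.
#' @export
ses_significance <- function(observed, simulated, assessment = NULL,
                             threshold = 1.96, probs = c(0.025, 0.975)) {
  if (is.null(assessment)) assessment <- assess_distribution(simulated)
  work_obs <- observed
  work_sim <- simulated
  if (assessment$transform == "log" && assessment$normal) {
    if (observed <= 0) stop("cannot log-transform a non-positive observed value")
    work_obs <- log(observed)
    work_sim <- log(simulated)
  }
  z <- ses(work_obs, work_sim)
  bounds <- quantile(simulated, probs, type = 7, names = FALSE)
  if (assessment$normal) {
    sig <- abs(z) > threshold
    pathway <- "gaussian"
  } else {
    sig <- observed < bounds[1] || observed > bounds[2]
    pathway <- "percentile"
  }
  c(list(ses = z, pathway = pathway, significant = sig,
         lower = bounds[1], upper = bounds[2]), assessment)
}

null_index_values <- function(index, coords, w, idx) {
  n_sim <- ncol(idx)
  if (index == "fric") {
    return(.cpp_hull_volumes(coords, idx))
  }
  vapply(seq_len(n_sim), function(b) {
    pts <- coords[idx[, b], , drop = FALSE]
    switch(index,
      feve = fd_feve(pts, w),
      fdis = fd_fdis(pts, w),
      fdiv = tryCatch(fd_fdiv(pts, w), error = function(e) NA_real_)
    )
  }, numeric(1))
}

observed_index_value <- function(index, space, present, w, m) {
  switch(index,
    fric = fd_fric(space, species = present, m = m)$volume,
    feve = fd_feve(space, w, species = present, m = m),
    fdis = fd_fdis(space, w, species = present, m = m),
    fdiv = fd_fdiv(space, w, species = present, m = m)
  )
}

#' Null-model SES inference for functional diversity indices
#'
#' For each assemblage and index, computes the observed value, generates
#' `n_sim` trait-randomized null assemblages ([randomize_traits()]: whole
#' coordinate rows resampled with replacement from the full species pool,
#' biomass weights held fixed), and runs the SES significance decision tree
#' ([ses_significance()]). Null draws whose deduplicated points cannot span
#' the space (possible under resampling with replacement) are dropped from
#' that null distribution.
#'
#' @param space A `"functional_space"` object (the randomization pool is all
#'   species in the space).
#' @param assemblages Assemblage x species biomass matrix; zero = absent.
#' @param indices Which indices to test (default all four).
#' @param n_sim Number of null draws (default 999).
#' @param seed Integer seed (one RNG stream across assemblages and indices).
#' @param threshold Gaussian SES cutoff (default 1.96).
#' @param alpha Shapiro-Wilk level (default 0.05).
#' @param keep_null If `TRUE`, attach the null draws for audit.
#' @return Object of class `"fd_ses"`: data frame with one row per
#'   assemblage x index (`observed`, `mean_sim`, `sd_sim`, `ses`,
#'   `shapiro_p`, `skewness`, `transform`, `pathway`, `significant`,
#'   `lower`, `upper`, `n_sim_used`).
#' @export
fd_ses <- function(space, assemblages, indices = c("fric", "feve", "fdis",
                                                   "fdiv"),
                   n_sim = 999, seed = 1, threshold = 1.96, alpha = 0.05,
                   keep_null = FALSE) {
  indices <- match.arg(indices, several.ok = TRUE)
  assemblages <- as.matrix(assemblages)
  pool <- space$coords[, seq_len(space$m), drop = FALSE]
  set.seed(seed)
  nulls <- list()
  rows <- list()
  for (a in rownames(assemblages)) {
    wfull <- assemblages[a, ]
    present <- colnames(assemblages)[wfull > 0]
    w <- normalize_weights(wfull[present])
    idx <- randomize_traits(nrow(pool), length(present), n_sim)
    for (ind in indices) {
      obs <- observed_index_value(ind, space, present, w, space$m)
      sim <- null_index_values(ind, pool, w, idx)
      sim <- sim[is.finite(sim)]
      assessment <- assess_distribution(sim, alpha)
      dec <- ses_significance(obs, sim, assessment, threshold)
      rows[[length(rows) + 1]] <- data.frame(
        assemblage = a, index = ind, observed = obs, mean_sim = mean(sim),
        sd_sim = sd(sim), ses = dec$ses, shapiro_p = dec$shapiro_p,
        skewness = dec$skewness, transform = dec$transform,
        pathway = dec$pathway, significant = dec$significant,
        lower = dec$lower, upper = dec$upper, n_sim_used = length(sim),
        stringsAsFactors = FALSE
      )
      if (keep_null) nulls[[paste(a, ind, sep = ".")]] <- sim
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fd_ses", "data.frame")
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  attr(out, "threshold") <- threshold
  if (keep_null) attr(out, "null_draws") <- nulls
  out
}

#' @export
print.fd_ses <- function(x, ...) {
  cat(sprintf("Null-model SES (n_sim = %d, seed = %d, |SES| threshold %.2f)\n",
              attr(x, "n_sim"), attr(x, "seed"), attr(x, "threshold")))
  df <- as.data.frame(x)
  df$observed <- signif(df$observed, 4)
  df$ses <- round(df$ses, 2)
  df$shapiro_p <- signif(df$shapiro_p, 2)
  df$skewness <- round(df$skewness, 2)
  print(df[c("assemblage", "index", "observed", "ses", "transform",
             "pathway", "significant")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.fd_ses <- function(object, ...) {
  df <- as.data.frame(object)
  sig <- df[df$significant, ]
  cat(sprintf("%d of %d assemblage x index tests deviate from the null\n",
              nrow(sig), nrow(df)))
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      cat(sprintf("  %s / %s: SES = %.2f (%s) -> %s\n",
                  sig$assemblage[r], sig$index[r], sig$ses[r], sig$pathway[r],
                  if (sig$ses[r] < 0) "convergence (filtering)"
                  else "divergence (limiting similarity)"))
    }
  }
  invisible(object)
}
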