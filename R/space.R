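#' Gower dissimilarity on a mixed-type trait matrix
#'
#' Computes `d_ij = (1/K) * sum_k delta_ijk` over the K trait columns with
#' equal weights. Continuous columns contribute `|x_i - x_j| / range`;
#' ordinal columns are first replaced by tie-averaged ranks and then treated
#' as continuous (Podani-style rank scaling); binary columns use simple
#' matching (0 when equal, 1 otherwise). A constant column contributes 0 to
#' every pair but stays in the denominator, with a warning.
#'
#' @param x Complete numeric species x trait matrix (ordinals as integer
#'   ranks, binaries 0/1), e.g. from [summarise_species()].
#' @param kinds Named kind vector (`"continuous"`/`"ordinal"`/`"binary"`) for
#'   the columns of `x`; defaults to the `"kinds"` attribute, then to
#'   [trait_kinds()] matched by column name.
#' @return Symmetric species x species matrix of dissimilarities in \[0, 1\]
#'   with zero diagonal and a `"kinds"` attribute.
#' @export
gower_dist <- function(x, kinds = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 species")
  if (anyNA(x)) stop("trait matrix must be complete")
  if (is.null(kinds)) kinds <- attr(x, "kinds")
  if (is.null(kinds)) kinds <- trait_kinds()[colnames(x)]
  if (anyNA(kinds) || length(kinds) != ncol(x)) {
    stop("could not resolve a kind for every trait column")
  }
  n <- nrow(x)
  acc <- matrix(0, n, n)
  constant <- character(0)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (kinds[j] == "ordinal") v <- rank(v)  # tie-averaged ranks
    if (kinds[j] == "binary") {
      delta <- outer(v, v, FUN = "!=") * 1
    } else {
      rng <- max(v) - min(v)
      if (rng == 0) {
        constant <- c(constant, colnames(x)[j])
        next
      }
      delta <- abs(outer(v, v, "-")) / rng
    }
    acc <- acc + delta
  }
  if (length(constant) == ncol(x)) {
    stop("all trait columns are constant; functional space is degenerate")
  }
  if (length(constant)) {
    warning("constant trait column(s) contribute zero dissimilarity: ",
            paste(constant, collapse = ", "))
  }
  d <- acc / ncol(x)
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "kinds") <- kinds
  d
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Gower-centres `-d^2/2` and eigendecomposes it (via [stats::cmdscale()]).
#' When negative eigenvalues exceed tolerance, the configured correction is
#' applied and the embedding recomputed: `"sqrt"` (default) takes the square
#' root of the dissimilarities, which is Euclidean-embeddable for Gower
#' distances; `"cailliez"` adds the Cailliez constant; `"none"` keeps the raw
#' embedding and records a warning flag. Coordinates are scaled by the square
#' root of the eigenvalues and percent variation is computed over positive
#' eigenvalues only.
#'
#' @param d Square dissimilarity matrix (or `dist`).
#' @param m Target dimensionality of the functional space (default 4, the
#'   quality/parsimony compromise; must be >= 2).
#' @param correction `"sqrt"`, `"cailliez"` or `"none"`.
#' @param tol Relative tolerance below which negative eigenvalues are ignored.
#' @return Object of class `"functional_space"`: list with `coords` (species
#'   x axes, all retained positive-eigenvalue axes), `eig`, `pct_var`,
#'   `cum_var`, `m`, `correction`, `correction_applied`,
#'   `negative_eig_warning` and the input `d`.
#' @export
pcoa_space <- function(d, m = 4, correction = c("sqrt", "cailliez", "none"),
                       tol = 1e-8) {
  correction <- match.arg(correction)
  if (m < 2) stop("m must be at least 2")
  dm <- as.matrix(d)
  n <- nrow(dm)
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE))
  scale0 <- max(abs(fit$eig))
  negative <- min(fit$eig) < -tol * scale0
  applied <- "none"
  warn <- FALSE
  if (negative && correction == "sqrt") {
    fit <- suppressWarnings(cmdscale(as.dist(sqrt(dm)), k = n - 1, eig = TRUE))
    applied <- "sqrt"
  } else if (negative && correction == "cailliez") {
    fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE,
                                     add = TRUE))
    applied <- "cailliez"
  } else if (negative) {
    warn <- TRUE
  }
  eig <- fit$eig
  pos <- eig > tol * max(abs(eig))
  coords <- fit$points[, seq_len(sum(pos[seq_len(ncol(fit$points))])),
                       drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  pct <- 100 * eig[pos] / sum(eig[pos])
  m_used <- min(m, ncol(coords))
  structure(list(
    coords = coords, eig = eig, pct_var = pct, cum_var = cumsum(pct),
    m = m_used, correction = correction, correction_applied = applied,
    negative_eig_warning = warn, d = dm
  ), class = "functional_space")
}

#' @export
print.functional_space <- function(x, ...) {
  cat("Functional space:", nrow(x$coords), "species,",
      ncol(x$coords), "positive axes (m =", x$m, "retained)\n")
  cat(sprintf("Correction: %s%s\n", x$correction_applied,
              if (x$negative_eig_warning) " (negative eigenvalues present)"
              else ""))
  k <- min(x$m, length(x$pct_var))
  cat(sprintf("Percent variation, axes 1-%d: %s (cumulative %.1f%%)\n", k,
              paste(sprintf("%.1f%%", x$pct_var[seq_len(k)]), collapse = ", "),
              x$cum_var[k]))
  if (!is.null(x$quality)) {
    cat("Space quality (mSD) by dimensionality:\n")
    print(round(x$quality, 6))
  }
  if (!is.null(x$hull)) {
    cat(sprintf("Community hull: %d vertex species, volume %.4g\n",
                length(x$hull$vertices), x$hull$volume))
  }
  invisible(x)
}

#' Quality of reduced-dimensional functional spaces
#'
#' For each candidate dimensionality `m`, Euclidean distances on the first
#' `m` axes are rescaled so their maximum equals the maximum input
#' dissimilarity, and the mean squared deviation (mSD) between the two
#' distance sets over all unordered pairs is reported. Lower is better; an
#' embedding that reproduces `d` exactly scores 0.
#'
#' @param d The trait-based dissimilarity matrix.
#' @param space A `"functional_space"` object (or a coordinate matrix).
#' @param m_range Dimensionalities to assess (default `2:min(S-1, 10)`).
#' @return Named numeric vector of mSD values, one per dimensionality.
#' @export
space_quality <- function(d, space, m_range = NULL) {
  coords <- if (inherits(space, "functional_space")) space$coords else space
  dm <- as.matrix(d)
  S <- nrow(dm)
  if (is.null(m_range)) m_range <- 2:min(S - 1, 10, ncol(coords))
  if (any(m_range < 2)) stop("dimensionality must be at least 2")
  if (max(m_range) > ncol(coords)) stop("m exceeds available axes")
  lower <- lower.tri(dm)
  dvec <- dm[lower]
  out <- vapply(m_range, function(m) {
    s <- as.matrix(dist(coords[, seq_len(m), drop = FALSE]))[lower]
    s <- s * max(dvec) / max(s)
    mean((s - dvec)^2)
  }, numeric(1))
  names(out) <- paste0("m", m_range)
  out
}

#' Convex hull of species in functional space
#'
#' Quickhull-style convex hull of the points in the first `m` axes; returns
#' the vertex species (the most extreme trait combinations, defining the
#' shape of the occupied space), the non-vertex species and the hull volume.
#'
#' @param space A `"functional_space"` object or coordinate matrix.
#' @param species Optional subset of species (rownames) to use.
#' @param m Dimensionality (default: the space's `m`, or all columns of a
#'   plain matrix).
#' @return List with `vertices`, `nonvertices`, `volume` and `m`.
#' @export
hull_vertices <- function(space, species = NULL, m = NULL) {
  coords <- if (inherits(space, "functional_space")) space$coords else
    as.matrix(space)
  if (is.null(m)) {
    m <- if (inherits(space, "functional_space")) space$m else ncol(coords)
  }
  if (m > ncol(coords)) {
    stop(sprintf("cannot span %d axes: only %d available", m, ncol(coords)))
  }
  coords <- coords[, seq_len(m), drop = FALSE]
  if (!is.null(species)) coords <- coords[species, , drop = FALSE]
  if (nrow(coords) < m + 1) {
    stop(sprintf("dimensionality-deficient set: %d points cannot span %d axes",
                 nrow(coords), m))
  }
  h <- .cpp_convhull(coords)
  if (h$status != 0) {
    stop(sprintf("dimensionality-deficient set: points are degenerate in %d axes",
                 m))
  }
  nm <- rownames(coords)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(coords)))
  list(vertices = nm[h$vertices], nonvertices = setdiff(nm, nm[h$vertices]),
       volume = h$volume, m = m)
}

#' Build a functional space from a species x trait matrix
#'
#' Convenience wrapper chaining [gower_dist()], [pcoa_space()],
#' [space_quality()] and [hull_vertices()]: the standard route from a
#' complete species x trait matrix to an embedded functional space with its
#' quality profile and community convex hull.
#'
#' @inheritParams pcoa_space
#' @param x Species x trait matrix (e.g. from [summarise_species()]).
#' @param kinds Optional kind vector, passed to [gower_dist()].
#' @return A `"functional_space"` object additionally carrying `quality`
#'   (mSD by dimensionality) and `hull` (community hull).
#' @export
functional_space <- function(x, m = 4, correction = c("sqrt", "cailliez",
                                                      "none"), kinds = NULL) {
  d <- gower_dist(x, kinds)
  sp <- pcoa_space(d, m = m, correction = correction)
  sp$quality <- space_quality(d, sp)
  sp$hull <- hull_vertices(sp)
  sp
}
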