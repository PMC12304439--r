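# minimum spanning tree by Prim's algorithm on a distance matrix;
# ties broken by lexicographic (row, column) order so FEve is deterministic
prim_mst <- function(dm) {
  n <- nrow(dm)
  in_tree <- c(1L, rep(0L, n - 1))
  edges <- matrix(0L, n - 1, 2)
  best_d <- dm[1, ]
  best_from <- rep(1L, n)
  for (e in seq_len(n - 1)) {
    cand <- which(in_tree == 0L)
    j <- cand[order(best_d[cand], best_from[cand], cand)[1]]
    edges[e, ] <- c(best_from[j], j)
    in_tree[j] <- 1L
    upd <- which(in_tree == 0L & dm[j, ] < best_d)
    best_d[upd] <- dm[j, upd]
    best_from[upd] <- j
  }
  edges
}

normalize_weights <- function(w) {
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be non-negative")
  if (sum(w) <= 0) stop("weights must have positive sum")
  w / sum(w)
}

#' Functional richness: convex-hull volume of an assemblage
#'
#' Volume of the convex hull of the present species in the first `m` axes of
#' the functional space, and optionally the fraction of the community hull it
#' represents. Assemblages too species-poor (or too degenerate) for an
#' `m`-dimensional hull fall back to the largest feasible dimensionality,
#' flagged in the result; the fraction is only reported at full
#' dimensionality.
#'
#' @param space A `"functional_space"` object or coordinate matrix.
#' @param species Species present (rownames into the coordinates); default
#'   all.
#' @param m Dimensionality (default: the space's `m`).
#' @param community_volume Reference hull volume for the fraction (default:
#'   the space's community hull at the same `m`).
#' @return List with `volume`, `fraction`, `m_used` and `flag` (`NA` or
#'   `"reduced_dimensionality"`).
#' @export
fd_fric <- function(space, species = NULL, m = NULL,
                    community_volume = NULL) {
  coords <- if (inherits(space, "functional_space")) space$coords else
    as.matrix(space)
  if (is.null(m)) {
    m <- if (inherits(space, "functional_space")) space$m else ncol(coords)
  }
  if (is.null(community_volume)) {
    community_volume <- if (inherits(space, "functional_space") &&
                            !is.null(space$hull) && space$hull$m == m)
      space$hull$volume else .cpp_convhull(coords[, seq_len(m),
                                                  drop = FALSE])$volume
  }
  pts <- coords[if (is.null(species)) seq_len(nrow(coords)) else species,
                seq_len(m), drop = FALSE]
  pts <- unique(pts)
  m_used <- m
  h <- if (nrow(pts) >= m + 1) .cpp_convhull(pts) else list(status = 1L)
  while (h$status != 0 && m_used > 2) {
    m_used <- m_used - 1
    sub <- unique(pts[, seq_len(m_used), drop = FALSE])
    h <- if (nrow(sub) >= m_used + 1) .cpp_convhull(sub) else
      list(status = 1L)
  }
  if (h$status != 0) {
    stop("dimensionality-deficient assemblage: convex hull undefined even in 2 axes")
  }
  list(volume = h$volume,
       fraction = if (m_used == m) h$volume / community_volume else NA_real_,
       m_used = m_used,
       flag = if (m_used == m) NA_character_ else "reduced_dimensionality")
}

#' Functional evenness: regularity of biomass along the minimum spanning tree
#'
#' Builds the MST over Euclidean distances among the present species in
#' functional space, weights each edge by `dist(i, j) / (w_i + w_j)`, and
#' measures how evenly these partial weights are spread:
#' `FEve = (sum_l min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`,
#' where `PEW_l` are the edge weights normalized to sum to one. Equals 1 for
#' equally spaced species with equal biomass; approaches 0 when biomass and
#' branch lengths concentrate on a single edge.
#'
#' @inheritParams fd_fric
#' @param w Biomass weights of the present species (normalized internally).
#' @return FEve in \[0, 1\].
#' @export
fd_feve <- function(space, w, species = NULL, m = NULL) {
  coords <- index_coords(space, species, m)
  w <- normalize_weights(w)
  S <- nrow(coords)
  if (S < 3) stop("FEve undefined for fewer than 3 species")
  if (length(w) != S) stop("need one weight per present species")
  dm <- as.matrix(dist(coords))
  edges <- prim_mst(dm)
  ew <- dm[edges] / (w[edges[, 1]] + w[edges[, 2]])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional dispersion: biomass-weighted distance to the weighted centroid
#'
#' `FDis = sum_i w_i * ||x_i - c||` with `c = sum_i w_i x_i` the
#' biomass-weighted centroid of the present species.
#'
#' @inheritParams fd_feve
#' @return FDis (>= 0; 0 for a single species).
#' @export
fd_fdis <- function(space, w, species = NULL, m = NULL) {
  coords <- index_coords(space, species, m)
  w <- normalize_weights(w)
  if (length(w) != nrow(coords)) stop("need one weight per present species")
  centroid <- colSums(coords * w)
  sum(w * sqrt(rowSums(sweep(coords, 2, centroid)^2)))
}

#' Functional divergence: biomass concentration on extreme species
#'
#' Villeger's construction: `G` is the unweighted centroid of the convex-hull
#' vertices; with `dG_i = ||x_i - G||`, `dbar` their unweighted mean,
#' `Dd = sum_i w_i (dG_i - dbar)` and `D|d| = sum_i w_i |dG_i - dbar|`,
#' `FDiv = (Dd + dbar) / (D|d| + dbar)`. Close to 1 when biomass sits on
#' species far from the centre of the occupied space; below 0.5 when it
#' concentrates near `G`.
#'
#' @inheritParams fd_feve
#' @return FDiv in \[0, 1\].
#' @export
fd_fdiv <- function(space, w, species = NULL, m = NULL) {
  coords <- index_coords(space, species, m)
  w <- normalize_weights(w)
  if (length(w) != nrow(coords)) stop("need one weight per present species")
  m_used <- ncol(coords)
  upts <- unique(coords)
  if (nrow(upts) < m_used + 1) {
    stop("dimensionality-deficient assemblage: convex hull undefined")
  }
  h <- .cpp_convhull(upts)
  if (h$status != 0) {
    stop("dimensionality-deficient assemblage: convex hull undefined")
  }
  G <- colMeans(upts[h$vertices, , drop = FALSE])
  dG <- sqrt(rowSums(sweep(coords, 2, G)^2))
  dbar <- mean(dG)
  delta_d <- sum(w * (dG - dbar))
  delta_abs <- sum(w * abs(dG - dbar))
  (delta_d + dbar) / (delta_abs + dbar)
}

index_coords <- function(space, species, m) {
  coords <- if (inherits(space, "functional_space")) space$coords else
    as.matrix(space)
  if (is.null(m)) {
    m <- if (inherits(space, "functional_space")) space$m else ncol(coords)
  }
  coords[if (is.null(species)) seq_len(nrow(coords)) else species,
         seq_len(m), drop = FALSE]
}

#' All four functional diversity indices for a set of assemblages
#'
#' @param space A `"functional_space"` object.
#' @param assemblages Assemblage x species biomass matrix (e.g. from
#'   [build_assemblages()]); column names must match species in the space.
#'   Zero entries mark absent species.
#' @return Tidy data frame: `assemblage`, `index`, `value`, `m_used`, `flag`.
#' @export
fd_indices <- function(space, assemblages) {
  assemblages <- as.matrix(assemblages)
  out <- lapply(rownames(assemblages), function(a) {
    w <- assemblages[a, ]
    present <- names(w)[w > 0]
    wr <- normalize_weights(w[present])
    fr <- fd_fric(space, species = present)
    data.frame(
      assemblage = a,
      index = c("fric", "fric_fraction", "feve", "fdis", "fdiv"),
      value = c(fr$volume, fr$fraction,
                fd_feve(space, wr, species = present),
                fd_fdis(space, wr, species = present),
                fd_fdiv(space, wr, species = present, m = fr$m_used)),
      m_used = fr$m_used,
      flag = fr$flag,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
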