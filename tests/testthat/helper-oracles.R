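# Independent oracles used to validate the package's kernels.
# These deliberately use different algorithms from the implementation:
# exhaustive facet enumeration instead of incremental quickhull, Prufer-
# sequence tree enumeration instead of Prim, LP separation instead of
# hull membership, direct formula sums instead of vectorized code.

# convex hull by exhaustive facet enumeration: every d-subset whose
# hyperplane has all remaining points on one side is a facet
bf_hull <- function(x, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  combos <- utils::combn(n, d)
  centroid <- colMeans(x)
  facets <- list()
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    edges <- t(x[idx[-1], , drop = FALSE]) - x[idx[1], ]
    sv <- svd(t(edges), nu = 0, nv = d)
    if (sv$d[d - 1] < tol) next          # degenerate subset
    nrm <- sv$v[, d]
    off <- sum(nrm * x[idx[1], ])
    s <- x %*% nrm - off
    if (all(s <= tol) || all(s >= -tol)) {
      facets[[length(facets) + 1]] <- idx
    }
  }
  verts <- sort(unique(unlist(facets)))
  vol <- 0
  for (f in facets) {
    m <- t(x[f, , drop = FALSE]) - centroid
    # skip facets through the centroid's side duplication: each supporting
    # hyperplane appears once per point subset, so sum of cone volumes works
    vol <- vol + abs(det(m)) / factorial(d)
  }
  list(vertices = verts, volume = vol)
}

# redundancy-check oracle: x[j, ] is a non-vertex iff it lies in the convex
# hull of the remaining points; by Caratheodory's theorem that holds iff some
# (d+1)-subset of the others contains it with non-negative barycentric
# coordinates, so exhaustive enumeration of all subsets is an exact check
bf_is_vertex <- function(x, j, tol = 1e-9) {
  x <- as.matrix(x)
  d <- ncol(x)
  others <- x[-j, , drop = FALSE]
  target <- c(x[j, ], 1)
  size <- min(d + 1, nrow(others))
  combos <- utils::combn(nrow(others), size)
  for (k in seq_len(ncol(combos))) {
    sub <- others[combos[, k], , drop = FALSE]
    A <- rbind(t(sub), 1)
    lam <- tryCatch(qr.solve(A, target), error = function(e) NULL)
    if (is.null(lam)) next
    resid <- max(abs(A %*% lam - target))
    if (resid < 1e-8 && all(lam >= -tol)) return(FALSE)
  }
  TRUE
}

# decode a Prufer sequence into the edge list of a labeled tree
prufer_edges <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  ptr <- 1L
  for (k in seq_along(pr)) {
    leaf <- which(degree == 1L)[1]
    edges[ptr, ] <- c(leaf, pr[k])
    ptr <- ptr + 1L
    degree[leaf] <- 0L
    degree[pr[k]] <- degree[pr[k]] - 1L
  }
  edges[ptr, ] <- which(degree == 1L)
  edges
}

# exhaustive minimum spanning tree over all n^(n-2) labeled trees
bf_mst <- function(dm) {
  n <- nrow(dm)
  if (n == 2) return(list(edges = matrix(c(1L, 2L), 1), weight = dm[1, 2]))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- NULL
  best_w <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_edges(seqs[r, ], n)
    w <- sum(dm[e])
    if (w < best_w - 1e-12) {
      best_w <- w
      best <- e
    }
  }
  list(edges = best, weight = best_w)
}

# FEve by direct formula over an externally supplied MST
bf_feve <- function(coords, w) {
  dm <- as.matrix(dist(coords))
  mst <- bf_mst(dm)
  S <- nrow(coords)
  ew <- numeric(S - 1)
  for (l in seq_len(S - 1)) {
    i <- mst$edges[l, 1]
    j <- mst$edges[l, 2]
    ew[l] <- dm[i, j] / (w[i] + w[j])
  }
  pew <- ew / sum(ew)
  (sum(pmin(pew, 1 / (S - 1))) - 1 / (S - 1)) / (1 - 1 / (S - 1))
}

bf_fdis <- function(coords, w) {
  cen <- rep(0, ncol(coords))
  for (i in seq_len(nrow(coords))) cen <- cen + w[i] * coords[i, ]
  tot <- 0
  for (i in seq_len(nrow(coords))) {
    tot <- tot + w[i] * sqrt(sum((coords[i, ] - cen)^2))
  }
  tot
}

bf_fdiv <- function(coords, w) {
  h <- bf_hull(coords)
  G <- colMeans(coords[h$vertices, , drop = FALSE])
  dG <- apply(coords, 1, function(p) sqrt(sum((p - G)^2)))
  dbar <- mean(dG)
  dd <- sum(w * (dG - dbar))
  dabs <- sum(w * abs(dG - dbar))
  (dd + dbar) / (dabs + dbar)
}

# Gower dissimilarity of two rows by direct per-trait accumulation
bf_gower_pair <- function(x, i, j, kinds) {
  tot <- 0
  for (k in seq_len(ncol(x))) {
    v <- x[, k]
    if (kinds[k] == "binary") {
      tot <- tot + as.numeric(v[i] != v[j])
    } else {
      if (kinds[k] == "ordinal") v <- rank(v)
      rng <- max(v) - min(v)
      if (rng > 0) tot <- tot + abs(v[i] - v[j]) / rng
    }
  }
  unname(tot / ncol(x))
}

# small regular fixtures
unit_square <- function() {
  m <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  rownames(m) <- paste0("sp", 1:5)
  m
}

regular_simplex3 <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
        c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
}
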