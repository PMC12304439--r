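test_that("Gower dissimilarity matches direct per-pair accumulation", {
  x <- mixed_trait_matrix(8)
  d <- gower_dist(x)
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  kinds <- attr(x, "kinds")
  for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
    expect_equal(d[pair[1], pair[2]],
                 bf_gower_pair(x, pair[1], pair[2], kinds),
                 tolerance = 1e-12)
  }

  # identical rows are at distance zero
  x2 <- rbind(x, x[1, , drop = FALSE])
  rownames(x2)[9] <- "dup"
  expect_equal(gower_dist(x2)["sp01", "dup"], 0)
})

test_that("two species differing only in the 8 binaries are 8/26 apart", {
  x <- mixed_trait_matrix(4)
  kinds <- attr(x, "kinds")
  bin <- names(kinds)[kinds == "binary"]
  x[2, ] <- x[1, ]
  x[2, bin] <- 1 - x[1, bin]
  d <- gower_dist(x)
  expect_equal(d[1, 2], 8 / 26, tolerance = 1e-12)
})

test_that("Gower on a continuous grid matches exhaustive hand computation", {
  x <- cbind(a = c(0, 1, 2), b = c(0, 2, 4))
  rownames(x) <- c("s1", "s2", "s3")
  d <- gower_dist(x, kinds = c(a = "continuous", b = "continuous"))
  # per trait delta = |xi - xj| / range; mean over the two traits
  expect_equal(d["s1", "s2"], mean(c(1 / 2, 2 / 4)))
  expect_equal(d["s1", "s3"], 1)
  expect_equal(d["s2", "s3"], mean(c(1 / 2, 2 / 4)))
})

test_that("Gower agrees with cluster::daisy and is invariant to relabelling", {
  skip_if_not_installed("cluster")
  set.seed(5)
  x <- matrix(runif(24), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:4)))
  kinds <- setNames(rep("continuous", 4), colnames(x))
  d <- gower_dist(x, kinds)
  dd <- as.matrix(cluster::daisy(as.data.frame(x), metric = "gower"))
  expect_equal(unclass(d), dd, tolerance = 1e-10, ignore_attr = TRUE)

  # column order and monotone ordinal relabelling do not matter
  xm <- mixed_trait_matrix(7)
  d1 <- gower_dist(xm)
  perm <- sample(ncol(xm))
  d2 <- gower_dist(xm[, perm], kinds = attr(xm, "kinds")[perm])
  expect_equal(unclass(d1), unclass(d2), ignore_attr = TRUE)
  xm2 <- xm
  xm2[, "gill_raker_type"] <- c(10, 20, 40)[xm[, "gill_raker_type"]]
  d3 <- gower_dist(xm2, kinds = attr(xm, "kinds"))
  expect_equal(unclass(d1), unclass(d3), ignore_attr = TRUE)

  # constant columns contribute zero but stay in the denominator
  xc <- xm
  xc[, "body_depth"] <- 1
  expect_warning(dc <- gower_dist(xc, kinds = attr(xm, "kinds")), "constant")
})

test_that("PCoA embeds Euclidean configurations exactly", {
  pts <- rbind(c(0, 0), c(3, 0), c(3, 4), c(0, 4))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:4)
  sp <- pcoa_space(d, m = 2)
  expect_equal(as.matrix(dist(sp$coords[, 1:2])), unname(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(sp$correction_applied, "none")

  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  sp3 <- pcoa_space(d3, m = 2)
  pos <- sp3$eig[sp3$eig > 1e-8]
  expect_equal(pos[1], pos[2], tolerance = 1e-8)
})

test_that("sqrt correction yields a full-rank embedding reproducing sqrt(d)", {
  x <- mixed_trait_matrix(10)
  d <- gower_dist(x)
  sp <- pcoa_space(d, m = 4, correction = "sqrt")
  expect_identical(sp$correction_applied, "sqrt")
  emb <- as.matrix(dist(sp$coords))
  expect_equal(emb, unname(sqrt(unclass(d))), tolerance = 1e-6,
               ignore_attr = TRUE)
  # percent variation over positive eigenvalues sums to 100
  expect_equal(sum(sp$pct_var), 100)
  expect_true(all(diff(sp$eig) <= 1e-9))

  # correction = none flags remaining negative eigenvalues
  spn <- pcoa_space(d, m = 4, correction = "none")
  expect_true(spn$negative_eig_warning)
})

test_that("PCoA agrees with the ape reference on a metric input", {
  skip_if_not_installed("ape")
  set.seed(8)
  pts <- matrix(rnorm(35), 7, 5)
  d <- as.matrix(dist(pts))
  sp <- pcoa_space(d, m = 4)
  ref <- ape::pcoa(as.dist(d))
  k <- min(4, ncol(ref$vectors))
  expect_equal(abs(sp$coords[, 1:k]), abs(unname(ref$vectors[, 1:k])),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("space quality is zero for exact embeddings and non-increasing in m", {
  pts <- matrix(rnorm(40), 10, 4)
  d <- as.matrix(dist(pts))
  sp <- pcoa_space(d, m = 4)
  q <- space_quality(d, sp, m_range = 2:4)
  expect_lt(q["m4"], 1e-12)
  expect_true(all(diff(q) <= 1e-12))

  # 5-point toy at m = 2 matches the direct pair-sum computation
  x <- mixed_trait_matrix(5)
  d5 <- gower_dist(x)
  sp5 <- pcoa_space(d5, m = 2)
  co <- sp5$coords[, 1:2]
  lower <- lower.tri(d5)
  s <- as.matrix(dist(co))[lower]
  s <- s * max(d5[lower]) / max(s)
  expect_equal(unname(space_quality(d5, sp5, m_range = 2)["m2"]),
               mean((s - d5[lower])^2), tolerance = 1e-12)
  expect_error(space_quality(d5, sp5, m_range = 1:2), "at least 2")
})

test_that("convex hull volume and vertices match closed forms and oracles", {
  sq <- unit_square()
  h <- hull_vertices(sq)
  expect_setequal(h$vertices, paste0("sp", 1:4))
  expect_identical(h$nonvertices, "sp5")
  expect_equal(h$volume, 1)

  expect_equal(hull_vertices(regular_simplex3())$volume, 1 / (6 * sqrt(2)),
               tolerance = 1e-12)

  # 20 random 4D points: agreement with facet enumeration and LP membership
  set.seed(31)
  x <- matrix(rnorm(80), 20, 4)
  h4 <- hull_vertices(x)
  bf <- bf_hull(x)
  expect_setequal(as.integer(h4$vertices), bf$vertices)
  expect_equal(h4$volume, bf$volume, tolerance = 1e-9)
  redundancy <- which(vapply(1:20, function(j) bf_is_vertex(x, j),
                             logical(1)))
  expect_setequal(as.integer(h4$vertices), redundancy)
})

test_that("hull volume grows monotonically as species are added", {
  set.seed(12)
  x <- matrix(rnorm(45), 15, 3)
  vols <- vapply(5:15, function(k)
    hull_vertices(x[1:k, , drop = FALSE])$volume, numeric(1))
  expect_true(all(diff(vols) >= -1e-12))

  # degenerate configurations are reported, not silently embedded
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(hull_vertices(flat), "degenerate|dimensionality")
  expect_error(hull_vertices(matrix(rnorm(6), 3, 2), m = 3), "span")
})

test_that("functional_space chains the full construction", {
  x <- mixed_trait_matrix(12)
  sp <- functional_space(x)
  expect_s3_class(sp, "functional_space")
  expect_equal(sp$m, 4)
  expect_true(all(c("quality", "hull") %in% names(sp)))
  expect_setequal(c(sp$hull$vertices, sp$hull$nonvertices), rownames(x))
  expect_output(print(sp), "Functional space")
})
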