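test_that("FRic reports hull volume and community fraction", {
  sq <- unit_square()
  fr <- fd_fric(sq)
  expect_equal(fr$volume, 1)
  expect_equal(fr$fraction, 1)
  fr2 <- fd_fric(sq, species = paste0("sp", c(1, 2, 3, 5)))
  expect_equal(fr2$volume, 0.5)
  expect_equal(fr2$fraction, 0.5)

  # nested assemblages have monotone non-decreasing volumes
  set.seed(4)
  x <- matrix(rnorm(64), 16, 4)
  rownames(x) <- paste0("s", 1:16)
  subsets <- lapply(6:16, function(k) rownames(x)[1:k])
  vols <- vapply(subsets, function(s) fd_fric(x, species = s)$volume,
                 numeric(1))
  expect_true(all(diff(vols) >= -1e-12))
  expect_equal(vols[length(vols)], bf_hull(x)$volume, tolerance = 1e-10)

  # species-poor assemblages fall back to fewer axes with a flag
  fr3 <- fd_fric(x, species = rownames(x)[1:4])
  expect_identical(fr3$flag, "reduced_dimensionality")
  expect_lt(fr3$m_used, 4)
  expect_true(is.na(fr3$fraction))
})

test_that("FEve analytic cases: equal spacing gives 1, concentration drives it down", {
  line <- cbind(0:4, 0)
  rownames(line) <- paste0("s", 1:5)
  expect_equal(fd_feve(line, rep(0.2, 5)), 1, tolerance = 1e-12)

  # one dominant MST edge (in weighted length) pushes FEve towards 0
  gap <- cbind(c(0, 1, 2, 3, 100), 0)
  rownames(gap) <- paste0("s", 1:5)
  expect_lt(fd_feve(gap, rep(0.2, 5)), 0.1)
  # concentrating biomass mid-line lowers evenness below the uniform case
  w_conc <- c(1e-6, 1e-6, 1 - 4e-6, 1e-6, 1e-6)
  expect_lt(fd_feve(line, w_conc), 0.5)
  expect_error(fd_feve(line[1:2, ], c(0.5, 0.5)), "fewer than 3")
})

test_that("FEve matches the exhaustive spanning-tree oracle on random toys", {
  for (seed in 1:4) {
    set.seed(seed)
    S <- sample(4:6, 1)
    coords <- matrix(rnorm(S * 3), S)
    rownames(coords) <- paste0("s", seq_len(S))
    w <- runif(S)
    w <- w / sum(w)
    expect_equal(fd_feve(coords, w), bf_feve(coords, w), tolerance = 1e-10)
  }
  # the Prim tree agrees with vegan's spanning tree weight
  skip_if_not_installed("vegan")
  set.seed(77)
  coords <- matrix(rnorm(24), 8, 3)
  dm <- as.matrix(dist(coords))
  e <- deepfd:::prim_mst(dm)
  sv <- vegan::spantree(as.dist(dm))
  expect_equal(sum(dm[e]), sum(sv$dist), tolerance = 1e-12)
})

test_that("FDis closed forms and direct-sum oracle", {
  expect_equal(fd_fdis(matrix(c(1, 2), 1), 1), 0)
  two <- rbind(c(0, 0), c(1, 0))
  expect_equal(fd_fdis(two, c(0.5, 0.5)), 0.5)
  # general two-point closed form 2 * w1 * w2 * d
  expect_equal(fd_fdis(two, c(0.3, 0.7)), 2 * 0.3 * 0.7)

  set.seed(2)
  coords <- matrix(rnorm(32), 8, 4)
  w <- runif(8)
  w <- w / sum(w)
  expect_equal(fd_fdis(coords, w), bf_fdis(coords, w), tolerance = 1e-10)

  # with equal weights FDis is the mean distance to the unweighted centroid
  weq <- rep(1 / 8, 8)
  cen <- colMeans(coords)
  expect_equal(fd_fdis(coords, weq),
               mean(sqrt(rowSums(sweep(coords, 2, cen)^2))),
               tolerance = 1e-12)
})

test_that("FDiv analytic cases and formula oracle", {
  # all species equidistant from the vertex centroid: FDiv = 1
  theta <- seq(0, 2 * pi, length.out = 7)[-7]
  circ <- cbind(cos(theta), sin(theta))
  w <- runif(6)
  w <- w / sum(w)
  expect_equal(fd_fdiv(circ, w), 1, tolerance = 1e-10)

  # biomass on species close to the centre gives FDiv < 0.5
  pts <- rbind(circ, c(0.01, 0), c(-0.01, 0))
  w2 <- c(rep(0.001, 6), 0.497, 0.497)
  expect_lt(fd_fdiv(pts, w2), 0.5)

  set.seed(14)
  coords <- matrix(rnorm(21), 7, 3)
  w3 <- runif(7)
  w3 <- w3 / sum(w3)
  expect_equal(fd_fdiv(coords, w3), bf_fdiv(coords, w3), tolerance = 1e-10)
})

test_that("indices are invariant to rigid motions of the space", {
  set.seed(6)
  coords <- matrix(rnorm(36), 9, 4)
  rownames(coords) <- paste0("s", 1:9)
  w <- runif(9)
  w <- w / sum(w)
  rot <- qr.Q(qr(matrix(rnorm(16), 4)))
  moved <- coords %*% rot + matrix(rep(c(3, -1, 2, 0.5), each = 9), 9)
  expect_equal(fd_fric(moved)$volume, fd_fric(coords)$volume,
               tolerance = 1e-9)
  expect_equal(fd_feve(moved, w), fd_feve(coords, w), tolerance = 1e-9)
  expect_equal(fd_fdis(moved, w), fd_fdis(coords, w), tolerance = 1e-9)
  expect_equal(fd_fdiv(moved, w), fd_fdiv(coords, w), tolerance = 1e-9)
})

test_that("fd_indices assembles the tidy per-assemblage table", {
  x <- mixed_trait_matrix(12)
  sp <- functional_space(x)
  asm <- rbind(
    all = setNames(rep(1, 12), rownames(x)),
    half = setNames(c(rep(1, 7), rep(0, 5)), rownames(x))
  )
  tab <- fd_indices(sp, asm)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$value[tab$assemblage == "all" &
                           tab$index == "fric_fraction"], 1)
  expect_true(all(tab$value[tab$index == "feve"] >= 0 &
                    tab$value[tab$index == "feve"] <= 1))
  expect_true(all(tab$value[tab$index == "fdiv"] >= 0 &
                    tab$value[tab$index == "fdiv"] <= 1))
})
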