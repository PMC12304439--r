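test_that("SES follows its definition and affine invariance", {
  sim <- c(1, 2, 3, 4, 5)
  expect_equal(ses(3, sim), 0)
  expect_equal(ses(mean(sim) + 2 * sd(sim), sim), 2)
  expect_error(ses(1, c(2, 2, 2)), "zero spread")
  expect_error(ses(1, 2), "at least 2")

  # invariant to a common affine rescaling of observed and null values
  set.seed(10)
  sim2 <- rnorm(200)
  obs <- 1.3
  expect_equal(ses(5 + 2 * obs, 5 + 2 * sim2), ses(obs, sim2),
               tolerance = 1e-12)

  # large-sample check: obs 3 null SDs out scores about 3
  set.seed(11)
  simn <- rnorm(999)
  expect_equal(ses(3, simn), 3, tolerance = 0.15)
})

test_that("trait randomization draws uniformly with replacement and is seeded", {
  set.seed(99)
  idx <- randomize_traits(42, 13, 999)
  expect_equal(dim(idx), c(13, 999))
  expect_true(all(idx >= 1 & idx <= 42))
  set.seed(99)
  expect_identical(randomize_traits(42, 13, 999), idx)

  # draw frequencies are uniform over the pool (chi-squared at alpha = 0.001)
  set.seed(7)
  big <- randomize_traits(42, 10, 10000)
  tab <- tabulate(big, 42)
  chi <- sum((tab - length(big) / 42)^2 / (length(big) / 42))
  expect_lt(chi, qchisq(0.999, df = 41))

  # a one-species pool collapses every draw
  set.seed(1)
  expect_true(all(randomize_traits(1, 5, 10) == 1))
  expect_error(randomize_traits(0, 5), "empty")
})

test_that("distribution assessment applies the Shapiro / log / skewness tree", {
  set.seed(21)
  x <- rnorm(999)
  a <- assess_distribution(x)
  expect_true(a$normal)
  expect_identical(a$transform, "none")
  expect_lt(abs(a$skewness), 0.2)

  ln <- rlnorm(999, 0, 1)
  al <- assess_distribution(ln)
  expect_identical(al$transform, "log")
  expect_true(al$normal)

  # negative values block the log pathway
  neg <- c(rlnorm(500, 0, 1.5), -0.5)
  an <- assess_distribution(neg)
  expect_identical(an$transform, "none")
  expect_false(an$normal)

  # strongly skewed samples that cannot be log-rescued are flagged
  set.seed(22)
  skewed <- c(-0.1, rlnorm(998, 0, 1.2))
  as <- assess_distribution(skewed)
  expect_false(as$normal)
  expect_true(as$asymmetric)
})

test_that("significance pathways: gaussian threshold and percentile bounds", {
  set.seed(3)
  sim <- rnorm(999, 10, 1)
  dec1 <- ses_significance(10 + 1.95 * sd(sim) + (mean(sim) - 10), sim)
  expect_identical(dec1$pathway, "gaussian")
  expect_false(dec1$significant)
  dec2 <- ses_significance(mean(sim) + 4.8 * sd(sim), sim)
  expect_true(dec2$significant)

  # non-normal nulls: decision by 2.5/97.5 percentiles
  set.seed(4)
  skw <- c(rexp(700, 1), rexp(299, 0.2))
  a <- assess_distribution(skw)
  hi <- quantile(skw, 0.975, type = 7, names = FALSE)
  dechi <- ses_significance(hi * 1.05, skw, a)
  declo <- ses_significance(median(skw), skw, a)
  if (!a$normal) {
    expect_identical(dechi$pathway, "percentile")
    expect_true(dechi$significant)
    expect_false(declo$significant)
  }
})

test_that("fd_ses runs the full inference and is reproducible", {
  x <- mixed_trait_matrix(15, seed = 3)
  sp <- functional_space(x)
  asm <- rbind(
    shallow = setNames(c(runif(8), rep(0, 7)), rownames(x)),
    deep = setNames(runif(15), rownames(x))
  )
  r1 <- fd_ses(sp, asm, n_sim = 99, seed = 5)
  r2 <- fd_ses(sp, asm, n_sim = 99, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 8)
  expect_true(all(r1$pathway %in% c("gaussian", "percentile")))
  gg <- r1$pathway == "gaussian"
  expect_identical(r1$significant[gg], abs(r1$ses[gg]) > 1.96)
  expect_output(print(r1), "Null-model SES")

  # a one-species pool collapses the null: degenerate spread is an error
  one <- x[1, , drop = FALSE]
  spone <- list(coords = sp$coords[1, , drop = FALSE], m = 2)
  expect_error(
    ses(fd_fdis(spone$coords, 1),
        rep(fd_fdis(spone$coords, 1), 10)), "zero spread")
})
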