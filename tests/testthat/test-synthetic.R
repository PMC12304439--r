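test_that("the generator is deterministic end-to-end under the master seed", {
  c1 <- simulate_community(community_spec(seed = 5))
  c2 <- simulate_community(community_spec(seed = 5))
  expect_identical(c1$pool$traits, c2$pool$traits)
  expect_identical(c1$individuals, c2$individuals)
  expect_identical(c1$catches, c2$catches)
  c3 <- simulate_community(community_spec(seed = 6))
  expect_false(identical(c1$individuals, c3$individuals))
})

test_that("noise-free individuals reproduce archetype traits exactly", {
  spec <- community_spec(n_species = 6, noise_sd = 0, sl_noise_sd = 0,
                         missing_rate = 0, richness = c(3, 4, 5, 6),
                         n_hauls = c(2, 2, 2, 2), seed = 2)
  set.seed(2)
  pool <- generate_pool(spec)
  set.seed(3)
  ind <- generate_individuals(pool, spec)
  tr <- derive_traits(ind)
  tn <- names(trait_kinds())
  ratio <- setdiff(tn, c("caudal_throttle_width", "gill_outflow"))
  for (s in rownames(pool$traits)) {
    rows <- tr[tr$species == s, ]
    for (j in ratio) {
      expect_equal(unique(round(rows[[j]], 10)),
                   round(pool$traits[s, j], 10))
    }
  }
})

test_that("missingness injection is exact in count and size-dependent", {
  spec <- community_spec(missing_rate = 0.02, seed = 4)
  set.seed(4)
  pool <- generate_pool(spec)
  set.seed(5)
  ind <- generate_individuals(pool, spec)
  meas <- deepfd:::raw_measurements()
  n_na <- sum(is.na(ind[meas]))
  expect_equal(n_na, round(0.02 * nrow(ind) * length(meas)))
  expect_false(anyNA(ind$standard_length))

  # small individuals lose more cells (inverse-size weighting)
  na_per_row <- rowSums(is.na(ind[meas]))
  small <- ind$standard_length < median(ind$standard_length)
  expect_gt(mean(na_per_row[small]), mean(na_per_row[!small]))
})

test_that("generated trait values stay within their families' ranges", {
  spec <- community_spec(seed = 8)
  set.seed(8)
  pool <- generate_pool(spec)
  tr <- pool$traits
  kinds <- trait_kinds()
  expect_true(all(tr[, kinds == "binary"] %in% 0:1))
  expect_true(all(tr[, "gill_raker_type"] %in% 1:3))
  expect_true(all(tr[, "oral_gape_axis"] %in% 1:5))
  expect_true(all(tr[, kinds == "continuous"] > 0))
  a <- pool$archetypes
  expect_true(all(a$sl_mean >= 3 & a$sl_mean <= 55))
  expect_true(all(a$depth_min >= 20 & a$depth_max <= 2000))
  expect_true(all(a$depth_min < a$depth_max))
})

test_that("assembly mechanisms leave their signature in pairwise Gower distances", {
  filt <- numeric(6)
  neut <- numeric(6)
  divg <- numeric(6)
  for (r in 1:6) {
    spec <- community_spec(assembly = c("filtered", "neutral", "neutral",
                                        "divergent"),
                           richness = c(13, 13, 13, 13), seed = 100 + r)
    set.seed(100 + r)
    pool <- generate_pool(spec)
    set.seed(200 + r)
    asm <- generate_assemblages(pool, spec)
    gd <- gower_dist(pool$traits)
    sub <- function(members) gd[members, members]
    filt[r] <- mean(sub(asm$membership$epipelagic)[lower.tri(diag(13))])
    neut[r] <- mean(sub(asm$membership$upper_mesopelagic)[lower.tri(diag(13))])
    divg[r] <- min(sub(asm$membership$bathypelagic)[lower.tri(diag(13))])
    neut_min <- min(sub(asm$membership$lower_mesopelagic)[lower.tri(diag(13))])
    expect_gt(divg[r], neut_min)
  }
  expect_true(all(filt < neut))
})

test_that("the pool feeds a coherent full community data set", {
  cc <- simulate_community(community_spec(seed = 12))
  expect_setequal(unique(cc$catches$species), rownames(cc$pool$traits))
  expect_true(all(cc$catches$mass_kg > 0))
  expect_true(all(cc$occurrences$depth >= 20 & cc$occurrences$depth <= 2000))
  # every layer member is caught at least once in that layer
  lay <- assign_layer(cc$hauls$immersion_depth)
  for (l in names(cc$membership)) {
    st <- cc$hauls$station_id[lay == l]
    caught <- unique(cc$catches$species[cc$catches$station_id %in% st])
    expect_setequal(caught, cc$membership[[l]])
  }
})
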