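test_that("trait derivation follows the measurement formulas", {
  rec <- make_record(sl = 10, eye_diameter = 1.5, head_depth = 1.5)
  tr <- derive_traits(rec)
  expect_equal(tr$eye_size, 1.0)  # eye diameter equal to head depth

  rec2 <- make_record(sl = 10, mouth_width = 1, mouth_depth = 1,
                      body_width = 2, body_depth = 2)
  expect_equal(derive_traits(rec2)$oral_gape_surface, 0.25)

  # absolute traits are carried over unchanged
  expect_equal(tr$caudal_throttle_width, rec$caudal_peduncle_depth)
  expect_equal(tr$gill_outflow, rec$operculum_width)

  # ordinal labels are recoded to ranks
  rec3 <- make_record(gill_raker_type = "well_developed",
                      oral_gape_axis = "superior")
  tr3 <- derive_traits(rec3)
  expect_identical(tr3$gill_raker_type, 3L)
  expect_identical(tr3$oral_gape_axis, 1L)
})

test_that("missing inputs propagate to missing traits, binaries pass through", {
  rec <- make_record()
  for (col in setdiff(deepfd:::raw_measurements(), "standard_length")) {
    rec[[col]] <- NA_real_
  }
  tr <- derive_traits(rec)
  cont <- names(trait_kinds())[trait_kinds() == "continuous"]
  expect_true(all(is.na(tr[cont])))
  expect_identical(tr$small_teeth, 1L)
  expect_identical(tr$gill_raker_type, 2L)

  # zero denominator: missing cells plus logged anomalies
  warns <- capture_warnings(tr0 <- derive_traits(make_record(head_depth = 0)))
  expect_true(any(grepl("zero denominator", warns)))
  expect_true(is.na(tr0$eye_size))
  expect_true(is.na(tr0$eye_position))

  # standard length is mandatory
  expect_error(derive_traits(make_record(standard_length = NA)),
               "standard_length")
})

test_that("trait derivation is scale-aware", {
  rec <- make_record(sl = 10)
  rec2 <- rec
  meas <- c("standard_length", deepfd:::raw_measurements())
  rec2[meas] <- rec[meas] * 2
  t1 <- derive_traits(rec)
  t2 <- derive_traits(rec2)
  kinds <- trait_kinds()
  ratio <- setdiff(names(kinds)[kinds == "continuous"],
                   c("caudal_throttle_width", "gill_outflow"))
  expect_equal(unlist(t2[ratio]), unlist(t1[ratio]))
  expect_equal(t2$caudal_throttle_width, 2 * t1$caudal_throttle_width)
  expect_equal(t2$gill_outflow, 2 * t1$gill_outflow)
})

test_that("sparse-species exclusion applies the 25% missing-trait rule", {
  tab <- rbind(make_records(3, "keep"), make_records(2, "drop"),
               make_records(2, "edge"))
  tr <- derive_traits(tab)
  tn <- names(trait_kinds())
  # drop: 7 of 26 traits wholly missing (26.9% > 25%)
  tr[tr$species == "drop", tn[1:7]] <- NA
  # edge: 6 of 26 (23.1%) stays
  tr[tr$species == "edge", tn[1:6]] <- NA
  res <- exclude_sparse_species(tr)
  expect_identical(res$excluded$species, "drop")
  expect_setequal(unique(res$traits$species), c("keep", "edge"))
  expect_equal(res$excluded$missing_fraction, 7 / 26)

  # a complete table passes through untouched
  res2 <- exclude_sparse_species(derive_traits(tab))
  expect_equal(nrow(res2$excluded), 0)
  expect_equal(nrow(res2$traits), nrow(tab))

  expect_error(exclude_sparse_species(tr, threshold = 0), "threshold")
  expect_error(exclude_sparse_species(tr, threshold = 1.2), "threshold")
})

test_that("species summary aggregates by kind and records size metadata", {
  one <- derive_traits(make_record(species = "solo"))
  m1 <- summarise_species(one)
  tn <- names(trait_kinds())
  expect_equal(unname(m1["solo", tn]), unname(unlist(one[tn])))

  recs <- rbind(make_records(2, "a", sl = 8), make_records(3, "b", sl = 12))
  tr <- derive_traits(recs)
  tr$gill_raker_type <- c(1L, 3L, 1L, 2L, 2L)   # medians 2 and 2
  tr$small_teeth <- c(1L, 0L, 0L, 0L, 1L)       # majority: a -> 1 (tie), b -> 0
  m <- summarise_species(tr)
  expect_equal(m["a", "gill_raker_type"], 2)
  expect_equal(m["a", "small_teeth"], 1)
  expect_equal(m["b", "small_teeth"], 0)
  meta <- attr(m, "meta")
  expect_equal(meta$n_individuals, c(2, 3))
  expect_equal(meta$sl_mean, c(8, 12))

  # species means recover generator archetypes within 2 standard errors
  spec <- community_spec(seed = 21)
  set.seed(22)
  pool <- generate_pool(spec)
  spec30 <- community_spec(n_species = 42, n_individuals = c(30, 30),
                           missing_rate = 0, seed = 21)
  set.seed(23)
  ind <- generate_individuals(pool, spec30)
  sm <- summarise_species(derive_traits(ind))
  for (trt in c("body_depth", "eye_size", "oral_gape_surface")) {
    est <- sm[, trt]
    truth <- pool$traits[rownames(sm), trt]
    se <- vapply(split(derive_traits(ind)[[trt]], ind$species),
                 function(v) sd(v) / sqrt(length(v)), numeric(1))[rownames(sm)]
    expect_gt(mean(abs(est - truth) <= 2 * se + 1e-12), 0.85)
  }
})
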