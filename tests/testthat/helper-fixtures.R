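# a minimal complete raw morphometric record, scaled by standard length
make_record <- function(id = "i1", species = "sp1", sl = 10,
                        depth = 500, ...) {
  rec <- data.frame(
    individual_id = id, species = species, capture_depth = depth,
    standard_length = sl,
    body_depth = 0.2 * sl, body_width = 0.1 * sl, head_length = 0.25 * sl,
    head_depth = 0.15 * sl, eye_diameter = 0.05 * sl, eye_height = 0.08 * sl,
    lower_jaw_length = 0.12 * sl, mouth_width = 0.08 * sl,
    mouth_depth = 0.1 * sl, operculum_width = 0.06 * sl,
    operculum_depth = 0.07 * sl, predorsal_length = 0.45 * sl,
    prepectoral_length = 0.3 * sl, caudal_peduncle_depth = 0.04 * sl,
    upjaw_bottom_head = 0.1 * sl, pectoral_bottom_body = 0.09 * sl,
    body_depth_pectoral = 0.19 * sl,
    gill_raker_type = 2L, oral_gape_axis = 3L,
    chin_barbel = 0L, fang_teeth = 0L, gland_head = 0L, internal_teeth = 1L,
    large_teeth = 0L, ventral_photophores = 1L, retractable_teeth = 0L,
    small_teeth = 1L, stringsAsFactors = FALSE
  )
  args <- list(...)
  for (nm in names(args)) rec[[nm]] <- args[[nm]]
  rec
}

make_records <- function(n, species = "sp1", sl = 10, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(id = sprintf("%s_i%d", species, i), species = species,
                sl = sl, ...)
  }))
}

# small mixed-type species x trait matrix for space tests
mixed_trait_matrix <- function(n = 10, seed = 7) {
  set.seed(seed)
  kinds <- trait_kinds()
  x <- matrix(NA_real_, n, length(kinds),
              dimnames = list(sprintf("sp%02d", 1:n), names(kinds)))
  for (j in seq_along(kinds)) {
    x[, j] <- switch(kinds[[j]],
      continuous = rlnorm(n, 0, 0.4),
      ordinal = sample.int(if (grepl("axis", names(kinds)[j])) 5 else 3, n,
                           replace = TRUE),
      binary = rbinom(n, 1, 0.5))
  }
  attr(x, "kinds") <- kinds
  x
}
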