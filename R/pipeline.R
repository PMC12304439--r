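#' Configuration for a full pipeline run
#'
#' @param hauls,catches,morphometrics Input CSV paths (see [read_hauls()],
#'   [read_catches()] and [derive_traits()] for the expected columns), or
#'   in-memory data frames.
#' @param outdir Output directory; created if absent. All intermediate
#'   artifacts are written there as labelled CSV plus a JSON run report.
#' @param layers Depth-layer definitions.
#' @param m Functional-space dimensionality (default 4).
#' @param correction PCoA negative-eigenvalue correction (default `"sqrt"`).
#' @param n_sim Null-model draws (default 999).
#' @param alpha Shapiro-Wilk level (default 0.05).
#' @param ses_threshold Gaussian SES cutoff (default 1.96).
#' @param n_boot,boot_sample CWM bootstrap draw count and per-draw sample
#'   size.
#' @param exclude_threshold Sparse-species exclusion threshold.
#' @param layer_aggregate `"mean"` or `"sum"` of haul densities within layers.
#' @param seed Master seed; stages use `seed + 10, 20, 30, ...`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(hauls, catches, morphometrics, outdir,
                            layers = pelagic_layers(), m = 4,
                            correction = "sqrt", n_sim = 999, alpha = 0.05,
                            ses_threshold = 1.96, n_boot = 999,
                            boot_sample = 200, exclude_threshold = 0.25,
                            layer_aggregate = "mean", seed = 1) {
  stopifnot(m >= 2, n_sim >= 2, alpha > 0, alpha < 1, ses_threshold > 0,
            n_boot >= 2, boot_sample >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

load_table <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full trait-based analysis pipeline
#'
#' Executes, in order: biomass ingest and assemblage construction; trait
#' derivation, sparse-species exclusion, chained-equation imputation and
#' species summary; Gower/PCoA functional space with quality profile and
#' community hull; per-layer functional diversity indices; null-model SES
#' inference; bootstrapped community-weighted means per haul depth, layer
#' medians and their PCA; and functional rarity. Every intermediate artifact
#' is written to `config$outdir` together with a machine-readable JSON
#' report (settings, seeds, warnings, timings).
#'
#' @param config A `"pipeline_config"`.
#' @return Invisibly, a list with all stage results (`assemblages`,
#'   `species_matrix`, `space`, `indices`, `ses`, `cwm`, `cwm_pca`,
#'   `rarity`, `report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }
  timings <- c()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        note("[%s] %s", name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    timings[name] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    res
  }
  out_csv <- function(x, name, rows = TRUE) {
    write.csv(x, file.path(config$outdir, paste0(name, ".csv")),
              row.names = rows)
  }

  # -- ingest ----------------------------------------------------------------
  hauls <- load_table(config$hauls, read_hauls)
  catches <- load_table(config$catches, read_catches)
  assemblages <- stage("ingest", build_assemblages(
    hauls, catches, level = "layer", layers = config$layers,
    aggregate = config$layer_aggregate))
  haul_assemblages <- stage("ingest_haul", build_assemblages(
    hauls, catches, level = "haul", layers = config$layers))
  out_csv(assemblages, "assemblage_layer")
  out_csv(haul_assemblages, "assemblage_haul")

  # -- traits ----------------------------------------------------------------
  morpho <- load_table(config$morphometrics, function(p)
    read.csv(p, stringsAsFactors = FALSE))
  traits <- stage("derive_traits", derive_traits(morpho))
  excl <- stage("exclude_sparse", exclude_sparse_species(
    traits, config$exclude_threshold))
  if (nrow(excl$excluded)) {
    note("excluded sparse species: %s",
         paste(excl$excluded$species, collapse = ", "))
  }
  imputed <- stage("impute", impute_missing(excl$traits,
                                            seed = config$seed + 10))
  species_matrix <- stage("summarise", summarise_species(imputed))
  out_csv(species_matrix, "species_traits")
  keep <- intersect(colnames(assemblages), rownames(species_matrix))
  assemblages <- assemblages[, keep, drop = FALSE]
  haul_depths <- attr(haul_assemblages, "depth")
  haul_assemblages <- haul_assemblages[, keep, drop = FALSE]
  attr(haul_assemblages, "depth") <- haul_depths

  # -- functional space ------------------------------------------------------
  space <- stage("space", functional_space(species_matrix, m = config$m,
                                           correction = config$correction))
  out_csv(space$d, "gower_dissimilarity")
  out_csv(space$coords, "pcoa_coordinates")
  jsonlite::write_json(
    list(vertices = space$hull$vertices, volume = space$hull$volume,
         m = space$m, pct_var = space$pct_var[seq_len(space$m)],
         cum_var = space$cum_var[space$m], quality = as.list(space$quality)),
    file.path(config$outdir, "functional_space.json"),
    auto_unbox = TRUE, digits = NA)

  # -- diversity indices + SES ----------------------------------------------
  indices <- stage("indices", fd_indices(space, assemblages))
  out_csv(indices, "fd_indices", rows = FALSE)
  ses_tab <- stage("ses", fd_ses(space, assemblages, n_sim = config$n_sim,
                                 seed = config$seed + 20,
                                 threshold = config$ses_threshold,
                                 alpha = config$alpha))
  out_csv(as.data.frame(ses_tab), "ses", rows = FALSE)

  # -- community-weighted means ---------------------------------------------
  cwm <- stage("cwm", cwm_by_depth(haul_assemblages, imputed, config))
  out_csv(cwm$by_depth, "cwm_by_depth", rows = FALSE)
  out_csv(cwm$layer_median, "cwm_layer_median")
  pca <- stage("cwm_pca", cwm_pca(cwm$layer_median))
  out_csv(pca$loadings, "cwm_pca_loadings")
  out_csv(pca$scores, "cwm_pca_scores")

  # -- rarity ----------------------------------------------------------------
  occurrences <- merge(
    data.frame(station_id = catches$station_id, species = catches$species,
               stringsAsFactors = FALSE),
    hauls[c("station_id", "immersion_depth")], by = "station_id")
  names(occurrences)[names(occurrences) == "immersion_depth"] <- "depth"
  occurrences <- occurrences[occurrences$species %in% rownames(space$d), ]
  rarity <- stage("rarity", functional_rarity(
    space$d, occurrences,
    extent = c(min(config$layers$depth_min), max(config$layers$depth_max))))
  out_csv(rarity, "rarity", rows = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("deepfd")),
    seed = config$seed,
    settings = config[c("m", "correction", "n_sim", "alpha", "ses_threshold",
                        "n_boot", "boot_sample", "exclude_threshold",
                        "layer_aggregate")],
    excluded_species = excl$excluded$species,
    n_species = nrow(species_matrix),
    cwm_pca_pct_var = pca$pct_var,
    warnings = warnings_log,
    timings_sec = as.list(round(timings, 3)),
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  )
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(assemblages = assemblages,
                 haul_assemblages = haul_assemblages,
                 species_matrix = species_matrix, space = space,
                 indices = indices, ses = ses_tab, cwm = cwm, cwm_pca = pca,
                 rarity = rarity, report = report))
}

# bootstrap CWM at every haul depth, then take layer medians of the per-depth
# bootstrap means; individuals are matched to the haul's layer by capture
# depth when available, falling back to the species-wide pool
cwm_by_depth <- function(haul_assemblages, individuals, config) {
  depths <- attr(haul_assemblages, "depth")
  layers_of <- assign_layer(depths, config$layers)
  kinds <- trait_kinds()
  trait_cols <- intersect(names(kinds)[kinds != "ordinal"],
                          names(individuals))
  ind_layer <- assign_layer(
    pmin(pmax(individuals$capture_depth, min(config$layers$depth_min)),
         max(config$layers$depth_max)), config$layers)
  rows <- list()
  for (i in seq_len(nrow(haul_assemblages))) {
    w <- haul_assemblages[i, ]
    present <- names(w)[w > 0]
    if (!length(present)) next
    local <- individuals$species %in% present &
      ind_layer == layers_of[i]
    pool <- individuals[local, , drop = FALSE]
    missing_sp <- setdiff(present, pool$species)
    if (length(missing_sp)) {  # species-wide fallback
      pool <- rbind(pool, individuals[individuals$species %in% missing_sp, ,
                                      drop = FALSE])
    }
    cb <- suppressWarnings(cwm_bootstrap(
      pool, w[present], traits = trait_cols, n_boot = config$n_boot,
      sample_size = config$boot_sample, seed = config$seed + 30 + i))
    rows[[i]] <- data.frame(
      station = rownames(haul_assemblages)[i], depth = depths[i],
      layer = layers_of[i], trait = cb$summary$trait,
      boot_mean = cb$summary$mean, ci_low = cb$summary$ci_low,
      ci_high = cb$summary$ci_high, stringsAsFactors = FALSE)
  }
  by_depth <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(split(by_depth, by_depth$layer), function(g) {
    vapply(split(g$boot_mean, g$trait), median, numeric(1))
  }))
  med <- med[intersect(config$layers$layer, rownames(med)), , drop = FALSE]
  list(by_depth = by_depth, layer_median = med)
}
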