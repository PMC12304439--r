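#' Species depth-range and size summary of the measured community
#'
#' The taxonomic placement, observed depth range (m), number of measured
#' individuals and standard length (mean and SD, cm) of the 42 species of a
#' measured Bay of Biscay deep-pelagic fish community. Useful as a realism
#' reference for the synthetic generator and
#' for depth-range restrictedness examples: the size range across species is
#' 51.5 cm (from *Argyropelecus hemigymnus*, 3.1 cm, to *Serrivomer beanii*,
#' 54.6 cm).
#'
#' @return Data frame with columns `order`, `family`, `species`,
#'   `depth_min`, `depth_max`, `n_individuals`, `sl_mean`, `sl_sd`.
#' @export
species_depth_size <- function() {
  read.csv(system.file("extdata", "species_depth_size.csv",
                       package = "deepfd"),
           stringsAsFactors = FALSE)
}
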