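#' Standardize a trawl catch mass by the volume of water filtered
#'
#' Converts a catch mass to a biomass density by dividing by the volume
#' filtered during the haul, `vertical * horizontal * distance` — the mouth
#' area of the net times the distance towed at constant immersion depth.
#'
#' @param mass Catch mass in kg (scalar or vector); must be `>= 0`.
#' @param vertical Vertical mouth opening of the net, m.
#' @param horizontal Horizontal mouth opening, m.
#' @param distance Distance trawled, m (e.g. one hour at 4 kn is 7408 m).
#' @return Biomass density in kg m^-3.
#' @examples
#' standardize_biomass(1, vertical = 24, horizontal = 58, distance = 7408)
#' @export
standardize_biomass <- function(mass, vertical, horizontal, distance) {
  if (any(!is.finite(vertical)) || any(!is.finite(horizontal)) ||
      any(!is.finite(distance)) ||
      any(vertical <= 0) || any(horizontal <= 0) || any(distance <= 0)) {
    stop("invalid gear geometry: vertical, horizontal and distance must all be > 0")
  }
  if (any(!is.finite(mass)) || any(mass < 0)) {
    stop("invalid catch: mass must be >= 0")
  }
  mass / (vertical * horizontal * distance)
}

#' Depth-layer definitions for the sampled water column
#'
#' The four pelagic depth layers partitioning the 20-2000 m sampled range:
#' epipelagic (20-175 m), upper mesopelagic (175-700 m), lower mesopelagic
#' (700-1000 m) and bathypelagic (1000-2000 m). Intervals are half-open
#' `[min, max)`; 2000 m belongs to the bathypelagic layer.
#'
#' @return A data frame with columns `layer`, `depth_min`, `depth_max`.
#' @export
pelagic_layers <- function() {
  data.frame(
    layer = c("epipelagic", "upper_mesopelagic", "lower_mesopelagic",
              "bathypelagic"),
    depth_min = c(20, 175, 700, 1000),
    depth_max = c(175, 700, 1000, 2000),
    stringsAsFactors = FALSE
  )
}

#' Assign sampling depths to depth layers
#'
#' @param depth Numeric vector of immersion depths, m. All values must lie
#'   within the overall sampled range of `layers`.
#' @param layers Layer definition table as returned by [pelagic_layers()].
#' @return Character vector of layer names, ordered as `depth`.
#' @examples
#' assign_layer(c(100, 175, 2000))
#' @export
assign_layer <- function(depth, layers = pelagic_layers()) {
  lo <- min(layers$depth_min)
  hi <- max(layers$depth_max)
  if (any(!is.finite(depth)) || any(depth < lo) || any(depth > hi)) {
    stop(sprintf("depth outside sampled range [%g, %g]", lo, hi))
  }
  idx <- findInterval(depth, sort(layers$depth_min))
  layers$layer[order(layers$depth_min)][idx]
}

#' Read haul and catch tables from CSV
#'
#' `read_hauls()` expects columns `station_id`, `immersion_depth`,
#' `vertical_opening`, `horizontal_opening` and (optionally)
#' `distance_trawled`; a missing distance column is derived from the standard
#' haul protocol of one hour towed at 4 kn (7408 m) with a warning.
#' `read_catches()` expects long-format columns `station_id`, `species`,
#' `mass_kg`.
#'
#' @param path Path to a CSV file.
#' @return A data frame.
#' @export
read_hauls <- function(path) {
  h <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "immersion_depth", "vertical_opening",
            "horizontal_opening")
  missing_cols <- setdiff(need, names(h))
  if (length(missing_cols)) {
    stop("haul table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(h$distance_trawled)) {
    warning("no distance_trawled column; using 1 h at 4 kn (7408 m)")
    h$distance_trawled <- 1852 * 4
  }
  h
}

#' @rdname read_hauls
#' @export
read_catches <- function(path) {
  ct <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "species", "mass_kg")
  missing_cols <- setdiff(need, names(ct))
  if (length(missing_cols)) {
    stop("catch table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ct
}

#' Build assemblage tables of standardized biomass
#'
#' Combines a haul table and a long-format catch table into a sampling-unit x
#' species matrix of biomass densities (kg m^-3). At `level = "haul"` each row
#' is one station; at `level = "layer"` haul rows are aggregated within the
#' depth layer of their immersion depth, by default as the per-species mean
#' density across the layer's hauls (`aggregate = "sum"` totals them instead).
#'
#' @param hauls Data frame of hauls (see [read_hauls()] for columns).
#' @param catches Long-format data frame with `station_id`, `species`,
#'   `mass_kg`.
#' @param level `"haul"` or `"layer"`.
#' @param layers Layer definitions, used when `level = "layer"`.
#' @param aggregate `"mean"` (default) or `"sum"` across hauls within a layer.
#' @return A numeric matrix (rows: sampling units, sorted; columns: species,
#'   sorted) with attribute `"depth"` giving each haul row's immersion depth
#'   at haul level.
#' @export
build_assemblages <- function(hauls, catches, level = c("haul", "layer"),
                              layers = pelagic_layers(),
                              aggregate = c("mean", "sum")) {
  level <- match.arg(level)
  aggregate <- match.arg(aggregate)
  if (nrow(hauls) < 1) stop("need at least one haul")

  catches <- merge(catches, hauls, by = "station_id")
  catches$density <- standardize_biomass(
    catches$mass_kg, catches$vertical_opening,
    catches$horizontal_opening, catches$distance_trawled
  )

  stations <- sort(unique(hauls$station_id))
  empty <- setdiff(stations, unique(catches$station_id[catches$density > 0]))
  if (length(empty)) {
    warning("dropping hauls with empty catch: ", paste(empty, collapse = ", "))
    stations <- setdiff(stations, empty)
  }
  species <- sort(unique(catches$species))
  tab <- matrix(0, length(stations), length(species),
                dimnames = list(stations, species))
  keep <- catches$station_id %in% stations
  agg <- aggregate(density ~ station_id + species, data = catches[keep, ],
                   FUN = sum)
  tab[cbind(match(agg$station_id, stations), match(agg$species, species))] <-
    agg$density
  depth <- hauls$immersion_depth[match(stations, hauls$station_id)]

  if (level == "haul") {
    attr(tab, "depth") <- depth
    return(tab)
  }
  lay <- assign_layer(depth, layers)
  fun <- if (aggregate == "mean") colMeans else colSums
  out <- t(vapply(layers$layer[layers$layer %in% lay], function(L) {
    fun(tab[lay == L, , drop = FALSE])
  }, numeric(ncol(tab))))
  rownames(out) <- layers$layer[layers$layer %in% lay]
  attr(out, "n_hauls") <- as.vector(table(factor(lay, rownames(out))))
  out
}
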