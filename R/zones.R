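# Permafrost zonation used as the upscaling strata.

#' Permafrost zone codes, south to north
#'
#' The five strata used throughout the package, ordered from the
#' permafrost-free south to the continuous-permafrost north.
#'
#' @return Character vector of the five zone codes.
#' @export
#' @examples
#' zone_levels()
zone_levels <- function() {
  c("absent", "isolated", "sporadic", "discontinuous", "continuous")
}

#' Normalize permafrost zone labels
#'
#' Accepts case variants, surrounding whitespace, and the common synonyms
#' `"permafrost-free"`/`"free"`/`"none"` for the southern zone. Unknown
#' labels raise an error naming the offending values.
#'
#' @param x Character vector of zone labels.
#' @return Factor with levels `zone_levels()`, ordered south to north.
#' @export
#' @examples
#' normalize_zone(c("Sporadic", "permafrost-free", " CONTINUOUS "))
normalize_zone <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  lab[lab %in% c("permafrost-free", "permafrost free", "free", "none",
                 "no permafrost")] <- "absent"
  bad <- setdiff(unique(lab[!is.na(lab)]), zone_levels())
  if (length(bad) > 0L) {
    stop("unknown permafrost zone label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(lab, levels = zone_levels(), ordered = TRUE)
}

#' Default permafrost zone table
#'
#' Land area and latitude band for each zone of the Western Siberian
#' lowland (Ob', Pur and Taz basins). Land areas are calibrated defaults
#' summing to ~3.55 million km2; latitude bands are simplified contiguous
#' strips used for season-length modelling, not real zone geometries.
#'
#' @param land_area_km2 Optional numeric vector of five per-zone land
#'   areas (km2), south to north, overriding the defaults.
#' @return `data.frame` with columns `zone`, `land_area_km2`, `lat_min`,
#'   `lat_max`.
#' @export
#' @examples
#' permafrost_zones()
permafrost_zones <- function(land_area_km2 = NULL) {
  land <- if (is.null(land_area_km2)) {
    c(1400000, 400000, 450000, 550000, 750000)
  } else {
    land_area_km2
  }
  if (length(land) != 5L || any(!is.finite(land)) || any(land <= 0)) {
    stop("five strictly positive land areas are required", call. = FALSE)
  }
  data.frame(
    zone = normalize_zone(zone_levels()),
    land_area_km2 = land,
    lat_min = c(55.0, 60.5, 62.5, 64.5, 67.5),
    lat_max = c(60.5, 62.5, 64.5, 67.5, 73.0)
  )
}

# midpoint latitude per zone, used for class-level season lengths
zone_mid_latitude <- function(zones = permafrost_zones()) {
  stats::setNames((zones$lat_min + zones$lat_max) / 2,
                  as.character(zones$zone))
}
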