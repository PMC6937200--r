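#' Assign a predator length group
#'
#' Three total-length groups used for diet comparisons: small (<= 33 cm),
#' medium (34-38 cm) and large (>= 39 cm). The original survey description
#' printed inverted inequality signs for S and L; this is the only
#' internally consistent reading of those integer-cm boundaries.
#'
#' @param length total length, cm (vectorised).
#' @return factor with levels `S`, `M`, `L`.
#' @export
assign_length_group <- function(length) {
  if (any(!is.finite(length)) || any(length <= 0))
    stop_validation("length must be positive and finite")
  factor(ifelse(length <= 33, "S", ifelse(length <= 38, "M", "L")),
         levels = c("S", "M", "L"))
}

#' Assign a 6-hour time period of day
#'
#' The day is split into four 6-hour blocks by local hour:
#' P1 = \[00:00, 06:00), P2 = \[06:00, 12:00), P3 = \[12:00, 18:00),
#' P4 = \[18:00, 24:00). Half-open blocks close the gap left by the survey
#' description's printed "00:00-05:00" style endpoints.
#'
#' @param datetime `POSIXct` or parseable string (vectorised).
#' @return factor with levels `P1`..`P4`.
#' @export
assign_time_period <- function(datetime) {
  dt <- as.POSIXct(datetime, tz = "UTC")
  if (any(is.na(dt))) stop_validation("unparseable datetime")
  hour <- as.integer(format(dt, "%H"))
  factor(paste0("P", hour %/% 6L + 1L), levels = paste0("P", 1:4))
}

#' Assign a distance-to-shore (depth profile) class
#'
#' Four classes by bottom depth: 1 = 0-200 m, 2 = 201-500 m,
#' 3 = 501-1000 m, 4 = > 1000 m.
#'
#' @param bottom_depth m (vectorised).
#' @return factor with levels `D1`..`D4` (shallowest first).
#' @export
assign_shore_class <- function(bottom_depth) {
  if (any(!is.finite(bottom_depth)) || any(bottom_depth < 0))
    stop_validation("bottom_depth must be non-negative")
  factor(ifelse(bottom_depth <= 200, "D1",
         ifelse(bottom_depth <= 500, "D2",
         ifelse(bottom_depth <= 1000, "D3", "D4"))),
         levels = paste0("D", 1:4))
}

#' Default sub-area polygons around Iceland
#'
#' The five survey sub-areas (N, E, SE, SW, W) are not published as
#' coordinates; this default is a documented set of rectangles
#' approximating the survey map, adequate for synthetic data and for
#' testing. Each polygon is a two-column matrix of (longitude, latitude)
#' vertices; the list order `N > E > SE > SW > W` is also the precedence
#' order for points on shared edges.
#'
#' @return named list of polygon matrices.
#' @export
default_area_polygons <- function() {
  rect <- function(lon1, lon2, lat1, lat2)
    cbind(lon = c(lon1, lon2, lon2, lon1), lat = c(lat1, lat1, lat2, lat2))
  list(N  = rect(-30, -8, 66, 70),
       E  = rect(-15, -5, 63, 66),
       SE = rect(-19, -15, 62, 66),
       SW = rect(-24, -19, 62, 66),
       W  = rect(-30, -24, 62, 66))
}

# Even-odd ray casting; points exactly on an edge count as inside, so
# precedence order of the polygon list resolves shared-edge ties.
point_in_polygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check (collinear and within the segment's bounding box)
    cross <- (xj - xi) * (lat - yi) - (yj - yi) * (lon - xi)
    if (abs(cross) < 1e-12 &&
        lon >= min(xi, xj) - 1e-12 && lon <= max(xi, xj) + 1e-12 &&
        lat >= min(yi, yj) - 1e-12 && lat <= max(yi, yj) + 1e-12)
      return(TRUE)
    if ((yi > lat) != (yj > lat) &&
        lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

#' Assign a survey sub-area from position
#'
#' Tests the point against each configured polygon in order
#' (`N > E > SE > SW > W` by default); the first containing polygon wins,
#' which fixes the label for points on shared boundaries. Points outside
#' all polygons are labelled `"unassigned"` with a warning.
#'
#' @param longitude,latitude decimal degrees (vectorised together).
#' @param polygons named list of (lon, lat) vertex matrices, in precedence
#'   order; see [default_area_polygons()].
#' @return character vector of area labels.
#' @export
assign_area <- function(longitude, latitude,
                        polygons = default_area_polygons()) {
  stopifnot(length(longitude) == length(latitude))
  vapply(seq_along(longitude), function(i) {
    for (nm in names(polygons)) {
      if (point_in_polygon(longitude[i], latitude[i], polygons[[nm]]))
        return(nm)
    }
    warning(sprintf("point (%.3f, %.3f) outside all area polygons; unassigned",
                    longitude[i], latitude[i]), call. = FALSE)
    "unassigned"
  }, character(1))
}

#' Fulton's condition factor
#'
#' K = 100 W / L^3 with W the whole body weight in grams and L the total
#' length in centimetres.
#'
#' @param body_weight g (vectorised).
#' @param length cm.
#' @return numeric K.
#' @export
fulton_k <- function(body_weight, length) {
  if (any(!is.finite(body_weight)) || any(body_weight <= 0) ||
      any(!is.finite(length)) || any(length <= 0))
    stop_validation("fulton_k: body_weight and length must be positive")
  100 * body_weight / length^3
}

#' Expand a subsampled prey item to whole-stomach scale
#'
#' Dense zooplankton stomach contents are counted in a small measured
#' subsample; counts and weights scale linearly with the volume ratio.
#'
#' @param item a [prey_item()].
#' @param total_volume total mixture volume, mL.
#' @param subsample_volume counted volume, mL; `0 < subsample <= total`.
#' @return a new `prey_item` with scaled count and weight; the scaling
#'   factor is recorded in attribute `"subsample_factor"`.
#' @export
expand_subsample <- function(item, total_volume, subsample_volume) {
  stopifnot(inherits(item, "prey_item"))
  if (!is_number(total_volume) || !is_number(subsample_volume) ||
      total_volume <= 0 || subsample_volume <= 0)
    stop_validation("expand_subsample: volumes must be positive")
  if (subsample_volume > total_volume)
    stop_validation("expand_subsample: subsample_volume exceeds total_volume")
  f <- total_volume / subsample_volume
  out <- prey_item(item$taxon_name, item$prey_group, item$count * f,
                   item$weight * f, item$prey_length)
  attr(out, "subsample_factor") <- f
  out
}
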