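#' @name geometry
#' @title Coccosphere geometry
#'
#' @description
#' Coccosphere volume is computed from the two axes measurable on a 2-D SEM
#' image using one of three idealised shape classes assigned per taxon:
#' prolate spheroid (also used for spherical, sub-spherical and elongated
#' ellipsoid coccospheres, since the third axis cannot be measured),
#' cone-plus-half-sphere, and double cone (strongly elongated, tapering
#' coccospheres such as *Calciosolenia*). Coccosphere size is reported as the
#' equivalent spherical diameter (ESD), the diameter of a sphere of the same
#' volume. All lengths are in micrometres, volumes in cubic micrometres.
NULL

#' Shape classes recognised for coccosphere volume computation
#' @export
SHAPE_CLASSES <- c("PROLATE_SPHERE", "CONE_HALF_SPHERE", "DOUBLE_CONE")

#' Normalise coccosphere axis measurements
#'
#' Ensures the short axis does not exceed the long axis, swapping the two
#' (with a warning) when the inputs arrive reversed. Field tables sometimes
#' carry the axes in either order.
#'
#' @param short_axis_d short-axis measurement d (µm)
#' @param long_axis_h long-axis measurement h (µm)
#' @return list with components `d` and `h`, `d <= h`
#' @export
normalize_axes <- function(short_axis_d, long_axis_h) {
  if (any(!is.finite(short_axis_d)) || any(!is.finite(long_axis_h)) ||
      any(short_axis_d <= 0) || any(long_axis_h <= 0)) {
    stop("coccosphere axes must be positive finite lengths (um)")
  }
  swapped <- short_axis_d > long_axis_h
  if (any(swapped)) {
    warning(sprintf("%d axis pair(s) arrived with d > h; swapped to d <= h",
                    sum(swapped)))
    tmp <- short_axis_d[swapped]
    short_axis_d[swapped] <- long_axis_h[swapped]
    long_axis_h[swapped] <- tmp
  }
  list(d = short_axis_d, h = long_axis_h)
}

#' Coccosphere volume by shape class
#'
#' Prolate spheroid: (pi/6) d^2 h; cone + half sphere: (pi/4) h d^2;
#' double cone: (pi/12) h d^2, where d is the short-axis and h the long-axis
#' measurement of the coccosphere.
#'
#' @param short_axis_d short-axis measurement d (µm)
#' @param long_axis_h long-axis measurement h (µm)
#' @param shape_class one of [SHAPE_CLASSES]
#' @return volume (µm^3)
#' @examples
#' coccosphere_volume(2, 2)                  # sphere, 4*pi/3
#' coccosphere_volume(2, 6, "DOUBLE_CONE")   # 2*pi
#' @export
coccosphere_volume <- function(short_axis_d, long_axis_h,
                               shape_class = "PROLATE_SPHERE") {
  shape_class <- match.arg(shape_class, SHAPE_CLASSES)
  ax <- normalize_axes(short_axis_d, long_axis_h)
  coef <- switch(shape_class,
                 PROLATE_SPHERE = pi / 6,
                 CONE_HALF_SPHERE = pi / 4,
                 DOUBLE_CONE = pi / 12)
  coef * ax$d^2 * ax$h
}

#' Equivalent spherical diameter from volume
#'
#' Inverse of the sphere volume formula: (6 V / pi)^(1/3).
#'
#' @param volume coccosphere volume (µm^3)
#' @return equivalent spherical diameter (µm)
#' @export
equivalent_spherical_diameter <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be a positive finite value (um^3)")
  }
  (6 * volume / pi)^(1 / 3)
}

#' Cell diameter from coccosphere equivalent spherical diameter
#'
#' The organic cell is hidden by the coccosphere, so cell size is estimated
#' from coccosphere size via the taxon-specific fraction y of coccosphere
#' volume occupied by the cell; the equivalent spherical cell diameter
#' reduces to `esd * y^(1/3)`.
#'
#' @param esd coccosphere equivalent spherical diameter (µm)
#' @param y_fraction cell volume / coccosphere volume, in (0, 1]
#' @return equivalent spherical cell diameter (µm)
#' @export
cell_diameter_from_coccosphere <- function(esd, y_fraction) {
  if (any(!is.finite(esd)) || any(esd <= 0)) {
    stop("esd must be a positive finite length (um)")
  }
  if (any(!is.finite(y_fraction)) || any(y_fraction <= 0) ||
      any(y_fraction > 1)) {
    stop("y_fraction must lie in (0, 1]")
  }
  esd * y_fraction^(1 / 3)
}

#' Multilayer coccosphere diameter correction
#'
#' Some taxa (notably *Emiliania huxleyi*) build coccospheres with more than
#' one coccolith layer. Applying the single-layer cell-volume fraction to a
#' multilayer coccosphere would overestimate cell size, so the measured
#' diameter is reduced to that of an equivalent single-layer coccosphere by
#' subtracting twice the coccolith thickness per extra layer:
#' `esd - 2 * (n_layers - 1) * thickness`.
#'
#' @param esd measured coccosphere equivalent spherical diameter (µm)
#' @param n_layers number of coccolith layers (>= 1)
#' @param coccolith_thickness mean coccolith thickness (µm); 0.13 for
#'   *E. huxleyi*
#' @return corrected diameter (µm)
#' @export
multilayer_corrected_diameter <- function(esd, n_layers,
                                          coccolith_thickness = 0.13) {
  if (any(esd <= 0)) stop("esd must be positive")
  if (any(n_layers < 1) || any(n_layers != round(n_layers))) {
    stop("n_layers must be an integer >= 1")
  }
  if (any(coccolith_thickness <= 0)) stop("coccolith_thickness must be positive")
  corrected <- esd - 2 * (n_layers - 1) * coccolith_thickness
  if (any(corrected <= 0)) {
    stop("multilayer correction exceeds coccosphere diameter (degenerate coccosphere)")
  }
  corrected
}

#' Approximate coccolith length from a partial measurement
#'
#' When no complete flat-lying coccolith is visible, the distance from the
#' central-area mid-point to the distal shield edge is measured and doubled.
#'
#' @param half_length centre-to-rim measurement (µm)
#' @return approximated full coccolith length (µm)
#' @export
full_length_from_partial <- function(half_length) {
  if (any(!is.finite(half_length)) || any(half_length <= 0)) {
    stop("half_length must be a positive finite length (um)")
  }
  2 * half_length
}
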