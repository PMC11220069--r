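#' @name calcite
#' @title Coccolith and cellular calcite estimation
#'
#' @description
#' Coccolith calcite mass is estimated from coccolith size via the
#' shape-factor model: `coccolith PIC (pg CaCO3) = C_L^3 * Ks * 2.7`, where
#' `C_L` is the taxon's size metric (usually distal shield length, µm), `Ks`
#' a dimensionless species- or genus-specific shape factor, and 2.7 the
#' density of calcite in pg per µm^3. Cellular calcite multiplies coccolith
#' PIC by the number of coccoliths per cell (`C_N`) and adds taxon-specific
#' components: exothecal coccoliths, appendage coccoliths, and the spinose
#' half of dimorphic coccospheres.
NULL

#' Density of calcite used throughout the calcite-mass model (pg per µm^3)
#' @export
CALCITE_DENSITY <- 2.7

#' Calcite mass of a single coccolith
#'
#' @param c_l coccolith size metric (µm)
#' @param ks dimensionless shape factor (extant species span ca. 0.01-0.2)
#' @return coccolith calcite mass (pg CaCO3)
#' @examples
#' coccolith_pic(1.8, 0.03) # 0.47 pg, an Ophiaster osteolith
#' @export
coccolith_pic <- function(c_l, ks) {
  if (any(!is.finite(c_l)) || any(c_l <= 0)) stop("c_l must be positive")
  if (any(!is.finite(ks)) || any(ks <= 0)) stop("ks must be positive")
  ks * c_l^3 * CALCITE_DENSITY
}

#' Back-calculate a shape factor from a known coccolith mass
#'
#' Inverse of [coccolith_pic()]: `Ks = mass / (C_L^3 * 2.7)`. Used to derive
#' shape factors for taxa with an independently measured coccolith calcite
#' mass (e.g. *Calciosolenia*, from a 2.5 pg birefringence-based estimate at
#' 5 µm length).
#'
#' @param coccolith_mass coccolith calcite mass (pg)
#' @param c_l coccolith size metric (µm)
#' @return dimensionless shape factor
#' @export
back_calculate_ks <- function(coccolith_mass, c_l) {
  if (any(coccolith_mass <= 0)) stop("coccolith_mass must be positive")
  if (any(c_l <= 0)) stop("c_l must be positive")
  coccolith_mass / (c_l^3 * CALCITE_DENSITY)
}

#' Cellular (coccosphere) calcite from per-coccolith calcite
#'
#' @param coccolith_pic calcite mass of one coccolith (pg)
#' @param c_n number of coccoliths per cell (>= 1; fractional counts from
#'   the dimorphic 50/50 split are permitted)
#' @return coccosphere calcite (pg)
#' @export
cellular_pic <- function(coccolith_pic, c_n) {
  if (any(c_n < 1)) stop("c_n must be >= 1")
  coccolith_pic * c_n
}

#' Appendage calcite for arm-bearing Syracosphaeraceae
#'
#' Two rules exist. *Michaelsarsia*: a fixed mass per appendage (12.5 pg,
#' from 4 segments of typical length 5.5 µm at Ks 0.007) times the counted
#' number of appendages, assuming the default count (8, i.e. 100 pg) when
#' appendages could not be counted. *Ophiaster*: a fixed total (33 pg,
#' from on average 5 arms of 14 osteoliths of 1.8 µm at Ks 0.03) added
#' only when arms are clearly present.
#'
#' @param params resolved taxon parameters (see [resolve_taxon()])
#' @param n_appendages counted appendages, or `NA` when unknown
#' @param present for the fixed-total rule: are appendages present?
#' @return list with `mass` (pg) and `assumed` (logical: default count used)
#' @export
appendage_calcite <- function(params, n_appendages = NA, present = NA) {
  per <- params$appendage_pg_per_appendage
  tot <- params$appendage_fixed_total_pg
  if (!is.na(per)) {
    if (is.na(n_appendages)) {
      return(list(mass = per * params$appendage_default_count, assumed = TRUE))
    }
    if (n_appendages < 0) stop("n_appendages must be >= 0")
    return(list(mass = per * n_appendages, assumed = FALSE))
  }
  if (!is.na(tot)) {
    if (isTRUE(present) || (!is.na(n_appendages) && n_appendages > 0)) {
      return(list(mass = tot, assumed = FALSE))
    }
    return(list(mass = 0, assumed = FALSE))
  }
  stop("taxon has no appendage rule")
}

#' Exothecal coccolith calcite
#'
#' Some *Syracosphaera* species carry an outer layer of exothecal coccoliths
#' (XCs) over the body coccoliths. Their calcite is added by counting them
#' and applying a single shape factor (default 0.02) across the diverse XC
#' morphologies.
#'
#' @param n_xc number of exothecal coccoliths (>= 0)
#' @param c_l_xc exothecal coccolith length (µm)
#' @param ks_xc shape factor for exothecal coccoliths
#' @return total exothecal calcite (pg)
#' @export
exothecal_calcite <- function(n_xc, c_l_xc, ks_xc = 0.02) {
  if (any(n_xc < 0)) stop("n_xc must be >= 0")
  if (n_xc == 0) return(0)
  n_xc * coccolith_pic(c_l_xc, ks_xc)
}

#' Back-calculate coccolith count for holococcolithophores
#'
#' Holococcoliths are often too small and numerous to count, so `C_N` is
#' estimated from the ratio of coccosphere surface area to coccolith
#' footprint area. The coccolith footprint is modelled as an ellipse
#' (`pi * C_L * C_W / 4`) on a spherical coccosphere of surface `pi * esd^2`,
#' assuming single-layer coverage with no overlap, giving
#' `round(packing * 4 * esd^2 / (C_L * C_W))`.
#'
#' @param coccosphere_esd coccosphere equivalent spherical diameter (µm)
#' @param c_l coccolith length (µm)
#' @param c_w coccolith width (µm); must not exceed `c_l`
#' @param packing fraction of the sphere surface covered by coccoliths
#'   (default 1, full coverage)
#' @return estimated integer coccolith count (>= 1)
#' @export
holococcolith_cn_estimate <- function(coccosphere_esd, c_l, c_w,
                                      packing = 1) {
  if (any(coccosphere_esd <= 0) || any(c_l <= 0) || any(c_w <= 0)) {
    stop("lengths must be positive")
  }
  if (any(c_w > c_l)) stop("c_w must not exceed c_l")
  n <- round(packing * 4 * coccosphere_esd^2 / (c_l * c_w))
  if (any(n < 1)) {
    stop("coccolith footprint exceeds coccosphere surface (count < 1)")
  }
  n
}

#' Average coccolith length of an Umbellosphaera coccosphere
#'
#' *Umbellosphaera* coccospheres carry coccoliths of widely varying size, so
#' the largest (measurable) coccolith is not representative. From a fully
#' measured (collapsed) coccosphere, the coccosphere calcite
#' `sum(Ks * C_Li^3 * 2.7)` is back-converted to the single length that
#' would reproduce it at the same count:
#' `average C_L = (coccosphere calcite / (Ks * C_N * 2.7))^(1/3)`, i.e. the
#' cubic mean of the lengths. The ratio of this average to the largest
#' measured coccolith motivates the fixed 0.7 factor applied to intact
#' coccospheres.
#'
#' @param collapsed_cls coccolith lengths measured on one collapsed
#'   coccosphere (µm)
#' @param ks shape factor (cancels in the ratio; kept for fidelity to the
#'   mass-based derivation)
#' @return list with `average_cl` (µm) and `ratio_to_max` in (0, 1]
#' @export
umbellosphaera_average_cl <- function(collapsed_cls, ks = 0.06) {
  if (length(collapsed_cls) == 0) stop("collapsed_cls must be non-empty")
  if (any(collapsed_cls <= 0)) stop("lengths must be positive")
  total <- sum(coccolith_pic(collapsed_cls, ks))
  avg <- (total / (ks * length(collapsed_cls) * CALCITE_DENSITY))^(1 / 3)
  list(average_cl = avg, ratio_to_max = avg / max(collapsed_cls))
}

#' Calcite of a dimorphic (spinose/non-spinose) coccosphere
#'
#' *Rhabdosphaera* coccospheres mix coccoliths with and without spines; a
#' 50/50 split is assumed. The non-spinose half uses coccolith length and
#' the body shape factor; the spinose half uses spine length (falling back
#' to a fixed 5 µm when it could not be measured) and the spinose shape
#' factor. Fractional coccolith counts are carried as real numbers.
#'
#' @param c_l coccolith length (µm)
#' @param spine_length measured spine length (µm) or `NA`
#' @param c_n total coccoliths per cell (>= 1)
#' @param params resolved taxon parameters with `dimorphic_spinose_fraction`,
#'   `ks_body`, `ks_spinose` and `fixed_spine_length`
#' @return list with `body_total`, `spinose_total` (pg) and
#'   `spine_fallback_used` (logical)
#' @export
dimorphic_pic <- function(c_l, spine_length, c_n, params) {
  f <- params$dimorphic_spinose_fraction
  if (is.na(f)) stop("taxon has no dimorphic_spinose_fraction")
  if (c_n < 1) stop("c_n must be >= 1")
  if (f > 0 && is.na(params$ks_spinose)) {
    stop("dimorphic taxon lacks ks_spinose")
  }
  fallback <- is.na(spine_length)
  if (fallback) spine_length <- params$fixed_spine_length
  body_total <- (1 - f) * c_n * coccolith_pic(c_l, params$ks_body)
  spinose_total <- if (f > 0) {
    f * c_n * coccolith_pic(spine_length, params$ks_spinose)
  } else 0
  list(body_total = body_total, spinose_total = spinose_total,
       spine_fallback_used = fallback && f > 0)
}

#' Total cellular calcite with all taxon-specific corrections
#'
#' Orchestrates the calcite computation for one measured coccosphere:
#' effective coccolith length (measured value, partial-length doubling
#' applied upstream; fixed fallback length for *Alisphaera* polycrater;
#' 0.7 x largest length for *Umbellosphaera*), effective coccolith count
#' (measured total plus loose adjacent coccoliths; fixed fallback counts
#' for *Florisphaera*/*Alisphaera*; surface-area back-calculation for
#' holococcolithophores), body (+ circum-flagellar) calcite via the
#' shape-factor model, and additive exothecal, appendage and dimorphic
#' spinose components. Circum-flagellar coccoliths use the same shape
#' factor as body coccoliths, so they are carried inside the body count.
#'
#' @param record a single measurement record: a list (or one-row data frame
#'   coerced to list) with the fields documented in [read_measurements()];
#'   `coccolith_length_um` must already be the full length
#' @param params resolved taxon parameters (see [resolve_taxon()])
#' @param ks_scale,cl_scale multiplicative perturbations of the shape factor
#'   and of every measured length entering the calcite model (used by the
#'   sensitivity analysis; default 1)
#' @param cn_delta additive perturbation of the effective coccolith count,
#'   floored at 1 (default 0)
#' @return object of class `calcite_breakdown`: list with
#'   `body_coccolith_pic` (pg per body coccolith), `body_total`, `cfc_total`,
#'   `exothecal_total`, `appendage_total`, `cellular_pic` (pg),
#'   `size_metric_used`, and a character vector `flags` of provenance
#'   markers (`fixed_cn_used`, `fixed_cl_used`, `cn_backcalculated`,
#'   `partial_length`, `appendages_assumed`, `spine_fallback`,
#'   `xc_counted`, `xc_length_from_body`, `loose_included`,
#'   `dimorphic_split`, `visible_count_scaled`, `measured_overrides_fixed`)
#' @export
total_cell_calcite <- function(record, params, ks_scale = 1, cl_scale = 1,
                               cn_delta = 0) {
  flags <- character(0)
  g <- function(name) {
    v <- record[[name]]
    if (is.null(v) || length(v) == 0) NA else v
  }

  ## effective coccolith length
  cl_meas <- g("coccolith_length_um")
  if (isTRUE(g("partial_length_flag"))) flags <- c(flags, "partial_length")
  if (!is.na(cl_meas)) {
    cl <- cl_meas
    if (!is.na(params$fixed_cl)) flags <- c(flags, "measured_overrides_fixed")
  } else if (!is.na(params$fixed_cl)) {
    cl <- params$fixed_cl
    flags <- c(flags, "fixed_cl_used")
  } else {
    stop(sprintf("record %s: no coccolith length and no fixed fallback",
                 g("record_id")))
  }
  if (!is.na(params$umbellosphaera_cl_factor)) {
    cl <- params$umbellosphaera_cl_factor * cl
    flags <- c(flags, "average_cl_factor")
  }
  cl_eff <- cl * cl_scale

  ## effective coccolith count
  cn_total <- g("total_coccolith_count")
  loose <- g("loose_adjacent_count")
  if (is.na(loose)) loose <- 0
  if (is.na(cn_total) && !is.na(g("visible_coccolith_count"))) {
    cn_total <- g("visible_coccolith_count") * params$cn_multiplier
    flags <- c(flags, "visible_count_scaled")
  }
  if (!is.na(cn_total)) {
    cn <- cn_total + loose
    if (loose > 0) flags <- c(flags, "loose_included")
    if (!is.na(params$fixed_cn)) flags <- c(flags, "measured_overrides_fixed")
  } else if (!is.na(params$fixed_cn)) {
    cn <- params$fixed_cn
    flags <- c(flags, "fixed_cn_used")
  } else if (params$life_cycle_phase == "holococcolith") {
    d <- g("coccosphere_short_axis_um"); h <- g("coccosphere_long_axis_um")
    if (is.na(d) || is.na(h)) {
      stop(sprintf("record %s: holococcolith count back-calculation needs coccosphere axes",
                   g("record_id")))
    }
    esd <- equivalent_spherical_diameter(
      coccosphere_volume(d, h, params$shape_class))
    cw <- g("coccolith_width_um")
    if (is.na(cw)) {
      cw <- cl
      flags <- c(flags, "width_from_length")
    }
    cn <- holococcolith_cn_estimate(esd, cl, cw)
    flags <- c(flags, "cn_backcalculated")
  } else {
    stop(sprintf("record %s: no coccolith count and no fallback rule",
                 g("record_id")))
  }
  cn_eff <- max(1, cn + cn_delta)

  ks_eff <- params$ks_body * ks_scale

  ## body (+ CFC) calcite; dimorphic split where configured
  if (!is.na(params$dimorphic_spinose_fraction)) {
    spine <- g("process_height_um")
    if (!is.na(spine)) spine <- spine * cl_scale
    p2 <- params
    p2$ks_body <- ks_eff
    p2$ks_spinose <- params$ks_spinose * ks_scale
    p2$fixed_spine_length <- params$fixed_spine_length * cl_scale
    dm <- dimorphic_pic(cl_eff, spine, cn_eff, p2)
    body_total <- dm$body_total + dm$spinose_total
    flags <- c(flags, "dimorphic_split")
    if (dm$spine_fallback_used) flags <- c(flags, "spine_fallback")
    body_pic <- coccolith_pic(cl_eff, ks_eff)
  } else {
    body_pic <- coccolith_pic(cl_eff, ks_eff)
    body_total <- cellular_pic(body_pic, cn_eff)
  }

  ## exothecal coccoliths
  n_xc <- g("n_exothecal")
  if (is.na(n_xc)) n_xc <- 0
  exo_total <- 0
  if (n_xc > 0) {
    xc_len <- g("exothecal_length_um")
    if (is.na(xc_len)) {
      xc_len <- cl
      flags <- c(flags, "xc_length_from_body")
    }
    exo_total <- exothecal_calcite(n_xc, xc_len * cl_scale,
                                   params$ks_exothecal * ks_scale)
    flags <- c(flags, "xc_counted")
  }

  ## appendages (fixed masses; deliberately not scaled by perturbations)
  app_total <- 0
  has_app_rule <- !is.na(params$appendage_pg_per_appendage) ||
    !is.na(params$appendage_fixed_total_pg)
  if (has_app_rule) {
    app <- appendage_calcite(params, n_appendages = g("n_appendages"),
                             present = isTRUE(g("appendages_present")))
    app_total <- app$mass
    if (app$assumed) flags <- c(flags, "appendages_assumed")
  }

  cfc_total <- 0  # CFCs share the body Ks and are counted within C_N
  structure(list(
    body_coccolith_pic = body_pic,
    body_total = body_total,
    cfc_total = cfc_total,
    exothecal_total = exo_total,
    appendage_total = app_total,
    cellular_pic = body_total + cfc_total + exo_total + app_total,
    effective_cl = cl_eff,
    effective_cn = cn_eff,
    size_metric_used = params$size_metric,
    flags = unique(flags)
  ), class = "calcite_breakdown")
}
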