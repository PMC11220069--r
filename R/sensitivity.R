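# One-at-a-time sensitivity of estimated cellular calcite to the three
# parameters of the shape-factor model: Ks and C_L varied by +/-5..30%
# (relative), C_N by +/-2 and +/-5 coccoliths (absolute, floored at 1).

#' Closed-form percent change of cellular calcite under perturbation
#'
#' Analytic twin of [run_sensitivity()] for records without fixed-mass
#' components: a relative change `delta` in `C_L` changes cellular calcite
#' by `100 * ((1 + delta)^3 - 1)` percent (cubic law); a relative change in
#' `Ks` changes it by `100 * delta` percent (linearity); an absolute
#' miscount `Delta` changes it by `100 * Delta / C_N` percent.
#'
#' @param parameter one of `"KS"`, `"CL"`, `"CN"`
#' @param magnitude signed relative perturbation (KS/CL) or signed coccolith
#'   count change (CN)
#' @param c_n baseline coccolith count, required for `"CN"`
#' @return percent change of cellular calcite
#' @examples
#' closed_form_change("CL", 0.30)  # +119.7
#' closed_form_change("CL", -0.30) # -65.7
#' closed_form_change("CN", -2, c_n = 9) # -22.2
#' @export
closed_form_change <- function(parameter, magnitude, c_n = NULL) {
  parameter <- match.arg(parameter, c("KS", "CL", "CN"))
  switch(parameter,
         CL = 100 * ((1 + magnitude)^3 - 1),
         KS = 100 * magnitude,
         CN = {
           if (is.null(c_n)) stop("CN perturbation requires c_n")
           100 * magnitude / c_n
         })
}

#' Perturbation specification for the sensitivity analysis
#'
#' @param rel_magnitudes unsigned relative magnitudes applied as +/- to Ks
#'   and C_L
#' @param cn_deltas unsigned absolute coccolith-count changes applied as +/-
#' @param parameters which parameters to perturb
#' @return list of class `perturbation_spec`
#' @export
perturbation_spec <- function(rel_magnitudes = c(0.05, 0.10, 0.15, 0.20,
                                                 0.25, 0.30),
                              cn_deltas = c(2L, 5L),
                              parameters = c("KS", "CL", "CN")) {
  if (any(rel_magnitudes <= 0) || any(rel_magnitudes >= 1)) {
    stop("relative magnitudes must lie in (0, 1)")
  }
  if (any(cn_deltas != round(cn_deltas)) || any(cn_deltas < 1)) {
    stop("cn_deltas must be positive integers")
  }
  parameters <- match.arg(parameters, c("KS", "CL", "CN"), several.ok = TRUE)
  structure(list(rel_magnitudes = rel_magnitudes, cn_deltas = cn_deltas,
                 parameters = parameters), class = "perturbation_spec")
}

#' Sensitivity of cellular calcite to Ks, C_L and C_N perturbations
#'
#' For each record, the baseline cellular calcite is computed with all
#' taxon-specific corrections, then recomputed with a single parameter
#' perturbed (every measured length for C_L, every shape factor for Ks, the
#' effective count, floored at 1, for C_N) and the percent change reported.
#' Fixed appendage masses deliberately do not scale, so arm-bearing taxa
#' attenuate the closed-form response.
#'
#' @param records a data frame of measurement records (see
#'   [read_measurements()] / [generate_coccospheres()])
#' @param registry a `taxon_registry`
#' @param spec a [perturbation_spec()]
#' @return object of class `sensitivity_table`: a data frame with one row
#'   per record x parameter x signed magnitude, columns `record_id`,
#'   `taxon`, `parameter`, `magnitude`, `baseline_pic`, `perturbed_pic`,
#'   `pct_change`
#' @export
run_sensitivity <- function(records, registry, spec = perturbation_spec()) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame")
  }
  grid <- data.frame(parameter = character(0), magnitude = numeric(0))
  for (p in spec$parameters) {
    mags <- if (p == "CN") c(-spec$cn_deltas, spec$cn_deltas) else
      c(-spec$rel_magnitudes, spec$rel_magnitudes)
    grid <- rbind(grid, data.frame(parameter = p, magnitude = sort(mags)))
  }
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, ])
    key <- record_taxon_key(rec)
    params <- resolve_taxon(key, registry)
    base <- total_cell_calcite(rec, params)
    pert <- numeric(nrow(grid))
    for (j in seq_len(nrow(grid))) {
      m <- grid$magnitude[j]
      b <- switch(grid$parameter[j],
                  KS = total_cell_calcite(rec, params, ks_scale = 1 + m),
                  CL = total_cell_calcite(rec, params, cl_scale = 1 + m),
                  CN = total_cell_calcite(rec, params, cn_delta = m))
      pert[j] <- b$cellular_pic
    }
    rid <- rec$record_id
    if (is.null(rid) || is.na(rid)) rid <- as.character(i)
    out[[i]] <- data.frame(
      record_id = rid,
      taxon = taxon_label(key, params),
      parameter = grid$parameter,
      magnitude = grid$magnitude,
      baseline_pic = base$cellular_pic,
      perturbed_pic = pert,
      pct_change = 100 * (pert - base$cellular_pic) / base$cellular_pic,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  structure(res, class = c("sensitivity_table", "data.frame"))
}

#' Summarise a sensitivity table across records
#'
#' @param x a `sensitivity_table`
#' @return data frame with min/mean/max percent change per taxon, parameter
#'   and signed magnitude
#' @export
summarize_sensitivity <- function(x) {
  stopifnot(inherits(x, "sensitivity_table"))
  agg <- stats::aggregate(pct_change ~ taxon + parameter + magnitude,
                          data = as.data.frame(x),
                          FUN = function(v) c(min = min(v), mean = mean(v),
                                              max = max(v)))
  out <- cbind(agg[c("taxon", "parameter", "magnitude")],
               as.data.frame(agg$pct_change))
  out[order(out$taxon, out$parameter, out$magnitude), ]
}

#' @export
print.sensitivity_table <- function(x, ...) {
  need <- c("taxon", "parameter", "magnitude", "pct_change")
  if (!all(need %in% names(x))) return(NextMethod())
  cat(sprintf("<sensitivity_table: %d rows, %d records>\n", nrow(x),
              length(unique(x$record_id))))
  print(utils::head(summarize_sensitivity(x), 12), digits = 4)
  invisible(x)
}

#' Plot a sensitivity table
#'
#' One panel per perturbed parameter, percent change in cellular calcite
#' against perturbation magnitude, one line per taxon (mean across records,
#' min-max whiskers).
#'
#' @param x a `sensitivity_table`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.sensitivity_table <- function(x, ...) {
  s <- summarize_sensitivity(x)
  pars <- unique(s$parameter)
  old <- graphics::par(mfrow = c(1, length(pars)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    sp <- s[s$parameter == p, ]
    taxa <- unique(sp$taxon)
    xlab <- if (p == "CN") "count change (coccoliths)" else
      "relative change"
    graphics::plot(NA, xlim = range(sp$magnitude), ylim = range(sp$min, sp$max),
                   xlab = xlab, ylab = "cellular calcite change (%)",
                   main = p, ...)
    graphics::abline(h = 0, col = "grey70")
    for (k in seq_along(taxa)) {
      st <- sp[sp$taxon == taxa[k], ]
      graphics::lines(st$magnitude, st$mean, col = k, type = "b", pch = 16)
      graphics::segments(st$magnitude, st$min, st$magnitude, st$max, col = k)
    }
    if (p == pars[1]) {
      graphics::legend("topleft", legend = taxa, col = seq_along(taxa),
                       lty = 1, bty = "n", cex = 0.7)
    }
  }
  invisible(x)
}
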