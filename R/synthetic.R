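# Seeded synthetic-data generator. Emulates the structure of the published
# per-coccosphere measurement table (one row per intact coccosphere,
# plain-language columns plus a notes column with flag tokens) with
# self-consistent geometry: coccosphere surface area matches the coccolith
# footprint of the placed coccoliths, and cell size follows the taxon's
# cell-to-coccosphere volume fraction. Ground truth is returned alongside
# so recovery can be tested without the archived dataset.

#' Measurement-noise configuration for the synthetic generator
#'
#' @param partial_prob probability a coccolith length is recorded as a
#'   centre-to-rim half length (doubling mode); the doubling error has mean
#'   -0.6\% and is truncated at +/-8\%, matching the loose-coccolith
#'   calibration of the measurement protocol
#' @param partial_mean,partial_sd,partial_max doubling-error distribution
#'   (relative; normal, truncated at `partial_max`)
#' @param miscount_prob probability the visible coccolith count carries a
#'   counting error
#' @param miscount_max maximum absolute counting error (coccoliths, 1-5)
#' @param spine_record_prob probability a spine length is measurable (the
#'   fixed 5 um fallback is used otherwise)
#' @param appendage_record_prob probability the appendage count is
#'   observable (the default count is assumed otherwise)
#' @return list of class `noise_config`
#' @export
noise_config <- function(partial_prob = 0.15, partial_mean = -0.006,
                         partial_sd = 0.04, partial_max = 0.08,
                         miscount_prob = 0.10, miscount_max = 5,
                         spine_record_prob = 0.8,
                         appendage_record_prob = 0.7) {
  structure(list(partial_prob = partial_prob, partial_mean = partial_mean,
                 partial_sd = partial_sd, partial_max = partial_max,
                 miscount_prob = miscount_prob, miscount_max = miscount_max,
                 spine_record_prob = spine_record_prob,
                 appendage_record_prob = appendage_record_prob),
            class = "noise_config")
}

#' Noise-free configuration (all measurements exact, all fields observable)
#' @export
no_noise <- function() {
  noise_config(partial_prob = 0, miscount_prob = 0, spine_record_prob = 1,
               appendage_record_prob = 1)
}

# One list entry per taxon in the default mix. median_cl is the median
# coccolith length (um, lognormal), sdlog its log-scale SD between
# coccospheres; cn_mu/cn_size parameterise the visible-count model
# visible = 4 + NegBin(mu, size); cw_ratio is coccolith width / length.
default_taxon_mix <- function() {
  list(
    list(abundance = 0.25, family = "Noelaerhabdaceae", genus = "Emiliania",
         species = "huxleyi", phase = "heterococcolith", median_cl = 3.0,
         sdlog = 0.15, cn_mu = 7, cn_size = 8, cw_ratio = 0.8,
         layer_probs = c(0.80, 0.15, 0.05), loose_prob = 0.2),
    list(abundance = 0.12, family = "Syracosphaeraceae",
         genus = "Syracosphaera", morpho_group = "pulchra group",
         phase = "heterococcolith", median_cl = 6.0, sdlog = 0.15,
         cn_mu = 8, cn_size = 8, cw_ratio = 0.7, xc_prob = 0.7,
         xc_mean = 6, xc_len_ratio = 0.8),
    list(abundance = 0.08, family = "Syracosphaeraceae",
         genus = "Syracosphaera", morpho_group = "molischii group",
         phase = "heterococcolith", median_cl = 2.5, sdlog = 0.15,
         cn_mu = 10, cn_size = 8, cw_ratio = 0.7),
    list(abundance = 0.07, family = "Syracosphaeraceae",
         genus = "Michaelsarsia", phase = "heterococcolith",
         median_cl = 3.5, sdlog = 0.12, cn_mu = 10, cn_size = 8,
         cw_ratio = 0.7, appendage_range = 6:12),
    list(abundance = 0.07, family = "Syracosphaeraceae", genus = "Ophiaster",
         phase = "heterococcolith", median_cl = 2.0, sdlog = 0.12,
         cn_mu = 8, cn_size = 8, cw_ratio = 0.7, arm_prob = 0.6),
    list(abundance = 0.08, family = "Rhabdosphaeraceae",
         genus = "Rhabdosphaera", species = "clavigera",
         phase = "heterococcolith", median_cl = 2.5, sdlog = 0.12,
         cn_mu = 6, cn_size = 8, cw_ratio = 0.8, spine_median = 5,
         spine_sdlog = 0.10),
    list(abundance = 0.08, family = "Umbellosphaeraceae",
         genus = "Umbellosphaera", phase = "heterococcolith",
         median_cl = 7.0, sdlog = 0.15, cn_mu = 4, cn_size = 8,
         cw_ratio = 0.9, umbellosphaera = TRUE),
    list(abundance = 0.08, family = "incertae sedis", genus = "Florisphaera",
         species = "profunda", phase = "nannolith", median_cl = 2.0,
         sdlog = 0.10, cw_ratio = 0.5, fixed_cn_truth = 145),
    list(abundance = 0.07, family = "Alisphaeraceae", genus = "Alisphaera",
         phase = "polycrater", cw_ratio = 0.7, fixed_cn_truth = 400,
         fixed_cl_truth = 0.8, unmeasured = TRUE),
    list(abundance = 0.05, family = "Calyptrosphaeraceae",
         genus = "Calyptrolithina", species = "multipora",
         phase = "holococcolith", median_cl = 1.5, sdlog = 0.12,
         cn_mu = 40, cn_size = 10, cw_ratio = 0.75, holococcolith = TRUE),
    list(abundance = 0.05, family = "Calciosoleniaceae",
         genus = "Calciosolenia", phase = "heterococcolith",
         median_cl = 5.0, sdlog = 0.12, cn_mu = 16, cn_size = 8,
         cw_ratio = 0.5, double_cone = TRUE)
  )
}

#' Synthetic-data generator configuration
#'
#' @param taxon_mix list of per-taxon models (see `default_taxon_mix`
#'   in the package source); relative abundances must sum to 1
#' @param within_sd within-coccosphere coccolith-size spread (relative SD
#'   on the log scale; sizes on one coccosphere vary by up to ca. 30\%, and
#'   0.10 is the default "reasonable" level)
#' @param noise a [noise_config()]
#' @param seed integer seed fixing the full output
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(taxon_mix = default_taxon_mix(),
                             within_sd = 0.10, noise = noise_config(),
                             seed = 1L) {
  ab <- vapply(taxon_mix, function(t) t$abundance, numeric(1))
  if (abs(sum(ab) - 1) > 1e-8) stop("taxon mix abundances must sum to 1")
  if (within_sd < 0) stop("within_sd must be >= 0")
  stopifnot(inherits(noise, "noise_config"))
  structure(list(taxon_mix = taxon_mix, within_sd = within_sd,
                 noise = noise, seed = as.integer(seed)),
            class = "synthetic_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

axes_from_esd <- function(esd, double_cone = FALSE) {
  if (double_cone) {
    r <- stats::runif(1, 3, 5)           # strongly elongated, tapering
    d <- (2 / r)^(1 / 3) * esd
    list(d = d, h = r * d)
  } else {
    r <- stats::runif(1, 1, 1.3)         # sphere to mild prolate
    list(d = esd * r^(-1 / 3), h = esd * r^(2 / 3))
  }
}

#' Generate synthetic per-coccosphere measurement records with ground truth
#'
#' Draws records from the configured taxon mix. For each record the
#' coccolith count and per-coccolith sizes are drawn first, the coccosphere
#' equivalent spherical diameter is set so that its surface area equals the
#' placed coccoliths' elliptical footprints (divided over the coccolith
#' layers), and the axes are drawn at a random aspect ratio preserving that
#' diameter. The recorded measurement emulates SEM practice: one coccolith
#' length draw per coccosphere, the visible-hemisphere count, and the
#' configured noise modes (partial-length doubling error, coccolith
#' miscounts, unmeasurable spines/appendage counts). *Umbellosphaera*
#' coccolith sizes are rescaled so their cubic mean is exactly 0.7 x the
#' largest coccolith, making the fixed average-length factor exact for
#' generated data. Identical seed and config give identical output.
#'
#' @param config a [synthetic_config()]
#' @param n_records number of coccospheres to generate (>= 1)
#' @return list with `records` (data frame in the machine schema of
#'   [read_measurements()], counts recorded as visible-hemisphere counts)
#'   and `truth` (data frame: `record_id`, `taxon`, `true_cn`,
#'   `true_mean_cl`, `true_esd`, `true_cell_diameter`, `true_cellular_pic`)
#' @export
generate_coccospheres <- function(config, n_records) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(n_records) != 1 || n_records < 1 ||
      n_records != round(n_records)) {
    stop("n_records must be a positive integer")
  }
  set.seed(config$seed)
  registry <- default_registry()
  noise <- config$noise
  ws <- config$within_sd
  mix <- config$taxon_mix
  ab <- vapply(mix, function(t) t$abundance, numeric(1))

  recs <- vector("list", n_records)
  tru <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    t <- mix[[sample.int(length(mix), 1, prob = ab)]]
    key <- taxon_key(genus = t$genus, species = t$species %||% NULL,
                     morpho_group = t$morpho_group %||% NULL,
                     family = t$family, life_cycle_phase = t$phase)
    params <- resolve_taxon(key, registry)

    rec <- stats::setNames(as.list(rep(NA, length(RECORD_COLS))), RECORD_COLS)
    rec$record_id <- sprintf("syn%04d", i)
    rec$station <- "SYN"; rec$water_depth_m <- 10
    rec$image_id <- sprintf("img%04d", i)
    rec$family <- t$family; rec$genus <- t$genus
    rec$species <- t$species %||% NA_character_
    rec$morpho_group <- t$morpho_group %||% NA_character_
    rec$life_cycle_phase <- t$phase
    rec$n_layers <- 1; rec$n_exothecal <- 0; rec$loose_adjacent_count <- 0
    rec$partial_length_flag <- FALSE
    notes <- character(0)

    fixed_cl <- t$fixed_cl_truth %||% NA
    fixed_cn <- t$fixed_cn_truth %||% NA

    ## true coccolith sizes and count
    if (!is.na(fixed_cl)) {                       # Alisphaera polycrater
      cn_true <- fixed_cn
      lens <- fixed_cl * exp(stats::rnorm(cn_true, 0, ws))
      cl_meas <- NA
    } else {
      L0 <- stats::rlnorm(1, log(t$median_cl), t$sdlog)
      if (!is.na(fixed_cn)) {                     # Florisphaera
        cn_true <- fixed_cn
        lens <- L0 * exp(stats::rnorm(cn_true, 0, ws))
        cl_meas <- L0
      } else {
        visible <- 4 + stats::rnbinom(1, size = t$cn_size, mu = t$cn_mu)
        cn_true <- visible * params$cn_multiplier
        lens <- L0 * exp(stats::rnorm(cn_true, 0, ws))
        cl_meas <- if (isTRUE(t$umbellosphaera)) L0 else sample(lens, 1)
      }
    }
    if (isTRUE(t$umbellosphaera)) {
      # rescale so the cubic mean is exactly 0.7 * the largest (measured)
      lens <- lens * (0.7 * L0) / mean(lens^3)^(1 / 3)
    }
    cw <- t$cw_ratio * (if (is.na(cl_meas)) fixed_cl else cl_meas)

    ## layers and loose coccoliths (E. huxleyi)
    k_layers <- 1
    if (!is.null(t$layer_probs)) {
      k_layers <- sample.int(length(t$layer_probs), 1, prob = t$layer_probs)
      rec$n_layers <- k_layers
      if (k_layers > 1) notes <- c(notes, sprintf("multilayer:%d", k_layers))
    }
    loose <- 0
    if (!is.null(t$loose_prob) && stats::runif(1) < t$loose_prob) {
      loose <- sample(1:3, 1)
      lens <- c(lens, lens[seq_len(loose)])       # shed from this coccosphere
      rec$loose_adjacent_count <- loose
      notes <- c(notes, sprintf("loose:%d", loose))
    }

    ## geometry: surface area consistent with placed coccolith footprints
    mean_len <- mean(lens[seq_len(cn_true)])
    if (isTRUE(t$holococcolith)) {
      # exact closure with the surface-area count back-calculation
      esd_single <- sqrt(cn_true * cl_meas * cw) / 2
    } else {
      esd_single <- sqrt((cn_true / k_layers) * mean_len * cw) / 2
    }
    thick <- params$coccolith_thickness
    esd_meas <- esd_single +
      if (k_layers > 1 && !is.na(thick)) 2 * (k_layers - 1) * thick else 0
    ax <- axes_from_esd(esd_meas, double_cone = isTRUE(t$double_cone))
    rec$coccosphere_short_axis_um <- ax$d
    rec$coccosphere_long_axis_um <- ax$h
    true_cell_d <- esd_single * params$y_fraction^(1 / 3)

    ## calcite truth assembled from the per-coccolith list + fixed rules
    ks <- params$ks_body
    if (!is.na(params$dimorphic_spinose_fraction)) {
      f <- params$dimorphic_spinose_fraction
      spine_true <- stats::rlnorm(1, log(t$spine_median), t$spine_sdlog)
      body_pic_true <- sum((1 - f) * ks * lens^3 * CALCITE_DENSITY +
                             f * params$ks_spinose * spine_true^3 *
                               CALCITE_DENSITY)
      rec$process_height_um <- if (stats::runif(1) < noise$spine_record_prob)
        spine_true else NA
    } else {
      spine_true <- NA
      body_pic_true <- sum(ks * lens^3 * CALCITE_DENSITY)
    }

    exo_true <- 0
    if (!is.null(t$xc_prob) && stats::runif(1) < t$xc_prob) {
      n_xc <- 1 + stats::rpois(1, t$xc_mean - 1)
      xc_len <- t$xc_len_ratio * cl_meas
      exo_true <- exothecal_calcite(n_xc, xc_len, params$ks_exothecal)
      rec$n_exothecal <- n_xc
      rec$exothecal_length_um <- xc_len
      notes <- c(notes, sprintf("xc:%d", n_xc))
    }

    app_true <- 0
    if (!is.null(t$appendage_range)) {            # Michaelsarsia
      n_app <- sample(t$appendage_range, 1)
      app_true <- params$appendage_pg_per_appendage * n_app
      if (stats::runif(1) < noise$appendage_record_prob) {
        rec$n_appendages <- n_app
        notes <- c(notes, sprintf("appendages:%d", n_app))
      }
    } else if (!is.null(t$arm_prob)) {            # Ophiaster
      present <- stats::runif(1) < t$arm_prob
      rec$appendages_present <- present
      if (present) {
        app_true <- params$appendage_fixed_total_pg
        notes <- c(notes, "appendages:present")
      }
    }

    ## recorded measurement with noise modes; the emitted table follows the
    ## reader-normalised convention (full lengths, provenance flag), so the
    ## partial-length mode applies its doubling error to the full length
    if (!is.na(cl_meas)) {
      cl_rec <- cl_meas
      if (stats::runif(1) < noise$partial_prob) {
        err <- clamp(stats::rnorm(1, noise$partial_mean, noise$partial_sd),
                     -noise$partial_max, noise$partial_max)
        cl_rec <- cl_meas * (1 + err)
        rec$partial_length_flag <- TRUE
      }
      rec$coccolith_length_um <- cl_rec
      rec$coccolith_width_um <- cw
    }
    if (is.na(fixed_cn) && !isTRUE(t$holococcolith)) {
      vis_rec <- cn_true / params$cn_multiplier
      if (stats::runif(1) < noise$miscount_prob) {
        vis_rec <- max(2, vis_rec + sample(c(-1, 1), 1) *
                         sample.int(noise$miscount_max, 1))
      }
      rec$visible_coccolith_count <- vis_rec
    }
    rec$notes <- if (length(notes)) paste(notes, collapse = ";") else
      NA_character_

    recs[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    tru[[i]] <- data.frame(
      record_id = rec$record_id,
      taxon = taxon_label(key, params),
      true_cn = cn_true + loose,
      true_mean_cl = mean_len,
      true_esd = esd_meas,
      true_cell_diameter = true_cell_d,
      true_cellular_pic = body_pic_true + exo_true + app_true,
      stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, tru))
}

#' Recovery of ground truth by the pipeline
#'
#' Joins generated records, their ground truth, and the pipeline output by
#' record id and reports relative bias and relative RMSE of cellular
#' calcite and cell diameter, overall and per taxon.
#'
#' @param truth truth table from [generate_coccospheres()]
#' @param results `trait_results` from [compute_traits()] on the matching
#'   records
#' @return list of class `recovery_report` with elements `overall` (data
#'   frame: quantity, bias, rmse, both relative) and `per_taxon`
#' @export
recovery_report <- function(truth, results) {
  df <- merge(truth, as.data.frame(results), by = "record_id")
  if (nrow(df) != nrow(truth) || nrow(df) != nrow(results)) {
    stop("truth and results are misaligned: record ids do not match 1:1")
  }
  rel_pic <- (df$cellular_pic_pg - df$true_cellular_pic) /
    df$true_cellular_pic
  rel_cd <- (df$cell_diameter_um - df$true_cell_diameter) /
    df$true_cell_diameter
  overall <- data.frame(
    quantity = c("cellular_pic", "cell_diameter"),
    bias = c(mean(rel_pic), mean(rel_cd)),
    rmse = c(sqrt(mean(rel_pic^2)), sqrt(mean(rel_cd^2))))
  per_taxon <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$taxon.x),
                                     function(idx) {
    data.frame(taxon = df$taxon.x[idx[1]], n = length(idx),
               pic_bias = mean(rel_pic[idx]),
               pic_rmse = sqrt(mean(rel_pic[idx]^2)),
               cell_d_rmse = sqrt(mean(rel_cd[idx]^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_taxon) <- NULL
  structure(list(overall = overall, per_taxon = per_taxon,
                 rel_errors = data.frame(record_id = df$record_id,
                                         pic = rel_pic, cell_d = rel_cd)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\noverall (relative):\n")
  print(x$overall, digits = 4)
  cat("per taxon:\n")
  print(x$per_taxon, digits = 4)
  invisible(x)
}
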