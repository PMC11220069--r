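# End-to-end pipeline: read per-coccosphere measurement tables, resolve
# taxa against the registry, apply geometry and calcite computations, and
# write the trait table / per-taxon summaries.

# Machine column schema (all lengths um, depths m, masses pg). The reader
# also accepts the plain-language headings of the published dataset
# descriptor via RECORD_ALIASES, and user-supplied column maps.
RECORD_COLS <- c(
  "record_id", "station", "water_depth_m", "image_id",
  "family", "genus", "species", "morpho_group", "life_cycle_phase",
  "visible_coccolith_count", "total_coccolith_count",
  "coccolith_length_um", "coccolith_width_um", "process_height_um",
  "coccosphere_long_axis_um", "coccosphere_short_axis_um",
  "n_layers", "n_exothecal", "exothecal_length_um",
  "n_appendages", "appendages_present", "loose_adjacent_count",
  "partial_length_flag", "notes")

RECORD_ALIASES <- c(
  "station"                  = "station",
  "water depth"              = "water_depth_m",
  "water depth (m)"          = "water_depth_m",
  "sem image number"         = "image_id",
  "family"                   = "family",
  "genus"                    = "genus",
  "species"                  = "species",
  "number of coccoliths per cell"       = "visible_coccolith_count",
  "coccolith length"                    = "coccolith_length_um",
  "coccolith length (um)"               = "coccolith_length_um",
  "coccolith width"                     = "coccolith_width_um",
  "coccolith width (um)"                = "coccolith_width_um",
  "coccosphere diameter long axis"      = "coccosphere_long_axis_um",
  "coccosphere diameter long axis (um)" = "coccosphere_long_axis_um",
  "coccosphere diameter short axis"     = "coccosphere_short_axis_um",
  "coccosphere diameter short axis (um)" = "coccosphere_short_axis_um",
  "additional information"              = "notes")

record_taxon_key <- function(rec) {
  phase <- rec$life_cycle_phase
  if (is.null(phase) || is.na(phase) || phase == "") phase <- "heterococcolith"
  taxon_key(genus = rec$genus, species = rec$species,
            morpho_group = rec$morpho_group, family = rec$family,
            life_cycle_phase = phase)
}

taxon_label <- function(key, params = NULL) {
  g <- key$genus
  if (is.na(g)) g <- "holococcolithophore"
  s <- key$species
  if (!is.na(s)) paste(g, s) else if (!is.na(key$morpho_group)) {
    paste(g, key$morpho_group)
  } else g
}

# Controlled-vocabulary tokens parsed out of the free-text notes column:
#   multilayer:<k>   number of coccolith layers
#   xc:<n>           exothecal coccolith count
#   appendages:<n|present>
#   loose:<n>        loose adjacent coccoliths included in the count
#   partial          coccolith length recorded as centre-to-rim half length
parse_notes <- function(notes) {
  out <- list(n_layers = NA_real_, n_exothecal = NA_real_,
              n_appendages = NA_real_, appendages_present = NA,
              loose = NA_real_, partial = FALSE)
  if (is.null(notes) || is.na(notes) || notes == "") return(out)
  for (tok in strsplit(tolower(notes), "[;,]")[[1]]) {
    tok <- trimws(tok)
    if (grepl("^multilayer:[0-9]+$", tok)) {
      out$n_layers <- as.numeric(sub("multilayer:", "", tok))
    } else if (grepl("^xc:[0-9]+$", tok)) {
      out$n_exothecal <- as.numeric(sub("xc:", "", tok))
    } else if (grepl("^appendages:present$", tok)) {
      out$appendages_present <- TRUE
    } else if (grepl("^appendages:[0-9]+$", tok)) {
      out$n_appendages <- as.numeric(sub("appendages:", "", tok))
    } else if (grepl("^loose:[0-9]+$", tok)) {
      out$loose <- as.numeric(sub("loose:", "", tok))
    } else if (tok == "partial") {
      out$partial <- TRUE
    }
  }
  out
}

#' Read a per-coccosphere measurement table
#'
#' Accepts delimited text with either the machine column names or the
#' plain-language headings of the published dataset descriptor (matched
#' case-insensitively; a user-supplied `col_map` wins over both). The
#' free-text notes column is scanned for a small controlled vocabulary of
#' flag tokens (`multilayer:<k>`, `xc:<n>`, `appendages:<n|present>`,
#' `loose:<n>`, `partial`); everything else is passed through.
#'
#' Two normalisations are applied on read: a `partial` flag doubles the
#' recorded centre-to-rim half length into a full coccolith length, and
#' when `cn_is_visible` is `TRUE` the recorded count is taken as the number
#' of coccoliths on the visible hemisphere and multiplied by the taxon's
#' count multiplier (2 for single-layer coccospheres; 3 for
#' *Umbellosphaera*, whose hidden coccolith layer a doubling would miss).
#' Coccosphere axes are normalised so the short axis does not exceed the
#' long axis.
#'
#' @param path input file path
#' @param cn_is_visible is the recorded coccolith count the visible-surface
#'   count (default `TRUE`, the SEM convention)?
#' @param partial_is_half do partial-flagged rows record the centre-to-rim
#'   half length (default `TRUE`, the measurement convention)? Set to
#'   `FALSE` for tables already carrying full lengths, e.g. written back
#'   from [generate_coccospheres()] output, where the flag is provenance
#'   only
#' @param registry a `taxon_registry` used for the count multiplier
#' @param strict error on unresolved taxa (otherwise the multiplier
#'   defaults to 2 with a warning)
#' @param sep field delimiter
#' @param col_map optional named character vector mapping input column
#'   names to machine names
#' @return data frame of records in the machine schema
#' @export
read_measurements <- function(path, cn_is_visible = TRUE,
                              registry = default_registry(), strict = TRUE,
                              sep = ",", col_map = NULL,
                              partial_is_half = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "", encoding = "UTF-8",
                          check.names = FALSE)
  nm <- names(df)
  mapped <- nm
  for (k in seq_along(nm)) {
    low <- tolower(trimws(nm[k]))
    if (!is.null(col_map) && nm[k] %in% names(col_map)) {
      mapped[k] <- col_map[[nm[k]]]
    } else if (low %in% names(RECORD_ALIASES)) {
      mapped[k] <- RECORD_ALIASES[[low]]
    }
  }
  unknown <- setdiff(mapped, RECORD_COLS)
  if (length(unknown) && strict) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  }
  names(df) <- mapped
  df <- df[, mapped %in% RECORD_COLS, drop = FALSE]
  for (col in setdiff(RECORD_COLS, names(df))) {
    df[[col]] <- if (col %in% c("partial_length_flag", "appendages_present")) {
      NA
    } else if (col %in% c("record_id", "station", "image_id", "family",
                          "genus", "species", "morpho_group",
                          "life_cycle_phase", "notes")) {
      NA_character_
    } else NA_real_
  }
  df <- df[RECORD_COLS]
  if (all(is.na(df$record_id))) df$record_id <- as.character(seq_len(nrow(df)))

  num_cols <- c("water_depth_m", "visible_coccolith_count",
                "total_coccolith_count", "coccolith_length_um",
                "coccolith_width_um", "process_height_um",
                "coccosphere_long_axis_um", "coccosphere_short_axis_um",
                "n_layers", "n_exothecal", "exothecal_length_um",
                "n_appendages", "loose_adjacent_count")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("line %d: column '%s' is not numeric ('%s')",
                   bad[1] + 1, col, df[[col]][bad[1]]))
    }
    df[[col]] <- v
  }
  df$partial_length_flag <- as.logical(df$partial_length_flag)
  df$appendages_present <- as.logical(df$appendages_present)

  for (i in seq_len(nrow(df))) {
    tok <- parse_notes(df$notes[i])
    if (is.na(df$n_layers[i]) && !is.na(tok$n_layers)) df$n_layers[i] <- tok$n_layers
    if (is.na(df$n_exothecal[i]) && !is.na(tok$n_exothecal)) {
      df$n_exothecal[i] <- tok$n_exothecal
    }
    if (is.na(df$n_appendages[i]) && !is.na(tok$n_appendages)) {
      df$n_appendages[i] <- tok$n_appendages
    }
    if (is.na(df$appendages_present[i]) && !is.na(tok$appendages_present)) {
      df$appendages_present[i] <- tok$appendages_present
    }
    if (is.na(df$loose_adjacent_count[i]) && !is.na(tok$loose)) {
      df$loose_adjacent_count[i] <- tok$loose
    }
    if (is.na(df$partial_length_flag[i])) df$partial_length_flag[i] <- tok$partial
  }
  df$n_layers[is.na(df$n_layers)] <- 1
  df$n_exothecal[is.na(df$n_exothecal)] <- 0
  df$loose_adjacent_count[is.na(df$loose_adjacent_count)] <- 0
  df$partial_length_flag[is.na(df$partial_length_flag)] <- FALSE

  partial <- if (partial_is_half) {
    which(df$partial_length_flag & !is.na(df$coccolith_length_um))
  } else integer(0)
  if (length(partial)) {
    df$coccolith_length_um[partial] <-
      full_length_from_partial(df$coccolith_length_um[partial])
  }

  ok_axes <- !is.na(df$coccosphere_short_axis_um) &
    !is.na(df$coccosphere_long_axis_um)
  if (any(ok_axes)) {
    ax <- normalize_axes(df$coccosphere_short_axis_um[ok_axes],
                         df$coccosphere_long_axis_um[ok_axes])
    df$coccosphere_short_axis_um[ok_axes] <- ax$d
    df$coccosphere_long_axis_um[ok_axes] <- ax$h
  }

  if (cn_is_visible) {
    for (i in which(!is.na(df$visible_coccolith_count))) {
      params <- resolve_taxon(record_taxon_key(as.list(df[i, ])), registry,
                              strict = strict)
      mult <- if (is.null(params)) {
        warning(sprintf("record %s: unresolved taxon, count multiplier 2 assumed",
                        df$record_id[i]))
        2
      } else params$cn_multiplier
      df$total_coccolith_count[i] <- df$visible_coccolith_count[i] * mult
    }
  } else {
    na_tot <- is.na(df$total_coccolith_count) &
      !is.na(df$visible_coccolith_count)
    df$total_coccolith_count[na_tot] <- df$visible_coccolith_count[na_tot]
  }
  df
}

#' Compute morphometric traits for a table of records
#'
#' Per record: coccosphere volume by the taxon's shape class, equivalent
#' spherical diameter, multilayer-corrected diameter (before the cell-size
#' conversion, when more than one coccolith layer is present and the taxon
#' has a known coccolith thickness), cell diameter and volume via the
#' taxon's cell-to-coccosphere volume fraction, and cellular calcite with
#' all taxon-specific corrections ([total_cell_calcite()]). When a process
#' height (spine/trumpet) is recorded, an ESD variant including the process
#' is also emitted; the excluding-process value is primary.
#'
#' @param records data frame in the machine schema (see
#'   [read_measurements()]); `total_coccolith_count` must already hold the
#'   whole-coccosphere count
#' @param registry a `taxon_registry`
#' @param strict error on the first failing record; in lenient mode failing
#'   records are skipped with a warning and listed in
#'   `attr(result, "skipped")`
#' @return data frame of class `trait_results`
#' @export
compute_traits <- function(records, registry = default_registry(),
                           strict = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame")
  }
  rows <- vector("list", nrow(records))
  skipped <- character(0)
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, ])
    res <- tryCatch({
      key <- record_taxon_key(rec)
      params <- resolve_taxon(key, registry)
      if (is.na(rec$coccosphere_short_axis_um) ||
          is.na(rec$coccosphere_long_axis_um)) {
        stop(sprintf("record %s: missing coccosphere axes", rec$record_id))
      }
      vol <- coccosphere_volume(rec$coccosphere_short_axis_um,
                                rec$coccosphere_long_axis_um,
                                params$shape_class)
      esd <- equivalent_spherical_diameter(vol)
      n_layers <- if (is.na(rec$n_layers)) 1 else rec$n_layers
      esd_cell_basis <- esd
      if (n_layers > 1 && !is.na(params$coccolith_thickness)) {
        esd_cell_basis <- multilayer_corrected_diameter(
          esd, n_layers, params$coccolith_thickness)
      }
      cell_d <- cell_diameter_from_coccosphere(esd_cell_basis,
                                               params$y_fraction)
      cell_vol <- params$y_fraction * (pi / 6) * esd_cell_basis^3
      esd_incl <- NA_real_
      if (!is.na(rec$process_height_um)) {
        esd_incl <- equivalent_spherical_diameter(coccosphere_volume(
          rec$coccosphere_short_axis_um + 2 * rec$process_height_um,
          rec$coccosphere_long_axis_um + 2 * rec$process_height_um,
          params$shape_class))
      }
      bd <- total_cell_calcite(rec, params)
      data.frame(
        record_id = rec$record_id,
        taxon = taxon_label(key, params),
        resolution_level = params$resolution_level,
        coccolith_length_um = bd$effective_cl,
        coccosphere_volume_um3 = vol,
        coccosphere_esd_um = esd,
        coccosphere_esd_incl_process_um = esd_incl,
        cell_diameter_um = cell_d,
        cell_volume_um3 = cell_vol,
        coccolith_pic_pg = bd$body_coccolith_pic,
        body_pic_pg = bd$body_total,
        exothecal_pic_pg = bd$exothecal_total,
        appendage_pic_pg = bd$appendage_total,
        cellular_pic_pg = bd$cellular_pic,
        flags = paste(bd$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(res)
      warning(sprintf("record %s skipped: %s", rec$record_id,
                      conditionMessage(res)))
      skipped <- c(skipped, as.character(rec$record_id))
      rows[[i]] <- NULL
    } else {
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop("no record could be computed")
  attr(out, "skipped") <- skipped
  structure(out, class = c("trait_results", "data.frame"))
}

fmt_num <- function(x, kind) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (kind == "mass") sprintf("%.2f", v) else format(signif(v, 4),
                                                       scientific = FALSE)
  }, character(1))
}

#' Write a trait-result table to delimited text
#'
#' Lengths, diameters and volumes are written to 4 significant figures and
#' calcite masses to 2 decimal places (the dataset convention); internal
#' computation is full precision. Writing is idempotent under a
#' read/recompute/write round trip because the formatting is a projection.
#'
#' @param results a `trait_results` data frame
#' @param path output file path
#' @param sep field delimiter
#' @export
write_traits <- function(results, path, sep = ",") {
  stopifnot(inherits(results, "trait_results"))
  df <- as.data.frame(results)
  mass_cols <- grep("_pg$", names(df), value = TRUE)
  len_cols <- grep("_um$|_um3$", names(df), value = TRUE)
  for (col in mass_cols) df[[col]] <- fmt_num(df[[col]], "mass")
  for (col in len_cols) df[[col]] <- fmt_num(df[[col]], "length")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-taxon summary of a trait-result table
#'
#' @param results a `trait_results` data frame
#' @return data frame with n and min/median/max of coccolith length, ESD,
#'   cell diameter and cellular calcite per taxon
#' @export
summarize_traits <- function(results) {
  stopifnot(inherits(results, "trait_results"))
  if (nrow(results) == 0) stop("cannot summarise zero records")
  df <- as.data.frame(results)
  one <- function(sub) {
    rng <- function(v) {
      v <- v[is.finite(v)]
      if (!length(v)) return(c(NA, NA, NA))
      c(min(v), stats::median(v), max(v))
    }
    cl <- rng(sub$coccolith_length_um); es <- rng(sub$coccosphere_esd_um)
    cd <- rng(sub$cell_diameter_um); pic <- rng(sub$cellular_pic_pg)
    data.frame(taxon = sub$taxon[1], n = nrow(sub),
               cl_min = cl[1], cl_median = cl[2], cl_max = cl[3],
               esd_min = es[1], esd_median = es[2], esd_max = es[3],
               cell_d_min = cd[1], cell_d_median = cd[2], cell_d_max = cd[3],
               pic_min = pic[1], pic_median = pic[2], pic_max = pic[3],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(df, df$taxon), one))
  rownames(out) <- NULL
  out[order(out$taxon), ]
}

#' @export
print.trait_results <- function(x, ...) {
  need <- c("record_id", "taxon", "coccosphere_esd_um", "cell_diameter_um",
            "cellular_pic_pg")
  if (!all(need %in% names(x))) return(NextMethod())
  cat(sprintf("<trait_results: %d coccospheres, %d taxa>\n", nrow(x),
              length(unique(x$taxon))))
  print(utils::head(as.data.frame(x)[, c("record_id", "taxon",
                                         "coccosphere_esd_um",
                                         "cell_diameter_um",
                                         "cellular_pic_pg")], 10),
        digits = 4)
  if (length(attr(x, "skipped"))) {
    cat("skipped:", paste(attr(x, "skipped"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.trait_results <- function(object, ...) summarize_traits(object)
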