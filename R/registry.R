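# Taxon parameter registry: per-taxon shape class, shape factor (Ks),
# cell-volume fraction (y) and the constants behind the taxon-specific
# correction rules. One row per taxon key; resolution walks
# species -> morpho-group -> genus -> life-cycle-phase default.

LIFE_CYCLE_PHASES <- c("heterococcolith", "holococcolith", "nannolith",
                       "polycrater")
SIZE_METRICS <- c("distal_shield_length", "trumpet_width", "spine_length")

REGISTRY_NUMERIC_COLS <- c(
  "ks_body", "ks_spinose", "ks_exothecal", "y_fraction",
  "y_fraction_incl_process", "cn_multiplier", "fixed_cn", "fixed_cl",
  "fixed_spine_length", "dimorphic_spinose_fraction",
  "appendage_pg_per_appendage", "appendage_default_count",
  "appendage_fixed_total_pg", "coccolith_thickness",
  "umbellosphaera_cl_factor")
REGISTRY_CHAR_COLS <- c("family", "genus", "species", "morpho_group",
                        "life_cycle_phase", "shape_class", "size_metric",
                        "source_note")
REGISTRY_COLS <- c(REGISTRY_CHAR_COLS[1:5], "shape_class",
                   REGISTRY_NUMERIC_COLS[1:3], "size_metric",
                   REGISTRY_NUMERIC_COLS[4:15], "source_note")

norm_txt <- function(x) {
  x <- trimws(gsub("[[:space:]]+", " ", as.character(x)))
  x[is.na(x) | x == ""] <- NA_character_
  x
}

#' Construct a taxon key
#'
#' @param genus genus name (required for heterococcolith keys; the
#'   holococcolith phase default resolves without one)
#' @param species species epithet, optional
#' @param morpho_group within-genus morphological group, optional (e.g.
#'   the *Syracosphaera* "pulchra group")
#' @param family family name, optional (carried for provenance only)
#' @param life_cycle_phase one of heterococcolith, holococcolith, nannolith,
#'   polycrater
#' @return object of class `taxon_key`
#' @export
taxon_key <- function(genus = NULL, species = NULL, morpho_group = NULL,
                      family = NULL, life_cycle_phase = "heterococcolith") {
  life_cycle_phase <- match.arg(life_cycle_phase, LIFE_CYCLE_PHASES)
  key <- list(family = norm_txt(family %||% NA),
              genus = norm_txt(genus %||% NA),
              species = norm_txt(species %||% NA),
              morpho_group = norm_txt(morpho_group %||% NA),
              life_cycle_phase = life_cycle_phase)
  if (is.na(key$genus) && life_cycle_phase != "holococcolith") {
    stop("taxon_key requires a non-empty genus")
  }
  structure(key, class = "taxon_key")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_registry_row <- function(row, i) {
  fail <- function(field, msg) {
    stop(sprintf("registry row %d (%s %s): field '%s' %s", i,
                 ifelse(is.na(row$genus), "<phase default>", row$genus),
                 ifelse(is.na(row$species), "", row$species), field, msg),
         call. = FALSE)
  }
  if (is.na(row$ks_body) || row$ks_body <= 0 || row$ks_body >= 1) {
    fail("ks_body", "must lie in (0, 1)")
  }
  if (!row$shape_class %in% SHAPE_CLASSES) fail("shape_class", "unknown")
  if (!row$life_cycle_phase %in% LIFE_CYCLE_PHASES) {
    fail("life_cycle_phase", "unknown")
  }
  if (!is.na(row$size_metric) && !row$size_metric %in% SIZE_METRICS) {
    fail("size_metric", "unknown")
  }
  if (!row$cn_multiplier %in% c(2, 3)) fail("cn_multiplier", "must be 2 or 3")
  if (is.na(row$y_fraction) || row$y_fraction <= 0 || row$y_fraction > 1) {
    fail("y_fraction", "must lie in (0, 1]")
  }
  if (!is.na(row$fixed_cn) && row$fixed_cn < 1) fail("fixed_cn", "must be >= 1")
  per <- !is.na(row$appendage_pg_per_appendage)
  cnt <- !is.na(row$appendage_default_count)
  tot <- !is.na(row$appendage_fixed_total_pg)
  if (per != cnt) {
    fail("appendage_pg_per_appendage",
         "per-appendage mass and default count must be set together")
  }
  if (per && tot) {
    fail("appendage_fixed_total_pg",
         "per-appendage and fixed-total appendage rules are mutually exclusive")
  }
  invisible(TRUE)
}

#' Load a taxon parameter registry
#'
#' Reads a delimited-text registry (UTF-8, header row, columns named as the
#' registry fields), validates every row, and returns an immutable registry
#' table. The packaged default registry ([default_registry()]) encodes the
#' constants of the estimation method; rows whose `source_note` contains
#' "placeholder" carry externally sourced values that users should confirm.
#'
#' @param path registry file path
#' @param strict error on validation problems (always on for structural
#'   problems; reserved for forward compatibility)
#' @param sep field delimiter
#' @return object of class `taxon_registry` (a data frame)
#' @export
load_registry <- function(path, strict = TRUE, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "", fill = FALSE,
                          encoding = "UTF-8")
  missing <- setdiff(REGISTRY_COLS, names(df))
  if (length(missing)) {
    stop("registry file lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[REGISTRY_COLS]
  if (nrow(df) == 0) stop("registry file contains no rows")
  for (col in REGISTRY_CHAR_COLS) df[[col]] <- norm_txt(df[[col]])
  for (col in REGISTRY_NUMERIC_COLS) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("registry row %d: field '%s' is not numeric ('%s')",
                   bad[1], col, df[[col]][bad[1]]))
    }
    df[[col]] <- v
  }
  df$ks_exothecal[is.na(df$ks_exothecal)] <- 0.02
  df$cn_multiplier[is.na(df$cn_multiplier)] <- 2
  df$size_metric[is.na(df$size_metric)] <- "distal_shield_length"
  for (i in seq_len(nrow(df))) validate_registry_row(df[i, ], i)
  keys <- tolower(paste(df$genus, df$species, df$morpho_group,
                        df$life_cycle_phase, sep = "|"))
  if (anyDuplicated(keys)) {
    d <- keys[duplicated(keys)][1]
    stop("duplicate taxon key in registry: ", d)
  }
  structure(df, class = c("taxon_registry", "data.frame"))
}

#' The packaged default registry
#'
#' @return a `taxon_registry` loaded from the file shipped with the package
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "taxon_registry.csv",
                            package = "coccotraits", mustWork = TRUE))
}

#' Write a registry back to delimited text
#'
#' Round-trips exactly: `load_registry(write_registry(r, f))` reproduces all
#' numeric fields.
#'
#' @param registry a `taxon_registry`
#' @param path output file path
#' @param sep field delimiter
#' @export
write_registry <- function(registry, path, sep = ",") {
  stopifnot(inherits(registry, "taxon_registry"))
  df <- as.data.frame(registry)
  for (col in REGISTRY_NUMERIC_COLS) {
    df[[col]] <- vapply(df[[col]], function(x) {
      if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE)
    }, character(1))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve a taxon key against a registry
#'
#' Resolution order: exact species match, then morpho-group match, then
#' genus-level row, then life-cycle-phase default (e.g. the holococcolith
#' default with Ks 0.036 and y 0.80). Genus/species matching is
#' case-insensitive; morpho-group matching is exact after whitespace
#' normalisation; the life-cycle phase of the key must equal the row's phase
#' at every level. The returned parameter list records which level matched.
#'
#' @param key a [taxon_key()]
#' @param registry a `taxon_registry`
#' @param strict if `TRUE` (default) an unresolved key is an error;
#'   otherwise `NULL` is returned
#' @return a list of taxon parameters with an extra `resolution_level`
#'   element (`"species"`, `"morpho_group"`, `"genus"` or `"phase_default"`),
#'   or `NULL` in lenient mode when nothing matches
#' @export
resolve_taxon <- function(key, registry, strict = TRUE) {
  stopifnot(inherits(key, "taxon_key"), inherits(registry, "taxon_registry"))
  df <- registry
  phase_ok <- df$life_cycle_phase == key$life_cycle_phase
  genus_ok <- !is.na(df$genus) & !is.na(key$genus) &
    tolower(df$genus) == tolower(key$genus)
  pick <- function(sel, level) {
    i <- which(sel)
    if (!length(i)) return(NULL)
    row <- as.list(df[i[1], ])
    row$resolution_level <- level
    row
  }
  res <- NULL
  if (!is.na(key$species)) {
    res <- pick(phase_ok & genus_ok & !is.na(df$species) &
                  tolower(df$species) == tolower(key$species), "species")
  }
  if (is.null(res) && !is.na(key$morpho_group)) {
    res <- pick(phase_ok & genus_ok & !is.na(df$morpho_group) &
                  tolower(df$morpho_group) == tolower(key$morpho_group),
                "morpho_group")
  }
  if (is.null(res)) {
    res <- pick(phase_ok & genus_ok & is.na(df$species) &
                  is.na(df$morpho_group), "genus")
  }
  if (is.null(res)) {
    res <- pick(phase_ok & is.na(df$genus), "phase_default")
  }
  if (is.null(res)) {
    if (strict) {
      stop(sprintf("unresolved taxon: genus='%s' species='%s' group='%s' phase='%s'",
                   key$genus, key$species, key$morpho_group,
                   key$life_cycle_phase))
    }
    return(NULL)
  }
  res
}

#' @export
print.taxon_registry <- function(x, ...) {
  cat(sprintf("<taxon_registry: %d rows>\n", nrow(x)))
  print(as.data.frame(x)[, c("genus", "species", "morpho_group",
                             "life_cycle_phase", "shape_class", "ks_body",
                             "y_fraction")], ...)
  invisible(x)
}
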