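# Domain types, CSV readers/writers, QC filtering, and the numerical
# corrections applied to reduced instrument values before any inference.

#' Amino acid three-letter codes accepted throughout the package
#'
#' Asx and Glx denote the acid-hydrolysis pools (Asp+Asn, Glu+Gln).
#' @export
AA_CODES <- c("Gly", "Ser", "Phe", "Lys", "Ala", "Val", "Leu", "Ile",
              "Pro", "Asx", "Glx", "Thr", "Tyr")

SAMPLE_CATEGORIES <- c("human", "rat", "fish", "marine_mammal", "bird",
                       "terrestrial_bird", "mussel", "plant", "soil", "reed")
SAMPLE_ORIGINS <- c("archaeological", "modern", "historic")

#' Specification of numerical corrections for compound-specific d13C values
#'
#' Bundles the constants needed to undo derivatization carbon addition,
#' harmonize values measured in different laboratories, and apply a Suess
#' (industrial-era atmospheric CO2) offset.
#'
#' @param x_fraction Mole fraction of amino acid carbon in the derivative,
#'   in (0, 1]. `1` means no derivative carbon was added.
#' @param d13c_iso d13C (permil, V-PDB) of the isopropanol reagent whose
#'   carbon is incorporated during esterification.
#' @param interlab_offsets Named numeric vector of permil offsets, one per
#'   amino acid code, added to that amino acid's d13C to bring external
#'   laboratory values onto the local scale. The default carries the
#'   calibration for N-acetyl methyl ester training data
#'   (Leu -0.86, Lys -0.32, Phe -3.75, Val -0.76).
#' @param offset_sign `+1` to add the offsets as listed, `-1` to subtract
#'   them (the inter-laboratory sign convention is configurable).
#' @param suess_offset Permil offset added by [suess_correct()]; year
#'   dependent and supplied by the user (e.g. +0.5 for mid-1950s material,
#'   +1.4 for recent material).
#' @return An object of class `correction_spec`.
#' @export
correction_spec <- function(x_fraction = 1,
                            d13c_iso = 0,
                            interlab_offsets = c(Leu = -0.86, Lys = -0.32,
                                                 Phe = -3.75, Val = -0.76),
                            offset_sign = 1,
                            suess_offset = 0) {
  if (!is.numeric(x_fraction) || length(x_fraction) != 1 ||
      is.na(x_fraction) || x_fraction <= 0 || x_fraction > 1) {
    stop("`x_fraction` must be a single number in (0, 1]", call. = FALSE)
  }
  if (length(interlab_offsets) > 0) {
    if (is.null(names(interlab_offsets)) ||
        !all(names(interlab_offsets) %in% AA_CODES)) {
      stop("`interlab_offsets` must be named with amino acid codes from AA_CODES",
           call. = FALSE)
    }
    if (!all(is.finite(interlab_offsets))) {
      stop("`interlab_offsets` must be finite", call. = FALSE)
    }
  }
  if (!offset_sign %in% c(-1, 1)) {
    stop("`offset_sign` must be +1 or -1", call. = FALSE)
  }
  stopifnot(is.finite(d13c_iso), is.finite(suess_offset))
  structure(
    list(x_fraction = x_fraction, d13c_iso = d13c_iso,
         interlab_offsets = interlab_offsets, offset_sign = offset_sign,
         suess_offset = suess_offset),
    class = "correction_spec"
  )
}

#' Load per-sample isotope records from long-form CSV files
#'
#' The on-disk dialect is two comma-separated UTF-8 tables: a per-sample
#' header table (`sample_id, category, origin, bulk_d13c, bulk_d15n,
#' cn_molar`) and an optional long-form amino acid table
#' (`sample_id, element, aa, mean, sd, n`) with one row per
#' (sample, element, amino acid). `element` is `"N"` or `"C"`. Empty cells
#' become `NA`, never zeros.
#'
#' @param samples_csv Path to the per-sample table.
#' @param aa_csv Optional path to the long-form amino acid table.
#' @return A `sample_set`: a list with tibbles `samples` and `aa`.
#' @export
load_samples <- function(samples_csv, aa_csv = NULL) {
  samples <- read_checked_csv(
    samples_csv,
    required = c("sample_id", "category", "origin"),
    numeric_cols = c("bulk_d13c", "bulk_d15n", "cn_molar")
  )
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id in ", samples_csv, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(samples$category), SAMPLE_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  bad_org <- setdiff(unique(samples$origin), SAMPLE_ORIGINS)
  if (length(bad_org)) {
    stop("unknown origin: ", paste(bad_org, collapse = ", "), call. = FALSE)
  }

  if (is.null(aa_csv)) {
    aa <- tibble::tibble(sample_id = character(), element = character(),
                         aa = character(), mean = numeric(),
                         sd = numeric(), n = integer())
  } else {
    aa <- read_checked_csv(
      aa_csv,
      required = c("sample_id", "element", "aa"),
      numeric_cols = c("mean", "sd", "n")
    )
    bad_aa <- setdiff(unique(aa$aa), AA_CODES)
    if (length(bad_aa)) {
      stop("unknown amino acid code: ", paste(bad_aa, collapse = ", "),
           call. = FALSE)
    }
    if (!all(aa$element %in% c("N", "C"))) {
      stop("`element` must be 'N' or 'C' in ", aa_csv, call. = FALSE)
    }
    if (any(!is.na(aa$sd) & aa$sd < 0)) {
      stop("amino acid replicate sd must be >= 0", call. = FALSE)
    }
    if (any(!is.na(aa$n) & aa$n < 1)) {
      stop("amino acid replicate count must be >= 1", call. = FALSE)
    }
    orphan <- setdiff(unique(aa$sample_id), samples$sample_id)
    if (length(orphan)) {
      stop("amino acid rows reference unknown sample_id: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    aa$n <- as.integer(aa$n)
  }
  new_sample_set(samples, aa)
}

new_sample_set <- function(samples, aa,
                           interlab_calibrated = FALSE) {
  structure(
    list(samples = tibble::as_tibble(samples), aa = tibble::as_tibble(aa)),
    interlab_calibrated = interlab_calibrated,
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples, %d amino acid measurements\n",
              nrow(x$samples), nrow(x$aa)))
  print(x$samples, ...)
  invisible(x)
}

# Strict CSV reader: every numeric cell must parse or the error names the
# offending row and column; blanks become NA.
read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(raw))) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("malformed numeric value '%s' at row %d, column '%s' of %s",
                   vals[bad[1]], bad[1], col, path), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  for (col in setdiff(numeric_cols, names(raw))) raw[[col]] <- NA_real_
  tibble::as_tibble(raw)
}

#' Write a sample set back to the two-table CSV dialect
#'
#' Inverse of [load_samples()]: `load_samples()` applied to the emitted
#' files reproduces the sample set exactly.
#'
#' @param x A `sample_set`.
#' @param samples_csv,aa_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_samples <- function(x, samples_csv, aa_csv) {
  stopifnot(inherits(x, "sample_set"))
  utils::write.csv(x$samples, samples_csv, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(x$aa, aa_csv, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(samples_csv, aa_csv))
}

#' Quality-control filter on collagen molar C:N ratio
#'
#' Collagen with a molar C:N ratio outside the commonly accepted
#' preservation window (default closed interval \[2.9, 3.6\]) is rejected.
#' Samples without a C:N value (plants, soils, reeds, which have no
#' collagen) pass with a warning rather than failing.
#'
#' @param x A `sample_set`.
#' @param lo,hi Bounds of the closed acceptance interval.
#' @return A `qc_report`: list with `kept` (character vector of ids) and
#'   `rejected` (tibble of `sample_id`, `reason`).
#' @export
filter_cn <- function(x, lo = 2.9, hi = 3.6) {
  stopifnot(inherits(x, "sample_set"))
  if (!(lo < hi)) stop("`lo` must be < `hi`", call. = FALSE)
  cn <- x$samples$cn_molar
  ids <- x$samples$sample_id
  no_cn <- is.na(cn)
  out_of_range <- !no_cn & (cn < lo | cn > hi)
  if (any(no_cn)) {
    warning("samples without C:N pass QC unchecked: ",
            paste(ids[no_cn], collapse = ", "), call. = FALSE)
  }
  rejected <- tibble::tibble(
    sample_id = ids[out_of_range],
    reason = sprintf("C:N out of range [%.1f, %.1f]: %.2f", lo, hi,
                     cn[out_of_range])
  )
  structure(list(kept = ids[!out_of_range], rejected = rejected),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> kept %d, rejected %d\n",
              length(x$kept), nrow(x$rejected)))
  if (nrow(x$rejected)) print(x$rejected, ...)
  invisible(x)
}

#' Remove derivative carbon from a measured compound-specific d13C value
#'
#' Derivatization adds reagent carbon to each amino acid; the measured
#' value is a mole-fraction mixture of amino acid and reagent carbon. The
#' correction inverts that mixture:
#' `d13c_aa = (d13c_csia - (1 - X) * d13c_iso) / X`
#' where `X` is the mole fraction of amino acid carbon in the derivative
#' and `d13c_iso` the reagent (isopropanol) value.
#'
#' @param d13c_csia Measured derivative d13C (permil); vectorized.
#' @param spec A [correction_spec()] providing `x_fraction` and `d13c_iso`.
#' @return Corrected amino acid d13C (permil).
#' @export
correct_derivatization <- function(d13c_csia, spec) {
  stopifnot(inherits(spec, "correction_spec"))
  x <- spec$x_fraction
  (d13c_csia - (1 - x) * spec$d13c_iso) / x
}

#' Apply inter-laboratory calibration offsets to amino acid d13C values
#'
#' Shifts the d13C mean of each amino acid listed in
#' `spec$interlab_offsets` by its offset (times `spec$offset_sign`);
#' amino acids without an offset are untouched, as are all d15N rows.
#' The returned set carries a provenance flag and applying the calibration
#' a second time is an error.
#'
#' @param x A `sample_set`.
#' @param spec A [correction_spec()].
#' @return The calibrated `sample_set`.
#' @export
apply_interlab_calibration <- function(x, spec) {
  stopifnot(inherits(x, "sample_set"), inherits(spec, "correction_spec"))
  if (isTRUE(attr(x, "interlab_calibrated"))) {
    stop("inter-laboratory calibration already applied to this sample set",
         call. = FALSE)
  }
  aa <- x$aa
  offs <- spec$interlab_offsets * spec$offset_sign
  hit <- aa$element == "C" & aa$aa %in% names(offs)
  if (any(hit)) {
    aa$mean[hit] <- aa$mean[hit] + unname(offs[aa$aa[hit]])
  }
  new_sample_set(x$samples, aa, interlab_calibrated = TRUE)
}

#' Suess-effect correction of a d13C value
#'
#' Adds a user-supplied, year-dependent offset compensating the
#' industrial-era decline of atmospheric CO2 d13C, so that modern plant
#' values can be compared with pre-industrial material.
#'
#' @param d13c d13C (permil); vectorized.
#' @param offset Permil offset to add (e.g. +0.5 for 1950s material).
#' @return Corrected d13C (permil).
#' @export
suess_correct <- function(d13c, offset) {
  stopifnot(is.numeric(offset), all(is.finite(offset)))
  d13c + offset
}
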