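#' Construct a validated spectrum
#'
#' A single acquisition: paired m/z and intensity vectors. The m/z axis must
#' be strictly increasing after construction; out-of-order rows are sorted
#' with a warning and duplicate m/z values are intensity-averaged. Negative
#' intensities (possible in baseline-subtracted exports) are clipped to zero
#' with a warning.
#'
#' @param mz Numeric vector of m/z values in Th.
#' @param intensity Numeric vector, same length.
#' @param sample_id Optional sample identifier.
#' @return An object of class `spectrum` (list with `mz`, `intensity`,
#'   `sample_id`).
#' @export
new_spectrum <- function(mz, intensity, sample_id = NA_character_) {
  if (length(mz) != length(intensity)) {
    stopf("`mz` and `intensity` must have equal length")
  }
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stopf("spectrum values must be finite")
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    if (is.unsorted(mz)) {
      warnf("m/z axis not sorted; sorting rows")
      o <- order(mz)
      mz <- mz[o]
      intensity <- intensity[o]
    }
    if (anyDuplicated(mz)) {
      warnf("duplicate m/z values; averaging intensities")
      intensity <- as.numeric(tapply(intensity, mz, mean))
      mz <- sort(unique(mz))
    }
  }
  if (any(intensity < 0)) {
    warnf("negative intensities clipped to zero")
    intensity <- pmax(intensity, 0)
  }
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 sample_id = sample_id),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum%s: %d points, m/z %.1f-%.1f, max intensity %.3g\n",
              if (is.na(x$sample_id)) "" else paste0(" ", x$sample_id),
              length(x$mz), min(x$mz), max(x$mz), max(x$intensity)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$mz)

#' Read a two-column ASCII spectrum
#'
#' Parses the whitespace-delimited (m/z, intensity) export format. Lines
#' beginning with `#` are comments. At least 10 data rows and a nonzero
#' intensity somewhere are required; a non-numeric payload is a format error
#' naming the offending line.
#'
#' @param path File path.
#' @param sample_id Sample id to attach; default the file name without
#'   extension.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stopf("spectrum file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 10) {
    stopf("format error in %s: fewer than 10 data rows", path)
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  ncol <- vapply(fields, length, 1L)
  bad <- which(ncol < 2)
  if (length(bad)) {
    stopf("format error in %s at line %d: expected >= 2 columns", path, idx[bad[1]])
  }
  mz <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad)) {
    stopf("format error in %s at line %d: non-numeric value", path, idx[bad[1]])
  }
  if (all(it == 0)) stopf("format error in %s: all intensities are zero", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  new_spectrum(mz, it, sample_id)
}

#' Write a spectrum as two-column ASCII
#'
#' @param spectrum A spectrum object.
#' @param path Output path.
#' @param digits Significant digits written (round-trip contract: values
#'   reproduce to 6 significant digits or better).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, digits = 9) {
  stopifnot(inherits(spectrum, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id: %s", spectrum$sample_id), con)
  writeLines(paste(formatC(spectrum$mz, digits = digits, format = "g"),
                   formatC(spectrum$intensity, digits = digits, format = "g")),
             con)
  invisible(path)
}

validate_manifest <- function(manifest) {
  missing <- setdiff(MANIFEST_REQUIRED, names(manifest))
  if (length(missing)) {
    stopf("manifest schema error: missing mandatory column(s) %s",
          paste(missing, collapse = ", "))
  }
  if (anyDuplicated(manifest$sample_id)) {
    stopf("manifest schema error: duplicate sample_id")
  }
  invisible(manifest)
}

#' Read / write a sample manifest
#'
#' The manifest is a CSV with one row per sample. Mandatory columns:
#' `sample_id`, `class_label`. Typical optional columns: `cohort_id`,
#' `genotype_group`, the clinical covariates `hb`, `hbf`, `hba2`, QC flags
#' and (for synthetic cohorts) `truth_*` columns.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(manifest)
}

#' @rdname read_manifest
#' @param manifest Data frame with the mandatory columns.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature table
#'
#' One row per sample: `sample_id`, label columns, then the ten feature
#' columns in canonical order (`alpha_1p` ... `diff_ab_2p`). Masked features
#' are empty cells (NA).
#'
#' @param features Data frame from [assemble_feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  missing <- setdiff(c("sample_id", FEATURE_COLUMNS), names(features))
  if (length(missing)) {
    stopf("feature table schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  }
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  features <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", FEATURE_COLUMNS), names(features))
  if (length(missing)) {
    stopf("feature table schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  }
  features
}

#' Write model reports as JSON
#'
#' @param reports A list of model reports (see [run_model_suite()]) or a
#'   single report.
#' @param path JSON path.
#' @export
write_model_report <- function(reports, path) {
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Write a run provenance record
#'
#' Drops a `run.json` in `dir` recording the configuration hash, seed and
#' package/R versions, so a run directory is self-describing.
#'
#' @param dir Output directory.
#' @param config The configuration list used.
#' @param seed The master seed.
#' @export
write_run_record <- function(dir, config, seed) {
  rec <- list(
    package = "thalscreen",
    package_version = as.character(utils::packageVersion("thalscreen")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash(config),
    config = config
  )
  jsonlite::write_json(rec, file.path(dir, "run.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, "run.json"))
}

config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          null = "null")
  # small stable polynomial hash (two 16-bit lanes); avoids a digest
  # dependency and stays within double precision
  bytes <- utf8ToInt(as.character(txt))
  h1 <- 17L; h2 <- 59L
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 65521
    h2 <- (h2 * 37 + b) %% 65519
  }
  sprintf("%04x%04x", as.integer(h1), as.integer(h2))
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension).
#'
#' @param path Config path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
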