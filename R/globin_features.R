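#' Compute the ten screening features for one sample
#'
#' From the normalised peak assignments of one spectrum: the six
#' internal-standard-normalised chain intensities (alpha, beta, gamma at 1+
#' and 2+), the alpha/beta ratio and the alpha minus beta difference at each
#' charge state. A ratio is masked (NA) when its denominator slot is missing
#' or zero; a difference is defined only when both operands are present.
#' Nothing is imputed.
#'
#' @param assignments Normalised assignments from [normalize_assignments()]
#'   or [process_spectrum()].
#' @return Named numeric vector of length 10 in canonical column order
#'   (`alpha_1p` ... `diff_ab_2p`), NA where masked; QC flags for masked
#'   ratios in `attr(, "qc_flags")`.
#' @export
#' @examples
#' a <- data.frame(species = c("alpha", "beta", "internal_standard"),
#'                 charge = 1L, mz_obs = 0, mz_ref = 0, ppm_error = 0,
#'                 intensity_raw = c(80, 40, 100),
#'                 intensity_norm = c(0.8, 0.4, 1))
#' compute_features(a)
compute_features <- function(assignments) {
  slot <- function(sp, z) {
    i <- which(assignments$species == sp & assignments$charge == z)
    if (length(i) != 1L) return(NA_real_)
    assignments$intensity_norm[i]
  }
  fv <- c(alpha_1p = slot("alpha", 1L), beta_1p = slot("beta", 1L),
          gamma_1p = slot("gamma", 1L), alpha_2p = slot("alpha", 2L),
          beta_2p = slot("beta", 2L), gamma_2p = slot("gamma", 2L))
  qc <- character(0)
  ratio_diff <- function(z) {
    a <- fv[[paste0("alpha_", z, "p")]]
    b <- fv[[paste0("beta_", z, "p")]]
    ratio <- if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
    diff <- if (is.na(a) || is.na(b)) NA_real_ else a - b
    if (is.na(ratio)) qc <<- union(qc, paste0("ratio_masked_", z, "p"))
    c(ratio = ratio, diff = diff)
  }
  r1 <- ratio_diff(1)
  r2 <- ratio_diff(2)
  out <- c(fv,
           ratio_ab_1p = r1[["ratio"]], ratio_ab_2p = r2[["ratio"]],
           diff_ab_1p = r1[["diff"]], diff_ab_2p = r2[["diff"]])
  out <- out[FEATURE_COLUMNS]
  attr(out, "qc_flags") <- qc
  out
}

#' Assemble the per-cohort feature table
#'
#' Row-aligns one feature vector per manifest row, carries the label columns
#' through, and drops samples that failed QC (calibration failure or missing
#' internal standard) with a logged count. Duplicate sample ids are a schema
#' error.
#'
#' @param manifest Manifest data.frame (mandatory columns `sample_id`,
#'   `class_label`).
#' @param feature_vectors Named list (by sample_id) of [compute_features()]
#'   vectors, one per manifest row.
#' @param qc_flags Optional named list (by sample_id) of character QC flags
#'   from [process_spectrum()]; samples flagged `calibration_failed` or
#'   `is_missing` are excluded.
#' @return data.frame: manifest columns, then the ten feature columns, plus
#'   a `qc` column with the flags (`;`-joined).
#' @export
assemble_feature_table <- function(manifest, feature_vectors,
                                   qc_flags = NULL) {
  validate_manifest(manifest)
  if (!nrow(manifest)) stopf("empty manifest")
  missing <- setdiff(manifest$sample_id, names(feature_vectors))
  if (length(missing)) {
    stopf("no feature vector for sample(s): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  feats <- do.call(rbind, lapply(manifest$sample_id, function(sid) {
    v <- feature_vectors[[sid]]
    as.data.frame(as.list(v[FEATURE_COLUMNS]))
  }))
  qc_chr <- vapply(manifest$sample_id, function(sid) {
    flags <- union(attr(feature_vectors[[sid]], "qc_flags") %||% character(0),
                   if (!is.null(qc_flags)) qc_flags[[sid]] %||% character(0)
                   else character(0))
    paste(flags, collapse = ";")
  }, "")
  out <- cbind(manifest, feats, qc = unname(qc_chr),
               stringsAsFactors = FALSE)
  fail <- grepl("calibration_failed|is_missing", out$qc)
  if (any(fail)) {
    message(sprintf("excluding %d sample(s) failing QC", sum(fail)))
    out <- out[!fail, , drop = FALSE]
  }
  if (!nrow(out)) stopf("all samples failed QC")
  rownames(out) <- NULL
  out
}

#' Process a whole cohort into a feature table
#'
#' Runs [process_spectrum()] on each spectrum and assembles the feature
#' table against the manifest.
#'
#' @param spectra Named list of spectrum objects (names = sample ids).
#' @param manifest Manifest data.frame.
#' @param panel A [globin_panel()].
#' @param ... Passed to [process_spectrum()].
#' @return Feature table data.frame (see [assemble_feature_table()]).
#' @export
extract_cohort_features <- function(spectra, manifest, panel, ...) {
  validate_manifest(manifest)
  fvs <- list()
  qcs <- list()
  for (sid in manifest$sample_id) {
    sp <- spectra[[sid]]
    if (is.null(sp)) stopf("no spectrum for sample %s", sid)
    proc <- process_spectrum(sp, panel, ...)
    fvs[[sid]] <- compute_features(proc$assignments)
    qcs[[sid]] <- proc$qc_flags
  }
  assemble_feature_table(manifest, fvs, qcs)
}
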