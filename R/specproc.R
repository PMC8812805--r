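#' Smooth a spectrum
#'
#' Moving-average (default) or Savitzky-Golay smoothing on the intensity
#' trace. Edges are handled by reflecting the signal, so a constant spectrum
#' is a fixed point everywhere and total intensity is conserved for interior
#' points.
#'
#' @param spectrum A spectrum object.
#' @param window_points Odd window length >= 3 and < the spectrum length.
#' @param method `"moving_average"` or `"savitzky_golay"` (quadratic).
#' @return A smoothed spectrum on the same m/z axis.
#' @export
smooth_spectrum <- function(spectrum, window_points = 7,
                            method = c("moving_average", "savitzky_golay")) {
  stopifnot(inherits(spectrum, "spectrum"))
  method <- match.arg(method)
  n <- length(spectrum$mz)
  if (window_points %% 2 == 0) stopf("`window_points` must be odd")
  if (window_points < 3 || window_points >= n) {
    stopf("`window_points` must be >= 3 and < spectrum length (%d)", n)
  }
  h <- (window_points - 1L) / 2L
  coef <- if (method == "moving_average") {
    rep(1 / window_points, window_points)
  } else {
    sg_coefficients(h, degree = 2L)
  }
  y <- spectrum$intensity
  # reflect edges so the convolution is defined everywhere
  padded <- c(rev(y[2:(h + 1L)]), y, rev(y[(n - h):(n - 1L)]))
  sm <- stats::filter(padded, coef, sides = 2)
  sm <- as.numeric(sm[(h + 1L):(h + n)])
  new_spectrum(spectrum$mz, pmax(sm, 0), spectrum$sample_id)
}

# Savitzky-Golay smoothing weights: central row of the least-squares
# polynomial projection matrix for window -h..h.
sg_coefficients <- function(h, degree = 2L) {
  x <- -h:h
  A <- outer(x, 0:degree, `^`)
  P <- A %*% solve(crossprod(A), t(A))
  P[h + 1L, ]
}

#' Estimate and remove the baseline (SNIP)
#'
#' Statistics-sensitive Non-linear Iterative Peak-clipping with the standard
#' log-log-square-root (LLS) compression. The estimated baseline is pointwise
#' below or equal to the input, and `corrected + baseline` reconstructs the
#' input exactly.
#'
#' @param spectrum A (preferably smoothed) spectrum.
#' @param iterations Number of clipping iterations; the effective half-window
#'   in grid points equals the iteration count.
#' @return List with `corrected` and `baseline`, both spectrum objects.
#' @export
remove_baseline <- function(spectrum, iterations = 60L) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (!is_count(iterations)) stopf("`iterations` must be a positive integer")
  y <- spectrum$intensity
  n <- length(y)
  v <- log(log(sqrt(y + 1) + 1) + 1)   # LLS compression
  m_max <- min(as.integer(iterations), (n - 1L) %/% 2L)
  for (m in seq_len(m_max)) {
    i <- (m + 1L):(n - m)
    v[i] <- pmin(v[i], (v[i - m] + v[i + m]) / 2)
  }
  b <- (exp(exp(v) - 1) - 1)^2 - 1     # invert LLS
  b <- pmin(pmax(b, 0), y)             # guard against round-off overshoot
  list(
    corrected = new_spectrum(spectrum$mz, y - b, spectrum$sample_id),
    baseline = new_spectrum(spectrum$mz, b, spectrum$sample_id)
  )
}

#' Pick peaks from a baseline-corrected spectrum
#'
#' Local maxima whose signal-to-noise ratio reaches `snr_min`. The noise
#' scale is 1.4826 x the median absolute deviation of the detail residual
#' (input minus a `noise_window`-point moving average; the window is wider
#' than the default smoothing window so residual noise survives into the
#' estimate). The height entering the SNR is the apex prominence above a
#' `background_window`-point running median, which removes any small
#' constant floor left by baseline estimation; the reported `intensity` is
#' the apex height itself. Peaks closer than `min_spacing` are merged,
#' keeping the taller. On a noise-free spectrum the noise scale degenerates
#' to a floor of 1e-6 x the maximum intensity so that genuine peaks get very
#' large SNR values and numerical ripple is rejected.
#'
#' @param spectrum Baseline-removed (and typically smoothed) spectrum.
#' @param snr_min Minimum signal-to-noise ratio.
#' @param min_spacing Minimum peak separation in Th.
#' @param noise_window Moving-average window (points) for the detail
#'   residual used in the noise estimate.
#' @param background_window Running-median window (points) for the local
#'   background; must exceed the widest expected peak.
#' @return data.frame with columns `mz_obs`, `intensity`, `snr`, sorted by
#'   m/z. Empty for an all-zero spectrum.
#' @export
pick_peaks <- function(spectrum, snr_min = 3, min_spacing = 10,
                       noise_window = 21, background_window = 101) {
  stopifnot(inherits(spectrum, "spectrum"))
  y <- spectrum$intensity
  n <- length(y)
  if (n < 7 || all(y == 0)) {
    return(data.frame(mz_obs = numeric(0), intensity = numeric(0),
                      snr = numeric(0)))
  }
  odd_cap <- function(k) {
    k <- min(k, n - 2L)
    if (k %% 2 == 0) k <- k - 1L
    max(k, 3L)
  }
  detail <- y - as.numeric(
    smooth_spectrum(spectrum, odd_cap(noise_window))$intensity)
  scale <- 1.4826 * stats::median(abs(detail - stats::median(detail)))
  if (scale <= 0) scale <- 1e-6 * max(y)
  bg <- stats::runmed(y, odd_cap(background_window))
  core <- 2:(n - 1L)
  is_max <- y[core] > y[core - 1L] & y[core] >= y[core + 1L] & y[core] > 0
  idx <- core[is_max]
  if (!length(idx)) {
    return(data.frame(mz_obs = numeric(0), intensity = numeric(0),
                      snr = numeric(0)))
  }
  snr <- pmax(y[idx] - bg[idx], 0) / scale
  keep <- snr >= snr_min
  idx <- idx[keep]
  snr <- snr[keep]
  if (!length(idx)) {
    return(data.frame(mz_obs = numeric(0), intensity = numeric(0),
                      snr = numeric(0)))
  }
  # merge within min_spacing, tallest first
  o <- order(y[idx], decreasing = TRUE)
  kept <- integer(0)
  kept_snr <- numeric(0)
  for (k in o) {
    if (!length(kept) ||
        all(abs(spectrum$mz[idx[k]] - spectrum$mz[kept]) >= min_spacing)) {
      kept <- c(kept, idx[k])
      kept_snr <- c(kept_snr, snr[k])
    }
  }
  o2 <- order(spectrum$mz[kept])
  data.frame(mz_obs = spectrum$mz[kept][o2],
             intensity = y[kept][o2],
             snr = kept_snr[o2])
}

#' One-point m/z recalibration on the internal standard
#'
#' Finds the picked peak closest (in ppm) to the singly protonated internal
#' standard within `search_ppm` and rescales every peak m/z by
#' `mz_ref(IS, 1+) / mz_obs(IS, 1+)`. After calibration the IS 1+ ppm error
#' is zero by construction. If no candidate is found the sample is flagged,
#' not silently passed.
#'
#' @param peaks data.frame from [pick_peaks()].
#' @param panel A [globin_panel()].
#' @param search_ppm Search window in ppm (should be at least the matching
#'   tolerance used downstream).
#' @return List with `peaks` (rescaled), `correction_factor` and
#'   `calibration_failed` (logical).
#' @export
calibrate_mz <- function(peaks, panel, search_ppm = 5000) {
  stopifnot(is.data.frame(peaks), inherits(panel, "globin_panel"))
  ref <- mz_reference(panel, "internal_standard", 1L)
  if (!nrow(peaks)) {
    return(list(peaks = peaks, correction_factor = NA_real_,
                calibration_failed = TRUE))
  }
  ppm <- (peaks$mz_obs - ref) / ref * 1e6
  cand <- which(abs(ppm) <= search_ppm)
  if (!length(cand)) {
    return(list(peaks = peaks, correction_factor = NA_real_,
                calibration_failed = TRUE))
  }
  best <- cand[which.min(abs(ppm[cand]))]
  factor <- ref / peaks$mz_obs[best]
  peaks$mz_obs <- peaks$mz_obs * factor
  list(peaks = peaks, correction_factor = factor, calibration_failed = FALSE)
}

ppm_error <- function(obs, ref) (obs - ref) / ref * 1e6

#' Match picked peaks to (species, charge) slots
#'
#' Each slot takes the candidate peak with the smallest absolute ppm error
#' within `tolerance_ppm`; assignment is greedy by ascending ppm error and a
#' peak can fill at most one slot. Unmatched slots are absent from the output.
#'
#' @param peaks Calibrated peaks data.frame.
#' @param panel A [globin_panel()].
#' @param tolerance_ppm Matching tolerance (default 3000 ppm).
#' @return data.frame with columns `species`, `charge`, `mz_obs`, `mz_ref`,
#'   `ppm_error`, `intensity_raw`, `intensity_norm` (NA until
#'   [normalize_assignments()]).
#' @export
match_peaks <- function(peaks, panel, tolerance_ppm = 3000) {
  stopifnot(is.data.frame(peaks), inherits(panel, "globin_panel"))
  empty <- data.frame(species = character(0), charge = integer(0),
                      mz_obs = numeric(0), mz_ref = numeric(0),
                      ppm_error = numeric(0), intensity_raw = numeric(0),
                      intensity_norm = numeric(0))
  if (!nrow(peaks)) return(empty)
  species <- names(panel$species_masses)
  refs <- expand.grid(species = species, charge = panel$charges,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  refs$mz_ref <- (panel$species_masses[refs$species] +
                    refs$charge * panel$proton_mass) / refs$charge
  np <- nrow(peaks)
  grid <- refs[rep(seq_len(nrow(refs)), each = np), , drop = FALSE]
  grid$peak <- rep(seq_len(np), times = nrow(refs))
  grid$ppm <- ppm_error(peaks$mz_obs[grid$peak], grid$mz_ref)
  grid <- grid[abs(grid$ppm) <= tolerance_ppm, , drop = FALSE]
  if (!nrow(grid)) return(empty)
  grid <- grid[order(abs(grid$ppm)), , drop = FALSE]
  used_peak <- logical(nrow(peaks))
  used_slot <- character(0)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    slot <- paste(grid$species[i], grid$charge[i])
    if (used_peak[grid$peak[i]] || slot %in% used_slot) next
    used_peak[grid$peak[i]] <- TRUE
    used_slot <- c(used_slot, slot)
    rows[[length(rows) + 1L]] <- data.frame(
      species = grid$species[i],
      charge = as.integer(grid$charge[i]),
      mz_obs = peaks$mz_obs[grid$peak[i]],
      mz_ref = grid$mz_ref[i],
      ppm_error = grid$ppm[i],
      intensity_raw = peaks$intensity[grid$peak[i]],
      intensity_norm = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Internal-standard normalisation of matched peaks
#'
#' Divides each globin peak intensity by the internal-standard peak of the
#' same charge state (default), falling back to the IS 1+ peak when the IS
#' 2+ slot is unmatched; `method = "one_plus"` always divides by IS 1+. The
#' IS slots themselves get `intensity_norm = 1`. With no IS assignment at all
#' the sample fails QC.
#'
#' @param assignments data.frame from [match_peaks()].
#' @param method `"same_charge"` or `"one_plus"`.
#' @return The assignments with `intensity_norm` filled; QC flags (e.g.
#'   `is_missing`, `is2_fallback`) in `attr(, "qc_flags")`.
#' @export
normalize_assignments <- function(assignments,
                                  method = c("same_charge", "one_plus")) {
  method <- match.arg(method)
  qc <- character(0)
  is_rows <- assignments$species == "internal_standard"
  if (!any(is_rows)) {
    attr(assignments, "qc_flags") <- "is_missing"
    return(assignments)
  }
  is_int <- stats::setNames(assignments$intensity_raw[is_rows],
                            assignments$charge[is_rows])
  get_is <- function(z) {
    if (method == "same_charge" && as.character(z) %in% names(is_int)) {
      return(is_int[[as.character(z)]])
    }
    if (method == "same_charge" && !"1" %in% names(is_int)) return(NA_real_)
    if (method == "same_charge") {
      qc <<- union(qc, "is2_fallback")
      return(is_int[["1"]])
    }
    if (!"1" %in% names(is_int)) return(NA_real_)
    is_int[["1"]]
  }
  norm <- numeric(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    if (is_rows[i]) {
      norm[i] <- 1
    } else {
      denom <- get_is(assignments$charge[i])
      norm[i] <- if (is.na(denom) || denom <= 0) NA_real_ else
        assignments$intensity_raw[i] / denom
    }
  }
  assignments$intensity_norm <- norm
  attr(assignments, "qc_flags") <- qc
  assignments
}

#' Process one spectrum end to end
#'
#' The full chain: smoothing, SNIP baseline removal, peak picking, one-point
#' internal-standard m/z recalibration, 3000 ppm peak matching and
#' internal-standard normalisation.
#'
#' @param spectrum Raw spectrum.
#' @param panel A [globin_panel()].
#' @param smooth_window,smooth_method Passed to [smooth_spectrum()].
#' @param snip_iterations Passed to [remove_baseline()].
#' @param snr_min,min_spacing Passed to [pick_peaks()].
#' @param search_ppm Passed to [calibrate_mz()].
#' @param tolerance_ppm Passed to [match_peaks()].
#' @param is_norm Passed to [normalize_assignments()].
#' @return List with `assignments`, `correction_factor`, `qc_flags`
#'   (character; `calibration_failed`, `is_missing`, `slot_missing:<name>`).
#' @export
process_spectrum <- function(spectrum, panel,
                             smooth_window = 7,
                             smooth_method = "moving_average",
                             snip_iterations = 60L,
                             snr_min = 3, min_spacing = 10,
                             search_ppm = 5000, tolerance_ppm = 3000,
                             is_norm = "same_charge") {
  sm <- smooth_spectrum(spectrum, smooth_window, smooth_method)
  bl <- remove_baseline(sm, snip_iterations)
  peaks <- pick_peaks(bl$corrected, snr_min, min_spacing)
  cal <- calibrate_mz(peaks, panel, search_ppm)
  qc <- character(0)
  if (cal$calibration_failed) {
    return(list(assignments = match_peaks(peaks[0, , drop = FALSE], panel,
                                          tolerance_ppm),
                correction_factor = NA_real_,
                qc_flags = "calibration_failed"))
  }
  assignments <- match_peaks(cal$peaks, panel, tolerance_ppm)
  assignments <- normalize_assignments(assignments, is_norm)
  qc <- union(qc, attr(assignments, "qc_flags") %||% character(0))
  slots <- expand.grid(species = setdiff(names(panel$species_masses),
                                         "internal_standard"),
                       charge = panel$charges, stringsAsFactors = FALSE)
  have <- paste(assignments$species, assignments$charge)
  miss <- paste(slots$species, slots$charge)[!paste(slots$species, slots$charge) %in% have]
  if (length(miss)) {
    qc <- union(qc, paste0("slot_missing:", gsub(" ", "_", miss)))
  }
  list(assignments = assignments,
       correction_factor = cal$correction_factor,
       qc_flags = qc)
}
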