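#' Simulate one linear-mode MALDI-TOF blood spectrum
#'
#' Forward model: for every species in the panel with drawn abundance > 0 and
#' every covered charge state z, a Gaussian peak is placed at
#' `(M + z * proton) / z`, scaled by the abundance (and additionally by
#' `charge2_fraction` for z = 2), with the whole m/z axis multiplied by
#' `1 + calibration_shift_ppm * 1e-6` to emulate calibration drift. A decaying
#' exponential baseline and additive Gaussian noise are then added, and the
#' summed signal is truncated at zero. Per-sample abundances are lognormal
#' around the profile means with the profile's between-sample CV; the clinical
#' covariates are Gaussian around class means with the profile's linear links
#' (gamma abundance raises Hb F, alpha+beta raises Hb).
#'
#' @param panel A [globin_panel()].
#' @param profile A [disease_profile()].
#' @param acq An [acquisition_model()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param sample_id Identifier stored in the spectrum and record.
#' @param cohort_id Cohort identifier stored in the record.
#' @return A list with `spectrum` (a [new_spectrum()]) and `record` (one-row
#'   data.frame: ids, `class_label`, `genotype_group`, clinical covariates
#'   `hb`, `hbf`, `hba2`, and `truth_*` columns holding the drawn abundances
#'   and the true alpha/beta ratio).
#' @export
#' @examples
#' s <- simulate_spectrum(globin_panel(), default_profiles()$control,
#'                        acquisition_model(noise_sd = 0), seed = 1)
#' s$spectrum
simulate_spectrum <- function(panel, profile, acq, seed,
                              sample_id = "S1", cohort_id = "cohort1") {
  stopifnot(inherits(panel, "globin_panel"),
            inherits(profile, "disease_profile"),
            inherits(acq, "acquisition_model"))
  check_peaks_in_range(panel, acq)
  with_seed(seed, {
    ab <- draw_abundances(profile)
    clin <- draw_clinical(profile, ab)
    spec <- render_spectrum(panel, ab, acq, sample_id)
    record <- data.frame(
      sample_id = sample_id,
      cohort_id = cohort_id,
      class_label = if (profile$class_name == "control")
        NEGATIVE_CLASS else POSITIVE_CLASS,
      genotype_group = switch(profile$class_name,
                              control = "none",
                              alpha_thal = "alpha",
                              beta_thal = "beta",
                              alphabeta_compound = "alphabeta"),
      hb = clin[["hb"]], hbf = clin[["hbf"]], hba2 = clin[["hba2"]],
      truth_alpha = ab[["alpha"]],
      truth_beta = ab[["beta"]],
      truth_gamma = ab[["gamma"]],
      truth_ratio_ab = ab[["alpha"]] / ab[["beta"]],
      stringsAsFactors = FALSE
    )
    list(spectrum = spec, record = record)
  })
}

check_peaks_in_range <- function(panel, acq) {
  for (sp in names(panel$species_masses)) {
    for (z in panel$charges) {
      centre <- mz_reference(panel, sp, z)
      if (centre < acq$mz_range[1] || centre > acq$mz_range[2]) {
        stopf("peak centre for %s %d+ (%.2f Th) falls outside mz_range [%g, %g]; adjust the acquisition model",
              sp, z, centre, acq$mz_range[1], acq$mz_range[2])
      }
    }
  }
  invisible(TRUE)
}

# Lognormal draws with exact mean = profile mean and CV = between_sample_cv.
draw_abundances <- function(profile) {
  mu <- profile$mean_abundance
  cv <- profile$between_sample_cv
  if (cv == 0) return(mu)
  sdlog <- sqrt(log(1 + cv^2))
  out <- mu
  pos <- mu > 0
  out[pos] <- stats::rlnorm(sum(pos),
                            meanlog = log(mu[pos]) - sdlog^2 / 2,
                            sdlog = sdlog)
  out
}

# Clinical covariates: Gaussian around class baselines with linear links to
# the drawn abundances. Units: Hb g/L, Hb F %, Hb A2 %.
draw_clinical <- function(profile, ab) {
  hb <- 85 + profile$hb_link * (ab[["alpha"]] + ab[["beta"]]) +
    stats::rnorm(1, 0, 5)
  hbf <- 0.5 + profile$hbf_link * ab[["gamma"]] + stats::rnorm(1, 0, 0.4)
  hba2_mean <- switch(profile$class_name,
                      control = 2.6, alpha_thal = 2.3,
                      beta_thal = 4.8, alphabeta_compound = 4.0)
  hba2 <- hba2_mean + stats::rnorm(1, 0, 0.3)
  c(hb = max(hb, 30), hbf = max(hbf, 0), hba2 = max(hba2, 0.2))
}

render_spectrum <- function(panel, abundances, acq, sample_id) {
  mz <- seq(acq$mz_range[1], acq$mz_range[2], by = acq$sampling_step)
  signal <- numeric(length(mz))
  shift <- 1 + acq$calibration_shift_ppm * 1e-6
  amps <- numeric(0)
  for (sp in names(panel$species_masses)) {
    a <- if (sp == "internal_standard") 1 else abundances[[sp]] %||% 0
    if (is.na(a) || a <= 0) next
    for (z in panel$charges) {
      centre <- mz_reference(panel, sp, z) * shift
      sigma <- acq$peak_sigma / z
      amp <- a * if (z == 2) acq$charge2_fraction else 1
      if (amp <= 0) next
      amps <- c(amps, amp)
      win <- abs(mz - centre) <= 6 * sigma
      signal[win] <- signal[win] +
        amp * exp(-((mz[win] - centre)^2) / (2 * sigma^2))
    }
  }
  base_amp <- acq$baseline_amplitude
  if (is.null(base_amp)) {
    # auto: baseline at the low m/z edge is 5x the median peak amplitude
    base_amp <- 5 * stats::median(amps) / exp(-acq$mz_range[1] / acq$baseline_decay)
  }
  baseline <- base_amp * exp(-mz / acq$baseline_decay)
  intensity <- signal + baseline
  if (acq$noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(mz), 0, acq$noise_sd)
  }
  intensity <- pmax(intensity, 0)
  new_spectrum(mz, intensity, sample_id)
}

#' Simulate a cohort of spectra with a manifest
#'
#' Draws the exact requested number of samples per disease class, simulates
#' each spectrum with an independently derived sub-seed, and returns the
#' spectra together with a manifest whose row order is randomised by the seed
#' (acquisition order is not class-blocked in practice).
#'
#' @param panel A [globin_panel()].
#' @param profiles Named list of [disease_profile()] objects.
#' @param n_per_class Named integer vector/list, names a subset of
#'   `names(profiles)`; total must be > 0.
#' @param acq An [acquisition_model()].
#' @param seed Master seed.
#' @param cohort_id Cohort identifier stamped on every record.
#' @param id_prefix Prefix for generated sample ids.
#' @return List with `spectra` (named list of spectrum objects) and
#'   `manifest` (data.frame, one row per sample, randomised order).
#' @export
simulate_cohort <- function(panel, profiles, n_per_class, acq, seed,
                            cohort_id = "cohort1", id_prefix = cohort_id) {
  n_per_class <- unlist(n_per_class)
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% names(profiles))) {
    stopf("names of `n_per_class` must be a subset of names(profiles)")
  }
  if (sum(n_per_class) <= 0) stopf("`n_per_class` must request at least one sample")
  n_per_class <- n_per_class[n_per_class > 0]
  classes <- rep(names(n_per_class), times = n_per_class)
  n <- length(classes)
  seeds <- derive_seeds(seed, n + 1L)
  spectra <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("%s_%04d", id_prefix, i)
    sim <- simulate_spectrum(panel, profiles[[classes[i]]], acq,
                             seed = seeds[i], sample_id = sid,
                             cohort_id = cohort_id)
    spectra[[i]] <- sim$spectrum
    records[[i]] <- sim$record
  }
  manifest <- do.call(rbind, records)
  ord <- with_seed(seeds[n + 1L], sample.int(n))
  manifest <- manifest[ord, , drop = FALSE]
  rownames(manifest) <- NULL
  spectra <- spectra[ord]
  names(spectra) <- manifest$sample_id
  list(spectra = spectra, manifest = manifest)
}

#' Write a simulated cohort to disk
#'
#' One two-column ASCII file per spectrum plus `manifest.csv`, the layout the
#' ingestion side of the pipeline expects.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$spectra)) {
    write_spectrum(cohort$spectra[[sid]], file.path(dir, paste0(sid, ".txt")))
  }
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}
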