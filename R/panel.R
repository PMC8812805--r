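#' Globin reference panel
#'
#' Reference masses for the species quantified from a linear-mode MALDI-TOF
#' blood spectrum: the three haemoglobin chains and the spiked myoglobin
#' internal standard (IS). A singly or doubly protonated species of neutral
#' average mass M appears at m/z = (M + z * 1.00728) / z.
#'
#' The globin neutral average masses are domain constants from canonical human
#' globin sequences and can be overridden; the internal-standard mass is the
#' myoglobin preparation's nominal 16,952 Da.
#'
#' @param species_masses Named numeric vector of neutral average masses (Da).
#'   Must contain `internal_standard`.
#' @param proton_mass Proton mass in Da.
#' @param charges Integer vector of charge states covered.
#' @param tolerance_ppm Matching window used to check that the IS is resolvable
#'   from every globin chain.
#' @return An object of class `globin_panel`.
#' @export
#' @examples
#' panel <- globin_panel()
#' mz_reference(panel, "beta", 1)
globin_panel <- function(species_masses = c(alpha = 15126.4,
                                            beta = 15867.2,
                                            gamma = 15995.3,
                                            internal_standard = 16952.0),
                         proton_mass = 1.00728,
                         charges = c(1L, 2L),
                         tolerance_ppm = 3000) {
  if (is.null(names(species_masses)) || any(!nzchar(names(species_masses)))) {
    stopf("`species_masses` must be a fully named numeric vector")
  }
  if (!"internal_standard" %in% names(species_masses)) {
    stopf("`species_masses` must contain an `internal_standard` entry")
  }
  if (any(!is.finite(species_masses)) || any(species_masses <= 0)) {
    stopf("all species masses must be finite and > 0")
  }
  if (any(charges != as.integer(charges)) || any(charges < 1)) {
    stopf("`charges` must be positive integers")
  }
  m_is <- species_masses[["internal_standard"]]
  others <- species_masses[setdiff(names(species_masses), "internal_standard")]
  min_sep <- 2 * tolerance_ppm * 1e-6 * m_is
  if (length(others) && any(abs(others - m_is) <= min_sep)) {
    stopf("internal standard mass must differ from every globin mass by > %.1f Da (2 x %g ppm window)",
          min_sep, tolerance_ppm)
  }
  structure(
    list(species_masses = species_masses,
         proton_mass = proton_mass,
         charges = sort(unique(as.integer(charges)))),
    class = "globin_panel"
  )
}

#' Reference m/z of a protonated species
#'
#' @param panel A [globin_panel()].
#' @param species Species name present in the panel.
#' @param charge Charge state.
#' @return m/z in Th: `(M + charge * proton_mass) / charge`.
#' @export
mz_reference <- function(panel, species, charge) {
  stopifnot(inherits(panel, "globin_panel"))
  if (!species %in% names(panel$species_masses)) {
    stopf("unknown species '%s'", species)
  }
  m <- panel$species_masses[[species]]
  (m + charge * panel$proton_mass) / charge
}

#' @export
print.globin_panel <- function(x, ...) {
  cat("Globin panel:", length(x$species_masses), "species, charges",
      paste(x$charges, collapse = "/"), "\n")
  print(x$species_masses)
  invisible(x)
}

#' Disease abundance profile
#'
#' Expected relative abundances (internal standard fixed at 1) for one disease
#' class, the between-sample coefficient of variation of the abundance draws,
#' and the linear links tying the drawn abundances to simulated clinical
#' covariates: higher gamma-chain abundance raises Hb F, higher combined
#' alpha+beta abundance raises blood haemoglobin.
#'
#' @param class_name One of `control`, `alpha_thal`, `beta_thal`,
#'   `alphabeta_compound`.
#' @param mean_abundance Named vector of expected relative abundances for
#'   alpha, beta, gamma (arbitrary units relative to IS = 1).
#' @param between_sample_cv Fractional coefficient of variation of the
#'   per-sample lognormal abundance draws.
#' @param hbf_link Slope (percentage points of Hb F per abundance unit of
#'   gamma chain).
#' @param hb_link Slope (g/L of Hb per abundance unit of alpha + beta).
#' @return An object of class `disease_profile`.
#' @export
disease_profile <- function(class_name,
                            mean_abundance,
                            between_sample_cv = 0.15,
                            hbf_link = 8,
                            hb_link = 30) {
  class_name <- match.arg(class_name,
                          c("control", "alpha_thal", "beta_thal",
                            "alphabeta_compound"))
  need <- c("alpha", "beta", "gamma")
  if (!all(need %in% names(mean_abundance))) {
    stopf("`mean_abundance` must name %s", paste(need, collapse = ", "))
  }
  if (any(mean_abundance < 0)) stopf("abundances must be >= 0")
  if (between_sample_cv < 0) stopf("`between_sample_cv` must be >= 0")
  structure(
    list(class_name = class_name,
         mean_abundance = mean_abundance[need],
         between_sample_cv = between_sample_cv,
         hbf_link = hbf_link,
         hb_link = hb_link),
    class = "disease_profile"
  )
}

#' Default disease profiles
#'
#' The stated simulation world: controls have balanced chains
#' (alpha/beta expectation 1) and near-zero foetal gamma chain;
#' beta-thalassaemia halves beta-chain output and re-expresses gamma;
#' alpha-thalassaemia reduces alpha output; the compound class perturbs both.
#'
#' @param beta_deficit Multiplier applied to the beta-chain abundance of the
#'   beta-affected classes (default 0.5: halved output).
#' @param alpha_deficit Multiplier for the alpha-affected classes.
#' @param between_sample_cv Between-sample CV forwarded to every profile.
#' @return Named list of [disease_profile()] objects.
#' @export
default_profiles <- function(beta_deficit = 0.5, alpha_deficit = 0.55,
                             between_sample_cv = 0.15) {
  list(
    control = disease_profile(
      "control", c(alpha = 1, beta = 1, gamma = 0.05),
      between_sample_cv = between_sample_cv),
    alpha_thal = disease_profile(
      "alpha_thal", c(alpha = alpha_deficit, beta = 1, gamma = 0.10),
      between_sample_cv = between_sample_cv),
    beta_thal = disease_profile(
      "beta_thal", c(alpha = 1, beta = beta_deficit, gamma = 0.40),
      between_sample_cv = between_sample_cv),
    alphabeta_compound = disease_profile(
      "alphabeta_compound",
      c(alpha = 0.6 * (alpha_deficit / 0.55), beta = beta_deficit,
        gamma = 0.35),
      between_sample_cv = between_sample_cv)
  )
}

#' Acquisition model for synthetic spectra
#'
#' Forward model of one linear-mode acquisition: an m/z grid, Gaussian peak
#' widths (halved at 2+ as time-of-flight peak width shrinks with charge),
#' the fraction of each species' signal appearing at 2+, a decaying
#' exponential chemical baseline `A * exp(-mz / tau)`, additive Gaussian noise
#' truncated at zero after summation, and a multiplicative calibration error
#' in ppm.
#'
#' @param mz_range Length-2 numeric, acquisition window in Th.
#' @param sampling_step Grid spacing in Th.
#' @param peak_sigma Gaussian sigma at charge 1+ in Th (halved at 2+).
#' @param charge2_fraction Fraction of a species' amplitude emitted at 2+.
#' @param baseline_amplitude `A` of the exponential baseline; `NULL` picks
#'   A so the baseline at the low m/z edge is 5x the median peak amplitude,
#'   `0` disables the baseline.
#' @param baseline_decay `tau` of the exponential baseline in Th.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param calibration_shift_ppm Injected multiplicative m/z error in ppm.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(mz_range = c(2000, 20000),
                              sampling_step = 1,
                              peak_sigma = 8,
                              charge2_fraction = 0.25,
                              baseline_amplitude = NULL,
                              baseline_decay = 3000,
                              noise_sd = 0,
                              calibration_shift_ppm = 0) {
  if (length(mz_range) != 2 || mz_range[1] >= mz_range[2]) {
    stopf("`mz_range` must be c(low, high) with low < high")
  }
  if (sampling_step <= 0) stopf("`sampling_step` must be > 0")
  if (peak_sigma <= 0) stopf("`peak_sigma` must be > 0")
  if (charge2_fraction < 0 || charge2_fraction > 1) {
    stopf("`charge2_fraction` must be in [0, 1]")
  }
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (baseline_decay <= 0) stopf("`baseline_decay` must be > 0")
  structure(
    list(mz_range = as.numeric(mz_range),
         sampling_step = sampling_step,
         peak_sigma = peak_sigma,
         charge2_fraction = charge2_fraction,
         baseline_amplitude = baseline_amplitude,
         baseline_decay = baseline_decay,
         noise_sd = noise_sd,
         calibration_shift_ppm = calibration_shift_ppm),
    class = "acquisition_model"
  )
}
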