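# Shared fixtures: everything is generated in code at test time.

# Artefact-free acquisition: no noise, no baseline, no calibration drift.
quiet_acq <- function(...) {
  args <- list(noise_sd = 0, baseline_amplitude = 0,
               calibration_shift_ppm = 0)
  do.call(acquisition_model, utils::modifyList(args, list(...)))
}

# Coarser grid covering every panel peak; ~3x faster than the full default
# window for module-level tests (acceptance tests use the full default).
fast_acq <- function(...) {
  args <- list(mz_range = c(7000, 18000), sampling_step = 2,
               noise_sd = 0, baseline_amplitude = 0,
               calibration_shift_ppm = 0)
  do.call(acquisition_model, utils::modifyList(args, list(...)))
}

# Hand-built assignment table for feature/normalisation unit tests.
make_assignments <- function(species, charge, raw, norm = NA_real_) {
  data.frame(species = species, charge = as.integer(charge),
             mz_obs = 0, mz_ref = 0, ppm_error = 0,
             intensity_raw = raw, intensity_norm = norm,
             stringsAsFactors = FALSE)
}

# Direct two-class Gaussian feature table (no spectra): fast classifier
# fixtures. `delta` shifts the positive class on the first `n_shift` columns.
sim_feature_table <- function(n_pos, n_neg, delta = 2, n_shift = 3,
                              seed = 1, p = 5) {
  cols <- thalscreen:::FEATURE_COLUMNS[seq_len(p)]
  set.seed(seed)
  X <- matrix(rnorm((n_pos + n_neg) * p), ncol = p,
              dimnames = list(NULL, cols))
  X[seq_len(n_pos), seq_len(n_shift)] <- X[seq_len(n_pos), seq_len(n_shift)] + delta
  out <- data.frame(sample_id = sprintf("s%04d", seq_len(n_pos + n_neg)),
                    class_label = rep(c("thalassaemia", "control"),
                                      c(n_pos, n_neg)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(X))
}

# Independent midrank computation by pair counting (used by the rank oracles).
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Exhaustive pairwise AUC oracle: fraction of (pos, neg) pairs won plus half
# the ties.
oracle_auc <- function(values, y) {
  pos <- values[y == 1]
  neg <- values[y == 0]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# Rank-then-Pearson Spearman oracle with explicit midranks and the textbook
# Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
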