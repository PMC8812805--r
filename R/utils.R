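#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic entry points funnel through this so that (config, seed)
# determines output exactly.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` independent sub-seeds from a master seed (kept within int range).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x > 0

# Canonical feature column order; also the deterministic tie-break order for
# feature ranking.
FEATURE_COLUMNS <- c(
  "alpha_1p", "beta_1p", "gamma_1p",
  "alpha_2p", "beta_2p", "gamma_2p",
  "ratio_ab_1p", "ratio_ab_2p", "diff_ab_1p", "diff_ab_2p"
)

MANIFEST_REQUIRED <- c("sample_id", "class_label")

POSITIVE_CLASS <- "thalassaemia"
NEGATIVE_CLASS <- "control"

# Coerce a label vector to 0/1 with 1 = positive class.
as_binary_labels <- function(labels, positive = POSITIVE_CLASS) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stopf("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  as.integer(labels == positive)
}
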