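# shared internal helpers

MODALITIES <- c("XRAY", "FLG", "MMG")
EXPERIENCE_BANDS <- c("E0_1", "E1_5", "E5_10", "E10P")

# round half away from zero; base round() ties to even, which is wrong for
# display of values like 0.845 -> 0.85
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run code with a private RNG stream; restores the caller's .Random.seed
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# derive a per-purpose substream seed, kept inside 32-bit integer range
substream <- function(seed, offset) {
  (as.numeric(seed) * 31 + offset) %% 2147483647
}

check_binary_labels <- function(labels, call = rlang::caller_env()) {
  if (!all(labels %in% c(0, 1))) {
    abort("`labels` must be 0/1.", class = "readerbench_validation_error", call = call)
  }
  if (!any(labels == 1)) {
    abort("Cannot run ROC inference: no positive (label = 1) cases.",
      class = "readerbench_inference_error", call = call)
  }
  if (!any(labels == 0)) {
    abort("Cannot run ROC inference: no negative (label = 0) cases.",
      class = "readerbench_inference_error", call = call)
  }
  invisible(labels)
}

check_scores <- function(scores, labels, call = rlang::caller_env()) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length.",
      class = "readerbench_validation_error", call = call)
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort("`scores` must be finite and non-missing.",
      class = "readerbench_validation_error", call = call)
  }
  invisible(scores)
}
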