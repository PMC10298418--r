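# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# AUC by direct all-pairs counting (ties one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Consensus by direct transcription of the stated rules. The upper median is
# found by scanning the scale for the smallest score whose cumulative count
# reaches ceiling((n+1)/2) -- a different route than sorting.
oracle_consensus <- function(scores, min_responses = 5, apply_min_filter = TRUE) {
  n <- length(scores)
  if (sum(scores == 3) / n > 0.5) {
    return(list(excluded = TRUE, reason = "undefined_majority", value = NA_real_))
  }
  if (apply_min_filter && n < min_responses) {
    return(list(excluded = TRUE, reason = "too_few_responses", value = NA_real_))
  }
  need <- ceiling((n + 1) / 2)
  med <- NA_integer_
  for (s in 1:5) {
    if (sum(scores <= s) >= need) { med <- s; break }
  }
  list(excluded = FALSE, reason = "none", value = (med - 1) / 4)
}

# Youden scan by explicit confusion-matrix counting at every distinct score
oracle_youden <- function(scores, labels) {
  best <- list(j = -Inf, threshold = NA, se = NA, sp = NA)
  for (t in sort(unique(scores))) {
    tp <- sum(scores >= t & labels == 1)
    fn <- sum(scores < t & labels == 1)
    tn <- sum(scores < t & labels == 0)
    fp <- sum(scores >= t & labels == 0)
    se <- tp / (tp + fn)
    sp <- tn / (tn + fp)
    j <- se + sp - 1
    # strictly greater: ties keep the earlier (lower) threshold
    if (j > best$j + 1e-12) best <- list(j = j, threshold = t, se = se, sp = sp)
  }
  best
}

# Exhaustive paired-swap permutation p-value on per-arm rank scales
oracle_perm_p <- function(a, b, labels) {
  n <- length(labels)
  ra <- rank(a) / n
  rb <- rank(b) / n
  obs <- abs(oracle_auc(ra, labels) - oracle_auc(rb, labels))
  hits <- 0
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  for (k in seq_len(nrow(patterns))) {
    sw <- unlist(patterns[k, ])
    sa <- ifelse(sw, rb, ra)
    sb <- ifelse(sw, ra, rb)
    if (abs(oracle_auc(sa, labels) - oracle_auc(sb, labels)) >= obs - 1e-12) {
      hits <- hits + 1
    }
  }
  hits / nrow(patterns)
}

# equal-variance binormal scores with true AUC `auc`
make_binormal <- function(n_pos, n_neg, auc, seed) {
  d <- sqrt(2) * qnorm(auc)
  set.seed(seed)
  labels <- c(rep(1, n_pos), rep(0, n_neg))
  scores <- rnorm(n_pos + n_neg, labels * d)
  list(scores = scores, labels = labels, d = d)
}

# a small hand-held ratings fixture builder
ratings_tbl <- function(scores, case_id = "c1") {
  tibble::tibble(reader_id = paste0("r", seq_along(scores)),
    case_id = case_id, score = as.integer(scores))
}
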