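# internal: AUC from midranks; ties count one half
auc_from_ranks <- function(scores, pos_idx, n_pos, n_neg) {
  r <- rank(scores, ties.method = "average")
  (sum(r[pos_idx]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical AUROC (Mann-Whitney estimator)
#'
#' The probability that a random positive case scores above a random
#' negative one, with ties counted one half: the mean over all
#' (positive, negative) pairs of \eqn{1\{s_+ > s_-\} + \tfrac12 1\{s_+ = s_-\}}.
#'
#' @param scores Numeric classifier scores (higher = more likely
#'   pathological).
#' @param labels Binary ground truth (1 = with pathology).
#' @return The AUC, a single number in \[0, 1\].
#' @examples
#' empirical_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
empirical_auc <- function(scores, labels) {
  check_scores(scores, labels)
  check_binary_labels(labels)
  auc_from_ranks(scores, which(labels == 1), sum(labels == 1), sum(labels == 0))
}

# internal: empirical ROC points at every achievable threshold,
# predicted-positive convention score >= threshold
empirical_roc_points <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(neg >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(pos >= t), numeric(1))))
}

#' AUROC with a DeLong confidence interval
#'
#' Estimates the empirical AUROC and its variance by DeLong's nonparametric
#' method: the variance is the sum of the sample variances of the per-positive
#' and per-negative placement values, divided by the number of positives and
#' negatives respectively, and the interval is the normal-approximation CI
#' truncated to \[0, 1\]. Inference always uses the empirical curve; the
#' binormal smoothed curve (see [smooth_roc()]) is attached for display only.
#'
#' @inheritParams empirical_auc
#' @param level Confidence level (default 0.95).
#' @param smooth Attach a display-only smoothed curve? Default `TRUE`.
#' @return An object of class `roc_result`: `auc`, `conf_low`, `conf_high`,
#'   `variance`, `level`, `n_pos`, `n_neg`, `curve` (empirical points) and
#'   `smoothed_curve`. Under perfect separation the variance is 0 and the
#'   degenerate interval `[auc, auc]` is returned with a warning.
#' @examples
#' set.seed(1)
#' y <- rep(0:1, each = 50)
#' s <- rnorm(100, y)
#' delong_ci(s, y)
#' @export
delong_ci <- function(scores, labels, level = 0.95, smooth = TRUE) {
  check_scores(scores, labels)
  check_binary_labels(labels)
  if (level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "readerbench_validation_error")
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 < 2 || n0 < 2) {
    abort("DeLong variance needs at least 2 positive and 2 negative cases.",
      class = "readerbench_inference_error")
  }
  # placement values via ranks: V10[i] = P-hat(pos_i > random neg),
  # V01[j] = P-hat(random pos > neg_j); both average to the AUC
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(neg, ties.method = "average")) / n1
  auc <- mean(v10)
  variance <- var(v10) / n1 + var(v01) / n0
  if (variance == 0) {
    warn("Degenerate DeLong interval: zero variance (perfect separation or constant placements).")
    ci <- c(auc, auc)
  } else {
    z <- qnorm((1 + level) / 2)
    ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(variance), 0), 1)
  }
  smoothed <- if (smooth) {
    tryCatch(suppressWarnings(smooth_roc(scores, labels)), error = function(e) NULL)
  }
  structure(
    list(auc = auc, conf_low = ci[1], conf_high = ci[2], variance = variance,
      level = level, n_pos = n1, n_neg = n0,
      curve = empirical_roc_points(scores, labels), smoothed_curve = smoothed),
    class = "roc_result")
}

#' Binormal smoothing of a ROC curve (display only)
#'
#' Fits the binormal model by ordinary least squares on the
#' probit-transformed interior empirical ROC points,
#' \eqn{\Phi^{-1}(TPR) = a + b\,\Phi^{-1}(FPR)}, and returns the fitted
#' curve on a fixed FPR grid. The smoothed AUC of the fit is
#' \eqn{\Phi(a / \sqrt{1 + b^2})}. Smoothing is for plotting only; all
#' inference uses the empirical curve.
#'
#' @inheritParams empirical_auc
#' @param n_grid Number of FPR grid points (default 101).
#' @return A tibble `(fpr, tpr)` of class `roc_smooth` with attributes `a`,
#'   `b`, `auc` and `smoothed`. With fewer than 2 interior points (e.g.
#'   perfect separation) the empirical curve is returned with a warning and
#'   `smoothed = FALSE`.
#' @export
smooth_roc <- function(scores, labels, n_grid = 101) {
  check_scores(scores, labels)
  check_binary_labels(labels)
  pts <- empirical_roc_points(scores, labels)
  interior <- pts[pts$fpr > 0 & pts$fpr < 1 & pts$tpr > 0 & pts$tpr < 1, ]
  interior <- unique(interior[c("fpr", "tpr")])
  if (nrow(interior) < 2) {
    warn("Too few interior ROC points to smooth; returning the empirical curve.")
    out <- pts[c("fpr", "tpr")]
    attr(out, "smoothed") <- FALSE
    class(out) <- c("roc_smooth", class(out))
    return(out)
  }
  fit <- lm(qnorm(tpr) ~ qnorm(fpr), data = interior)
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  fpr <- seq(0, 1, length.out = n_grid)
  out <- tibble::tibble(fpr = fpr, tpr = pnorm(a + b * qnorm(fpr)))
  out$tpr[fpr == 0] <- 0
  out$tpr[fpr == 1] <- 1
  attr(out, "a") <- a
  attr(out, "b") <- b
  attr(out, "auc") <- pnorm(a / sqrt(1 + b^2))
  attr(out, "smoothed") <- TRUE
  class(out) <- c("roc_smooth", class(out))
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact interval from beta quantiles: the lower bound is 0 when `x = 0`
#' and the upper bound is 1 when `x = n`.
#'
#' @param x Number of successes (vectorized).
#' @param n Number of trials (vectorized).
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `estimate`, `conf_low`, `conf_high`.
#' @examples
#' binomial_ci(8, 8)   # lower bound 0.025^(1/8) = 0.63
#' @export
binomial_ci <- function(x, n, level = 0.95) {
  if (anyNA(x) || anyNA(n) || any(n < 1) || any(x < 0) || any(x > n)) {
    abort("Need 0 <= x <= n and n >= 1.", class = "readerbench_validation_error")
  }
  alpha <- 1 - level
  lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(estimate = x / n, conf_low = lo, conf_high = hi)
}

#' Youden-index operating point
#'
#' Scans all achievable thresholds (the distinct observed scores, with
#' predicted-positive defined as score >= threshold) for the maximum of the
#' Youden index \eqn{J(t) = Se(t) + Sp(t) - 1}. Ties across thresholds are
#' broken toward the lowest threshold, i.e. the highest sensitivity
#' (screening convention). Sensitivity, specificity and accuracy carry exact
#' Clopper-Pearson confidence intervals.
#'
#' @inheritParams empirical_auc
#' @param level Confidence level for the binomial intervals (default 0.95).
#' @return An object of class `operating_point`: `threshold`, `youden_j`,
#'   `sensitivity`, `specificity`, `accuracy` (each a one-row tibble from
#'   [binomial_ci()]), and the confusion counts `tp`, `fp`, `tn`, `fn`.
#'   `youden_j` equals sensitivity + specificity - 1 exactly, pre-rounding.
#' @examples
#' y <- c(1, 1, 1, 0, 0, 0)
#' s <- c(5, 4, 2, 3, 1, 1)
#' youden_operating_point(s, y)
#' @export
youden_operating_point <- function(scores, labels, level = 0.95) {
  check_scores(scores, labels)
  check_binary_labels(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  thr <- sort(unique(scores))
  se <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  sp <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- se + sp - 1
  best <- which(j == max(j))[1]  # thresholds ascending: first = lowest = highest Se
  t_star <- thr[best]
  tp <- sum(pos >= t_star)
  fn <- length(pos) - tp
  fp <- sum(neg >= t_star)
  tn <- length(neg) - fp
  structure(
    list(threshold = t_star, youden_j = j[best],
      sensitivity = binomial_ci(tp, tp + fn, level),
      specificity = binomial_ci(tn, tn + fp, level),
      accuracy = binomial_ci(tp + tn, tp + fn + tn + fp, level),
      tp = tp, fp = fp, tn = tn, fn = fn, level = level),
    class = "operating_point")
}

#' Paired permutation test for the difference of two AUROCs
#'
#' Tests the null hypothesis that two classifiers scored on the same cases
#' have the same AUROC. Both score vectors are first mapped to a common
#' per-arm rank scale (midranks / n), making per-case swaps scale-free; the
#' statistic is the absolute AUC difference. The null distribution is
#' generated by independently swapping, per case, the pair of scores with
#' probability one half; the p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{stat^* \ge stat\}) / (B + 1)}, so it is never smaller
#' than \eqn{1/(B+1)}. With `exhaustive = TRUE` all \eqn{2^n} swap patterns
#' are enumerated instead (only for small n) and
#' \eqn{p = \#\{stat^* \ge stat\} / 2^n}.
#'
#' @param scores_a,scores_b Numeric score vectors for the two classifiers,
#'   aligned case-by-case.
#' @inheritParams empirical_auc
#' @param n_permutations Number of random swap patterns (default 10000).
#' @param seed Integer seed; the p-value is reproducible bit-for-bit given
#'   (inputs, `n_permutations`, `seed`).
#' @param exhaustive Enumerate all \eqn{2^n} patterns (requires n <= 20)?
#' @param paired Use the paired per-case swap scheme (default); with
#'   `paired = FALSE` the null reassigns the pooled 2n rank-scale scores to
#'   the two arms at random, ignoring the case pairing.
#' @return An object of class `comparison_result`: `delta_auc`
#'   (AUC(a) - AUC(b), signed), `statistic` (its absolute value), `p_value`,
#'   `n_permutations`, `seed`.
#' @examples
#' y <- rep(0:1, 10)
#' set.seed(2)
#' a <- y + rnorm(20); b <- y + rnorm(20)
#' permutation_test_auc(a, b, y, n_permutations = 999, seed = 1)
#' @export
permutation_test_auc <- function(scores_a, scores_b, labels,
                                 n_permutations = 10000, seed = 1,
                                 exhaustive = FALSE, paired = TRUE) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    abort("`scores_a`, `scores_b` and `labels` must be paired (equal length).",
      class = "readerbench_validation_error")
  }
  check_scores(scores_a, labels)
  check_scores(scores_b, labels)
  check_binary_labels(labels)
  n <- length(labels)
  pos_idx <- which(labels == 1)
  n1 <- length(pos_idx)
  n0 <- n - n1
  ra <- rank(scores_a, ties.method = "average") / n
  rb <- rank(scores_b, ties.method = "average") / n
  stat_of <- function(sa, sb) {
    abs(auc_from_ranks(sa, pos_idx, n1, n0) - auc_from_ranks(sb, pos_idx, n1, n0))
  }
  observed <- stat_of(ra, rb)
  eps <- 1e-12
  if (exhaustive) {
    if (n > 20) {
      abort("Exhaustive enumeration is limited to n <= 20 cases.",
        class = "readerbench_validation_error")
    }
    if (!paired) {
      abort("Exhaustive enumeration is implemented for the paired scheme only.",
        class = "readerbench_validation_error")
    }
    n_pat <- 2^n
    hits <- 0L
    for (m in 0:(n_pat - 1)) {
      swap <- bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L
      sa <- ifelse(swap, rb, ra)
      sb <- ifelse(swap, ra, rb)
      if (stat_of(sa, sb) >= observed - eps) hits <- hits + 1L
    }
    p <- hits / n_pat
    n_permutations <- n_pat
  } else {
    stats_null <- with_seed(seed, {
      if (paired) {
        vapply(seq_len(n_permutations), function(b) {
          swap <- runif(n) < 0.5
          sa <- ifelse(swap, rb, ra)
          sb <- ifelse(swap, ra, rb)
          stat_of(sa, sb)
        }, numeric(1))
      } else {
        # unpaired: reassign the pooled 2n (score, label) observations to arms
        pool <- c(ra, rb)
        lab2 <- c(labels, labels)
        arm_auc <- function(s, y) {
          auc_from_ranks(s, which(y == 1), sum(y == 1), sum(y == 0))
        }
        vapply(seq_len(n_permutations), function(b) {
          take <- sample(2 * n, n)
          ya <- lab2[take]
          yb <- lab2[-take]
          if (length(unique(ya)) < 2 || length(unique(yb)) < 2) return(NA_real_)
          abs(arm_auc(pool[take], ya) - arm_auc(pool[-take], yb))
        }, numeric(1))
      }
    })
    p <- (1 + sum(stats_null >= observed - eps, na.rm = TRUE)) / (n_permutations + 1)
  }
  structure(
    list(
      delta_auc = empirical_auc(scores_a, labels) - empirical_auc(scores_b, labels),
      statistic = observed, p_value = p, n_permutations = n_permutations,
      seed = if (exhaustive) NA_integer_ else as.integer(seed),
      method = if (exhaustive) "exhaustive" else "monte-carlo"),
    class = "comparison_result")
}
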