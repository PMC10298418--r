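test_that("empirical AUC counts pairs with ties half-weighted", {
  expect_equal(empirical_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(empirical_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(empirical_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(empirical_auc(c(1, 2), c(1, 1)),
    class = "readerbench_inference_error", regexp = "negative")
})

test_that("empirical AUC matches all-pairs counting and obeys its symmetries", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0.1, 0.9, by = 0.2), n, replace = TRUE)  # forces ties
    a <- empirical_auc(s, y)
    expect_equal(a, oracle_auc(s, y))
    # invariant under strictly increasing transforms
    expect_equal(empirical_auc(exp(3 * s), y), a)
    # complement under label swap
    expect_equal(empirical_auc(s, 1 - y), 1 - a)
  }
})

test_that("DeLong variance matches the placement decomposition and pROC", {
  scores <- c(0.8, 0.3, 0.5, 0.1)
  labels <- c(1, 1, 0, 0)
  r <- delong_ci(scores, labels)
  expect_equal(r$auc, 0.75)
  # placements: positives {1.0, 0.5}, negatives' complement {0.5, 1.0};
  # sample variances 0.125 each -> 0.125/2 + 0.125/2
  expect_equal(r$variance, 0.125)
  # independent cross-check on a larger draw
  set.seed(21)
  y <- rep(0:1, each = 30)
  s <- round(rnorm(60, y), 1)
  ours <- delong_ci(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
  expect_equal(ours$variance, pROC::var(ref))
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(ours$conf_low, ours$conf_high), ref_ci[c(1, 3)], tolerance = 1e-9)
})

test_that("DeLong CI centres on the empirical AUC and narrows like 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    dat <- make_binormal(n, n, 0.8, seed = n)
    r <- delong_ci(dat$scores, dat$labels)
    expect_equal(r$auc, empirical_auc(dat$scores, dat$labels))
    expect_true(r$conf_low <= r$auc && r$auc <= r$conf_high)
    r$conf_high - r$conf_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # quadrupling n should roughly halve the width
  expect_lt(widths[2] / widths[1], 0.65)
})

test_that("perfect separation yields a degenerate interval with a warning", {
  expect_warning(
    r <- delong_ci(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)),
    "Degenerate")
  expect_equal(c(r$conf_low, r$conf_high), c(1, 1))
  expect_equal(r$variance, 0)
})

test_that("ROC curves run from (0,0) to (1,1) and are monotone", {
  dat <- make_binormal(30, 30, 0.85, seed = 3)
  r <- delong_ci(dat$scores, dat$labels)
  expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("binormal smoothing recovers the generating model on binormal data", {
  dat <- make_binormal(2000, 2000, 0.85, seed = 17)
  sm <- smooth_roc(dat$scores, dat$labels)
  expect_true(attr(sm, "smoothed"))
  # fitted intercept ~ d, slope ~ 1, smoothed AUC ~ Phi(a / sqrt(1 + b^2))
  expect_equal(attr(sm, "auc"),
    pnorm(attr(sm, "a") / sqrt(1 + attr(sm, "b")^2)))
  expect_lt(abs(attr(sm, "auc") - 0.85), 0.02)
  expect_equal(attr(sm, "b"), 1, tolerance = 0.1)
  expect_true(all(diff(sm$tpr) >= -1e-9))
  # display only: the inference object is untouched by smoothing
  r <- delong_ci(dat$scores, dat$labels, smooth = FALSE)
  expect_null(r$smoothed_curve)
  expect_equal(r$auc, empirical_auc(dat$scores, dat$labels))
})

test_that("smoothing degenerates gracefully under perfect separation", {
  expect_warning(
    sm <- smooth_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)),
    "interior")
  expect_false(attr(sm, "smoothed"))
  expect_equal(sm$fpr[1], 0)
})

test_that("the Youden point maximises J with ties broken toward sensitivity", {
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(5, 4, 2, 3, 1, 1)
  op <- youden_operating_point(s, y)
  ref <- oracle_youden(s, y)
  expect_equal(op$threshold, ref$threshold)
  expect_equal(op$youden_j, ref$j)
  expect_equal(op$youden_j,
    op$sensitivity$estimate + op$specificity$estimate - 1)
  # perfect classifier: J = 1 at a separating threshold
  op <- youden_operating_point(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(op$youden_j, 1)
  # explicit tie across thresholds: pos {2,4}, neg {1,3} gives J = 0.5 at
  # both t=2 and t=4; the lower threshold (higher Se) must win
  op <- youden_operating_point(c(2, 4, 1, 3), c(1, 1, 0, 0))
  expect_equal(op$threshold, 2)
  expect_equal(op$sensitivity$estimate, 1)
})

test_that("uninformative scores give a near-zero maximal J", {
  set.seed(5)
  y <- rep(0:1, each = 500)
  s <- runif(1000)
  op <- youden_operating_point(s, y)
  expect_lt(op$youden_j, 0.12)
})

test_that("Clopper-Pearson intervals match their boundary closed forms", {
  ci <- binomial_ci(8, 8)
  expect_equal(ci$conf_low, 0.025^(1 / 8))
  expect_equal(ci$conf_high, 1)
  ci <- binomial_ci(0, 10)
  expect_equal(ci$conf_low, 0)
  expect_equal(ci$conf_high, 1 - 0.025^(1 / 10))
  # cross-check against base R's exact test on an interior case
  bt <- stats::binom.test(13, 20)
  ci <- binomial_ci(13, 20)
  expect_equal(c(ci$conf_low, ci$conf_high), as.numeric(bt$conf.int))
  expect_error(binomial_ci(5, 4), class = "readerbench_validation_error")
})

test_that("the permutation test is exact on tiny instances and reproducible", {
  # identical arms: zero statistic, p = 1
  y <- c(1, 1, 0, 0)
  s <- c(0.9, 0.4, 0.6, 0.1)
  out <- permutation_test_auc(s, s, y, n_permutations = 99, seed = 4)
  expect_equal(out$delta_auc, 0)
  expect_equal(out$p_value, 1)
  # exhaustive enumeration matches the brute-force oracle exactly
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    a <- runif(n)
    b <- runif(n)
    out <- permutation_test_auc(a, b, y, exhaustive = TRUE)
    expect_equal(out$p_value, oracle_perm_p(a, b, y))
    expect_gte(out$p_value, 1 / (out$n_permutations + 1))
  }
  # bit-for-bit reproducibility given (inputs, B, seed)
  y <- rep(0:1, 15)
  set.seed(8)
  a <- y + rnorm(30)
  b <- y + rnorm(30)
  p1 <- permutation_test_auc(a, b, y, n_permutations = 500, seed = 11)
  p2 <- permutation_test_auc(a, b, y, n_permutations = 500, seed = 11)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 501)
  # rank-scale mapping makes the test scale-free
  p3 <- permutation_test_auc(exp(a), b, y, n_permutations = 500, seed = 11)
  expect_identical(p1$p_value, p3$p_value)
  # unpaired variant runs and returns a valid p
  p4 <- permutation_test_auc(a, b, y, n_permutations = 200, seed = 11, paired = FALSE)
  expect_true(p4$p_value > 0 && p4$p_value <= 1)
  expect_error(permutation_test_auc(a, b[-1], y[-1]),
    class = "readerbench_validation_error")
})

test_that("AUC, Youden and exhaustive-permutation agree with oracles jointly", {
  # systematic sweep over small datasets with few distinct scores
  set.seed(23)
  grid <- seq(0.2, 0.8, by = 0.2)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- sample(grid, n, replace = TRUE)
    expect_equal(empirical_auc(s, y), oracle_auc(s, y))
    ref <- oracle_youden(s, y)
    op <- youden_operating_point(s, y)
    expect_equal(op$threshold, ref$threshold)
    expect_equal(op$youden_j, ref$j)
  }
})

test_that("result objects tidy and glance like broom fittings", {
  dat <- make_binormal(20, 20, 0.9, seed = 2)
  r <- delong_ci(dat$scores, dat$labels)
  td <- tidy(r)
  expect_true(all(c("threshold", "fpr", "tpr") %in% names(td)))
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$auc, r$auc)
  op <- youden_operating_point(dat$scores, dat$labels)
  expect_identical(tidy(op)$metric, c("sensitivity", "specificity", "accuracy"))
  expect_equal(glance(op)$youden_j, op$youden_j)
  cmp <- permutation_test_auc(dat$scores, rev(dat$scores), dat$labels,
    n_permutations = 50, seed = 1)
  expect_equal(tidy(cmp)$p_value, cmp$p_value)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
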