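test_that("Mann-Whitney exact p equals exhaustive permutation", {
  # separated groups: U = 0, p = 2/20
  tr <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tr$statistic, 0)
  expect_equal(tr$p_value, 0.1)

  # identical multisets: U = n^2/2, p ~ 1
  tr2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tr2$u_x, 4.5)
  expect_gte(tr2$p_value, 0.99)

  # randomized small fixtures, with and without ties
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- if (i %% 2) rnorm(n1 + n2) else sample(1:4, n1 + n2, TRUE)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y)$p_value, perm_mwu_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney matches the tie-corrected normal
           approximation", {
  set.seed(4)
  x <- round(rnorm(30), 1); y <- round(rnorm(25, 0.4), 1)
  tr <- mann_whitney_u(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(tr$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches hand rank arithmetic and Bonferroni
           caps at 1", {
  # groups [1,2],[3,4],[5,6]: ranks 1..6, H = 12/42 * 2*((1.5-3.5)^2 +
  # 0 + (5.5-3.5)^2) = 32/7
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(32 / 7, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups: H ~ 0, p ~ 1
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  kw0 <- kruskal_wallis(g)
  expect_lt(kw0$statistic, 1e-9)
  expect_gte(kw0$p_value, 0.999)

  pw <- pairwise_bonferroni(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(nrow(pw), 3)
  expect_equal(pw$adjusted_p, pmin(1, pw$p * 3))
  expect_true(all(pw$adjusted_p >= pw$p))
  expect_error(kruskal_wallis(list(1:3, numeric(0), 1:3)), "empty")
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman_rho(1:5, 5:1)$statistic, -1)

  # tied fixture against brute-force average ranks + Pearson formula
  x <- c(1, 2, 2, 3, 5); y <- c(10, 10, 30, 40, 40)
  rx <- c(1, 2.5, 2.5, 4, 5); ry <- c(1.5, 1.5, 3, 4.5, 4.5)
  rho_manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y)$statistic, rho_manual, tolerance = 1e-12)

  expect_match(spearman_rho(1:20, 1:20 + rnorm(20, 0, 20))$band,
               "poor|mild|moderate|good")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "paired")
})

test_that("ICC(2,1) matches a hand ANOVA decomposition and penalizes bias", {
  expect_equal(icc_two_way_random(cbind(1:10, 1:10))$statistic, 1)

  # constant inter-reader bias with zero noise: absolute agreement < 1
  biased <- icc_two_way_random(cbind(1:10, 1:10 + 5))
  expect_lt(biased$statistic, 1)
  expect_gt(biased$statistic, 0)

  # 6x2 fixture: independent mean-squares arithmetic written out
  r <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  n <- 6; k <- 2
  gm <- mean(r)
  msr <- k * sum((rowMeans(r) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(r) - gm)^2) / (k - 1)
  sse <- sum((r - outer(rowMeans(r), rep(1, k)) -
                outer(rep(1, n), colMeans(r)) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc_manual <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  res <- icc_two_way_random(r)
  expect_equal(res$statistic, icc_manual, tolerance = 1e-10)
  expect_true(res$ci[1] <= res$statistic && res$statistic <= res$ci[2])

  expect_error(icc_two_way_random(cbind(1:3, 1:3)), "at least 5")
  expect_error(icc_two_way_random(cbind(c(1, NA, 3, 4, 5), 1:5)),
               "missing")
})

test_that("AUC is the rank statistic U/(n1 n0) and respects monotone
           transforms", {
  set.seed(31)
  for (i in 1:100) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    scores <- c(rnorm(n1, 0.6), rnorm(n0))
    if (i %% 3 == 0) scores <- round(scores, 1)  # force ties
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    roc <- roc_analysis(scores, labels, positive_low = FALSE)
    u <- mann_whitney_u(scores[labels], scores[!labels])$u_x
    expect_equal(roc$auc, u / (n1 * n0), tolerance = 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    roc2 <- roc_analysis(exp(2 * scores), labels, positive_low = FALSE)
    expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)
  }
})

test_that("ROC handles separation, orientation and the Youden cutoff", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c(FALSE, TRUE), each = 3)
  roc <- roc_analysis(scores, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity, 100)
  expect_equal(roc$specificity, 100)
  expect_false(roc$positive_low)
  expect_true(roc$cutoff > 3 && roc$cutoff < 10)

  # malignant-low orientation auto-detected
  roc_low <- roc_analysis(-scores, labels)
  expect_true(roc_low$positive_low)
  expect_equal(roc_low$auc, 1)

  expect_error(roc_analysis(1:4, rep(TRUE, 4)), "both classes")

  # label-independent scores: AUC near 1/2
  set.seed(8)
  rocn <- roc_analysis(rnorm(1000), rep(c(TRUE, FALSE), 500),
                       positive_low = FALSE)
  expect_gt(rocn$auc, 0.45); expect_lt(rocn$auc, 0.55)
})

test_that("ROC and DeLong agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  labels <- rep(c(TRUE, FALSE), c(30, 25))
  a <- rnorm(55, ifelse(labels, 1, 0))
  b <- rnorm(55, ifelse(labels, 0.6, 0))
  roc <- roc_analysis(a, labels, positive_low = FALSE)
  pr <- pROC::roc(labels, a, direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- pROC::ci.auc(pr, method = "delong")
  expect_equal(roc$ci, as.numeric(ci[c(1, 3)]), tolerance = 1e-9)

  dt <- delong_test(a, b, labels)
  prb <- pROC::roc(labels, b, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(pr, prb, method = "delong", paired = TRUE)
  expect_equal(dt$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong test is null on identical or rank-equivalent scores and
           its variance matches a paired bootstrap", {
  set.seed(14)
  labels <- rep(c(TRUE, FALSE), each = 20)
  a <- rnorm(40, ifelse(labels, 0.8, 0))
  expect_equal(delong_test(a, a, labels)$p_value, 1)
  expect_equal(delong_test(a, a, labels)$statistic, 0)
  mono <- delong_test(a, 5 * atan(a) - 2, labels)
  expect_equal(mono$statistic, 0)
  expect_equal(mono$p_value, 1)

  # bootstrap oracle for the variance of the AUC difference
  b <- rnorm(40, ifelse(labels, 0.5, 0))
  dt <- delong_test(a, b, labels)
  vd_delong <- (dt$statistic / dt$z)^2
  auc_of <- function(s, l) {
    r <- rank(s)
    (sum(r[l]) - sum(l) * (sum(l) + 1) / 2) / (sum(l) * sum(!l))
  }
  set.seed(99)
  diffs <- replicate(2000, {
    ix <- sample(40, replace = TRUE)
    l <- labels[ix]
    if (all(l) || !any(l)) return(NA_real_)
    auc_of(a[ix], l) - auc_of(b[ix], l)
  })
  ratio <- vd_delong / var(diffs, na.rm = TRUE)
  expect_gt(ratio, 0.7); expect_lt(ratio, 1.4)

  expect_error(delong_test(a[1:10], b, labels), "paired")
})

test_that("null calibration: rank-test type-I error sits near alpha", {
  n_rep <- 1000
  set.seed(2024)
  rej_mwu <- mean(replicate(n_rep,
    mann_whitney_u(rnorm(20), rnorm(20))$p_value < 0.05))
  expect_gte(rej_mwu, 0.03); expect_lte(rej_mwu, 0.07)

  rej_kw <- mean(replicate(n_rep,
    kruskal_wallis(list(rnorm(15), rnorm(15), rnorm(15)))$p_value < 0.05))
  expect_gte(rej_kw, 0.03); expect_lte(rej_kw, 0.07)

  rej_sp <- mean(replicate(n_rep,
    spearman_rho(rnorm(30), rnorm(30))$p_value < 0.05))
  expect_gte(rej_sp, 0.03); expect_lte(rej_sp, 0.07)
})

test_that("the multivariable logistic model reduces and combines sensibly", {
  set.seed(17)
  labels <- rep(c(TRUE, FALSE), c(60, 60))
  x1 <- rnorm(120, ifelse(labels, 1, 0))

  single <- combined_model_auc(matrix(x1), labels)
  ref <- roc_analysis(x1, labels, positive_low = FALSE)
  expect_equal(single$auc, ref$auc, tolerance = 1e-9)

  # a redundant duplicated column changes nothing
  dup <- combined_model_auc(cbind(x1, x1), labels)
  expect_equal(dup$auc, single$auc, tolerance = 1e-9)

  # two informative independent features: combination at least as good
  # as the best single metric (up to Monte-Carlo slack)
  x2 <- rnorm(120, ifelse(labels, 0.8, 0))
  both <- combined_model_auc(cbind(x1, x2), labels)
  best_single <- max(ref$auc, roc_analysis(x2, labels,
                                           positive_low = FALSE)$auc)
  expect_gte(both$auc, best_single - 0.01)

  # perfect separation is flagged but still ranked
  sep <- combined_model_auc(matrix(c(1:10, 21:30)),
                            rep(c(FALSE, TRUE), each = 10))
  expect_true(sep$separation)
  expect_equal(sep$auc, 1)
})
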