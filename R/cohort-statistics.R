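# Lesion-level statistical battery: Mann-Whitney, Kruskal-Wallis with
# Bonferroni pairwise correction, Spearman correlation, two-way random
# ICC, ROC/Youden analysis with DeLong variance, AUC comparison, and the
# multivariable logistic combination.

test_result <- function(statistic, p_value, adjusted_p = NA_real_,
                        direction = NA_character_, method = "",
                        extra = list()) {
  p_value <- min(max(p_value, 0), 1)
  if (!is.na(adjusted_p)) adjusted_p <- min(max(adjusted_p, p_value), 1)
  structure(c(list(statistic = statistic, p_value = p_value,
                   adjusted_p = adjusted_p, direction = direction,
                   method = method), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (!is.na(x$adjusted_p)) cat(sprintf(", adjusted p = %.4g", x$adjusted_p))
  if (!is.na(x$direction)) cat(" [", x$direction, "]", sep = "")
  cat("\n")
  invisible(x)
}

# U statistic (pairs where x beats y, ties half) from pooled mid-ranks.
u_statistic <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For pooled sizes up to `exact_max` the p-value
#' is computed by exhaustive enumeration of all group assignments (valid
#' under ties, where the classical exact tables are not); larger samples
#' use the normal approximation with tie and continuity corrections.
#' The reported statistic is the smaller of the two U conventions.
#'
#' @param x,y Numeric value vectors, each non-empty.
#' @param exact_max Pooled-size threshold for exhaustive enumeration;
#'   default 10.
#' @return A `test_result` with `statistic` = min(U_x, U_y), the two-sided
#'   `p_value`, `direction` ("x_higher"/"y_higher"/"none" by U), and
#'   `u_x` (the x-beats-y count) in the extras.
#' @export
mann_whitney_u <- function(x, y, exact_max = 10L) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ux <- u_statistic(x, y)
  mid <- n1 * n2 / 2
  if (n <= exact_max) {
    pooled <- c(x, y)
    combos <- utils::combn(n, n1)
    dev_obs <- abs(ux - mid)
    devs <- apply(combos, 2, function(ix)
      abs(u_statistic(pooled[ix], pooled[-ix]) - mid))
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    method <- "Mann-Whitney U (normal approximation)"
  }
  direction <- if (ux > mid) "x_higher" else if (ux < mid) "y_higher"
               else "none"
  test_result(statistic = min(ux, n1 * n2 - ux), p_value = p,
              direction = direction, method = method,
              extra = list(u_x = ux, n1 = n1, n2 = n2))
}

#' Kruskal-Wallis omnibus test across groups
#'
#' Tie-corrected H statistic against the chi-square reference, via
#' [stats::kruskal.test()].
#'
#' @param groups List of >= 3 non-empty numeric vectors.
#' @return A `test_result` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 3L)
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  kt <- stats::kruskal.test(groups)
  test_result(statistic = unname(kt$statistic), p_value = kt$p.value,
              method = "Kruskal-Wallis")
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' @param groups Named list of >= 2 non-empty numeric vectors.
#' @return Data frame with one row per pair: group names, U, raw p and
#'   Bonferroni-adjusted p (raw p times the number of pairs, capped at 1).
#' @export
pairwise_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    tr <- mann_whitney_u(groups[[pr[1]]], groups[[pr[2]]])
    data.frame(group1 = pr[1], group2 = pr[2], U = tr$statistic,
               p = tr$p_value, adjusted_p = min(1, tr$p_value * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation
#'
#' Average ranks for ties, Pearson correlation of the ranks, two-sided p
#' by the t approximation. The correlation-strength band follows the
#' conventional scheme: 0.75-1.00 good, 0.50-0.74 moderate, 0.25-0.49
#' mild, 0.00-0.24 poor.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `test_result` with `statistic` = rho and `band` in the
#'   extras.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  band <- cut(abs(rho), c(-Inf, 0.25, 0.50, 0.75, Inf),
              labels = c("poor", "mild", "moderate", "good"))
  test_result(statistic = rho, p_value = p, method = "Spearman rho",
              direction = if (rho >= 0) "positive" else "negative",
              extra = list(band = as.character(band), n = n))
}

#' Two-way random-effects ICC, absolute agreement, single measure
#'
#' ICC(2,1) from the two-way ANOVA decomposition of a lesions x readers
#' table, with the F-based 95\% confidence interval. Interpretation bands:
#' <= 0.40 poor, 0.40-0.59 fair, 0.60-0.74 good, 0.75-1.00 excellent.
#'
#' @param ratings Numeric matrix, rows = lesions (>= 5), columns =
#'   readers; no missing cells.
#' @param conf_level Confidence level, default 0.95.
#' @return A `test_result` with `statistic` = ICC, a `ci` 2-vector and
#'   `band` in the extras; `p_value` is the F-test of the ICC against 0.
#' @export
icc_two_way_random <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("missing cells in the ratings table")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 lesions")
  if (k < 2L) stop("need at least 2 readers")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  SSR <- k * sum((row_m - grand)^2)          # lesions (rows)
  SSC <- n * sum((col_m - grand)^2)          # readers (columns)
  SSE <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  icc <- if (denom <= 0) 1 else (MSR - MSE) / denom
  alpha <- 1 - conf_level
  if (MSE <= .Machine$double.eps * max(abs(ratings), 1)^2) {
    ci <- c(icc, icc); p <- 0
  } else {
    Fv <- MSR / MSE
    p <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lo, hi)
  }
  band <- if (icc <= 0.40) "poor" else if (icc < 0.60) "fair"
          else if (icc < 0.75) "good" else "excellent"
  test_result(statistic = icc, p_value = p, method = "ICC(2,1)",
              extra = list(ci = ci, band = band, n = n, k = k))
}

# DeLong placement values: for each positive the fraction of negatives it
# beats (ties half), and vice versa. scores oriented positive-high.
delong_placements <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  v10 <- vapply(sp, function(s) mean((s > sn) + 0.5 * (s == sn)), 1.0)
  v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), 1.0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("labels must be binary")
  # second level is the positive class (e.g. benign/malignant)
  f == levels(f)[2]
}

#' ROC analysis with Youden cutoff and DeLong confidence interval
#'
#' The AUC is the rank (Mann-Whitney) statistic U/(n1 n0). With
#' `positive_low = "auto"` the score is flipped when low values indicate
#' positivity, so the reported AUC is >= 0.5, with the orientation
#' recorded. The cutoff maximises the Youden index J = sensitivity +
#' specificity - 1 over midpoints between adjacent observed scores, ties
#' broken toward higher specificity. The CI is the DeLong
#' placement-variance normal interval.
#'
#' @param scores Numeric biomarker values.
#' @param labels Binary labels; a logical vector, or a 2-level factor
#'   whose second level is the positive class.
#' @param positive_low `"auto"`, `TRUE` (low score means positive) or
#'   `FALSE`.
#' @param conf_level CI level, default 0.95.
#' @return Object of class `roc_result`: `auc`, `auc_se`, `ci`, `cutoff`
#'   (original score units), `sensitivity` and `specificity` (percent),
#'   `positive_low`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive_low = "auto",
                         conf_level = 0.95) {
  pos <- as_positive(labels)
  if (length(scores) != length(pos)) stop("scores and labels must be paired")
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (identical(positive_low, "auto")) {
    positive_low <- delong_placements(scores, pos)$auc < 0.5
  }
  s <- if (positive_low) -scores else scores
  pl <- delong_placements(s, pos)
  n1 <- sum(pos); n0 <- sum(!pos)
  s10 <- if (n1 > 1) stats::var(pl$v10) else 0
  s01 <- if (n0 > 1) stats::var(pl$v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  half <- stats::qnorm(1 - (1 - conf_level) / 2) * se
  ci <- c(max(0, pl$auc - half), min(1, pl$auc + half))
  # Youden scan over midpoints between adjacent unique oriented scores
  su <- sort(unique(s))
  thr <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  sens <- vapply(thr, function(t) mean(s[pos] > t), 1.0)
  spec <- vapply(thr, function(t) mean(s[!pos] <= t), 1.0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]
  cutoff <- if (positive_low) -thr[best] else thr[best]
  structure(list(auc = pl$auc, auc_se = se, ci = ci, cutoff = cutoff,
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 positive_low = positive_low, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("ROC: AUC = %.3f (95%% CI %.3f-%.3f), cutoff = %.4g",
                     " (%s), sens = %.2f%%, spec = %.2f%%\n"),
              x$auc, x$ci[1], x$ci[2], x$cutoff,
              if (x$positive_low) "low = positive" else "high = positive",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' DeLong test comparing two correlated AUCs
#'
#' Both biomarkers score the same lesions; the AUC difference is tested
#' with the DeLong placement-value covariance estimate and a two-sided
#' z-test. Scores are compared in the positive-high orientation unless
#' `positive_low` is given (applied to both).
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels as in [roc_analysis()].
#' @param positive_low Logical; default FALSE.
#' @return A `test_result` with `statistic` = AUC difference (a - b),
#'   z and both AUCs in the extras.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive_low = FALSE) {
  pos <- as_positive(labels)
  if (length(scores_a) != length(pos) || length(scores_b) != length(pos))
    stop("scores must be paired with the labels")
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (positive_low) { scores_a <- -scores_a; scores_b <- -scores_b }
  pa <- delong_placements(scores_a, pos)
  pb <- delong_placements(scores_b, pos)
  n1 <- sum(pos); n0 <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / n1 + s01 / n0
  vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (vd <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(vd)
  p <- 2 * stats::pnorm(-abs(z))
  test_result(statistic = d, p_value = p, method = "DeLong AUC comparison",
              extra = list(z = z, auc_a = pa$auc, auc_b = pb$auc))
}

#' In-sample AUC of a multivariable logistic combination
#'
#' Standardises the metric columns, fits an additive logistic model by
#' maximum likelihood (IRLS via [stats::glm()]) and runs [roc_analysis()]
#' on the in-sample linear predictor. In-sample discrimination is
#' optimistic; the result carries a `separation` flag when the fit is on
#' the boundary (perfectly separated classes), in which case the AUC is
#' still valid as a ranking statistic of the diverging linear predictor.
#'
#' @param metric_matrix Numeric matrix or data frame, lesions x metrics
#'   (>= 2 columns).
#' @param labels Binary labels as in [roc_analysis()].
#' @return A `roc_result` with extra fields `coefficients` and
#'   `separation`.
#' @export
combined_model_auc <- function(metric_matrix, labels) {
  X <- as.matrix(metric_matrix)
  pos <- as_positive(labels)
  if (nrow(X) != length(pos)) stop("metrics and labels must be paired")
  keep <- apply(X, 2, stats::sd) > 0
  Xs <- scale(X[, keep, drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Xs), as.numeric(pos),
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100)))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0   # aliased (redundant) columns drop out
  lp <- drop(cbind(1, Xs) %*% coefs)
  # near-zero residual deviance marks (quasi-)separation
  separation <- !fit$converged || fit$deviance < 1e-6
  roc <- roc_analysis(lp, pos, positive_low = FALSE)
  roc$coefficients <- fit$coefficients
  roc$separation <- separation
  roc
}
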