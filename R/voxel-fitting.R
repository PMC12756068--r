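# Per-voxel parameter estimation: weighted log-linear ADC fit over the low
# b-range, bounded multi-start Levenberg-Marquardt for the FROC model over
# the full b-range, and volume-wise map generation.

#' Fitting configuration
#'
#' @param mono_b_max Largest b-value (s/mm^2) used by the mono-exponential
#'   fit; default 800.
#' @param froc_b_max Largest b-value used by the FROC fit; default 2000.
#' @param bounds Named list of `c(low, high)` pairs for `D`, `beta`, `mu`
#'   and a multiplier pair for `S0` (relative to the maximum observed
#'   signal). Defaults: D in \[1e-5, 5e-3\] mm^2/s, beta in \[0.2, 1\],
#'   mu in \[5e-4, 2e-2\] mm, S0 in (0, 10 x max signal\].
#' @param n_starts Number of multi-start initialisations (>= 1); the first
#'   is the mono-seeded start, the rest are jittered. Default 3.
#' @param max_iter Maximum optimizer iterations per start.
#' @param tolerance Relative convergence tolerance of the optimizer.
#' @param seed Integer seed for start jitter; makes fits deterministic.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(mono_b_max = 800, froc_b_max = 2000,
                       bounds = list(D = c(1e-5, 5e-3),
                                     beta = c(0.2, 1.0),
                                     mu = c(5e-4, 2e-2),
                                     S0 = c(1e-12, 10)),
                       n_starts = 3L, max_iter = 200L,
                       tolerance = 1e-10, seed = 1L) {
  stopifnot(mono_b_max <= froc_b_max, n_starts >= 1L)
  for (nm in c("D", "beta", "mu", "S0")) {
    bd <- bounds[[nm]]
    if (is.null(bd) || length(bd) != 2L || bd[1] >= bd[2])
      stop("bounds for ", nm, " must be a (low, high) pair with low < high")
  }
  structure(list(mono_b_max = mono_b_max, froc_b_max = froc_b_max,
                 bounds = bounds, n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "fit_config")
}

fit_result <- function(params, residual_norm, converged, n_iter,
                       flags = character()) {
  structure(list(params = params, residual_norm = residual_norm,
                 converged = converged, n_iter = n_iter, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result (", class(x$params)[1], "):\n", sep = "")
  str(unclass(x$params), give.attr = FALSE)
  cat(sprintf("  SSR = %.6g, converged = %s, iterations = %d\n",
              x$residual_norm, x$converged, x$n_iter))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Mono-exponential (ADC) fit of one voxel
#'
#' Weighted log-linear least squares of \eqn{\ln S} against b over
#' b <= `mono_b_max`, with weights proportional to the squared signal (the
#' variance-stabilising choice that makes the log-domain fit equivalent to
#' an unweighted fit in the signal domain to first order). The ADC estimate
#' is clamped at zero.
#'
#' @param signals Numeric signal vector, one value per protocol b-value.
#' @param protocol An [acquisition_protocol()].
#' @param config A [fit_config()].
#' @return A `fit_result` whose `params` is a [mono_params()];
#'   `residual_norm` is the sum of squared residuals in the signal domain
#'   over the b-values used.
#' @export
fit_mono <- function(signals, protocol, config = fit_config()) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  b <- protocol$b_values
  if (length(signals) != length(b))
    stop("signals and protocol b-values differ in length")
  use <- b <= config$mono_b_max & is.finite(signals)
  excluded <- sum(use & signals <= 0)
  use <- use & signals > 0
  if (sum(use) < 3L)
    stop("fewer than 3 usable b-values <= mono_b_max (",
         excluded, " non-positive excluded)")
  bb <- b[use]; ss <- signals[use]
  w <- ss^2
  # weighted least squares of log(S) ~ 1 + b
  X <- cbind(1, bb)
  fitc <- stats::lm.wfit(X, log(ss), w)$coefficients
  adc <- max(0, -fitc[[2]])
  S0 <- exp(fitc[[1]])
  pred <- S0 * exp(-bb * adc)
  flags <- if (excluded > 0) "nonpositive_excluded" else character()
  fit_result(mono_params(S0 = S0, adc = adc),
             residual_norm = sum((ss - pred)^2),
             converged = TRUE, n_iter = 1L, flags = flags)
}

# stage-1 residuals for the LM optimizer; par = (S0, A, beta) in the
# identifiable stretched-exponential form S0 * exp(-A * b^beta)
stretched_residuals <- function(par, b, signals) {
  signals - par[1] * exp(-par[2] * b^par[3])
}

# Decay amplitude A of the stretched-exponential form implied by
# (D, beta, mu) under a protocol: the FROC exponent equals A * b^beta.
froc_amplitude <- function(D, beta, mu, protocol) {
  bfac <- protocol$Delta - protocol$delta / 3
  teff <- protocol$Delta -
    ((2 * beta - 1) / (2 * beta + 1)) * protocol$delta
  D * mu^(2 * (beta - 1)) * teff * bfac^(-beta)
}

#' FROC model fit of one voxel
#'
#' With a single diffusion time (fixed \eqn{\delta}, \eqn{\Delta}; b-value
#' varied through the gradient amplitude) the FROC equation is exactly a
#' stretched exponential \eqn{S = S_0 \exp(-A b^\beta)} whose amplitude
#' \eqn{A = D \mu^{2(\beta-1)} t_{eff}(\beta) (\Delta-\delta/3)^{-\beta}}
#' is the only combination of D and mu the data determine: D and mu are
#' not separately identifiable. The fit therefore proceeds in the two
#' stages conventional for this model family:
#' \enumerate{
#'   \item bounded multi-start Levenberg-Marquardt on the untransformed
#'     signal in the identifiable coordinates \eqn{(S_0, A, \beta)} over
#'     b <= `froc_b_max`; the first start is seeded from [fit_mono()]
#'     with \eqn{\beta} = 0.9, the remaining `n_starts - 1` starts are
#'     deterministic jitters under `config$seed`; lowest residual wins,
#'     ties to the smaller \eqn{\beta};
#'   \item `D` is defined as the weighted log-linear ADC of the
#'     low-b segment (b <= `mono_b_max`, the Gaussian regime) and `mu`
#'     is solved from A in closed form given D and \eqn{\beta}, clamped
#'     to the configured bounds.
#' }
#' When the fitted \eqn{\beta} exceeds 0.98 the exponent
#' \eqn{2(\beta-1)} vanishes and `mu` carries no information; it is then
#' reported at its nominal 5e-3 mm and flagged `"mu_unidentifiable"`.
#'
#' @inheritParams fit_mono
#' @return A `fit_result` whose `params` is a [froc_params()], with the
#'   stage-1 amplitude in `$A`. A voxel on which no start converges is
#'   flagged `"nonconverged"`, not an error; all-equal signals return the
#'   degenerate `beta = 1`, `D` at its lower bound, flagged
#'   `"degenerate"`. Clamped stage-2 estimates are flagged
#'   `"d_at_bound"` / `"mu_at_bound"`.
#' @export
fit_froc <- function(signals, protocol, config = fit_config()) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  b <- protocol$b_values
  if (length(signals) != length(b))
    stop("signals and protocol b-values differ in length")
  use <- b <= config$froc_b_max & is.finite(signals) & signals > 0
  bu <- b[use]; su <- signals[use]
  if (length(unique(bu)) < 5L || !any(bu == 0) ||
      !any(bu > config$mono_b_max))
    stop("FROC fit needs >= 5 distinct b-values including b = 0 and one ",
         "above mono_b_max")
  bd <- config$bounds

  if (diff(range(su)) < .Machine$double.eps * max(su) * 8) {
    res <- fit_result(
      froc_params(S0 = su[1], D = bd$D[1], beta = 1, mu = 5e-3),
      residual_norm = sum((su - su[1])^2), converged = FALSE, n_iter = 0L,
      flags = c("degenerate", "mu_unidentifiable"))
    res$A <- 0
    return(res)
  }

  mono <- tryCatch(fit_mono(signals, protocol, config),
                   error = function(e) NULL)
  s0_seed <- if (is.null(mono)) max(su) else mono$params$S0
  adc_seed <- max(if (is.null(mono)) 1e-3 else mono$params$adc, 1e-5)
  lower <- c(S0 = bd$S0[1], A = 1e-9, beta = bd$beta[1])
  upper <- c(S0 = bd$S0[2] * max(su), A = 10, beta = bd$beta[2])
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  bref <- max(bu[bu <= config$mono_b_max])
  # seed A so the exponent at bref matches the mono fit: A bref^0.9 = adc bref
  start1 <- c(S0 = clamp(s0_seed, lower[[1]] * 1.01, upper[[1]] * 0.99),
              A = clamp(adc_seed * bref^0.1, 1e-8, 1), beta = 0.9)
  starts <- list(start1)
  if (config$n_starts > 1L) {
    jit <- local({
      set.seed(config$seed)
      lapply(seq_len(config$n_starts - 1L), function(i) stats::runif(3))
    })
    for (u in jit)
      starts[[length(starts) + 1L]] <- c(
        S0 = start1[["S0"]] * exp(0.2 * (u[1] - 0.5)),
        A = clamp(start1[["A"]] * exp(2 * (u[2] - 0.5)), 1e-8, 1),
        beta = bd$beta[1] + u[3] * (bd$beta[2] - bd$beta[1]))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper,
        fn = stretched_residuals, b = bu, signals = su,
        control = minpack.lm::nls.lm.control(
          maxiter = config$max_iter, ftol = config$tolerance,
          ptol = config$tolerance)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(par = fit$par, ssr = fit$deviance,
                 conv = fit$info %in% 1:4, niter = fit$niter)
    if (is.null(best)) { best <- cand; next }
    if (cand$conv && !best$conv) { best <- cand; next }
    if (cand$conv == best$conv) {
      rel <- (best$ssr - cand$ssr) / max(best$ssr, .Machine$double.eps)
      if (rel > 1e-6 ||
          (abs(rel) <= 1e-6 && cand$par[["beta"]] < best$par[["beta"]]))
        best <- cand
    }
  }
  if (is.null(best)) stop("optimizer failed to evaluate any start")

  S0 <- best$par[["S0"]]; A <- best$par[["A"]]; beta <- best$par[["beta"]]
  flags <- character()
  if (!best$conv) flags <- c(flags, "nonconverged")
  D <- clamp(adc_seed, bd$D[1], bd$D[2])
  if (D != adc_seed) flags <- c(flags, "d_at_bound")
  if (beta > 0.98) {
    # exponent 2(beta-1) ~ 0: A pins D directly, mu is pure convention
    mu <- 5e-3
    flags <- c(flags, "mu_unidentifiable")
    D2 <- A * (protocol$Delta - protocol$delta / 3)^beta /
      ((protocol$Delta -
          ((2 * beta - 1) / (2 * beta + 1)) * protocol$delta) *
         mu^(2 * (beta - 1)))
    D <- clamp(D2, bd$D[1], bd$D[2])
  } else {
    bfac <- protocol$Delta - protocol$delta / 3
    teff <- protocol$Delta -
      ((2 * beta - 1) / (2 * beta + 1)) * protocol$delta
    mu_raw <- (A * bfac^beta / (D * teff))^(1 / (2 * (beta - 1)))
    mu <- clamp(mu_raw, bd$mu[1], bd$mu[2])
    if (!is.finite(mu)) { mu <- 5e-3; flags <- c(flags, "mu_at_bound") }
    else if (mu != mu_raw) flags <- c(flags, "mu_at_bound")
  }
  pred <- S0 * exp(-A * bu^beta)
  res <- fit_result(
    froc_params(S0 = S0, D = D, beta = beta, mu = mu),
    residual_norm = sum((su - pred)^2), converged = best$conv,
    n_iter = best$niter, flags = flags)
  res$A <- A
  res
}

#' Fit a 4D volume voxel-by-voxel into parameter maps
#'
#' @param dwi 4D numeric array (x, y, z, frame) of diffusion-weighted
#'   signal; frames follow the protocol's b-value order.
#' @param mask 3D logical array on the same grid selecting voxels to fit.
#' @param protocol An [acquisition_protocol()].
#' @param config A [fit_config()].
#' @param model `"mono"` or `"froc"`.
#' @return An object of class `parameter_maps`: a list with `model`, a
#'   named list `maps` of 3D arrays (`S0` plus `adc`, or `D`/`beta`/`mu`),
#'   a `quality` map of per-voxel residual sums of squares, logical arrays
#'   `fitted`, `converged` and `mu_unidentifiable`, and the input `mask`.
#'   Voxels outside the mask, and voxels whose fit errored, are `NA` in
#'   every map and `FALSE` in `fitted`.
#' @export
fit_volume <- function(dwi, mask, protocol, config = fit_config(),
                       model = c("froc", "mono")) {
  model <- match.arg(model)
  stopifnot(length(dim(dwi)) == 4L, length(dim(mask)) == 3L,
            all(dim(dwi)[1:3] == dim(mask)))
  if (dim(dwi)[4] != length(protocol$b_values))
    stop("4th dimension of dwi must match the protocol's b-values")
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  grid <- dim(mask)
  nvox <- prod(grid)
  par_names <- if (model == "mono") c("S0", "adc") else
    c("S0", "D", "beta", "mu")
  maps <- stats::setNames(
    replicate(length(par_names), array(NA_real_, grid), simplify = FALSE),
    par_names)
  quality <- array(NA_real_, grid)
  fitted <- array(FALSE, grid)
  converged <- array(FALSE, grid)
  mu_unid <- array(FALSE, grid)
  sig_mat <- matrix(dwi, nrow = nvox)[idx, , drop = FALSE]
  for (k in seq_along(idx)) {
    res <- tryCatch({
      if (model == "mono") fit_mono(sig_mat[k, ], protocol, config)
      else fit_froc(sig_mat[k, ], protocol, config)
    }, error = function(e) NULL)
    if (is.null(res)) next
    v <- idx[k]
    for (nm in par_names) maps[[nm]][v] <- res$params[[nm]]
    quality[v] <- res$residual_norm
    fitted[v] <- TRUE
    converged[v] <- res$converged
    mu_unid[v] <- "mu_unidentifiable" %in% res$flags
  }
  structure(list(model = model, maps = maps, quality = quality,
                 fitted = fitted, converged = converged,
                 mu_unidentifiable = mu_unid, mask = mask,
                 config = config),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("Parameter maps (%s model), grid %s\n", x$model,
              paste(dim(x$mask), collapse = "x")))
  cat(sprintf("  %d masked voxels, %d fitted, %d converged\n",
              sum(x$mask), sum(x$fitted), sum(x$converged)))
  invisible(x)
}
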