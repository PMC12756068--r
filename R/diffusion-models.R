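# Forward signal models: the fractional-order-calculus (FROC) equation and
# the mono-exponential ADC model. Pure functions of (params, protocol).

#' FROC model parameters
#'
#' Per-voxel parameters of the fractional-order-calculus diffusion model:
#' `S0` (signal without diffusion weighting, arbitrary units), `D`
#' (diffusion coefficient, mm^2/s), `beta` (spatial fractional order,
#' dimensionless, 0 < beta <= 1) and `mu` (spatial constant, mm). `beta`
#' indexes intravoxel diffusion heterogeneity (1 = Gaussian,
#' mono-exponential limit); `mu` is a length scale that only enters the
#' signal when beta < 1.
#'
#' @param S0 Non-diffusion-weighted signal, > 0.
#' @param D Diffusion coefficient, mm^2/s, > 0.
#' @param beta Spatial fractional order in (0, 1].
#' @param mu Spatial constant, mm, > 0.
#' @return Object of class `froc_params`.
#' @export
froc_params <- function(S0, D, beta, mu) {
  stopifnot(is.numeric(S0), is.numeric(D), is.numeric(beta), is.numeric(mu))
  if (S0 <= 0) stop("S0 must be positive")
  if (D <= 0) stop("D must be positive")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  if (mu <= 0) stop("mu must be positive")
  structure(list(S0 = S0, D = D, beta = beta, mu = mu),
            class = "froc_params")
}

#' Mono-exponential model parameters
#'
#' @param S0 Non-diffusion-weighted signal, > 0.
#' @param adc Apparent diffusion coefficient, mm^2/s, >= 0.
#' @return Object of class `mono_params`.
#' @export
mono_params <- function(S0, adc) {
  stopifnot(is.numeric(S0), is.numeric(adc))
  if (S0 <= 0) stop("S0 must be positive")
  if (adc < 0) stop("adc must be non-negative")
  structure(list(S0 = S0, adc = adc), class = "mono_params")
}

# Dimensionless FROC decay exponent for b-values under a protocol.
# Split out so the fitter can call it without constructing param objects.
froc_exponent <- function(D, beta, mu, b, protocol) {
  Gd <- gradient_amplitude_for_b(b, protocol)
  gGd <- protocol$gamma * Gd * protocol$delta        # mm^-1
  teff <- protocol$Delta -
    ((2 * beta - 1) / (2 * beta + 1)) * protocol$delta
  D * mu^(2 * (beta - 1)) * gGd^(2 * beta) * teff
}

#' FROC diffusion signal
#'
#' Evaluates the fractional-order-calculus signal equation
#' \deqn{S(b) = S_0 \exp[-D\,\mu^{2(\beta-1)}\,(\gamma G_d \delta)^{2\beta}
#'   (\Delta - \frac{2\beta-1}{2\beta+1}\delta)]}
#' with \eqn{G_d} obtained from each b-value via
#' [gradient_amplitude_for_b()]. At \eqn{\beta = 1} the exponent collapses
#' to \eqn{bD} and the model reduces exactly to the mono-exponential.
#'
#' @param params A [froc_params()].
#' @param protocol An [acquisition_protocol()]; signals are returned for
#'   its `b_values`.
#' @return Numeric vector of signals, one per b-value; `S(0) = S0`.
#' @export
froc_signal <- function(params, protocol) {
  stopifnot(inherits(params, "froc_params"),
            inherits(protocol, "acquisition_protocol"))
  with(params,
       S0 * exp(-froc_exponent(D, beta, mu, protocol$b_values, protocol)))
}

#' Mono-exponential diffusion signal
#'
#' \eqn{S(b) = S_0 \exp(-b \cdot ADC)}.
#'
#' @param params A [mono_params()].
#' @param b_values Numeric b-values, s/mm^2.
#' @return Numeric vector of signals, one per b-value.
#' @export
mono_signal <- function(params, b_values) {
  stopifnot(inherits(params, "mono_params"))
  if (any(b_values < 0)) stop("b must be non-negative")
  params$S0 * exp(-b_values * params$adc)
}
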