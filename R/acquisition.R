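# Multi-b acquisition: b-values plus diffusion timing, and the b <-> gradient
# amplitude conversion the FROC signal equation needs.

#' Gyromagnetic ratio of the proton
#'
#' Default gamma used throughout, in rad s^-1 T^-1.
#' @export
GAMMA_1H <- 2.675222e8

#' Define a multi-b diffusion acquisition protocol
#'
#' Bundles the b-values of a diffusion-weighted series with the gradient
#' timing parameters needed to convert b-values into gradient amplitudes
#' under the rectangular-pulse Stejskal-Tanner relation
#' \eqn{b = (\gamma G \delta)^2 (\Delta - \delta/3)}.
#'
#' Units are fixed as: b in s/mm^2, `delta`/`Delta` in s, `gamma` in
#' rad s^-1 T^-1, so that gradient amplitudes come out in T/mm and
#' \eqn{\gamma G \delta} in mm^-1. This makes the FROC exponent
#' dimensionless by construction.
#'
#' @param b_values Numeric vector of b-values (s/mm^2), frame order.
#'   Repeated b-values (averaged frames) are allowed; the deduplicated set
#'   must be non-negative.
#' @param delta Diffusion gradient pulse width \eqn{\delta} in seconds.
#' @param Delta Gradient lobe separation \eqn{\Delta} in seconds; must
#'   exceed `delta`.
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1), default [GAMMA_1H].
#' @return An object of class `acquisition_protocol` with elements
#'   `b_values`, `delta`, `Delta`, `gamma`.
#' @examples
#' acquisition_protocol(c(0, 50, 100, 200, 400, 800, 1200, 2000),
#'                      delta = 19.3e-3, Delta = 40.0e-3)
#' @export
acquisition_protocol <- function(b_values, delta, Delta, gamma = GAMMA_1H) {
  stopifnot(is.numeric(b_values), length(b_values) >= 1L,
            is.numeric(delta), length(delta) == 1L,
            is.numeric(Delta), length(Delta) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (any(!is.finite(b_values)) || any(b_values < 0))
    stop("b-values must be finite and non-negative")
  if (!(delta > 0 && delta < Delta))
    stop("timing must satisfy 0 < delta < Delta")
  if (gamma <= 0) stop("gamma must be positive")
  structure(
    list(b_values = as.numeric(b_values),
         delta = as.numeric(delta), Delta = as.numeric(Delta),
         gamma = as.numeric(gamma)),
    class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("Multi-b acquisition protocol\n")
  cat("  b-values (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  cat(sprintf("  delta = %.4g ms, Delta = %.4g ms, gamma = %.6g rad/s/T\n",
              1e3 * x$delta, 1e3 * x$Delta, x$gamma))
  invisible(x)
}

#' Gradient amplitude for a given b-value
#'
#' Inverts the rectangular-pulse Stejskal-Tanner relation
#' \eqn{b = (\gamma G_d \delta)^2 (\Delta - \delta/3)} for the diffusion
#' gradient amplitude \eqn{G_d}.
#'
#' @param b b-value(s), s/mm^2, non-negative.
#' @param protocol An [acquisition_protocol()].
#' @return Gradient amplitude(s) in T/mm, same length as `b`.
#' @seealso [b_for_gradient_amplitude()] for the forward relation.
#' @export
gradient_amplitude_for_b <- function(b, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (any(!is.finite(b)) || any(b < 0))
    stop("b must be finite and non-negative")
  with(protocol, sqrt(b / (Delta - delta / 3)) / (gamma * delta))
}

#' b-value implied by a gradient amplitude
#'
#' Forward rectangular-pulse Stejskal-Tanner relation; the algebraic
#' inverse of [gradient_amplitude_for_b()].
#'
#' @param G_d Gradient amplitude(s), T/mm, non-negative.
#' @inheritParams gradient_amplitude_for_b
#' @return b-value(s) in s/mm^2.
#' @export
b_for_gradient_amplitude <- function(G_d, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (any(!is.finite(G_d)) || any(G_d < 0))
    stop("G_d must be finite and non-negative")
  with(protocol, (gamma * G_d * delta)^2 * (Delta - delta / 3))
}

#' Read an FSL-style .bval sidecar into a protocol
#'
#' @param bval_path Path to a plain-text file of whitespace-separated
#'   b-values, one per 4D frame.
#' @param delta,Delta,gamma Timing configuration, as in
#'   [acquisition_protocol()].
#' @param n_frames Optional expected frame count; a mismatch with the file
#'   is an error.
#' @return An [acquisition_protocol()] with b-values in frame order.
#' @export
read_protocol <- function(bval_path, delta, Delta, gamma = GAMMA_1H,
                          n_frames = NULL) {
  if (!file.exists(bval_path)) stop("bval sidecar not found: ", bval_path)
  tokens <- scan(bval_path, what = character(), quiet = TRUE)
  if (length(tokens) == 0L) stop("bval sidecar is empty: ", bval_path)
  b <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(b)))
    stop("non-numeric token in bval sidecar: ",
         paste(tokens[is.na(b)], collapse = ", "))
  if (!is.null(n_frames) && length(b) != n_frames)
    stop(sprintf("bval sidecar has %d entries but the volume has %d frames",
                 length(b), n_frames))
  acquisition_protocol(b, delta = delta, Delta = Delta, gamma = gamma)
}

#' Write a .bval sidecar
#' @param b_values Numeric b-values in frame order.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bval <- function(b_values, path) {
  writeLines(paste(format(b_values, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' The multi-b breast protocol used throughout the examples
#'
#' Eight b-values 0-2000 s/mm^2 with delta = 19.3 ms and Delta = 40.0 ms.
#' @return An [acquisition_protocol()].
#' @export
default_breast_protocol <- function() {
  acquisition_protocol(c(0, 50, 100, 200, 400, 800, 1200, 2000),
                       delta = 19.3e-3, Delta = 40.0e-3)
}
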