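# Whole-lesion first-order histogram features: 10th/90th percentiles,
# mean, median, entropy, kurtosis, skewness over the ROI voxel values of
# each parameter map.

#' First-order histogram metrics of a value list
#'
#' Percentiles use linear interpolation (`quantile` type 7). Skewness and
#' kurtosis use population (biased) central moments, \eqn{m_3/m_2^{3/2}}
#' and the non-excess (Pearson) \eqn{m_4/m_2^2}, so a Gaussian sits at
#' skewness 0 and kurtosis 3. Entropy is Shannon entropy in bits over
#' `n_bins` equal-width bins spanning the sample's own \[min, max\]
#' (empty bins contribute nothing), which makes all seven metrics either
#' affine-equivariant or affine-invariant. A constant sample returns
#' skewness 0, kurtosis 0 and entropy 0 by convention.
#'
#' @param values Numeric vector; non-finite entries are dropped with a
#'   warning, an all-non-finite input is an error.
#' @param n_bins Number of entropy bins; default 100.
#' @return Object of class `histogram_metrics`: a named list with `p10`,
#'   `p90`, `mean`, `median`, `entropy`, `kurtosis`, `skewness`,
#'   `n_voxels`, `n_bins`.
#' @export
compute_histogram_metrics <- function(values, n_bins = 100L) {
  x <- as.numeric(values)
  if (length(x) == 0L) stop("empty value list")
  if (any(!is.finite(x))) {
    warning(sum(!is.finite(x)), " non-finite values excluded")
    x <- x[is.finite(x)]
    if (length(x) == 0L) stop("all values non-finite")
  }
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
  } else {
    skew <- 0; kurt <- 0
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    entropy <- 0
  } else {
    bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L,
                n_bins)
    p <- tabulate(bin, nbins = n_bins) / n
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
  }
  q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  structure(list(p10 = q[1], p90 = q[3], mean = m, median = q[2],
                 entropy = entropy, kurtosis = kurt, skewness = skew,
                 n_voxels = n, n_bins = as.integer(n_bins)),
            class = "histogram_metrics")
}

#' @export
print.histogram_metrics <- function(x, ...) {
  cat(sprintf(paste0("Histogram metrics (n = %d): p10 = %.4g, ",
                     "median = %.4g, mean = %.4g, p90 = %.4g\n",
                     "  entropy = %.4g bits (%d bins), kurtosis = %.4g, ",
                     "skewness = %.4g\n"),
              x$n_voxels, x$p10, x$median, x$mean, x$p90, x$entropy,
              x$n_bins, x$kurtosis, x$skewness))
  invisible(x)
}

# Reporting-scale factors: diffusivities print as 1e-6 mm^2/s; beta as
# 1e-3; mu (internal unit mm) as 1e-3 micrometres, the scale the
# clinical tables print (6.5e-3 mm = 6.5 um -> 6500).
reporting_scale <- function(parameter) {
  switch(parameter,
         adc = 1e6, D = 1e6,
         beta = 1e3, mu = 1e6,
         S0 = 1,
         stop("unknown parameter: ", parameter))
}

#' Histogram features of every parameter map inside a lesion ROI
#'
#' Extracts the whole-lesion values of each fitted map via
#' [copy_roi_to_maps()] (mu-unidentifiable voxels excluded from mu) and
#' computes [compute_histogram_metrics()] per parameter, converted to the
#' clinical reporting scale: ADC and D in 1e-6 mm^2/s, beta and mu in
#' 1e-3 units. The affine scale change only affects the location metrics;
#' entropy, kurtosis and skewness are scale-invariant.
#'
#' @param maps A `parameter_maps` object from [fit_volume()].
#' @param roi3d A 3D [roi_mask()] on the same grid.
#' @param lesion_id Identifier written into the output rows.
#' @param n_bins Entropy bins, passed through.
#' @return A long-format data frame with one row per parameter x metric:
#'   columns `lesion_id`, `model`, `parameter`, `metric`, `value`,
#'   `n_voxels`. `S0` is bookkeeping, not a biomarker, and is omitted.
#' @export
features_for_lesion <- function(maps, roi3d, lesion_id = "lesion",
                                n_bins = 100L) {
  ext <- copy_roi_to_maps(roi3d, maps)
  pars <- setdiff(names(ext$values), "S0")
  rows <- lapply(pars, function(nm) {
    vals <- ext$values[[nm]] * reporting_scale(nm)
    if (length(vals) == 0L)
      stop("no usable voxels for parameter ", nm)
    hm <- compute_histogram_metrics(vals, n_bins = n_bins)
    data.frame(lesion_id = lesion_id, model = maps$model, parameter = nm,
               metric = c("p10", "p90", "mean", "median", "entropy",
                          "kurtosis", "skewness"),
               value = c(hm$p10, hm$p90, hm$mean, hm$median, hm$entropy,
                         hm$kurtosis, hm$skewness),
               n_voxels = hm$n_voxels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
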