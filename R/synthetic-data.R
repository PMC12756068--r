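# Synthetic data: (a) voxel-level multi-b DWI phantoms with known FROC
# ground truth and Rician noise at realistic SNR, (b) lesion-level
# cohorts with the group structure of the reference breast cohort. These
# define the study conditions every pipeline stage is tested under.

#' Add Rician noise to magnitude signals
#'
#' Magnitude-MRI noise model: the output is
#' \eqn{\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}} with independent
#' zero-mean Gaussian channel noise of SD `sigma`.
#'
#' @param signal Numeric vector/array of noise-free magnitudes.
#' @param sigma Channel noise SD, >= 0. Zero returns the input unchanged.
#' @param seed Optional integer seed for reproducibility.
#' @return Noisy magnitudes, same shape as `signal`.
#' @export
rician_noise <- function(signal, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

# Smooth standard-normal random field: white noise circularly convolved
# with a Gaussian kernel (FFT), re-standardised to zero mean / unit SD.
# corr_length <= 0 returns plain white noise.
gaussian_random_field <- function(grid, corr_length) {
  z <- array(stats::rnorm(prod(grid)), grid)
  if (corr_length <= 0) return(z)
  kerns <- lapply(grid, function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- exp(-0.5 * (d / corr_length)^2)
    k / sum(k)
  })
  kern <- outer(outer(kerns[[1]], kerns[[2]]), kerns[[3]])
  dim(kern) <- grid
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
    prod(grid)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Phantom specification
#'
#' Describes a rectangular DWI phantom containing one ellipsoidal lesion
#' in a uniform-statistics background. Each FROC parameter is a smooth
#' Gaussian random field (mean + SD x correlated field) clipped to the
#' model bounds, separately for lesion and background. Defaults emulate a
#' malignant breast lesion (low diffusivity, beta well below 1, so the
#' lesion is hyperintense on the high-b frames) against fibroglandular
#' background, with the malignant-lesion SNR of 119.56 at b = 2000
#' s/mm^2.
#'
#' @param grid Integer 3-vector of volume dimensions.
#' @param center,semiaxes Ellipsoid centre and semi-axes (voxels).
#' @param lesion,background Named lists with elements `S0`, `D`, `beta`,
#'   `mu`, each a `c(mean, sd)` pair (internal units: mm^2/s for D, mm
#'   for mu).
#' @param corr_length Spatial correlation length of the parameter fields,
#'   voxels.
#' @param snr_b2000 Target SNR (mean lesion signal at the highest b-value
#'   over the Gaussian channel sigma).
#' @param seed Integer seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64, 64, 16),
                         center = c(32, 32, 8),
                         semiaxes = c(10, 8, 4),
                         lesion = list(S0 = c(1000, 50),
                                       D = c(9.3e-4, 1.0e-4),
                                       beta = c(0.78, 0.04),
                                       mu = c(6.5e-3, 5e-4)),
                         background = list(S0 = c(800, 40),
                                           D = c(1.6e-3, 1.5e-4),
                                           beta = c(0.92, 0.03),
                                           mu = c(8.0e-3, 6e-4)),
                         corr_length = 2, snr_b2000 = 119.56,
                         seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid >= 4),
            all(center - semiaxes >= 1), all(center + semiaxes <= grid),
            snr_b2000 > 0, corr_length >= 0)
  for (side in list(lesion, background))
    for (nm in c("S0", "D", "beta", "mu")) {
      v <- side[[nm]]
      if (is.null(v) || length(v) != 2L || v[2] < 0)
        stop("parameter ", nm, " must be a c(mean, sd) pair with sd >= 0")
    }
  structure(list(grid = as.integer(grid), center = center,
                 semiaxes = semiaxes, lesion = lesion,
                 background = background, corr_length = corr_length,
                 snr_b2000 = snr_b2000, seed = as.integer(seed)),
            class = "phantom_spec")
}

# model bounds used for clipping sampled parameter fields
.param_clip <- list(S0 = c(1e-6, Inf), D = c(1e-5, 5e-3),
                    beta = c(0.2, 1.0), mu = c(5e-4, 2e-2))

#' Generate a multi-b DWI phantom with known FROC ground truth
#'
#' Samples smooth heterogeneous parameter fields for lesion and
#' background, evaluates the FROC signal at every protocol b-value, and
#' adds Rician noise with the channel sigma set so that the mean lesion
#' signal on the highest-b frame divided by sigma equals
#' `spec$snr_b2000`. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param protocol An [acquisition_protocol()].
#' @return List with `dwi` (4D noisy array), `dwi_clean` (noise-free),
#'   `truth` (named list of 3D parameter arrays `S0`, `D`, `beta`, `mu`),
#'   `roi` (true lesion [roi_mask()]), `sigma` (channel noise SD),
#'   `protocol`, `n_clipped` (per-parameter clip counts), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(),
                         protocol = default_breast_protocol()) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(protocol, "acquisition_protocol"))
  set.seed(spec$seed)
  grid <- spec$grid
  ax <- sweep(arrayInd(seq_len(prod(grid)), grid), 2, spec$center)
  inside <- rowSums(sweep(ax, 2, spec$semiaxes, "/")^2) <= 1
  lesion_mask <- array(inside, grid)

  truth <- list()
  n_clipped <- c(S0 = 0L, D = 0L, beta = 0L, mu = 0L)
  for (nm in c("S0", "D", "beta", "mu")) {
    field <- gaussian_random_field(grid, spec$corr_length)
    vals <- ifelse(lesion_mask,
                   spec$lesion[[nm]][1] + spec$lesion[[nm]][2] * field,
                   spec$background[[nm]][1] +
                     spec$background[[nm]][2] * field)
    cl <- .param_clip[[nm]]
    n_clipped[nm] <- sum(vals < cl[1] | vals > cl[2])
    truth[[nm]] <- array(pmin(pmax(vals, cl[1]), cl[2]), grid)
  }
  if (sum(n_clipped) > 0)
    warning("clipped ", sum(n_clipped),
            " sampled parameter values to the model bounds")

  b <- protocol$b_values
  dwi_clean <- array(0, c(grid, length(b)))
  gGd <- protocol$gamma * gradient_amplitude_for_b(b, protocol) *
    protocol$delta
  teff <- protocol$Delta -
    ((2 * truth$beta - 1) / (2 * truth$beta + 1)) * protocol$delta
  pre <- truth$D * truth$mu^(2 * (truth$beta - 1)) * teff
  for (i in seq_along(b))
    dwi_clean[, , , i] <- truth$S0 * exp(-pre * gGd[i]^(2 * truth$beta))

  i2000 <- which.max(b)
  sigma <- mean(dwi_clean[, , , i2000][lesion_mask]) / spec$snr_b2000
  dwi <- rician_noise(dwi_clean, sigma)

  list(dwi = dwi, dwi_clean = dwi_clean, truth = truth,
       roi = roi_mask(lesion_mask, "3d"), sigma = sigma,
       protocol = protocol, n_clipped = n_clipped, spec = spec)
}

#' Cohort specification
#'
#' Distributional blueprint for a synthetic benign/malignant lesion
#' cohort: per-metric Gaussian marginals for each group (defaults: the
#' reference-cohort group means and SDs of
#' [benign_malignant_reference()]), prognostic-label prevalences among
#' cancers ([prognostic_prevalences()]), label-conditional additive mean
#' shifts ([label_shift_reference()]), a single exchangeable inter-metric
#' correlation, and a second-reader noise fraction for reproducibility
#' fixtures.
#'
#' @param n_benign,n_malignant Group sizes; defaults 50 and 109.
#' @param reference Data frame in the shape of
#'   [benign_malignant_reference()].
#' @param prevalences As [prognostic_prevalences()].
#' @param label_shifts Data frame in the shape of
#'   [label_shift_reference()]; use a 0-row frame for none.
#' @param rho Exchangeable inter-metric correlation in \[0, 1); default
#'   0.5.
#' @param reader_sd_frac Second-reader noise SD as a fraction of each
#'   metric's group SD; default 1/3 (ICC around 0.9).
#' @param reader2_metrics Character vector of `parameter_metric` column
#'   names duplicated as a second-reader measurement.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 50L, n_malignant = 109L,
                        reference = benign_malignant_reference(),
                        prevalences = prognostic_prevalences(),
                        label_shifts = label_shift_reference(),
                        rho = 0.5, reader_sd_frac = 1 / 3,
                        reader2_metrics = c("adc_median", "D_mean",
                                            "beta_median", "mu_median"),
                        seed = 1L) {
  stopifnot(n_benign >= 1L, n_malignant >= 1L, rho >= 0, rho < 1,
            reader_sd_frac >= 0,
            all(reference$benign_sd >= 0),
            all(reference$malignant_sd >= 0))
  pr <- unlist(prevalences[c("ER", "PR", "HER2", "Ki67", "ALN")])
  stopifnot(all(pr >= 0 & pr <= 1),
            abs(sum(prevalences$subtype) - 1) < 1e-6)
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 reference = reference, prevalences = prevalences,
                 label_shifts = label_shifts, rho = rho,
                 reader_sd_frac = reader_sd_frac,
                 reader2_metrics = reader2_metrics,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# correlated Gaussian draws: n x p with given means/SDs and exchangeable
# correlation rho
draw_group <- function(n, means, sds, rho) {
  p <- length(means)
  R <- matrix(rho, p, p); diag(R) <- 1
  Sigma <- R * tcrossprod(sds)
  # zero-SD metrics degenerate to their mean; mvrnorm handles the psd case
  X <- MASS::mvrnorm(n, mu = means, Sigma = Sigma)
  if (n == 1L) X <- matrix(X, nrow = 1)
  X
}

#' Generate a synthetic lesion cohort table
#'
#' Draws per-lesion histogram metrics from correlated multivariate
#' normals with the specified group marginals, assigns prognostic labels
#' by prevalence among the malignant lesions, applies the
#' label-conditional mean shifts, and appends second-reader duplicates
#' (value + Gaussian noise) for the configured metrics. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of class `cohort_table`: `lesion_id`, `malignancy`
#'   (factor benign/malignant), `ER`/`PR`/`HER2`/`Ki67`/`ALN` (factor
#'   negative/positive, NA for benign), `subtype` (factor, NA for
#'   benign), one numeric column per `parameter_metric`, plus
#'   `<metric>_reader2` columns.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ref <- spec$reference
  cols <- paste(ref$parameter, ref$metric, sep = "_")
  nb <- spec$n_benign; nm <- spec$n_malignant

  Xb <- draw_group(nb, ref$benign_mean, ref$benign_sd, spec$rho)
  Xm <- draw_group(nm, ref$malignant_mean, ref$malignant_sd, spec$rho)
  colnames(Xb) <- colnames(Xm) <- cols

  pv <- spec$prevalences
  lab <- data.frame(
    ER = stats::rbinom(nm, 1, pv$ER),
    PR = stats::rbinom(nm, 1, pv$PR),
    HER2 = stats::rbinom(nm, 1, pv$HER2),
    Ki67 = stats::rbinom(nm, 1, pv$Ki67),
    ALN = stats::rbinom(nm, 1, pv$ALN))
  subtype <- sample(names(pv$subtype), nm, replace = TRUE,
                    prob = pv$subtype)

  sh <- spec$label_shifts
  if (!is.null(sh) && nrow(sh) > 0) {
    for (i in seq_len(nrow(sh))) {
      col <- paste(sh$parameter[i], sh$metric[i], sep = "_")
      if (!col %in% cols) next
      prev <- pv[[sh$label[i]]]
      overall <- prev * sh$positive_mean[i] +
        (1 - prev) * sh$negative_mean[i]
      delta <- ifelse(lab[[sh$label[i]]] == 1,
                      sh$positive_mean[i] - overall,
                      sh$negative_mean[i] - overall)
      Xm[, col] <- Xm[, col] + delta
    }
  }

  tab <- data.frame(
    lesion_id = sprintf("L%03d", seq_len(nb + nm)),
    malignancy = factor(rep(c("benign", "malignant"), c(nb, nm)),
                        levels = c("benign", "malignant")),
    stringsAsFactors = FALSE)
  to_factor <- function(x01)
    factor(ifelse(x01 == 1, "positive", "negative"),
           levels = c("negative", "positive"))
  for (nm2 in c("ER", "PR", "HER2", "Ki67", "ALN"))
    tab[[nm2]] <- factor(c(rep(NA, nb),
                           as.character(to_factor(lab[[nm2]]))),
                         levels = c("negative", "positive"))
  tab$subtype <- factor(c(rep(NA, nb), subtype),
                        levels = names(pv$subtype))
  X <- rbind(Xb, Xm)
  for (j in seq_along(cols)) tab[[cols[j]]] <- X[, j]

  pooled_sd <- apply(X, 2, stats::sd)
  for (m2 in intersect(spec$reader2_metrics, cols))
    tab[[paste0(m2, "_reader2")]] <- tab[[m2]] +
      stats::rnorm(nb + nm, 0, spec$reader_sd_frac * pooled_sd[m2])

  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Read / write a cohort table as CSV
#'
#' @param tab A `cohort_table` (for writing).
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   a `cohort_table` with the label columns re-levelled.
#' @export
write_cohort <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$malignancy <- factor(tab$malignancy,
                           levels = c("benign", "malignant"))
  for (nm in intersect(c("ER", "PR", "HER2", "Ki67", "ALN"), names(tab)))
    tab[[nm]] <- factor(tab[[nm]], levels = c("negative", "positive"))
  if ("subtype" %in% names(tab))
    tab$subtype <- factor(tab$subtype,
                          levels = c("luminal", "her2_positive",
                                     "triple_negative"))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
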