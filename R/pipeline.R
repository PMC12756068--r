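# End-to-end pipeline drivers and file I/O: NIfTI volumes and maps,
# cohort-level report tables, and the fully synthetic phantom pipeline
# (phantom -> fit -> segment -> features).

#' Write / read a 4D DWI volume as NIfTI with a .bval sidecar
#'
#' @param dwi 4D array.
#' @param protocol An [acquisition_protocol()]; its b-values go to the
#'   sidecar.
#' @param path Output path (`.nii` / `.nii.gz`); the sidecar replaces the
#'   extension with `.bval`.
#' @return `path`, invisibly.
#' @export
write_dwi <- function(dwi, protocol, path) {
  stopifnot(length(dim(dwi)) == 4L,
            dim(dwi)[4] == length(protocol$b_values))
  RNifti::writeNifti(dwi, path)
  write_bval(protocol$b_values,
             sub("\\.nii(\\.gz)?$", ".bval", path))
  invisible(path)
}

#' @rdname write_dwi
#' @param delta,Delta,gamma Timing configuration for the protocol.
#' @return `read_dwi` returns a list with `dwi` (4D array) and
#'   `protocol`.
#' @export
read_dwi <- function(path, delta, Delta, gamma = GAMMA_1H) {
  img <- RNifti::readNifti(path)
  dwi <- array(as.numeric(img), dim(img))
  protocol <- read_protocol(sub("\\.nii(\\.gz)?$", ".bval", path),
                            delta = delta, Delta = Delta, gamma = gamma,
                            n_frames = dim(dwi)[4])
  list(dwi = dwi, protocol = protocol)
}

#' Write fitted parameter maps as one NIfTI per parameter
#'
#' Non-fitted voxels are written as NA; a 0/1 mask of fitted voxels and
#' the residual-norm quality map are written alongside.
#'
#' @param maps A `parameter_maps` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; default the model name.
#' @return Named character vector of the files written, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, prefix = maps$model) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(maps$maps)) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(maps$maps[[nm]], f)
    files[nm] <- f
  }
  f <- file.path(dir, sprintf("%s_fitted_mask.nii.gz", prefix))
  RNifti::writeNifti(array(as.numeric(maps$fitted), dim(maps$fitted)), f)
  files["fitted_mask"] <- f
  f <- file.path(dir, sprintf("%s_quality.nii.gz", prefix))
  RNifti::writeNifti(maps$quality, f)
  files["quality"] <- f
  invisible(files)
}

#' Benign-vs-malignant comparison and diagnostic-performance report
#'
#' For every histogram-metric column of a cohort table: group mean and
#' SD, the two-sided Mann-Whitney p, and the ROC summary (AUC with DeLong
#' CI, Youden cutoff, sensitivity, specificity, orientation), with
#' malignant as the positive class.
#'
#' @param tab A `cohort_table` from [make_cohort()] or [read_cohort()].
#' @param metrics Metric columns to analyse; default every
#'   `parameter_metric` column (reader-2 duplicates excluded).
#' @return Data frame, one row per metric.
#' @export
benign_malignant_report <- function(tab, metrics = metric_columns(tab)) {
  pos <- tab$malignancy == "malignant"
  rows <- lapply(metrics, function(cn) {
    x <- tab[[cn]]
    mw <- mann_whitney_u(x[!pos], x[pos])
    roc <- roc_analysis(x, pos)
    data.frame(metric = cn,
               benign_mean = mean(x[!pos]), benign_sd = stats::sd(x[!pos]),
               malignant_mean = mean(x[pos]),
               malignant_sd = stats::sd(x[pos]),
               p = mw$p_value, auc = roc$auc,
               auc_lo = roc$ci[1], auc_hi = roc$ci[2],
               sensitivity = roc$sensitivity,
               specificity = roc$specificity,
               cutoff = roc$cutoff, positive_low = roc$positive_low,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Metric columns of a cohort table
#' @param tab A `cohort_table`.
#' @return Character vector of `parameter_metric` column names.
#' @export
metric_columns <- function(tab) {
  pats <- paste0("^(adc|D|beta|mu)_",
                 "(p10|p90|mean|median|entropy|kurtosis|skewness)$")
  grep(pats, names(tab), value = TRUE)
}

#' Prognostic-label comparison report among malignant lesions
#'
#' Mann-Whitney comparison of every metric between the negative and
#' positive groups of one binary label (ER, PR, HER2, Ki67, ALN).
#'
#' @param tab A `cohort_table`.
#' @param label One of `"ER"`, `"PR"`, `"HER2"`, `"Ki67"`, `"ALN"`.
#' @inheritParams benign_malignant_report
#' @return Data frame, one row per metric: group means/SDs and p.
#' @export
label_report <- function(tab, label, metrics = metric_columns(tab)) {
  stopifnot(label %in% c("ER", "PR", "HER2", "Ki67", "ALN"))
  sub <- tab[tab$malignancy == "malignant" & !is.na(tab[[label]]), ]
  pos <- sub[[label]] == "positive"
  rows <- lapply(metrics, function(cn) {
    x <- sub[[cn]]
    mw <- mann_whitney_u(x[!pos], x[pos])
    data.frame(label = label, metric = cn,
               negative_mean = mean(x[!pos]),
               negative_sd = stats::sd(x[!pos]),
               positive_mean = mean(x[pos]),
               positive_sd = stats::sd(x[pos]),
               p = mw$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Molecular-subtype comparison report
#'
#' Kruskal-Wallis omnibus test of each metric across the molecular
#' subtypes, with Bonferroni-corrected pairwise Mann-Whitney tests where
#' the omnibus p falls below `alpha`.
#'
#' @param tab A `cohort_table`.
#' @param alpha Significance level gating the pairwise follow-up.
#' @inheritParams benign_malignant_report
#' @return List with `omnibus` (metric, H, p) and `pairwise` (rows only
#'   for metrics with omnibus p < alpha).
#' @export
subtype_report <- function(tab, metrics = metric_columns(tab),
                           alpha = 0.05) {
  sub <- tab[tab$malignancy == "malignant" & !is.na(tab$subtype), ]
  groups_of <- function(cn) split(sub[[cn]], droplevels(sub$subtype))
  omni <- lapply(metrics, function(cn) {
    kw <- kruskal_wallis(groups_of(cn))
    data.frame(metric = cn, H = kw$statistic, p = kw$p_value,
               stringsAsFactors = FALSE)
  })
  omni <- do.call(rbind, omni)
  pw <- lapply(omni$metric[omni$p < alpha], function(cn) {
    cbind(metric = cn, pairwise_bonferroni(groups_of(cn)))
  })
  list(omnibus = omni,
       pairwise = if (length(pw)) do.call(rbind, pw) else NULL)
}

#' Spearman correlation matrix of metrics against prognostic labels
#'
#' @param tab A `cohort_table`.
#' @inheritParams benign_malignant_report
#' @param labels Binary label columns to correlate against
#'   (positive = 1).
#' @return List of matrices `rho` and `p`, metrics x labels.
#' @export
spearman_label_matrix <- function(tab, metrics = metric_columns(tab),
                                  labels = c("ER", "PR", "HER2", "Ki67",
                                             "ALN")) {
  sub <- tab[tab$malignancy == "malignant", ]
  rho <- p <- matrix(NA_real_, length(metrics), length(labels),
                     dimnames = list(metrics, labels))
  for (lb in labels) {
    y <- as.numeric(sub[[lb]] == "positive")
    ok <- !is.na(y)
    for (cn in metrics) {
      tr <- spearman_rho(sub[[cn]][ok], y[ok])
      rho[cn, lb] <- tr$statistic
      p[cn, lb] <- tr$p_value
    }
  }
  list(rho = rho, p = p)
}

#' Inter-reader reproducibility report
#'
#' ICC(2,1) for every metric carrying a `_reader2` duplicate column.
#'
#' @param tab A `cohort_table`.
#' @return Data frame: metric, icc, ci bounds, band.
#' @export
icc_report <- function(tab) {
  r2 <- grep("_reader2$", names(tab), value = TRUE)
  if (!length(r2)) stop("no second-reader columns in the table")
  rows <- lapply(r2, function(cn) {
    base <- sub("_reader2$", "", cn)
    res <- icc_two_way_random(cbind(tab[[base]], tab[[cn]]))
    data.frame(metric = base, icc = res$statistic,
               ci_lo = res$ci[1], ci_hi = res$ci[2],
               band = res$band, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the whole synthetic pipeline: phantom to feature report
#'
#' Generates a phantom, takes the true lesion's largest cross-section as
#' the 2D seed ROI, grows the whole-lesion 3D ROI by fuzzy C-means on the
#' b = 800 s/mm^2 frame, fits both diffusion models inside the ROI, and
#' computes the per-parameter histogram features. Everything is
#' deterministic given the spec and config seeds.
#'
#' @param spec A [phantom_spec()].
#' @param protocol An [acquisition_protocol()].
#' @param config A [fit_config()].
#' @param fcm An [fcm_config()].
#' @param n_bins Histogram bins.
#' @param output_dir Optional directory; when given, the DWI volume,
#'   maps, ROI masks, feature CSV and a JSON config echo are written
#'   there.
#' @return List with `features` (long data frame over both models),
#'   `roi3d`, `dice` (against the true lesion), `maps_froc`,
#'   `maps_mono`, `phantom`, `timings` (seconds per stage).
#' @export
run_phantom_pipeline <- function(spec = phantom_spec(),
                                 protocol = default_breast_protocol(),
                                 config = fit_config(),
                                 fcm = fcm_config(),
                                 n_bins = 100L, output_dir = NULL) {
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()
  phantom <- make_phantom(spec, protocol)
  timings["simulate"] <- tic() - t0

  # seed = true lesion cross-section on its largest slice
  t0 <- tic()
  per_slice <- apply(phantom$roi$mask, 3, sum)
  zmax <- which.max(per_slice)
  seed <- seed_roi(phantom$roi$mask[, , zmax], zmax, spec$grid)
  i800 <- which.min(abs(protocol$b_values - 800))
  roi3d <- segment_lesion_3d(phantom$dwi[, , , i800], seed, fcm)
  timings["segment"] <- tic() - t0

  t0 <- tic()
  maps_froc <- fit_volume(phantom$dwi, roi3d$mask, protocol, config,
                          model = "froc")
  maps_mono <- fit_volume(phantom$dwi, roi3d$mask, protocol, config,
                          model = "mono")
  timings["fit"] <- tic() - t0

  t0 <- tic()
  features <- rbind(
    features_for_lesion(maps_mono, roi3d, "phantom", n_bins),
    features_for_lesion(maps_froc, roi3d, "phantom", n_bins))
  timings["features"] <- tic() - t0

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_dwi(phantom$dwi, protocol, file.path(output_dir, "dwi.nii.gz"))
    write_parameter_maps(maps_froc, output_dir)
    write_parameter_maps(maps_mono, output_dir)
    RNifti::writeNifti(array(as.numeric(roi3d$mask), spec$grid),
                       file.path(output_dir, "roi3d.nii.gz"))
    utils::write.csv(features, file.path(output_dir, "features.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(
        list(grid = spec$grid, snr_b2000 = spec$snr_b2000,
             seed = spec$seed, b_values = protocol$b_values,
             delta = protocol$delta, Delta = protocol$Delta,
             n_starts = config$n_starts,
             fcm_clusters = fcm$n_clusters,
             n_bins = n_bins),
        file.path(output_dir, "run_config.json"), auto_unbox = TRUE)
  }

  list(features = features, roi3d = roi3d,
       dice = dice_coefficient(roi3d, phantom$roi),
       maps_froc = maps_froc, maps_mono = maps_mono,
       phantom = phantom, timings = timings)
}
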