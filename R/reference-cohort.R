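# Published group-level statistics of the benign/malignant breast-lesion
# cohort (50 benign, 109 malignant) that the synthetic cohort generator
# reproduces. Values are on the clinical reporting scale: ADC and D in
# 1e-6 mm^2/s, beta and mu in 1e-3 units; entropy in bits.

#' Benign/malignant reference distributions per histogram metric
#'
#' Group means and SDs of the seven first-order histogram metrics for each
#' diffusion parameter (ADC; FROC D, beta, mu) in the reference cohort,
#' together with the published diagnostic performance (AUC, sensitivity,
#' specificity, cutoff) of each metric for benign-vs-malignant
#' discrimination. These are the default marginals of [cohort_spec()].
#'
#' @return Data frame with columns `parameter`, `metric`, `benign_mean`,
#'   `benign_sd`, `malignant_mean`, `malignant_sd`, `auc`, `sensitivity`,
#'   `specificity`, `cutoff`.
#' @export
benign_malignant_reference <- function() {
  tbl <- rbind(
    c("adc",  "p10",      1182.070,  336.607,  656.414,  126.826, 0.940, 95.41, 86, 848.500),
    c("adc",  "p90",      1668.982,  297.146, 1068.590,  171.082, 0.959, 96.33, 92, 1361.000),
    c("adc",  "entropy",     4.165,    0.585,    4.376,    0.491, 0.616, 67.89, 58, 4.200),
    c("adc",  "kurtosis",    3.560,    2.483,    4.667,    2.433, 0.702, 81.65, 52, 2.880),
    c("adc",  "mean",     1431.755,  272.719,  843.832,  122.565, 0.979, 96.33, 94, 1028.440),
    c("adc",  "median",   1439.880,  285.282,  816.936,  121.969, 0.981, 96.33, 94, 1001.000),
    c("adc",  "skewness",    0.114,    0.818,    0.880,    0.704, 0.791, 75.23, 72, 0.330),
    c("D",    "p10",      1255.080,  333.550,  712.878,  148.349, 0.943, 96.33, 88, 933.000),
    c("D",    "p90",      1747.994,  282.887, 1181.537,  180.711, 0.954, 96.33, 88, 1484.000),
    c("D",    "entropy",     4.189,    0.562,    4.540,    0.489, 0.685, 70.64, 64, 4.250),
    c("D",    "kurtosis",    3.538,    2.341,    4.330,    1.960, 0.686, 77.06, 58, 3.030),
    c("D",    "mean",     1508.486,  256.272,  927.381,  132.942, 0.979, 96.33, 94, 1104.52),
    c("D",    "median",   1516.810,  269.924,  901.665,  133.399, 0.979, 97.25, 92, 1098.000),
    c("D",    "skewness",    0.117,    0.794,    0.785,    0.669, 0.770, 73.39, 76, 0.400),
    c("beta", "p10",       719.868,  176.372,  657.139,  116.150, 0.775, 96.33, 62, 742.000),
    c("beta", "p90",       960.416,   37.259,  895.620,   57.903, 0.811, 71.56, 92, 920.500),
    c("beta", "entropy",     3.275,    0.473,    3.592,    0.433, 0.697, 50.46, 90, 3.650),
    c("beta", "kurtosis",   17.212,   24.568,   14.520,   13.469, 0.603, 88.99, 46, 3.060),
    c("beta", "mean",      849.692,   54.255,  772.093,   35.107, 0.880, 97.25, 72, 824.500),
    c("beta", "median",    868.740,   54.812,  783.211,   38.641, 0.908, 84.40, 86, 812.500),
    c("beta", "skewness",   -2.153,    2.345,   -1.929,    1.675, 0.512, 90.83, 28, -3.790),
    c("mu",   "p10",      6035.350, 1591.250, 5435.192, 1191.744, 0.765, 96.33, 66, 6317.600),
    c("mu",   "p90",      9333.234, 1662.342, 8187.907, 1491.670, 0.774, 66.06, 84, 8176.00),
    c("mu",   "entropy",     5.525,    0.851,    6.066,    0.533, 0.723, 88.99, 54, 5.470),
    c("mu",   "kurtosis",   26.555,   22.290,   57.157,   67.352, 0.692, 66.97, 70, 24.930),
    c("mu",   "mean",     7866.594,  782.448, 6996.922,  702.785, 0.812, 77.98, 78, 7373.340),
    c("mu",   "median",   7329.720,  433.453, 6507.206,  353.028, 0.939, 88.99, 90, 6879.000),
    c("mu",   "skewness",    3.052,    3.051,    5.236,    3.801, 0.673, 66.97, 62, 3.810))
  out <- data.frame(parameter = tbl[, 1], metric = tbl[, 2],
                    stringsAsFactors = FALSE)
  num <- c("benign_mean", "benign_sd", "malignant_mean", "malignant_sd",
           "auc", "sensitivity", "specificity", "cutoff")
  for (i in seq_along(num)) out[[num[i]]] <- as.numeric(tbl[, i + 2])
  out
}

#' Prevalences of prognostic labels among malignant lesions
#'
#' Positivity rates of the clinical biomarkers in the reference cohort
#' (n = 109 cancers): ER 60.6\%, PR 63.3\%, HER2 29.4\%, high Ki-67
#' 80.7\%, axillary-node metastasis 34.9\%, and the molecular-subtype
#' split luminal 68.8\% / HER2-positive 11.9\% / triple-negative 19.3\%.
#'
#' @return Named list with elements `ER`, `PR`, `HER2`, `Ki67`, `ALN`
#'   (scalar probabilities) and `subtype` (named probability vector).
#' @export
prognostic_prevalences <- function() {
  list(ER = 0.606, PR = 0.633, HER2 = 0.294, Ki67 = 0.807, ALN = 0.349,
       subtype = c(luminal = 0.688, her2_positive = 0.119,
                   triple_negative = 0.193))
}

#' Label-conditional metric shifts among malignant lesions
#'
#' Group means of the metrics that differ significantly by prognostic
#' label in the reference cohort. The generator turns each row into an
#' additive shift (label-group mean minus the prevalence-weighted overall
#' mean), applied to malignant lesions according to their labels; metrics
#' the cohort reports as non-significant are left unshifted.
#'
#' @return Data frame with columns `label`, `parameter`, `metric`,
#'   `negative_mean`, `positive_mean` ("positive" = marker-positive /
#'   high Ki-67 / node metastasis).
#' @export
label_shift_reference <- function() {
  tbl <- rbind(
    c("ER",   "adc",  "mean",     874.645, 822.549),
    c("ER",   "D",    "p10",      747.947, 690.030),
    c("ER",   "D",    "mean",     955.875, 908.818),
    c("ER",   "D",    "median",   926.802, 885.288),
    c("ER",   "beta", "p10",      679.472, 642.588),
    c("ER",   "beta", "mean",     779.515, 767.258),
    c("ER",   "beta", "median",   788.058, 780.053),
    c("PR",   "beta", "p10",      676.808, 645.736),
    c("PR",   "beta", "mean",     779.004, 768.087),
    c("PR",   "beta", "median",   788.713, 780.022),
    c("Ki67", "beta", "p10",      635.762, 662.240),
    c("Ki67", "beta", "mean",     760.157, 774.943),
    c("Ki67", "beta", "entropy",    3.773,   3.548),
    c("ALN",  "adc",  "entropy",    4.297,   4.523),
    c("ALN",  "D",    "entropy",    4.458,   4.693),
    c("ALN",  "D",    "skewness",   0.898,   0.572),
    c("ALN",  "mu",   "entropy",    5.993,   6.203))
  data.frame(label = tbl[, 1], parameter = tbl[, 2], metric = tbl[, 3],
             negative_mean = as.numeric(tbl[, 4]),
             positive_mean = as.numeric(tbl[, 5]),
             stringsAsFactors = FALSE)
}

#' Reference inter-reader agreement of the lesion-mean parameters
#'
#' Published ICC(2,1) values for ADC, D, beta and mu measurements between
#' two readers in the reference cohort.
#' @return Named numeric vector.
#' @export
reference_icc <- function() {
  c(adc = 0.917, D = 0.928, beta = 0.833, mu = 0.827)
}

#' Reference image SNR at b = 2000 s/mm^2
#'
#' Mean signal-to-noise ratios measured on the b = 2000 volumes:
#' fibroglandular tissue 22.53, benign lesions 56.53, malignant lesions
#' 119.56.
#' @return Named numeric vector.
#' @export
reference_snr_b2000 <- function() {
  c(fgt = 22.53, benign = 56.53, malignant = 119.56)
}
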