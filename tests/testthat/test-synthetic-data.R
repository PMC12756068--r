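test_that("Rician noise matches its closed-form moments", {
  x <- c(10, 20, 30)
  expect_identical(rician_noise(x, 0), x)

  # zero signal: Rayleigh mean sigma * sqrt(pi/2)
  set.seed(1)
  draws <- rician_noise(rep(0, 1e6), 1)
  expect_equal(mean(draws), sqrt(pi / 2), tolerance = 2e-3)

  # high-SNR expansion: E[S_noisy] ~ S + sigma^2 / (2 S)
  set.seed(2)
  S <- 100
  draws2 <- rician_noise(rep(S, 1e6), 1)
  expect_lt(abs(mean(draws2) / (S + 1 / (2 * S)) - 1), 1e-3)

  expect_error(rician_noise(1:3, -1))
})

test_that("phantoms honour SNR, determinism and the inverse-crime identity", {
  proto <- breast_protocol()
  spec0 <- phantom_spec(grid = c(16, 16, 6), center = c(8, 8, 3),
                        semiaxes = c(5, 4, 2),
                        lesion = list(S0 = c(1000, 0), D = c(9.3e-4, 0),
                                      beta = c(0.78, 0), mu = c(6.5e-3, 0)),
                        background = list(S0 = c(800, 0), D = c(1.6e-3, 0),
                                          beta = c(0.92, 0),
                                          mu = c(8e-3, 0)),
                        snr_b2000 = 119.56, seed = 5)
  ph <- make_phantom(spec0, proto)

  # target SNR is hit: mean noisy lesion signal at max b over sigma
  i2000 <- which.max(proto$b_values)
  snr_meas <- mean(ph$dwi[, , , i2000][ph$roi$mask]) / ph$sigma
  expect_lt(abs(snr_meas / 119.56 - 1), 0.05)

  # same seed: bit-identical; different seed: different
  ph2 <- make_phantom(spec0, proto)
  expect_identical(ph$dwi, ph2$dwi)
  spec1 <- spec0; spec1$seed <- 6L
  expect_false(identical(make_phantom(spec1, proto)$dwi, ph$dwi))

  # SD = 0 truth fields are exactly the spec means
  expect_true(all(ph$truth$beta[ph$roi$mask] == 0.78))
  expect_true(all(ph$truth$D[!ph$roi$mask] == 1.6e-3))

  # noise-free forward signal at b = 0 equals S0
  expect_equal(ph$dwi_clean[, , , 1], ph$truth$S0, tolerance = 1e-12)
})

test_that("noise-free phantom fits recover the identifiable truth exactly", {
  proto <- breast_protocol()
  spec0 <- phantom_spec(grid = c(10, 10, 4), center = c(5, 5, 2),
                        semiaxes = c(3, 3, 1),
                        lesion = list(S0 = c(1000, 0), D = c(9.3e-4, 0),
                                      beta = c(0.78, 0), mu = c(6.5e-3, 0)),
                        background = list(S0 = c(800, 0), D = c(1.6e-3, 0),
                                          beta = c(0.92, 0),
                                          mu = c(8e-3, 0)),
                        seed = 3)
  ph <- make_phantom(spec0, proto)
  maps <- fit_volume(ph$dwi_clean, ph$roi$mask, proto, model = "froc")
  expect_true(all(abs(maps$maps$beta[ph$roi$mask] - 0.78) < 5e-3))
  expect_true(all(abs(maps$maps$S0[ph$roi$mask] / 1000 - 1) < 5e-3))
})

test_that("lesion-median beta recovery at the malignant SNR level", {
  proto <- breast_protocol()
  spec0 <- phantom_spec(grid = c(20, 20, 6), center = c(10, 10, 3),
                        semiaxes = c(6, 5, 2), snr_b2000 = 119.56,
                        seed = 11)
  ph <- make_phantom(spec0, proto)
  maps <- fit_volume(ph$dwi, ph$roi$mask, proto, model = "froc")
  beta_med_true <- median(ph$truth$beta[ph$roi$mask])
  beta_med_fit <- median(maps$maps$beta[ph$roi$mask], na.rm = TRUE)
  expect_lt(abs(beta_med_fit - beta_med_true), 0.05)
})

test_that("cohorts reproduce their marginals, labels and reader noise", {
  # SD -> 0: metrics collapse to the group means
  ref0 <- benign_malignant_reference()
  ref0$benign_sd[] <- 0; ref0$malignant_sd[] <- 0
  tab0 <- make_cohort(cohort_spec(n_benign = 5, n_malignant = 8,
                                  reference = ref0,
                                  label_shifts = label_shift_reference()[0, ],
                                  seed = 2))
  expect_true(all(tab0$adc_median[tab0$malignancy == "benign"] == 1439.880))
  expect_true(all(tab0$D_mean[tab0$malignancy == "malignant"] == 927.381))

  # full table is seed-reproducible
  tab_a <- make_cohort(cohort_spec(seed = 7))
  tab_b <- make_cohort(cohort_spec(seed = 7))
  expect_identical(tab_a, tab_b)
  expect_equal(nrow(tab_a), 159)
  expect_equal(sum(tab_a$malignancy == "benign"), 50)
  expect_true(all(is.na(tab_a$ER[tab_a$malignancy == "benign"])))
  expect_length(metric_columns(tab_a), 28)
  expect_true(all(paste0(c("adc_median", "D_mean", "beta_median",
                           "mu_median"), "_reader2") %in% names(tab_a)))

  # benign ADC-median group mean across replicates matches the spec mean
  reps <- vapply(1:200, function(s) {
    t <- make_cohort(cohort_spec(n_benign = 50, n_malignant = 2, seed = s))
    mean(t$adc_median[t$malignancy == "benign"])
  }, 1.0)
  se <- 285.282 / sqrt(50 * 200)
  expect_lt(abs(mean(reps) - 1439.880), 2 * se)
})

test_that("generated cohort AUCs converge to the analytic two-Gaussian
           value", {
  ref <- benign_malignant_reference()
  row <- ref[ref$parameter == "beta" & ref$metric == "median", ]
  analytic <- pnorm((row$benign_mean - row$malignant_mean) /
                      sqrt(row$benign_sd^2 + row$malignant_sd^2))
  aucs <- vapply(1:150, function(s) {
    tab <- make_cohort(cohort_spec(seed = s))
    roc_analysis(tab$beta_median, tab$malignancy == "malignant")$auc
  }, 1.0)
  expect_lt(abs(mean(aucs) - analytic), 0.01)
})

test_that("cohort CSV round-trips through the reader", {
  tab <- make_cohort(cohort_spec(n_benign = 6, n_malignant = 10, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, f)
  back <- read_cohort(f)
  expect_equal(back$adc_median, tab$adc_median, tolerance = 1e-12)
  expect_identical(as.character(back$malignancy),
                   as.character(tab$malignancy))
  expect_identical(levels(back$subtype), levels(tab$subtype))
})
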