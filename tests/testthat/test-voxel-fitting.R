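test_that("mono fit is exact on noise-free mono-exponential data", {
  p <- breast_protocol()
  sig <- mono_signal(mono_params(500, 1.2e-3), p$b_values)
  f <- fit_mono(sig, p)
  expect_equal(f$params$adc, 1.2e-3, tolerance = 1e-10)
  expect_equal(f$params$S0, 500, tolerance = 1e-10)
  expect_true(f$converged)

  # constant signal -> adc clamped at 0
  fc <- fit_mono(rep(321, 8), p)
  expect_equal(fc$params$adc, 0, tolerance = 1e-12)

  # insufficient usable points
  expect_error(fit_mono(c(100, 90, -1, -1, -1, -1, 50, 40), p),
               "fewer than 3")
})

test_that("mono fit ignores frames above mono_b_max", {
  p <- breast_protocol()
  sig <- mono_signal(mono_params(500, 1.0e-3), p$b_values)
  f_ref <- fit_mono(sig, p)
  # corrupt only the b > 800 frames
  sig2 <- sig
  sig2[p$b_values > 800] <- sig2[p$b_values > 800] * runif(2, 0.2, 1.5)
  f2 <- fit_mono(sig2, p)
  expect_identical(f_ref$params$adc, f2$params$adc)
  expect_identical(f_ref$params$S0, f2$params$S0)
})

test_that("mono fit recovers truth from Rician-noisy voxels", {
  p <- breast_protocol()
  truth <- mono_params(500, 1.2e-3)
  sig <- mono_signal(truth, p$b_values)
  set.seed(11)
  adc_hat <- replicate(200, {
    fit_mono(rician_noise(sig, 500 / 50), p)$params$adc
  })
  expect_lt(abs(median(adc_hat) / 1.2e-3 - 1), 0.05)
})

test_that("FROC fit recovers beta and the decay amplitude exactly on
           noise-free data, with D defined by the low-b regime", {
  p <- breast_protocol()
  cases <- list(c(D = 9.3e-4, beta = 0.78, mu = 6.5e-3),
                c(D = 1.5e-3, beta = 0.60, mu = 4.0e-3),
                c(D = 5.0e-4, beta = 0.90, mu = 1.0e-2))
  for (cs in cases) {
    truth <- froc_params(1000, cs[["D"]], cs[["beta"]], cs[["mu"]])
    f <- fit_froc(froc_signal(truth, p), p)
    expect_true(f$converged)
    expect_equal(f$params$beta, cs[["beta"]], tolerance = 5e-3)
    expect_equal(f$params$S0, 1000, tolerance = 5e-3)
    # the identifiable D-mu combination (stretched-exponential amplitude)
    A_true <- frocdwi:::froc_amplitude(cs[["D"]], cs[["beta"]],
                                       cs[["mu"]], p)
    expect_equal(f$A, A_true, tolerance = 5e-3)
    # the reported (D, mu) pair reproduces that amplitude: the fit sits
    # on the model's D-mu ridge at the documented low-b-ADC convention
    A_rep <- frocdwi:::froc_amplitude(f$params$D, f$params$beta,
                                      f$params$mu, p)
    expect_equal(A_rep, A_true, tolerance = 5e-3)
    expect_equal(f$params$D, fit_mono(froc_signal(truth, p), p)$params$adc,
                 tolerance = 1e-9)
  }
})

test_that("FROC fit of mono-exponential data hits the beta = 1 limit", {
  p <- breast_protocol()
  sig <- mono_signal(mono_params(700, 1.1e-3), p$b_values)
  f <- fit_froc(sig, p)
  expect_gte(f$params$beta, 0.995)
  expect_equal(f$params$D, 1.1e-3, tolerance = 5e-3)
  expect_true("mu_unidentifiable" %in% f$flags)
  expect_true(is.finite(f$params$mu))  # reported, not dropped

  # degenerate constant input
  fd <- fit_froc(rep(400, 8), p)
  expect_true("degenerate" %in% fd$flags)
  expect_identical(fd$params$beta, 1)
  expect_false(fd$converged)

  expect_error(fit_froc(c(100, 90, 80), acquisition_protocol(
    c(0, 100, 2000), 0.0193, 0.04)), ">= 5 distinct")
})

test_that("free-beta FROC residual never exceeds the beta = 1 fit", {
  p <- breast_protocol()
  truth <- froc_params(1000, 9.3e-4, 0.78, 6.5e-3)
  sig <- froc_signal(truth, p)
  set.seed(3)
  for (i in 1:10) {
    s <- rician_noise(sig, 8)
    f <- fit_froc(s, p)
    # beta = 1 constrained least squares over the same b-range
    con <- minpack.lm::nls.lm(
      par = c(S0 = max(s), A = 1e-3), lower = c(1e-6, 1e-9),
      upper = c(10 * max(s), 10),
      fn = function(par, b, y) y - par[1] * exp(-par[2] * b),
      b = p$b_values, y = s)
    expect_lte(f$residual_norm, con$deviance * (1 + 1e-6))
  }
})

test_that("beta error shrinks monotonically as SNR grows", {
  p <- breast_protocol()
  truth <- froc_params(1000, 9.3e-4, 0.78, 6.5e-3)
  sig <- froc_signal(truth, p)
  s2000 <- sig[which.max(p$b_values)]
  med_err <- vapply(c(20, 50, 120), function(snr) {
    set.seed(100 + snr)
    errs <- replicate(60, {
      f <- fit_froc(rician_noise(sig, s2000 / snr), p)
      abs(f$params$beta - 0.78)
    })
    median(errs)
  }, 1.0)
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 0.02)
})

test_that("volume fitting fills maps only inside the mask", {
  p <- breast_protocol()
  grid <- c(6, 6, 2)
  truth <- froc_params(1000, 9.3e-4, 0.78, 6.5e-3)
  sig <- froc_signal(truth, p)
  dwi <- array(rep(sig, each = prod(grid)), c(grid, length(sig)))
  mask <- array(FALSE, grid); mask[2:5, 2:5, ] <- TRUE

  maps <- fit_volume(dwi, mask, p, model = "froc")
  expect_s3_class(maps, "parameter_maps")
  inside <- maps$maps$beta[mask]
  expect_true(all(abs(inside - 0.78) < 5e-3))
  expect_true(all(is.na(maps$maps$beta[!mask])))
  expect_true(all(!maps$fitted[!mask]))

  # constant noise-free phantom -> constant maps (mono)
  dwim <- array(rep(mono_signal(mono_params(500, 1e-3), p$b_values),
                    each = prod(grid)), c(grid, 8))
  mm <- fit_volume(dwim, mask, p, model = "mono")
  expect_equal(unname(range(mm$maps$adc[mask])), rep(1e-3, 2),
               tolerance = 1e-9)

  expect_error(fit_volume(dwi, array(FALSE, grid), p), "empty")
})

test_that("two-region phantoms give bimodal parameter maps", {
  p <- breast_protocol()
  grid <- c(8, 8, 2)
  mask <- array(TRUE, grid)
  inner <- array(FALSE, grid); inner[3:6, 3:6, ] <- TRUE
  s_in <- froc_signal(froc_params(1000, 8e-4, 0.70, 6e-3), p)
  s_out <- froc_signal(froc_params(1000, 1.8e-3, 0.95, 9e-3), p)
  dwi <- array(0, c(grid, 8))
  for (i in 1:8) dwi[, , , i] <- ifelse(inner, s_in[i], s_out[i])
  maps <- fit_volume(dwi, mask, p, model = "froc")
  # beta is identifiable: modes at the two truths
  expect_true(all(abs(maps$maps$beta[inner] - 0.70) < 5e-3))
  expect_true(all(abs(maps$maps$beta[!inner] - 0.95) < 5e-3))
  # D separates the regions in the right order (low-b ADC convention)
  expect_lt(max(maps$maps$D[inner]), min(maps$maps$D[!inner]))
})
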