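# Segmentation, volume integration, equation-of-motion and SLICE fits.

test_that("volume integration matches closed forms", {
  # constant flow Q for T seconds ramps to Q*T
  v <- integrate_volume(rep(100, 401), 200)
  expect_equal(v[401], 100 * 2, tolerance = 1e-9)

  # zero-mean sinusoid over integer periods: peak volume = amp / (2 pi f)
  fs <- 200; f <- 5; t <- (0:399) / fs
  q <- 60 * sin(2 * pi * f * t)
  v <- integrate_volume(q, fs)
  expect_equal(max(abs(v)), 2 * 60 / (2 * pi * f), tolerance = 5e-3)

  # drift correction forces closure and reports the removed volume
  vd <- integrate_volume(rep(1, 201), 200, drift_correct = TRUE)
  expect_equal(vd[201], 0)
  expect_equal(attr(vd, "drift_ml"), 1, tolerance = 1e-9)
})

test_that("breaths are segmented at inspiration onsets, holds excluded", {
  lung <- make_linear_lung(resistance = 0.01, compliance = 20)
  proto <- peep_protocol(incremental = numeric(0), decremental = 12,
                         n_breaths = 12L, insp_hold_breath = 11L,
                         exp_hold_breath = 12L, hold_s = 2)
  sim <- simulate_peep_trial(lung, seed = 4, protocol = proto)

  br <- segment_breaths(sim$waveforms, sim$annotations)
  # RR = 30/min: the first 20 s of free breathing hold 9-10 onset-to-onset
  # segments
  n20 <- sum(br$t0 < 20)
  expect_gte(n20, 9); expect_lte(n20, 10)

  # onset times within one sample of the ventilator's inspiration starts
  expected <- (seq_len(10) - 1) * 2
  for (i in seq_len(min(10, nrow(br)))) {
    expect_lt(min(abs(br$t0[i] - expected)), 1.5 / 200)
  }

  # breaths overlapping holds were dropped
  hold <- sim$annotations[sim$annotations$label == "insp_hold", ]
  expect_false(any(br$t0 < hold$t_end_s & br$t_end > hold$t_start_s))

  # tidal volume recovered within 0.5%
  vt <- lung_vt <- sim$vent$tidal_volume
  expect_true(all(abs(br$vt_ml - vt) < 0.005 * vt))

  # drift correction stays below 2% of the tidal volume
  expect_true(all(abs(br$drift_ml) < 0.02 * vt))
})

test_that("equation-of-motion fit recovers exact coefficients", {
  br <- synth_eom_breaths(edyn = 0.05, rdyn = 0.01, eep = 12)
  fit <- fit_eom(br)
  expect_equal(fit$edyn, 0.05, tolerance = 1e-9)
  expect_equal(fit$rdyn, 0.01, tolerance = 1e-9)
  expect_equal(fit$eep, 12, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)

  # doubling flow and volume at fixed pressure halves both coefficients
  br2 <- synth_eom_breaths(edyn = 0.05, rdyn = 0.01, eep = 12, flow_scale = 2)
  br2$data <- purrr::map2(br2$data, br$data,
                          function(d, d0) { d$ptr_f <- d0$ptr_f; d })
  fit2 <- fit_eom(br2)
  expect_equal(fit2$edyn, 0.025, tolerance = 1e-9)
  expect_equal(fit2$rdyn, 0.005, tolerance = 1e-9)

  # tidy/glance expose the coefficients
  expect_equal(tidy(fit)$estimate, c(fit$edyn, fit$rdyn, fit$eep))
  expect_equal(glance(fit)$n_breaths, 3)

  # collinear design (exactly constant flow, volume proportional to time)
  t <- (0:399) / 200
  bad <- tibble::tibble(
    breath = 1L, t0 = 0, t_end = 2, vt_ml = 200, drift_ml = 0,
    insp_end = 400L,
    data = list(tibble::tibble(t_s = t, ptr_f = 5 + t, vao_f = 100,
                               volume = 100 * t, ptr_raw = 5 + t,
                               vao_raw = 100)))
  expect_error(fit_eom(bad), class = "oscillung_error_conditioning")
})

test_that("noisy equation-of-motion recovery stays within tolerance", {
  br0 <- synth_eom_breaths(edyn = 0.05, rdyn = 0.01, eep = 12, n_breaths = 5)
  errs <- purrr::map_dfr(1:50, function(s) {
    set.seed(s)
    br <- br0
    br$data <- purrr::map(br$data, function(d) {
      d$ptr_f <- d$ptr_f + rnorm(nrow(d), 0, 0.05); d
    })
    fit <- fit_eom(br)
    tibble::tibble(edyn = abs(fit$edyn - 0.05) / 0.05,
                   rdyn = abs(fit$rdyn - 0.01) / 0.01,
                   eep = abs(fit$eep - 12) / 12, rmse = fit$rmse)
  })
  expect_lt(mean(errs$edyn), 0.02)
  expect_lt(mean(errs$rdyn), 0.02)
  expect_lt(mean(errs$eep), 0.02)
  expect_equal(mean(errs$rmse), 0.05, tolerance = 0.15)
})

test_that("slice analysis matches the global fit on linear data", {
  br <- synth_eom_breaths(edyn = 0.05, rdyn = 0.01, eep = 12, n_breaths = 4)
  sl <- slice_analysis(br)
  expect_equal(nrow(sl), 6L)
  expect_true(all(sl$valid))
  expect_equal(sl$elastance, rep(0.05, 6), tolerance = 1e-6)
  expect_equal(attr(sl, "e_low"), sl$elastance[1])
  expect_equal(attr(sl, "e_high"), sl$elastance[6])
  expect_true(all(diff(sl$volume_center) > 0))
})

test_that("slice elastances rise along the stiffening PV curve", {
  lung <- make_injured_lung(0, n_units = 200L, seed = 6)
  proto <- peep_protocol(incremental = numeric(0), decremental = 12,
                         n_breaths = 10L, insp_hold_breath = 9L,
                         exp_hold_breath = 10L, hold_s = 2)
  # a breath period that is not an integer number of oscillation periods,
  # so residual oscillation de-phases across the pooled breaths
  sim <- simulate_peep_trial(lung, seed = 8, protocol = proto,
                             vent = ventilator_settings(respiratory_rate = 17),
                             noise_sd = c(0, 0))
  br <- segment_breaths(sim$waveforms, sim$annotations)
  br <- br[br$breath > 2, ] # steady state
  sl <- slice_analysis(br)
  expect_true(all(sl$valid))
  expect_true(all(diff(sl$elastance) > 0))
  expect_gt(attr(sl, "e_high"), attr(sl, "e_low"))

  # per-bin tangent elastance of the configured PV curve (numeric
  # differentiation oracle): E(V) at the bin-center absolute gas volume
  vmax_tot <- sum(lung$vmax); k <- lung$k[1]
  g_ee <- vmax_tot * (1 - exp(-k * 12))
  for (i in seq_len(6)) {
    v_abs <- g_ee + sl$volume_center[i]
    p_c <- -log(1 - v_abs / vmax_tot) / k
    h <- 1e-4
    e_tan <- h / (vmax_tot * (exp(-k * p_c) - exp(-k * (p_c + h))))
    expect_equal(sl$elastance[i], e_tan, tolerance = 0.05)
  }

  # linear noiseless system: every slice equals the global fit
  fit <- fit_eom(br)
  expect_gt(fit$edyn, attr(sl, "e_low"))
  expect_lt(fit$edyn, attr(sl, "e_high"))
})

test_that("oscillatory and tidal elastance carry the same information", {
  # on a quasi-static lung without time-constant heterogeneity, the
  # end-expiratory oscillatory elastance tracks E_LOW and the
  # end-inspiratory one tracks E_HIGH across a decremental trial
  lung <- make_injured_lung(0, n_units = 200L, seed = 51,
                            vmax_ml_per_kg = 30, k = 0.05)
  proto <- peep_protocol(incremental = numeric(0),
                         decremental = seq(20, 0, by = -4),
                         n_breaths = 10L, insp_hold_breath = 9L,
                         exp_hold_breath = 10L, hold_s = 5)
  sim <- simulate_peep_trial(lung, protocol = proto, seed = 52,
                             vent = ventilator_settings(respiratory_rate = 17))
  res <- analyze_animal(sim$waveforms, sim$annotations)
  d <- res$steps[res$steps$limb == "decremental", ]
  expect_gte(cor(d$ex5_ee, d$e_low), 0.95)
  expect_gte(cor(d$ex5_ei, d$e_high), 0.95)
  # whole-breath Edyn lies between the intra-tidal extremes
  expect_true(all(d$edyn > d$e_low - 1e-9 & d$edyn < d$e_high + 1e-9))
})
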