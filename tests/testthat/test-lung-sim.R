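# Unit-population construction, hysteresis rule, PV curve and simulator
# behaviour.

test_that("injured-lung populations follow the configured distributions", {
  # determinism
  l1 <- make_injured_lung(1, n_units = 100L, seed = 42)
  l2 <- make_injured_lung(1, n_units = 100L, seed = 42)
  expect_identical(l1, l2)

  # healthy lung never derecruits at ZEEP, for any seed
  for (s in c(1, 7, 99)) {
    lh <- make_injured_lung(0, n_units = 200L, seed = s)
    expect_true(all(lh$close_pressure < 0))
  }

  # opening above closing everywhere (hysteresis)
  li <- make_injured_lung(0.8, n_units = 500L, seed = 1)
  expect_true(all(li$open_pressure > li$close_pressure))

  # sampled tail mass matches the mixture's closed-form tail probability
  # within the binomial 95% CI
  p_tail <- close_pressure_tail_prob(0.8, 10)
  n_hit <- sum(li$close_pressure > 10)
  ci <- qbinom(c(0.025, 0.975), 500, p_tail)
  expect_gte(n_hit, ci[1])
  expect_lte(n_hit, ci[2])

  expect_error(make_injured_lung(1.2, seed = 1),
               class = "oscillung_error_parameter")
})

test_that("unit state update is bistable with the stated boundaries", {
  lung <- make_linear_lung()
  lung$open_pressure <- rep(14, nrow(lung))
  lung$close_pressure <- rep(8, nrow(lung))

  # exactly at the opening pressure a closed unit opens
  expect_true(all(unit_state_update(lung, 14, rep(FALSE, nrow(lung)))))
  # between the thresholds the state is retained
  expect_true(all(unit_state_update(lung, 11, rep(TRUE, nrow(lung)))))
  expect_false(any(unit_state_update(lung, 11, rep(FALSE, nrow(lung)))))

  # pressure sweep 0 -> 24 -> 0 on one unit: opens at 14 up, closes at 8 down
  one <- lung[1, ]
  ps <- c(seq(0, 24, by = 1), seq(23, 0, by = -1))
  st <- logical(length(ps)); cur <- FALSE
  for (i in seq_along(ps)) {
    cur <- unit_state_update(one, ps[i], cur)
    st[i] <- cur
  }
  up <- seq_len(25)
  expect_identical(which(st[up])[1], which(ps[up] == 14))
  down <- 26:49
  # open above 8 on the way down, closes when pressure reaches 8
  expect_identical(ps[down][which(!st[down])[1]], 8)
})

test_that("open-unit volume follows the exponential PV curve", {
  lung <- make_injured_lung(0.5, n_units = 1L, seed = 1)
  lung$vmax <- 2; lung$k <- 0.05

  expect_equal(open_unit_volume(lung, 0), 0)
  expect_equal(open_unit_volume(lung, 20), 2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(open_unit_volume(lung, 20, open = FALSE), 0)

  # tangent elastance dP/dv ratio between 20 and 10 cm H2O is e^{k * 10}
  h <- 1e-5
  e20 <- h / (open_unit_volume(lung, 20 + h) - open_unit_volume(lung, 20))
  e10 <- h / (open_unit_volume(lung, 10 + h) - open_unit_volume(lung, 10))
  expect_equal(e20 / e10, exp(0.5), tolerance = 1e-3)

  expect_warning(open_unit_volume(lung, -1), "clamped")
})

test_that("simulated records are deterministic and annotated consistently", {
  lung <- make_injured_lung(0.8, n_units = 60L, seed = 3)
  proto <- peep_protocol(incremental = c(0, 12), decremental = c(12, 0),
                         n_breaths = 5L, insp_hold_breath = 3L,
                         exp_hold_breath = 4L, hold_s = 2)
  s1 <- simulate_peep_trial(lung, protocol = proto, seed = 11)
  s2 <- simulate_peep_trial(lung, protocol = proto, seed = 11)
  expect_identical(s1$waveforms, s2$waveforms)
  expect_identical(s1$phantoms, s2$phantoms)

  # every step annotated with one inspiratory and one expiratory hold
  ann <- s1$annotations
  counts <- table(ann$label)
  expect_equal(unname(counts[c("peep_step", "insp_hold", "exp_hold")]),
               c(4L, 4L, 4L), ignore_attr = TRUE)

  # uniform grid at the FOT sample rate
  expect_lt(diff(range(diff(s1$waveforms$t_s))), 1e-9)
})

test_that("holds carry only the oscillatory flow", {
  fx <- make_fixture("linear_lung", seed = 2)
  eh <- fx$annotations[fx$annotations$label == "exp_hold", ]
  wf <- fx$waveforms
  hold <- wf[wf$t_s >= eh$t_start_s & wf$t_s < eh$t_end_s, ]
  # noiseless fixture: flow during the hold is a pure sinusoid at 5 Hz
  fit <- estimate_impedance_ls(hold[1:200, ], trend_order = 1)
  res_power <- fit$residual_fraction
  expect_lt(res_power, 1e-4)
  # no ventilatory (DC / low-frequency) flow component
  expect_lt(abs(mean(hold$vao_ml_s)), 0.5)
})

test_that("noiseless linear simulation recovers its own parameters", {
  fx <- make_fixture("linear_lung", seed = 5)
  br <- segment_breaths(fx$waveforms, fx$annotations)
  expect_gte(nrow(br), 1)
  fit <- fit_eom(br)
  expect_equal(fit$edyn, 1 / fx$params$compliance, tolerance = 1e-3)
  expect_equal(fit$rdyn, fx$params$resistance, tolerance = 1e-3)
  expect_equal(fit$eep, fx$params$peep, tolerance = 1e-3)
})

test_that("per-breath volume is conserved at steady state", {
  fx <- make_fixture("injured_lung", seed = 9)
  vt <- fx$vent$tidal_volume
  br <- segment_breaths(fx$waveforms, fx$annotations)
  # steady-state breaths: late breaths of decremental steps (early breaths
  # equilibrate after the PEEP change, and on the incremental limb ongoing
  # recruitment retains gas from breath to breath)
  ann <- fx$annotations[fx$annotations$label == "peep_step", ]
  dec <- ann[ann$limb == "decremental", ]
  late <- br[purrr::map_lgl(br$t0, function(t0) {
    any(t0 >= dec$t_start_s + 4.5 & t0 < dec$t_end_s)
  }), ]
  expect_gte(nrow(late), 2)
  # inspired equals expired: the volume trace returns to zero
  for (d in late$data) {
    v <- integrate_volume(d$vao_f, 200, drift_correct = FALSE)
    expect_lt(abs(v[length(v)]), 0.005 * vt)
  }
})

test_that("simulator hysteresis and monotone aeration hold in ground truth", {
  lung <- make_injured_lung(0.8, n_units = 300L, seed = 21)
  sim <- simulate_peep_trial(lung, seed = 22)
  gt <- sim$ground_truth$steps
  dec <- gt[gt$limb == "decremental", ]
  inc <- gt[gt$limb == "incremental", ]

  # decremental end-expiratory open fraction never below incremental at the
  # same PEEP
  both <- merge(dec, inc, by = "peep", suffixes = c("_dec", "_inc"))
  expect_true(all(both$open_fraction_end_expiration_dec >=
                    both$open_fraction_end_expiration_inc - 1e-12))

  # monotone aeration: open fraction non-increasing as PEEP decreases
  dec_o <- dec[order(dec$peep, decreasing = TRUE), ]
  expect_true(all(diff(dec_o$open_fraction_end_expiration) <= 1e-12))

  # true open-lung PEEP lies on the decremental grid
  expect_true(sim$ground_truth$true_peep_ol %in% dec$peep)
})

test_that("closed units hold no gas: phantom gas matches per-unit brute force", {
  lung <- make_injured_lung(0.8, n_units = 80L, seed = 31)
  proto <- peep_protocol(incremental = c(0, 16), decremental = c(16, 8, 0),
                         n_breaths = 5L, insp_hold_breath = 3L,
                         exp_hold_breath = 4L, hold_s = 2)
  sim <- simulate_peep_trial(lung, protocol = proto, seed = 32)
  gt <- sim$ground_truth$steps
  keys <- unique(sim$phantoms[, c("peep_cmH2O", "limb", "phase")])
  for (i in seq_len(nrow(keys))) {
    ph <- sim$phantoms[sim$phantoms$peep_cmH2O == keys$peep_cmH2O[i] &
                         sim$phantoms$limb == keys$limb[i] &
                         sim$phantoms$phase == keys$phase[i], ]
    gas_ph <- ph$voxel_ml - lung$tissue # per-voxel gas encoded in the phantom
    open <- gas_ph > 1e-9
    palv <- if (keys$phase[i] == "end_inspiration") {
      gt$palv_cmH2O_end_inspiration[gt$peep == keys$peep_cmH2O[i] &
                                      gt$limb == keys$limb[i]]
    } else {
      gt$palv_cmH2O_end_expiration[gt$peep == keys$peep_cmH2O[i] &
                                     gt$limb == keys$limb[i]]
    }
    # brute force: each open unit at the snapshot pressure, closed units zero
    v_bf <- open_unit_volume(lung, max(palv, 0), open)
    expect_equal(gas_ph, v_bf, tolerance = 1e-8)
  }
})
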