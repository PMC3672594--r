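# Multi-unit lung simulator: hysteretic recruitment/derecruitment with
# strain-stiffening units, volume-controlled ventilation and a superimposed
# forced oscillation, driven through an incremental/decremental PEEP protocol.

#' Distribution parameters of the unit opening/closing pressures
#'
#' The alveolar-unit population is a two-component mixture. A "healthy"
#' component has closing pressures drawn from a Gaussian truncated to stay
#' below zero, so those units never derecruit at ZEEP; an "injured"
#' (surfactant-depleted) component has closing pressures whose mean and
#' spread rise with injury severity. Opening pressures sit a positive,
#' randomly drawn offset above the closing pressures, which produces
#' pressure-volume hysteresis.
#'
#' @param severity injury severity in `[0, 1]`; 0 is a healthy lung.
#' @return a list with the mixture weight (`w_injured`), the healthy and
#'   injured closing-pressure components (`mean`, `sd`, truncation bounds,
#'   cm H2O) and the opening-pressure offset component.
#' @export
lung_population_params <- function(severity) {
  if (!is.numeric(severity) || length(severity) != 1L ||
      is.na(severity) || severity < 0 || severity > 1) {
    abort("`severity` must be a single number in [0, 1].",
          class = "oscillung_error_parameter")
  }
  list(
    w_injured = 0.7 * severity,
    healthy = list(mean = -4, sd = 2, upper = -0.5),
    injured = list(mean = 11.25 * severity - 0.5, sd = 0.5 + 0.625 * severity),
    delta   = list(mean = 9, sd = 3, lower = 2)
  )
}

#' Tail probability of the closing-pressure distribution
#'
#' Closed-form `P(Pc > q)` under the mixture returned by
#' [lung_population_params()]; used to check that sampled populations match
#' their configured distribution.
#'
#' @inheritParams lung_population_params
#' @param q threshold, cm H2O.
#' @export
close_pressure_tail_prob <- function(severity, q) {
  p <- lung_population_params(severity)
  h <- p$healthy
  # healthy component is truncated above at h$upper
  ph <- if (q >= h$upper) 0 else {
    num <- stats::pnorm(h$upper, h$mean, h$sd) - stats::pnorm(q, h$mean, h$sd)
    num / stats::pnorm(h$upper, h$mean, h$sd)
  }
  pi_ <- 1 - stats::pnorm(q, p$injured$mean, p$injured$sd)
  (1 - p$w_injured) * ph + p$w_injured * pi_
}

# inverse-CDF sampling from a one-sided truncated normal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Create a lavage-injured alveolar-unit population
#'
#' Draws `n_units` units whose closing pressures follow the severity-scaled
#' mixture of [lung_population_params()] and whose opening pressures are the
#' closing pressures plus a positive offset. Unit size is scaled to body
#' weight: each unit carries `vmax_ml_per_kg * body_weight / n_units` ml of
#' gas capacity (Salazar-Knowles exponential PV curve,
#' `v = vmax * (1 - exp(-k * P))`) and a fixed tissue volume.
#'
#' @param severity injury severity in `[0, 1]`. At 0 every closing pressure
#'   is below 0 cm H2O (no derecruitment at ZEEP).
#' @param n_units number of alveolar units.
#' @param seed integer seed; populations are reproducible given the seed.
#' @param body_weight kg.
#' @param vmax_ml_per_kg total gas capacity per kg (ml/kg).
#' @param tissue_ml_per_kg total tissue volume per kg (ml/kg).
#' @param k PV curvature, 1/cm H2O (tangent compliance falls as
#'   `exp(-k * P)`: strain stiffening).
#' @param airway_resistance common series airway resistance, cm H2O.s/ml.
#' @return a `lung_units` tibble with one row per unit (`open_pressure`,
#'   `close_pressure`, `vmax`, `k`, `tissue`, `linear`) and the airway
#'   resistance as an attribute.
#' @export
make_injured_lung <- function(severity, n_units = 300L, seed,
                              body_weight = 27,
                              vmax_ml_per_kg = 45,
                              tissue_ml_per_kg = 16.7,
                              k = 0.06,
                              airway_resistance = 0.012) {
  if (n_units < 1) abort("`n_units` must be >= 1.", class = "oscillung_error_parameter")
  p <- lung_population_params(severity)
  units <- withr::with_seed(as.integer(seed), {
    injured <- runif(n_units) < p$w_injured
    pc <- numeric(n_units)
    pc[!injured] <- rtruncnorm(sum(!injured), p$healthy$mean, p$healthy$sd,
                               upper = p$healthy$upper)
    pc[injured] <- rnorm(sum(injured), p$injured$mean, p$injured$sd)
    delta <- rtruncnorm(n_units, p$delta$mean, p$delta$sd, lower = p$delta$lower)
    tibble::tibble(
      unit = seq_len(n_units),
      close_pressure = pc,
      open_pressure = pc + delta,
      vmax = vmax_ml_per_kg * body_weight / n_units,
      k = k,
      tissue = tissue_ml_per_kg * body_weight / n_units,
      linear = FALSE
    )
  })
  new_lung_units(units, airway_resistance = airway_resistance,
                 severity = severity)
}

#' Create a single-compartment linear lung
#'
#' All units are permanently open with a linear PV curve (`v = c * P`); the
#' population behaves as one resistance-compliance compartment with the
#' given total compliance. Used for analytic-limit checks: the equation of
#' motion and the 5 Hz impedance of this lung are known in closed form.
#'
#' @param resistance airway resistance, cm H2O.s/ml.
#' @param compliance total compliance, ml/cm H2O.
#' @param n_units number of (identical) units.
#' @param tissue_ml tissue volume per unit, ml.
#' @export
make_linear_lung <- function(resistance = 0.01, compliance = 20,
                             n_units = 50L, tissue_ml = 1.5) {
  units <- tibble::tibble(
    unit = seq_len(n_units),
    close_pressure = -Inf,
    open_pressure = -Inf,
    vmax = compliance / n_units, # slope = vmax * k with k = 1
    k = 1,
    tissue = tissue_ml,
    linear = TRUE
  )
  new_lung_units(units, airway_resistance = resistance, severity = 0)
}

new_lung_units <- function(units, airway_resistance, severity) {
  stopifnot(all(units$open_pressure >= units$close_pressure),
            all(units$vmax > 0), all(units$k > 0), all(units$tissue > 0),
            airway_resistance > 0)
  structure(units,
            airway_resistance = airway_resistance,
            severity = severity,
            class = c("lung_units", class(tibble::tibble())))
}

#' Hysteretic opening/closing rule for alveolar units
#'
#' A closed unit opens when pressure reaches its opening pressure; an open
#' unit closes when pressure falls to its closing pressure; between the two
#' the unit keeps its state (bistability, the source of PV hysteresis).
#'
#' @param lung a `lung_units` tibble.
#' @param pressure cm H2O (scalar or per-unit).
#' @param was_open logical, current state per unit.
#' @return logical vector of updated states.
#' @export
unit_state_update <- function(lung, pressure, was_open) {
  stopifnot(length(was_open) == nrow(lung))
  ifelse(was_open, pressure > lung$close_pressure,
         pressure >= lung$open_pressure)
}

#' Gas volume of open units
#'
#' Open units follow `v = vmax * (1 - exp(-k * P))` (or `v = vmax * k * P`
#' for linear units); closed units hold no gas. Negative pressures are
#' clamped to zero.
#'
#' @inheritParams unit_state_update
#' @param open logical, unit states (default all open).
#' @return numeric vector of per-unit gas volumes, ml.
#' @export
open_unit_volume <- function(lung, pressure, open = TRUE) {
  if (any(pressure < 0)) {
    warn("negative pressure clamped to 0 in `open_unit_volume()`")
    pressure <- pmax(pressure, 0)
  }
  open <- rep_len(open, nrow(lung))
  v <- ifelse(lung$linear,
              lung$vmax * lung$k * pressure,
              lung$vmax * (1 - exp(-lung$k * pressure)))
  ifelse(open, v, 0)
}

#' Ventilator settings
#'
#' Volume-controlled ventilation with constant inspiratory flow.
#'
#' @param tidal_volume_per_kg ml/kg (default 6, a protective tidal volume).
#' @param body_weight kg.
#' @param respiratory_rate breaths/min.
#' @param insp_fraction inspiratory duty cycle in `(0, 1)`.
#' @export
ventilator_settings <- function(tidal_volume_per_kg = 6, body_weight = 27,
                                respiratory_rate = 30, insp_fraction = 1 / 3) {
  if (tidal_volume_per_kg <= 0 || insp_fraction <= 0 || insp_fraction >= 1) {
    abort("invalid ventilator settings", class = "oscillung_error_parameter")
  }
  list(tidal_volume_per_kg = tidal_volume_per_kg, body_weight = body_weight,
       respiratory_rate = respiratory_rate, insp_fraction = insp_fraction,
       tidal_volume = tidal_volume_per_kg * body_weight)
}

#' Forced-oscillation settings
#'
#' @param frequency oscillation frequency, Hz.
#' @param amplitude_pp tracheal pressure oscillation, cm H2O peak-to-peak.
#' @param sample_rate Hz.
#' @export
fot_settings <- function(frequency = 5, amplitude_pp = 1.5, sample_rate = 200) {
  if (frequency >= sample_rate / 2 || amplitude_pp <= 0) {
    abort("invalid FOT settings", class = "oscillung_error_parameter")
  }
  list(frequency = frequency, amplitude_pp = amplitude_pp,
       sample_rate = sample_rate)
}

#' PEEP titration protocol
#'
#' PEEP rises from 0 to 24 cm H2O in steps of 4, then falls from 24 to 0 in
#' steps of 2. Each step ventilates a fixed number of breaths with an
#' inspiratory and an expiratory hold inserted at stated breaths (holds are
#' where end-inspiratory and end-expiratory values are read). Step duration
#' is deliberately desk-scale; pass more breaths per step to approach the
#' original 8-minute steps.
#'
#' @param incremental,decremental PEEP levels, cm H2O.
#' @param n_breaths breaths per step.
#' @param insp_hold_breath breath whose end-inspiration is extended into the
#'   inspiratory hold.
#' @param exp_hold_breath breath whose end-expiration is extended into the
#'   expiratory hold.
#' @param hold_s hold duration, s (must exceed two oscillation cycles).
#' @export
peep_protocol <- function(incremental = seq(0, 24, by = 4),
                          decremental = seq(24, 0, by = -2),
                          n_breaths = 13L, insp_hold_breath = 9L,
                          exp_hold_breath = 11L, hold_s = 10) {
  stopifnot(insp_hold_breath <= n_breaths, exp_hold_breath <= n_breaths,
            insp_hold_breath < exp_hold_breath, hold_s > 0)
  list(incremental = incremental, decremental = decremental,
       n_breaths = as.integer(n_breaths),
       insp_hold_breath = as.integer(insp_hold_breath),
       exp_hold_breath = as.integer(exp_hold_breath), hold_s = hold_s)
}

# sample-level plan for one full trial: modes, prescribed flows, PEEP and
# annotation/snapshot bookkeeping
build_plan <- function(vent, fot, protocol) {
  fs <- fot$sample_rate
  n_breath <- round(60 / vent$respiratory_rate * fs)
  n_insp <- round(vent$insp_fraction * n_breath)
  n_exp <- n_breath - n_insp
  n_hold <- round(protocol$hold_s * fs)
  if (n_hold <= 2 * fs / fot$frequency) {
    abort("hold duration must exceed two oscillation cycles",
          class = "oscillung_error_parameter")
  }
  # under trapezoidal gas accumulation a rectangular n-sample flow pulse
  # delivers (n - 1/2) * q * dt by end-inspiration
  q_insp <- vent$tidal_volume / ((n_insp - 0.5) / fs)

  steps <- tibble::tibble(
    peep = c(protocol$incremental, protocol$decremental),
    limb = rep(c("incremental", "decremental"),
               c(length(protocol$incremental), length(protocol$decremental)))
  )

  mode <- integer(0); qv <- numeric(0); pv <- numeric(0)
  ann <- list(); snaps <- list()
  pos <- 0L # samples emitted so far
  for (s in seq_len(nrow(steps))) {
    step_start <- pos
    ih <- NULL; eh <- NULL
    for (b in seq_len(protocol$n_breaths)) {
      mode <- c(mode, rep(0L, n_insp)); qv <- c(qv, rep(q_insp, n_insp))
      pos <- pos + n_insp
      if (b == protocol$insp_hold_breath) {
        ih <- c(pos, pos + n_hold)
        mode <- c(mode, rep(2L, n_hold)); qv <- c(qv, rep(0, n_hold))
        pos <- pos + n_hold
      }
      mode <- c(mode, rep(1L, n_exp)); qv <- c(qv, rep(0, n_exp))
      pos <- pos + n_exp
      if (b == protocol$exp_hold_breath) {
        eh <- c(pos, pos + n_hold)
        mode <- c(mode, rep(2L, n_hold)); qv <- c(qv, rep(0, n_hold))
        pos <- pos + n_hold
      }
    }
    pv <- c(pv, rep(steps$peep[s], pos - step_start))
    ann[[s]] <- tibble::tibble(
      label = c("peep_step", "insp_hold", "exp_hold"),
      start = c(step_start, ih[1], eh[1]),
      end = c(pos, ih[2], eh[2]),
      peep = steps$peep[s], limb = steps$limb[s]
    )
    # snapshots at hold midpoints: end-inspiration then end-expiration
    snaps[[s]] <- tibble::tibble(
      step = s,
      idx = c(round(mean(ih)), round(mean(eh))),
      phase = c("end_inspiration", "end_expiration"),
      peep = steps$peep[s], limb = steps$limb[s]
    )
  }
  ann <- dplyr::bind_rows(ann)
  snaps <- dplyr::bind_rows(snaps)
  list(mode = mode, qvent = qv, peep = pv, fs = fs,
       annotations = dplyr::mutate(ann,
                                   t_start_s = .data$start / fs,
                                   t_end_s = .data$end / fs),
       snapshots = snaps, steps = steps)
}

#' Simulate a full PEEP titration trial
#'
#' Drives the unit population through the incremental/decremental PEEP
#' protocol under volume-controlled ventilation with the 5 Hz oscillation
#' superimposed throughout (including holds). Inspiration delivers the tidal
#' volume at constant flow; expiration is passive (exponential-like decay to
#' PEEP through the expiratory resistance); holds clamp ventilatory flow to
#' zero. Tracheal pressure is `Palv + Raw * Vao` plus measurement noise.
#'
#' @param lung a `lung_units` population.
#' @param vent,fot,protocol settings from [ventilator_settings()],
#'   [fot_settings()], [peep_protocol()].
#' @param noise_sd length-2 numeric, additive Gaussian noise SD on tracheal
#'   pressure (cm H2O) and flow (ml/s).
#' @param seed integer seed for the measurement noise (the mechanical
#'   simulation itself is deterministic).
#' @param exp_resistance_extra additional expiratory-path resistance beyond
#'   the airway resistance, cm H2O.s/ml.
#' @param open_threshold end-expiratory open fraction defining the true
#'   open-lung PEEP on the decremental limb.
#' @param hu_noise_sd per-voxel HU noise of the exported CT phantoms.
#' @return a `lung_sim_trial` list: `waveforms` (tibble `t_s, ptr_cmH2O,
#'   vao_ml_s`), `annotations`, `phantoms` (long voxel tibble keyed by
#'   `peep, limb, phase`), `ground_truth` (`$steps` per-step open fractions
#'   and pressures, `$true_peep_ol`), plus the inputs.
#' @export
simulate_peep_trial <- function(lung,
                                vent = ventilator_settings(),
                                fot = fot_settings(),
                                protocol = peep_protocol(),
                                noise_sd = c(ptr = 0.05, vao = 2),
                                seed,
                                exp_resistance_extra = 0,
                                open_threshold = 0.97,
                                hu_noise_sd = 0) {
  stopifnot(inherits(lung, "lung_units"))
  plan <- build_plan(vent, fot, protocol)
  r_aw <- attr(lung, "airway_resistance")

  first_peep <- plan$peep[1]
  open0 <- lung$close_pressure < first_peep
  if (!any(open0)) open0[which.min(lung$open_pressure)] <- TRUE
  g0 <- sum(open_unit_volume(lung, first_peep, open0))

  sim <- sim_core(lung$open_pressure, lung$close_pressure, lung$vmax, lung$k,
                  as.integer(lung$linear), plan$mode, plan$qvent, plan$peep,
                  as.integer(open0), g0, r_aw, r_aw + exp_resistance_extra,
                  fot$frequency, fot$amplitude_pp, 1 / plan$fs,
                  plan$snapshots$idx)

  n <- length(plan$mode)
  noise <- withr::with_seed(as.integer(seed), {
    list(ptr = rnorm(n, 0, noise_sd[[1]]), vao = rnorm(n, 0, noise_sd[[2]]),
         hu = rnorm(nrow(lung) * nrow(plan$snapshots), 0, max(hu_noise_sd, 1e-12)))
  })

  waveforms <- tibble::tibble(
    t_s = (seq_len(n) - 1) / plan$fs,
    ptr_cmH2O = sim$ptr + noise$ptr,
    vao_ml_s = sim$vao + noise$vao
  )
  annotations <- plan$annotations[, c("t_start_s", "t_end_s", "label",
                                      "peep", "limb")]
  names(annotations)[4] <- "peep_cmH2O"

  snaps <- plan$snapshots
  gt_steps <- dplyr::mutate(snaps,
                            open_fraction = colMeans(sim$snap_open),
                            palv_cmH2O = sim$snap_palv,
                            gas_ml = sim$snap_gas) |>
    dplyr::select(-"idx") |>
    tidyr::pivot_wider(id_cols = c("step", "peep", "limb"),
                       names_from = "phase",
                       values_from = c("open_fraction", "palv_cmH2O", "gas_ml"))

  dec_ee <- dplyr::filter(gt_steps, .data$limb == "decremental")
  ok_lvls <- dec_ee$peep[dec_ee$open_fraction_end_expiration >= open_threshold]
  true_peep_ol <- if (length(ok_lvls)) min(ok_lvls) else max(dec_ee$peep)

  phantoms <- purrr::map(seq_len(nrow(snaps)), function(i) {
    ph <- export_ct_phantom(lung, sim$snap_open[, i] > 0, sim$snap_palv[i],
                            hu_noise = if (hu_noise_sd > 0)
                              noise$hu[((i - 1) * nrow(lung) + 1):(i * nrow(lung))]
                            else 0)
    dplyr::mutate(ph, peep_cmH2O = snaps$peep[i], limb = snaps$limb[i],
                  phase = snaps$phase[i], .before = 1)
  }) |> dplyr::bind_rows()

  structure(
    list(waveforms = waveforms, annotations = annotations,
         phantoms = phantoms,
         ground_truth = list(steps = gt_steps, true_peep_ol = true_peep_ol,
                             open_threshold = open_threshold),
         lung = lung, vent = vent, fot = fot, protocol = protocol,
         noise_sd = noise_sd, seed = seed),
    class = "lung_sim_trial")
}

#' @export
print.lung_sim_trial <- function(x, ...) {
  cat("<lung_sim_trial>\n")
  cat(sprintf("  %d units, %.0f s at %g Hz, %d PEEP steps (%d phantom pairs)\n",
              nrow(x$lung), max(x$waveforms$t_s), x$fot$sample_rate,
              nrow(x$ground_truth$steps), nrow(x$ground_truth$steps)))
  cat(sprintf("  true open-lung PEEP: %g cm H2O (open fraction >= %g)\n",
              x$ground_truth$true_peep_ol, x$ground_truth$open_threshold))
  invisible(x)
}

#' Export a CT phantom of the current unit states
#'
#' One voxel per unit: voxel volume is the unit's gas plus tissue volume and
#' the HU value encodes the gas fraction (`HU = -1000 * v_gas / (v_gas +
#' v_tiss)`), so a closed unit reads 0 HU (non-aerated) and a gas-only voxel
#' reads -1000 HU. HU are clipped to `[-1000, 100]` after optional noise.
#'
#' @param lung a `lung_units` population.
#' @param open logical unit states.
#' @param pressure alveolar pressure at the scan, cm H2O.
#' @param hu_noise numeric, per-voxel additive HU noise (scalar 0 for none).
#' @return tibble `voxel_id, hu, voxel_ml`.
#' @export
export_ct_phantom <- function(lung, open, pressure, hu_noise = 0) {
  v_gas <- open_unit_volume(lung, pressure, open)
  gas_frac <- v_gas / (v_gas + lung$tissue)
  hu <- pmin(pmax(-1000 * gas_frac + hu_noise, -1000), 100)
  tibble::tibble(voxel_id = lung$unit, hu = hu,
                 voxel_ml = v_gas + lung$tissue)
}
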