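# Per-animal and cohort orchestration: E_X5 / mechanics / CT curves versus
# PEEP by limb and phase, open-lung PEEP titration, cohort summaries.

#' Analyze one animal's PEEP titration trial
#'
#' Runs the full pipeline on one waveform record: sliding-window impedance
#' tracking, end-expiratory/end-inspiratory elastance from the holds,
#' equation-of-motion and SLICE mechanics on the breaths preceding each
#' inspiratory hold, CT aeration accounting per step (when phantoms are
#' given), and the PEEP titration on the decremental limb.
#'
#' @param waveforms tibble `t_s, ptr_cmH2O, vao_ml_s`.
#' @param annotations tibble `t_start_s, t_end_s, label, peep_cmH2O, limb`.
#' @param phantoms optional long voxel tibble with columns
#'   `peep_cmH2O, limb, phase, voxel_id, hu, voxel_ml`.
#' @param frequency oscillation frequency, Hz.
#' @param window_periods,hop_s,trend_order impedance-tracking settings
#'   (see [track_impedance()]).
#' @param initial_fraction initial part of each hold used for the
#'   end-expiratory/end-inspiratory averages.
#' @param n_eom_breaths breaths preceding the inspiratory hold pooled into
#'   the equation-of-motion and SLICE fits.
#' @param settle_s breaths starting within this many seconds of the PEEP
#'   change are excluded from the mechanics fits (the end-expiratory volume
#'   is still equilibrating there, which would distort pooled fits).
#' @param n_slices SLICE volume bins.
#' @return a `peep_trial` object: `$steps` (one row per PEEP step and limb),
#'   `$titration` (`peep_ol`, `peep_min_ei`, `peep_min_delta`),
#'   `$hold_samples`, `$estimates`.
#' @export
analyze_animal <- function(waveforms, annotations, phantoms = NULL,
                           frequency = 5, window_periods = 5, hop_s = 0.2,
                           trend_order = 2, initial_fraction = 1 / 3,
                           n_eom_breaths = 8, settle_s = 4, n_slices = 6) {
  estimates <- track_impedance(waveforms, frequency, window_periods, hop_s,
                               trend_order)
  holds <- extract_hold_values(estimates, annotations, initial_fraction)
  breaths <- segment_breaths(waveforms, annotations, f_osc = frequency)

  step_ann <- dplyr::filter(annotations, .data$label == "peep_step")
  if (nrow(step_ann) == 0) {
    abort("no peep_step annotations", class = "oscillung_error_data")
  }
  hold_ann <- dplyr::filter(annotations, .data$label == "insp_hold")

  mech <- purrr::pmap(step_ann, function(t_start_s, t_end_s, peep_cmH2O, limb, ...) {
    ih <- hold_ann[hold_ann$peep_cmH2O == peep_cmH2O & hold_ann$limb == limb, ]
    if (nrow(ih) != 1) {
      abort(sprintf("missing inspiratory hold at PEEP %g (%s)", peep_cmH2O, limb),
            class = "oscillung_error_data")
    }
    bb <- breaths[breaths$t0 >= t_start_s - 1e-9 &
                    breaths$t_end <= ih$t_start_s + 1e-9, ]
    settled <- bb[bb$t0 >= t_start_s + settle_s, ]
    if (nrow(settled) >= 2) bb <- settled
    if (nrow(bb) == 0) {
      abort(sprintf("no analysable breaths at PEEP %g (%s)", peep_cmH2O, limb),
            class = "oscillung_error_data")
    }
    bb <- utils::tail(bb, n_eom_breaths)
    eom <- fit_eom(bb)
    sl <- slice_analysis(bb, n_slices = n_slices)
    tibble::tibble(
      peep_cmH2O = peep_cmH2O, limb = limb,
      edyn = eom$edyn, rdyn = eom$rdyn, eep = eom$eep, rmse = eom$rmse,
      e_low = attr(sl, "e_low"), e_high = attr(sl, "e_high"),
      slice_valid = attr(sl, "valid"),
      slices = list(tibble::as_tibble(sl)),
      n_breaths = nrow(bb), vt_ml = mean(bb$vt_ml),
      mean_drift_ml = mean(abs(bb$drift_ml))
    )
  }) |> dplyr::bind_rows()

  hw <- holds |>
    tidyr::pivot_wider(names_from = "phase",
                       values_from = c("ex5", "rrs", "xrs", "n_windows")) |>
    dplyr::rename(ex5_ee = "ex5_end_expiration", ex5_ei = "ex5_end_inspiration",
                  rrs_ee = "rrs_end_expiration", rrs_ei = "rrs_end_inspiration") |>
    dplyr::select("peep_cmH2O", "limb", "ex5_ee", "ex5_ei", "rrs_ee", "rrs_ei")

  steps <- dplyr::left_join(hw, mech, by = c("peep_cmH2O", "limb"))

  if (!is.null(phantoms)) {
    ct <- phantoms |>
      dplyr::group_by(.data$peep_cmH2O, .data$limb, .data$phase) |>
      dplyr::group_modify(function(d, g) glance(compartment_volumes(d))) |>
      dplyr::ungroup() |>
      dplyr::select("peep_cmH2O", "limb", "phase", "vtiss_na_pct",
                    "vtiss_a_pct", "v_gas_ml", "v_tiss_ml") |>
      tidyr::pivot_wider(names_from = "phase",
                         values_from = c("vtiss_na_pct", "vtiss_a_pct",
                                         "v_gas_ml", "v_tiss_ml")) |>
      dplyr::rename(vtiss_na_ee = "vtiss_na_pct_end_expiration",
                    vtiss_na_ei = "vtiss_na_pct_end_inspiration",
                    vtiss_a_ee = "vtiss_a_pct_end_expiration",
                    vtiss_a_ei = "vtiss_a_pct_end_inspiration",
                    v_gas_ee = "v_gas_ml_end_expiration",
                    v_gas_ei = "v_gas_ml_end_inspiration",
                    v_tiss_ee = "v_tiss_ml_end_expiration",
                    v_tiss_ei = "v_tiss_ml_end_inspiration") |>
      dplyr::mutate(intratidal_recruitment = .data$vtiss_na_ee - .data$vtiss_na_ei)
    steps <- dplyr::left_join(steps, ct, by = c("peep_cmH2O", "limb"))
  }

  dec <- dplyr::filter(steps, .data$limb == "decremental")
  titration <- list(
    peep_ol = find_argmin_peep(
      dplyr::transmute(dec, peep = .data$peep_cmH2O, value = .data$ex5_ee)),
    peep_min_ei = find_argmin_peep(
      dplyr::transmute(dec, peep = .data$peep_cmH2O, value = .data$ex5_ei)),
    peep_min_delta = find_argmin_peep(
      dplyr::transmute(dec, peep = .data$peep_cmH2O,
                       value = .data$ex5_ei - .data$ex5_ee))
  )

  structure(list(steps = steps, titration = titration,
                 hold_samples = holds, estimates = estimates),
            class = "peep_trial")
}

#' @export
print.peep_trial <- function(x, ...) {
  cat("<peep_trial>\n")
  cat(sprintf("  %d PEEP steps (%d decremental)\n", nrow(x$steps),
              sum(x$steps$limb == "decremental")))
  cat(sprintf("  PEEPol %g, min EI %g, min (EI - EE) %g cm H2O\n",
              x$titration$peep_ol, x$titration$peep_min_ei,
              x$titration$peep_min_delta))
  invisible(x)
}

#' @export
tidy.peep_trial <- function(x, ...) dplyr::select(x$steps, -dplyr::any_of("slices"))

#' @export
glance.peep_trial <- function(x, ...) {
  tibble::tibble(peep_ol = x$titration$peep_ol,
                 peep_min_ei = x$titration$peep_min_ei,
                 peep_min_delta = x$titration$peep_min_delta,
                 n_steps = nrow(x$steps))
}

#' PEEP of the minimum of a curve
#'
#' Returns the PEEP at which `value` is minimal; ties are broken toward the
#' lower PEEP (the lowest pressure achieving the minimum is preferred).
#' `NA` values are excluded.
#'
#' @param curve tibble with columns `peep` and `value`.
#' @param tie `"lower"` or `"higher"`.
#' @return PEEP, cm H2O.
#' @export
find_argmin_peep <- function(curve, tie = c("lower", "higher")) {
  tie <- match.arg(tie)
  curve <- curve[is.finite(curve$value), ]
  if (nrow(curve) == 0) {
    abort("no finite values in curve", class = "oscillung_error_data")
  }
  best <- curve$peep[curve$value == min(curve$value)]
  if (tie == "lower") min(best) else max(best)
}

#' Intra-tidal elastance difference curve
#'
#' Per PEEP step on the requested limb, the end-inspiratory minus
#' end-expiratory oscillatory elastance — an index of the cyclic stress
#' applied to the aerated tissue.
#'
#' @param steps `$steps` tibble of a `peep_trial` (or the object itself).
#' @param limb `"decremental"` or `"incremental"`.
#' @return tibble `peep_cmH2O, delta_ex5`.
#' @export
delta_ex5_curve <- function(steps, limb = "decremental") {
  if (inherits(steps, "peep_trial")) steps <- steps$steps
  steps |>
    dplyr::filter(.data$limb == !!limb) |>
    dplyr::transmute(peep_cmH2O = .data$peep_cmH2O,
                     delta_ex5 = .data$ex5_ei - .data$ex5_ee)
}

#' Cohort summary across animals
#'
#' Mean and SD per PEEP step, limb and phase for elastance, resistance and
#' the CT indices, plus the per-animal titration table and the cohort
#' open-lung PEEP.
#'
#' @param results list of `peep_trial` objects (one per animal).
#' @return list with `curves` (long tibble `peep_cmH2O, limb, phase, metric,
#'   mean, sd, n`), `titration` (per animal) and `peep_ol` (`mean`, `sd`).
#' @export
cohort_summary <- function(results) {
  stopifnot(length(results) >= 1, all(purrr::map_lgl(results, inherits, "peep_trial")))
  grids <- purrr::map(results, ~ paste(.x$steps$peep_cmH2O, .x$steps$limb))
  ref <- sort(grids[[1]])
  bad <- which(purrr::map_lgl(grids, ~ !identical(sort(.x), ref)))
  if (length(bad)) {
    abort(paste0("PEEP grid mismatch for animal(s): ", paste(bad, collapse = ", ")),
          class = "oscillung_error_data")
  }

  long <- purrr::imap(results, function(r, i) {
    r$steps |>
      dplyr::select(dplyr::any_of(c("peep_cmH2O", "limb", "ex5_ee", "ex5_ei",
                                    "rrs_ee", "rrs_ei", "vtiss_na_ee",
                                    "vtiss_na_ei", "v_gas_ee", "v_gas_ei"))) |>
      tidyr::pivot_longer(-c("peep_cmH2O", "limb"),
                          names_to = c("metric", "phase"),
                          names_pattern = "(.*)_(ee|ei)$") |>
      dplyr::mutate(animal = i)
  }) |> dplyr::bind_rows()

  curves <- long |>
    dplyr::group_by(.data$peep_cmH2O, .data$limb, .data$metric, .data$phase) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
                     n = dplyr::n(), .groups = "drop")

  titration <- purrr::imap(results, function(r, i) {
    dplyr::mutate(glance(r), animal = i, .before = 1)
  }) |> dplyr::bind_rows()

  list(curves = curves, titration = titration,
       peep_ol = list(mean = mean(titration$peep_ol),
                      sd = if (nrow(titration) > 1) sd(titration$peep_ol) else 0))
}

#' Simulate and analyze a synthetic cohort
#'
#' Convenience wrapper: builds `n_animals` injured lungs (one seed each,
#' derived from `seed`), simulates the full PEEP protocol and analyses each
#' animal, returning the per-animal results, the cohort summary and the
#' ground-truth recovery table.
#'
#' @param n_animals number of animals.
#' @param seed base integer seed.
#' @param severity injury severity passed to [make_injured_lung()].
#' @param n_units units per lung.
#' @param ... further arguments to [simulate_peep_trial()].
#' @return list with `trials`, `results`, `summary` and `recovery`
#'   (per-animal estimated vs true open-lung PEEP).
#' @export
run_cohort <- function(n_animals = 6, seed = 1, severity = 0.8,
                       n_units = 300L, ...) {
  seed <- as.integer(seed)
  sims <- purrr::map(seq_len(n_animals), function(i) {
    lung <- make_injured_lung(severity, n_units = n_units,
                              seed = seed + 7919L * i)
    simulate_peep_trial(lung, seed = seed + 7919L * i + 104729L, ...)
  })
  results <- purrr::map(sims, function(s) {
    analyze_animal(s$waveforms, s$annotations, s$phantoms)
  })
  recovery <- purrr::imap(results, function(r, i) {
    tibble::tibble(animal = i, peep_ol = r$titration$peep_ol,
                   true_peep_ol = sims[[i]]$ground_truth$true_peep_ol)
  }) |> dplyr::bind_rows()
  list(trials = sims, results = results, summary = cohort_summary(results),
       recovery = recovery)
}
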