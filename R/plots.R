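# ggplot2 displays of titration results.

#' Plot PEEP-titration curves
#'
#' One panel per metric (oscillatory elastance, resistance and — when CT
#' phantoms were analysed — non-aerated tissue percentage and gas volume),
#' PEEP on the x axis, end-expiration and end-inspiration as separate
#' series, incremental and decremental limbs distinguished by linetype.
#'
#' @param object a `peep_trial`.
#' @param metrics metrics to show (subset of `ex5`, `rrs`, `vtiss_na`, `v_gas`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.peep_trial <- function(object, metrics = c("ex5", "rrs", "vtiss_na",
                                                    "v_gas"), ...) {
  steps <- object$steps
  cols <- intersect(paste0(rep(metrics, each = 2), c("_ee", "_ei")), names(steps))
  long <- steps |>
    dplyr::select(dplyr::all_of(c("peep_cmH2O", "limb", cols))) |>
    tidyr::pivot_longer(dplyr::all_of(cols),
                        names_to = c("metric", "phase"),
                        names_pattern = "(.*)_(ee|ei)$") |>
    dplyr::mutate(phase = ifelse(.data$phase == "ee", "end-expiration",
                                 "end-inspiration"))
  ggplot2::ggplot(long, ggplot2::aes(.data$peep_cmH2O, .data$value,
                                     colour = .data$phase,
                                     linetype = .data$limb)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "PEEP (cm H2O)", y = NULL, colour = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Elastance-pressure loop
#'
#' Oscillatory elastance against the airway pressure at which it was read
#' (PEEP at end-expiration, plateau at end-inspiration), connecting the two
#' phases of each step — the divergence of the end-inspiratory and
#' end-expiratory branches below the open-lung pressure marks
#' recruitment/derecruitment.
#'
#' @param object a `peep_trial` (the steps must carry `eep`; the plateau is
#'   approximated as `eep + (ex5-weighted) tidal rise` when no hold pressure
#'   is stored, so this plot uses the per-step `eep` and `peep`).
#' @param limb limb to display.
#' @return a ggplot.
#' @export
plot_ex5_pressure_loop <- function(object, limb = "decremental") {
  steps <- dplyr::filter(object$steps, .data$limb == !!limb)
  ee <- dplyr::transmute(steps, pressure = .data$peep_cmH2O,
                         ex5 = .data$ex5_ee, phase = "end-expiration",
                         step = .data$peep_cmH2O)
  # end-inspiratory points sit at the plateau pressure reached by the tidal
  # volume: approximate from the equation-of-motion fit
  ei <- dplyr::transmute(steps,
                         pressure = .data$eep + .data$edyn * .data$vt_ml,
                         ex5 = .data$ex5_ei, phase = "end-inspiration",
                         step = .data$peep_cmH2O)
  long <- dplyr::bind_rows(ee, ei)
  ggplot2::ggplot(long, ggplot2::aes(.data$pressure, .data$ex5)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$step), linetype = 3,
                       colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$phase)) +
    ggplot2::labs(x = "Pressure (cm H2O)", y = "Oscillatory elastance (cm H2O/ml)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cohort mean curves
#'
#' Mean with SD ribbon per PEEP, limb and phase for a chosen metric.
#'
#' @param summary output of [cohort_summary()].
#' @param metric one of the metrics present in `summary$curves`.
#' @return a ggplot.
#' @export
plot_cohort_curves <- function(summary, metric = "ex5") {
  d <- dplyr::filter(summary$curves, .data$metric == !!metric)
  ggplot2::ggplot(d, ggplot2::aes(.data$peep_cmH2O, .data$mean,
                                  colour = .data$phase,
                                  linetype = .data$limb)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$phase),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "PEEP (cm H2O)", y = metric, colour = NULL,
                  fill = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
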