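# File dialects: waveform/annotation/phantom CSVs with units embedded in the
# column names, YAML run configuration, and deterministic test fixtures.

wf_cols <- c("t_s", "ptr_cmH2O", "vao_ml_s")
ann_cols <- c("t_start_s", "t_end_s", "label", "peep_cmH2O", "limb")
ph_cols <- c("voxel_id", "hu", "voxel_ml")

check_columns <- function(d, required, what) {
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    # a near-miss on a unit-bearing name is a unit error, not a missing column
    stems <- sub("_.*$", "", missing)
    near <- purrr::map_lgl(stems, function(s) any(startsWith(names(d), paste0(s, "_"))))
    if (any(near)) {
      abort(sprintf("%s: unit mismatch in column(s) %s (expected %s)",
                    what, paste(names(d)[startsWith(names(d), paste0(stems[near][1], "_"))],
                                collapse = ", "),
                    paste(missing[near], collapse = ", ")),
            class = "oscillung_error_units")
    }
    abort(sprintf("%s: missing column(s) %s", what, paste(missing, collapse = ", ")),
          class = "oscillung_error_format")
  }
  invisible(d)
}

#' Read and write waveform records
#'
#' Canonical CSV dialect `t_s, ptr_cmH2O, vao_ml_s` (units embedded in the
#' names to prevent silent litre/millilitre mix-ups). Reading verifies the
#' sampling grid is uniform (jitter below 1 microsecond) and all values are
#' finite.
#'
#' @param path file path.
#' @return tibble `t_s, ptr_cmH2O, vao_ml_s`.
#' @export
read_waveforms <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(d, wf_cols, "waveform file")
  d <- d[, wf_cols]
  bad <- which(!is.finite(d$ptr_cmH2O) | !is.finite(d$vao_ml_s) | !is.finite(d$t_s))
  if (length(bad)) {
    abort(sprintf("non-finite values at row(s) %s",
                  paste(utils::head(bad, 5), collapse = ", ")),
          class = "oscillung_error_data")
  }
  dt <- diff(d$t_s)
  if (length(dt) && diff(range(dt)) > 1e-6) {
    j <- which.max(abs(dt - stats::median(dt)))
    abort(sprintf("non-uniform sampling near row %d", j + 1),
          class = "oscillung_error_sampling")
  }
  d
}

#' @rdname read_waveforms
#' @param waveforms tibble to write.
#' @export
write_waveforms <- function(waveforms, path) {
  check_columns(waveforms, wf_cols, "waveform tibble")
  readr::write_csv(waveforms[, wf_cols], path)
  invisible(path)
}

#' Read and write protocol annotations
#'
#' Sidecar CSV `t_start_s, t_end_s, label, peep_cmH2O, limb` marking PEEP
#' steps and the inspiratory/expiratory holds.
#'
#' @param path file path.
#' @export
read_annotations <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(d, ann_cols, "annotation file")
  d[, ann_cols]
}

#' @rdname read_annotations
#' @param annotations tibble to write.
#' @export
write_annotations <- function(annotations, path) {
  check_columns(annotations, ann_cols, "annotation tibble")
  readr::write_csv(annotations[, ann_cols], path)
  invisible(path)
}

#' Read and write CT phantom voxel tables
#'
#' CSV `voxel_id, hu, voxel_ml`; long phantom tables carrying additional
#' keys (`peep_cmH2O, limb, phase`) round-trip too.
#'
#' @param path file path.
#' @export
read_phantom <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(d, ph_cols, "phantom file")
  d
}

#' @rdname read_phantom
#' @param phantom tibble to write.
#' @export
write_phantom <- function(phantom, path) {
  check_columns(phantom, ph_cols, "phantom tibble")
  readr::write_csv(phantom, path)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Validates top-level keys against the known schema and requires a `seed`.
#' Returns the settings objects ready to pass to [simulate_peep_trial()].
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("lung", "ventilator", "fot", "protocol", "noise_sd", "seed", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")),
          class = "oscillung_error_config")
  }
  if (is.null(cfg$seed)) {
    abort("`seed` is mandatory in the run configuration",
          class = "oscillung_error_config")
  }
  lung_args <- cfg$lung %||% list(severity = 0.8, n_units = 300L)
  lung_args$seed <- lung_args$seed %||% cfg$seed
  list(
    lung = do.call(make_injured_lung, lung_args),
    vent = do.call(ventilator_settings, cfg$ventilator %||% list()),
    fot = do.call(fot_settings, cfg$fot %||% list()),
    protocol = do.call(peep_protocol, cfg$protocol %||% list()),
    noise_sd = unlist(cfg$noise_sd %||% c(ptr = 0.05, vao = 2)),
    seed = cfg$seed,
    output = cfg$output
  )
}

#' Deterministic test fixtures
#'
#' Small, seeded datasets used by the test-suite and examples:
#' `linear_lung` (a single-compartment R-C trial whose mechanics are known
#' exactly), `injured_lung` (a short severe-injury trial), `ct_toy` (a
#' four-voxel volume with a hand-computable aeration report) and
#' `hold_only` (a pure-oscillation expiratory hold of an R-C system).
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @param dir optional directory; when given, the fixture files are written
#'   there (waveforms/annotations/phantom CSVs).
#' @return a list of fixture objects (invisible file paths written when
#'   `dir` is given are attached as `$paths`).
#' @export
make_fixture <- function(name = c("linear_lung", "injured_lung", "ct_toy",
                                  "hold_only"), seed = 1, dir = NULL) {
  name <- match.arg(name)
  fx <- switch(
    name,
    linear_lung = {
      lung <- make_linear_lung(resistance = 0.01, compliance = 20)
      sim <- simulate_peep_trial(
        lung,
        vent = ventilator_settings(respiratory_rate = 20, insp_fraction = 0.25),
        protocol = peep_protocol(incremental = numeric(0), decremental = 12,
                                 n_breaths = 7L, insp_hold_breath = 5L,
                                 exp_hold_breath = 6L, hold_s = 2),
        noise_sd = c(ptr = 0, vao = 0), seed = seed)
      c(sim, list(params = list(resistance = 0.01, compliance = 20, peep = 12)))
    },
    injured_lung = {
      lung <- make_injured_lung(0.8, n_units = 120L, seed = seed)
      sim <- simulate_peep_trial(
        lung,
        protocol = peep_protocol(incremental = c(0, 12, 24),
                                 decremental = c(24, 12, 0),
                                 n_breaths = 5L, insp_hold_breath = 3L,
                                 exp_hold_breath = 4L, hold_s = 2),
        seed = seed + 1L)
      sim
    },
    ct_toy = list(
      phantom = tibble::tibble(voxel_id = 1:4,
                               hu = c(-950, -700, -300, 0),
                               voxel_ml = 1),
      expected_vtiss_na_pct = 100 * 1.0 / (0.05 + 0.3 + 0.7 + 1.0)
    ),
    hold_only = {
      fs <- 200; f <- 5; dur <- 3
      t <- seq(0, dur - 1 / fs, by = 1 / fs)
      R <- 0.01; C <- 20; w <- 2 * pi * f
      q <- 50 * sin(w * t)
      # series R-C driven by a flow source: P = R q + (1/C) int q
      p <- 12 + R * q - 50 / (w * C) * cos(w * t)
      list(
        waveforms = tibble::tibble(t_s = t, ptr_cmH2O = p, vao_ml_s = q),
        annotations = tibble::tibble(t_start_s = 0, t_end_s = dur,
                                     label = "exp_hold", peep_cmH2O = 12,
                                     limb = "decremental"),
        params = list(resistance = R, compliance = C)
      )
    })

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    if (!is.null(fx$waveforms)) {
      paths["waveforms"] <- file.path(dir, paste0(name, "_waveforms.csv"))
      write_waveforms(fx$waveforms, paths["waveforms"])
    }
    if (!is.null(fx$annotations)) {
      paths["annotations"] <- file.path(dir, paste0(name, "_annotations.csv"))
      write_annotations(fx$annotations, paths["annotations"])
    }
    if (!is.null(fx$phantoms %||% fx$phantom)) {
      paths["phantom"] <- file.path(dir, paste0(name, "_phantom.csv"))
      write_phantom(fx$phantoms %||% fx$phantom, paths["phantom"])
    }
    fx$paths <- paths
  }
  fx
}
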