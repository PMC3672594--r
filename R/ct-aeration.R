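# CT aeration compartments: HU classification, gas/tissue decomposition,
# and intra-tidal recruitment quantification.

aeration_levels <- c("OA", "NORM", "PA", "NA")

#' Classify voxels into aeration compartments
#'
#' Standard Hounsfield-unit compartments: over-aerated `[-1000, -900)`,
#' normally aerated `[-900, -500)`, poorly aerated `[-500, -100)` and
#' non-aerated `[-100, +100]` (intervals half-open at the upper edge).
#' Voxels outside `[-1000, +100]` are excluded (`NA_character_`) and their
#' count reported with a message.
#'
#' @param hu numeric HU values.
#' @return character vector with levels `OA`, `NORM`, `PA`, `NA`.
#' @export
classify_aeration <- function(hu) {
  out <- dplyr::case_when(
    hu >= -1000 & hu < -900 ~ "OA",
    hu >= -900 & hu < -500 ~ "NORM",
    hu >= -500 & hu < -100 ~ "PA",
    hu >= -100 & hu <= 100 ~ "NA",
    TRUE ~ NA_character_
  )
  n_out <- sum(is.na(out) & !is.na(hu))
  if (n_out > 0) {
    inform(sprintf("%d voxel(s) outside [-1000, 100] HU excluded from the lung", n_out))
  }
  out
}

#' Gas and tissue volume of voxels
#'
#' The gas fraction of a voxel is `-HU / 1000` (air reads -1000 HU, water 0),
#' with HU clamped to `[-1000, 0]` so denser-than-water voxels count as pure
#' tissue. `v_gas = gas_fraction * voxel_volume`, `v_tiss` the remainder.
#'
#' @param hu numeric HU values.
#' @param voxel_ml voxel volume(s), ml.
#' @return tibble `v_gas, v_tiss` (ml).
#' @export
voxel_gas_tissue <- function(hu, voxel_ml) {
  gas_frac <- pmin(pmax(-hu, 0), 1000) / 1000
  tibble::tibble(v_gas = gas_frac * voxel_ml,
                 v_tiss = (1 - gas_frac) * voxel_ml)
}

#' Aeration-compartment accounting for one scan
#'
#' Classifies each masked voxel, splits it into gas and tissue and
#' accumulates per-compartment and whole-lung volumes. Reports the
#' derecruitment index `VtissNA%` (tissue in the non-aerated compartment as
#' a percentage of total tissue) and its aerated counterpart `VtissA%`
#' (OA + NORM).
#'
#' @param voxels tibble with columns `hu`, `voxel_ml` and optionally a
#'   logical `mask` (defaults to all in-lung).
#' @return an `aeration_report`: `$compartments` tibble
#'   (`compartment, volume_ml, v_gas_ml, v_tiss_ml`), whole-lung
#'   `volume_ml`, `v_gas_ml`, `v_tiss_ml`, `vtiss_na_pct`, `vtiss_a_pct`,
#'   `n_excluded`.
#' @export
compartment_volumes <- function(voxels) {
  stopifnot(all(c("hu", "voxel_ml") %in% names(voxels)))
  if ("mask" %in% names(voxels)) voxels <- voxels[voxels$mask, ]
  if (nrow(voxels) == 0) {
    abort("empty lung mask", class = "oscillung_error_data")
  }
  cls <- classify_aeration(voxels$hu)
  keep <- !is.na(cls)
  gt <- voxel_gas_tissue(voxels$hu[keep], voxels$voxel_ml[keep])
  comp <- tibble::tibble(compartment = factor(cls[keep], levels = aeration_levels),
                         voxel_ml = voxels$voxel_ml[keep],
                         v_gas = gt$v_gas, v_tiss = gt$v_tiss) |>
    dplyr::group_by(.data$compartment, .drop = FALSE) |>
    dplyr::summarise(volume_ml = sum(.data$voxel_ml),
                     v_gas_ml = sum(.data$v_gas),
                     v_tiss_ml = sum(.data$v_tiss), .groups = "drop") |>
    dplyr::mutate(compartment = as.character(.data$compartment))

  v_tiss_total <- sum(comp$v_tiss_ml)
  na_tiss <- comp$v_tiss_ml[comp$compartment == "NA"]
  aer_tiss <- sum(comp$v_tiss_ml[comp$compartment %in% c("OA", "NORM")])
  structure(
    list(compartments = comp,
         volume_ml = sum(comp$volume_ml),
         v_gas_ml = sum(comp$v_gas_ml),
         v_tiss_ml = v_tiss_total,
         vtiss_na_pct = 100 * na_tiss / v_tiss_total,
         vtiss_a_pct = 100 * aer_tiss / v_tiss_total,
         n_excluded = sum(!keep)),
    class = "aeration_report")
}

#' @export
print.aeration_report <- function(x, ...) {
  cat(sprintf("<aeration_report> %.1f ml lung (gas %.1f, tissue %.1f); VtissNA%% = %.2f\n",
              x$volume_ml, x$v_gas_ml, x$v_tiss_ml, x$vtiss_na_pct))
  print(x$compartments)
  invisible(x)
}

#' @export
tidy.aeration_report <- function(x, ...) x$compartments

#' @export
glance.aeration_report <- function(x, ...) {
  tibble::tibble(volume_ml = x$volume_ml, v_gas_ml = x$v_gas_ml,
                 v_tiss_ml = x$v_tiss_ml, vtiss_na_pct = x$vtiss_na_pct,
                 vtiss_a_pct = x$vtiss_a_pct, n_excluded = x$n_excluded)
}

#' Intra-tidal recruitment/derecruitment from paired scans
#'
#' The difference between end-expiratory and end-inspiratory `VtissNA%`:
#' positive values mean tissue that is non-aerated at end-expiration becomes
#' aerated at end-inspiration (tidal recruitment).
#'
#' @param ee,ei `aeration_report`s at end-expiration and end-inspiration of
#'   the same lung.
#' @return difference in percentage points.
#' @export
intratidal_recruitment <- function(ee, ei) {
  stopifnot(inherits(ee, "aeration_report"), inherits(ei, "aeration_report"))
  if (abs(ee$v_tiss_ml - ei$v_tiss_ml) > 0.05 * ee$v_tiss_ml) {
    warn("end-expiratory and end-inspiratory tissue volumes differ by more than 5%")
  }
  ee$vtiss_na_pct - ei$vtiss_na_pct
}
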