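#' Control-to-sample bioburden fraction
#'
#' Expresses a control's bioburden measurement (cell count, CFU count, DNA
#' concentration) as a percentage of the corresponding environmental
#' measurement. The quantity is scale-invariant, so values can be entered
#' in any common unit (e.g. both as x 10^4 cells/mL).
#'
#' @param control_value Measurement in the background control (>= 0).
#' @param reference_value Measurement in the environmental sample (> 0).
#' @return The percentage `100 * control / reference` (unrounded; round to
#'   one decimal for display). Vectorised over both arguments.
#' @examples
#' control_fraction(0.3e4, 36e4) # 0.833... -> prints as 0.8%
#' control_fraction(0.3e4, 3.4e4) # 8.82... -> prints as 8.8%
#' @export
control_fraction <- function(control_value, reference_value) {
  if (any(!is.finite(reference_value)) || any(reference_value <= 0)) {
    rlang::abort("`reference_value` must be > 0 (ratio undefined otherwise).",
                 class = "cryoclean_undefined_ratio_error")
  }
  if (any(control_value < 0)) {
    abort_format("`control_value` must be >= 0.")
  }
  100 * control_value / reference_value
}

#' Flag measurements below a detection limit
#'
#' Fluorometric DNA quantification has a hard detection limit (0.01 ng/uL
#' = 10 pg/uL for the high-sensitivity assay); a measurement below it, or a
#' reported "DL" token (entered as `NA`), carries no numeric value.
#' Quantified values pass through unmodified.
#'
#' @param value Numeric vector of concentrations (ng/uL); `NA` means the
#'   instrument reported below-detection.
#' @param limit Detection limit in the same units (> 0).
#' @return A tibble with columns `value` (NA where below detection) and
#'   `below_detection`.
#' @examples
#' flag_below_detection(c(0.9, 0.009, NA))
#' @export
flag_below_detection <- function(value, limit = 0.01) {
  stopifnot(is.numeric(limit), length(limit) == 1L, limit > 0)
  if (any(!is.na(value) & value < 0)) {
    abort_format("negative concentration is not a valid measurement.")
  }
  below <- is.na(value) | value < limit
  tibble::tibble(
    value = ifelse(below, NA_real_, value),
    below_detection = below
  )
}

#' Total CFU over a plate-count time series
#'
#' Plates read repeatedly over an incubation (here: every 5 days for 30
#' days) yield newly counted colonies per interval; the series total is
#' their sum. Dispersions are combined in quadrature (a documented
#' convention for independent per-interval counts, not a claim about the
#' original assay).
#'
#' @param series A data frame with columns `day` (strictly increasing),
#'   `cfu_per_ml` (per-interval mean) and optionally `dispersion`.
#' @return A one-row tibble with `total_cfu_per_ml`, `dispersion` and
#'   `n_timepoints`.
#' @examples
#' cfu <- seaice_cfu()
#' cfu_totals(cfu[cfu$sample_group == "processing_control", ])
#' @export
cfu_totals <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("day", "cfu_per_ml") %in% names(series)))
  if (anyDuplicated(series$day)) {
    abort_format("duplicate observation day in CFU series.")
  }
  if (is.unsorted(series$day, strictly = TRUE)) {
    abort_format("CFU observation days must be strictly increasing.")
  }
  if (any(series$cfu_per_ml < 0, na.rm = TRUE)) {
    abort_format("CFU/mL must be >= 0.")
  }
  disp <- if ("dispersion" %in% names(series)) series$dispersion else
    rep(0, nrow(series))
  tibble::tibble(
    total_cfu_per_ml = sum(series$cfu_per_ml),
    dispersion = sqrt(sum(disp^2, na.rm = TRUE)),
    n_timepoints = nrow(series)
  )
}

#' Bioburden report for a monitoring run
#'
#' Convenience wrapper assembling the culture, flow-cytometry and DNA
#' summaries of a monitoring study into one list: CFU totals per sample
#' group, control-to-sample cell-count fractions, and detection-limit
#' flagged DNA concentrations.
#'
#' @param cfu Long tibble as [seaice_cfu()] (`sample_group`, `day`,
#'   `cfu_per_ml`, `dispersion`).
#' @param cells Tibble as [seaice_cells()] (`sample_group`,
#'   `cells_per_ml`).
#' @param dna Tibble as [seaice_dna()] (`sample_id`, `dna_ng_per_ul`).
#' @param control_group Name of the control group in `cfu`/`cells`.
#' @param detection_limit DNA detection limit (ng/uL).
#' @return A list with `cfu_totals`, `cell_fractions` and `dna` tibbles.
#' @examples
#' rep <- bioburden_report(seaice_cfu(), seaice_cells(), seaice_dna())
#' rep$cell_fractions
#' @export
bioburden_report <- function(cfu, cells, dna,
                             control_group = "processing_control",
                             detection_limit = 0.01) {
  totals <- cfu |>
    dplyr::group_by(.data$sample_group) |>
    dplyr::group_modify(~ cfu_totals(.x)) |>
    dplyr::ungroup()
  ctrl <- cells$cells_per_ml[cells$sample_group == control_group]
  refs <- cells[cells$sample_group != control_group, , drop = FALSE]
  fractions <- tibble::tibble(
    reference_group = refs$sample_group,
    control_cells_per_ml = ctrl,
    reference_cells_per_ml = refs$cells_per_ml,
    control_pct = control_fraction(ctrl, refs$cells_per_ml)
  )
  flagged <- flag_below_detection(dna$dna_ng_per_ul, detection_limit)
  dna_out <- dna
  dna_out$dna_ng_per_ul <- flagged$value
  dna_out$below_detection <- flagged$below_detection
  list(cfu_totals = totals, cell_fractions = fractions, dna = dna_out)
}
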