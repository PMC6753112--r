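# ECG LVH indices, ECG LV mass, CMR mass/volume indices, chest geometry.

#' Body surface area
#'
#' Du Bois: `0.007184 * weight^0.425 * (height_cm)^0.725`; Mosteller:
#' `sqrt(height_cm * weight / 3600)`.
#'
#' @param height Height in metres.
#' @param weight Weight in kg.
#' @param formula `"dubois"` (default) or `"mosteller"`.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(height, weight,
                              formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  hcm <- height * 100
  switch(formula,
         dubois = 0.007184 * weight^0.425 * hcm^0.725,
         mosteller = sqrt(hcm * weight / 3600))
}

#' ECG voltage indices of LV hypertrophy
#'
#' Sokolow-Lyon voltage is `SV1 + RV5`; Cornell voltage is `RaVL + SV3` in
#' men with 0.6 voltage units added in women; the duration products multiply
#' each index by the QRS duration in ms. The 12-lead sum adds the
#' peak-to-nadir QRS amplitudes over all 12 leads (Siegel-Roberts
#' measurement), with its own duration product. Rows with a missing required
#' lead get `NA` indices (the record is unphenotyped, not an error),
#' mirroring exclusions for bundle branch block and similar.
#'
#' @param data Tibble with columns `sv1`, `rv5`, `ravl`, `sv3`,
#'   `qrs_duration`, `sex` (1 = male, 2 = female), and optionally the twelve
#'   `amp_*` per-lead amplitude columns.
#' @return The input with `sokolow_lyon`, `cornell`, `sokolow_lyon_product`,
#'   `cornell_product`, `twelve_lead_sum`, `twelve_lead_sum_product` added.
#' @export
ecg_voltage_indices <- function(data) {
  stopifnot(all(c("sv1", "rv5", "ravl", "sv3", "qrs_duration", "sex") %in%
                  names(data)))
  out <- dplyr::mutate(
    data,
    sokolow_lyon = .data$sv1 + .data$rv5,
    cornell = .data$ravl + .data$sv3 + ifelse(.data$sex == 2L, 0.6, 0),
    sokolow_lyon_product = .data$sokolow_lyon * .data$qrs_duration,
    cornell_product = .data$cornell * .data$qrs_duration
  )
  lead_cols <- grep("^amp_", names(data), value = TRUE)
  if (length(lead_cols) == 12L) {
    ls <- rowSums(as.matrix(data[lead_cols]))
    out$twelve_lead_sum <- ls
    out$twelve_lead_sum_product <- ls * data$qrs_duration
  }
  out
}

#' ECG-estimated left ventricular mass
#'
#' Sex-specific linear prediction from the Cornell-lead voltage sum and body
#' weight: `0.026 * (RaVL + SV3) + 1.25 * weight + 34.4` (men) and
#' `0.020 * (RaVL + SV3) + 1.12 * weight + 36.2` (women). The voltage sum is
#' multiplied by `voltage_scale` before entering the equation because the
#' published coefficients' voltage unit is ambiguous relative to
#' millivolt-scale lead sums (see the methods vignette).
#'
#' @param data Tibble with `ravl`, `sv3`, `weight`, `sex`.
#' @param voltage_scale Positive rescaling of the voltage sum (default 1.0).
#' @return Input with an `ecg_lvm` column (grams) added.
#' @export
ecg_lvm <- function(data, voltage_scale = 1.0) {
  stopifnot(voltage_scale > 0,
            all(c("ravl", "sv3", "weight", "sex") %in% names(data)))
  v <- (data$ravl + data$sv3) * voltage_scale
  data$ecg_lvm <- ifelse(data$sex == 1L,
                         0.026 * v + 1.25 * data$weight + 34.4,
                         0.020 * v + 1.12 * data$weight + 36.2)
  data
}

#' Default LVH classification thresholds
#'
#' Sokolow-Lyon 35 mV (both sexes); Cornell 28 mV in men, 20 mV in women;
#' Sokolow-Lyon duration product 2840 mV.ms; Cornell duration product
#' 2440 mV.ms.
#' @export
lvh_thresholds <- function() {
  list(sokolow_lyon = 35, cornell_male = 28, cornell_female = 20,
       sokolow_lyon_product = 2840, cornell_product = 2440)
}

#' Classify LV hypertrophy by ECG criteria
#'
#' A flag is set when the index is at or above its threshold (values below
#' the cut-off are non-LVH; the boundary convention is configurable).
#'
#' @param data Tibble with `sokolow_lyon`, `cornell`,
#'   `sokolow_lyon_product`, `cornell_product`, `sex`.
#' @param thresholds List as from [lvh_thresholds()].
#' @param strict If `TRUE`, use a strict `>` at the boundary instead of `>=`.
#' @return Input with logical `lvh_*` flag columns added.
#' @export
classify_lvh <- function(data, thresholds = lvh_thresholds(),
                         strict = FALSE) {
  cmp <- if (strict) `>` else `>=`
  cornell_thr <- ifelse(data$sex == 1L, thresholds$cornell_male,
                        thresholds$cornell_female)
  dplyr::mutate(
    data,
    lvh_sokolow = cmp(.data$sokolow_lyon, thresholds$sokolow_lyon),
    lvh_cornell = cmp(.data$cornell, cornell_thr),
    lvh_sokolow_product = cmp(.data$sokolow_lyon_product,
                              thresholds$sokolow_lyon_product),
    lvh_cornell_product = cmp(.data$cornell_product,
                              thresholds$cornell_product)
  )
}

#' CMR-derived masses, volumes and indices
#'
#' Myocardial mass is tissue volume times the specific density of myocardium
#' (1.05 g/cm^3); masses and volumes are indexed to body surface area;
#' ejection fraction is `(EDV - ESV) / EDV`.
#'
#' @param data Tibble with `lv_tissue_volume`, `rv_tissue_volume`, `lv_edv`,
#'   `lv_esv`, `rv_edv`, `rv_esv`, `height` (m), `weight` (kg).
#' @param bsa_formula Passed to [body_surface_area()].
#' @return Input with `cmr_lvm`, `rv_mass`, `bsa`, `*_index` and ejection
#'   fraction columns added.
#' @export
cmr_derived_measures <- function(data, bsa_formula = "dubois") {
  stopifnot(all(c("lv_tissue_volume", "lv_edv", "lv_esv",
                  "height", "weight") %in% names(data)))
  out <- dplyr::mutate(
    data,
    bsa = body_surface_area(.data$height, .data$weight, bsa_formula),
    cmr_lvm = 1.05 * .data$lv_tissue_volume,
    cmr_lvm_index = .data$cmr_lvm / .data$bsa,
    lv_edv_index = .data$lv_edv / .data$bsa,
    lv_esv_index = .data$lv_esv / .data$bsa,
    lv_ef = (.data$lv_edv - .data$lv_esv) / .data$lv_edv
  )
  if ("rv_tissue_volume" %in% names(data)) {
    out <- dplyr::mutate(
      out,
      rv_mass = 1.05 * .data$rv_tissue_volume,
      rv_mass_index = .data$rv_mass / .data$bsa)
  }
  if (all(c("rv_edv", "rv_esv") %in% names(data))) {
    out <- dplyr::mutate(
      out,
      rv_edv_index = .data$rv_edv / .data$bsa,
      rv_esv_index = .data$rv_esv / .data$bsa,
      rv_ef = (.data$rv_edv - .data$rv_esv) / .data$rv_edv)
  }
  out
}

#' Chest volume from chest dimensions
#'
#' Cylindrical approximation `pi * r^2 * h` with `r` half the lateral chest
#' diameter and `h` the chest height.
#'
#' @param chest_lateral_diameter Lateral chest diameter, cm (> 0).
#' @param chest_height Chest height, cm (> 0).
#' @return Chest volume in cm^3.
#' @export
chest_geometry <- function(chest_lateral_diameter, chest_height) {
  if (any(chest_lateral_diameter <= 0, na.rm = TRUE) ||
      any(chest_height <= 0, na.rm = TRUE)) {
    abort_famh2("chest dimensions must be positive")
  }
  pi * (chest_lateral_diameter / 2)^2 * chest_height
}

#' Derive all phenotypes from a raw measurement table
#'
#' Runs [ecg_voltage_indices()], [ecg_lvm()], [classify_lvh()],
#' [cmr_derived_measures()] and [chest_geometry()] over a combined
#' per-individual measurement table (as produced by [simulate_traits()] or
#' read from disk).
#'
#' @param data Measurement tibble keyed by `fid`, `iid`.
#' @param bsa_formula `"dubois"` or `"mosteller"`.
#' @param voltage_scale Voltage rescaling for the ECG LVM equation.
#' @return Tibble with all derived phenotype columns appended.
#' @export
derive_phenotypes <- function(data, bsa_formula = "dubois",
                              voltage_scale = 1.0) {
  out <- ecg_voltage_indices(data)
  out <- ecg_lvm(out, voltage_scale = voltage_scale)
  out <- classify_lvh(out)
  out <- cmr_derived_measures(out, bsa_formula = bsa_formula)
  if (all(c("chest_lateral_diameter", "chest_height") %in% names(data))) {
    out$chest_volume <- chest_geometry(out$chest_lateral_diameter,
                                       out$chest_height)
  }
  out
}
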