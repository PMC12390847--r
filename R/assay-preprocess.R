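#' Evaporation correction from standard wells
#'
#' Wells containing known 2 mM analyte standards concentrate as the plate
#' evaporates; sample readings at the same time point are rescaled by
#' \code{nominal / control} to undo the shared evaporation factor.
#'
#' @param sample sample reading(s), mM.
#' @param control standard-well reading at the same time point, mM.
#' @param nominal nominal standard concentration (default 2 mM).
#' @return corrected reading(s).
#' @export
evaporation_correct <- function(sample, control, nominal = 2) {
  if (any(control <= 0)) {
    stop("evaporation_correct: control reading must be positive")
  }
  sample * nominal / control
}

#' Moisture dilution correction of the nominal nitrate input
#'
#' The 2 mM nitrate is added with the slurry water, but the soil brings its
#' own moisture, diluting the amendment. Assuming additive volumes and
#' water density 1 g/ml, the effective initial nitrate is
#' \code{nominal * added_water / (added_water + soil_water)} per gram of
#' dry soil.
#'
#' @param water_content gravimetric water content, g water per g dry soil
#'   (0 to 0.5).
#' @param nominal_A0 nominal nitrate input, mM (default 2).
#' @param slurry_ratio added water per g dry soil, g/g (default 2, the 2:1
#'   water:soil slurry).
#' @return effective initial nitrate, mM.
#' @export
moisture_dilution_correct <- function(water_content, nominal_A0 = 2,
                                      slurry_ratio = 2) {
  stopifnot(all(water_content >= 0), all(water_content <= 0.5))
  nominal_A0 * slurry_ratio / (slurry_ratio + water_content)
}

#' Chloramphenicol background subtraction
#'
#' Chloramphenicol itself reads as 0.5 mM ammonium (its N-H moiety) and
#' 0.4 mgC/ml of water-soluble organic carbon; those constants (or measured
#' no-nitrate chl+ controls) are subtracted from chloramphenicol-treated
#' readings and the result floored at zero.
#'
#' @param reading raw reading(s).
#' @param analyte \code{"ammonium"} (mM) or \code{"wsoc"} (mgC/ml).
#' @param treatment \code{"chl+"} or \code{"chl-"}; untreated readings pass
#'   through unchanged.
#' @param background optional measured background overriding the constant.
#' @return corrected reading(s); a \code{"floored"} attribute flags values
#'   clipped at zero.
#' @export
chl_background_subtract <- function(reading, analyte = c("ammonium", "wsoc"),
                                    treatment = "chl+", background = NULL) {
  analyte <- match.arg(analyte)
  if (!all(treatment %in% c("chl+", "chl-"))) {
    stop("chl_background_subtract: treatment must be 'chl+' or 'chl-'")
  }
  bg <- background %||% switch(analyte, ammonium = 0.5, wsoc = 0.4)
  out <- ifelse(treatment == "chl+", reading - bg, reading)
  floored <- out < 0
  out <- pmax(out, 0)
  attr(out, "floored") <- floored
  out
}
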