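#' Mass of a spherical particle
#'
#' `mass = (pi/6) * d^3 * rho`, with the diameter in nm and the density in
#' g/cm^3, returned in grams. A 15.4 nm silver sphere (rho = 10.49 g/cm^3)
#' weighs 2.0e-17 g.
#'
#' @param diameter_nm diameter in nm.
#' @param density density in g/cm^3.
#' @return mass in g.
#' @seealso [esd_from_mass()] for the inverse.
#' @export
sphere_mass <- function(diameter_nm, density) {
  stopifnot(all(diameter_nm > 0), density > 0)
  pi / 6 * (diameter_nm * 1e-7)^3 * density  # nm -> cm
}

#' Number concentration of a reference particle dispersion
#'
#' Converts the certified mass concentration of a monodisperse reference
#' material (e.g. 30 nm gold, certificate mean diameter 27.6 nm, density
#' 19.3 g/cm^3, at 12.5 ng/L) into a particle number concentration via the
#' per-particle sphere mass.
#'
#' @param mass_conc analyte mass concentration (g per unit of dispersion;
#'   the unit carries through to the result).
#' @param diameter_nm certified mean particle diameter in nm.
#' @param density particle density in g/cm^3 (19.3 for gold).
#' @return particles per the same unit `mass_conc` referred to.
#' @export
reference_number_concentration <- function(mass_conc, diameter_nm, density) {
  check_positive(mass_conc, "mass_conc")
  mass_conc / sphere_mass(diameter_nm, density)
}

#' Transport efficiency by the particle frequency method
#'
#' The fraction of nebulized particles reaching the plasma, estimated as the
#' number of particles detected over the acquisition divided by the number
#' delivered to the nebulizer: `detected_count / (reference_number_conc *
#' flow * duration)`. Determined daily with a monodisperse gold reference
#' dispersion of known number concentration.
#'
#' @param detected_count particles detected during the acquisition.
#' @param reference_number_conc particle number concentration of the
#'   reference dispersion (per g or per mL, consistent with `flow`).
#' @param flow sample uptake (g/s or mL/s).
#' @param duration acquisition time in s.
#' @return transport efficiency in (0, 1].
#' @export
transport_efficiency_frequency <- function(detected_count,
                                           reference_number_conc,
                                           flow, duration) {
  check_positive(detected_count, "detected_count")
  check_positive(reference_number_conc, "reference_number_conc")
  check_positive(flow, "flow")
  check_positive(duration, "duration")
  eta <- detected_count / (reference_number_conc * flow * duration)
  if (eta > 1) {
    stop(sprintf(
      "detected more particles than delivered (efficiency %.3g > 1)", eta),
      call. = FALSE)
  }
  eta
}

#' Ionic mass calibration
#'
#' Fits the detector response to dissolved-analyte standards by ordinary
#' least squares of mean intensity against the analyte mass reaching the
#' plasma per dwell, `concentration * flow * dwell_time *
#' transport_efficiency`. The slope is therefore in counts per gram of
#' analyte per dwell and applies directly to single-particle pulses, whose
#' whole mass arrives within one dwell.
#'
#' @param standards data.frame (or list coercible to one) with columns
#'   `concentration` (g analyte per g of standard solution) and `intensity`
#'   (mean counts per dwell). At least two distinct concentrations,
#'   including a blank or near-blank, are required.
#' @param flow sample uptake (g/s); use 1 if the concentrations are already
#'   expressed as mass per dwell reaching the plasma.
#' @param dwell_time dwell time in s (1 for pre-scaled standards).
#' @param transport_efficiency transport efficiency (1 for pre-scaled
#'   standards).
#' @param reference_material,calibration_date provenance labels.
#' @param r_squared_min linearity warning threshold (default 0.99).
#' @return a `calibration_model`: list with `response_slope` (counts/g per
#'   dwell), `response_intercept` (counts), `transport_efficiency`, `flow`,
#'   `dwell_time`, `r_squared`, and the provenance labels.
#' @examples
#' ionic_calibration(data.frame(concentration = 0:2, intensity = c(0, 10, 20)),
#'                   flow = 1, dwell_time = 1, transport_efficiency = 1)
#' @export
ionic_calibration <- function(standards, flow = 1, dwell_time = 1,
                              transport_efficiency = 1,
                              reference_material = "ionic standards",
                              calibration_date = NA_character_,
                              r_squared_min = 0.99) {
  standards <- as.data.frame(standards)
  if (!all(c("concentration", "intensity") %in% names(standards))) {
    stop("standards need columns 'concentration' and 'intensity'",
         call. = FALSE)
  }
  if (length(unique(standards$concentration)) < 2L) {
    stop("at least two distinct standard concentrations are required",
         call. = FALSE)
  }
  if (min(standards$concentration) > 0.05 * max(standards$concentration)) {
    warning("no blank or near-blank standard in the series", call. = FALSE)
  }
  check_positive(flow, "flow")
  check_positive(dwell_time, "dwell_time")
  check_positive(transport_efficiency, "transport_efficiency")

  flux <- standards$concentration * flow * dwell_time * transport_efficiency
  fit <- stats::lm(intensity ~ flux, data = data.frame(
    intensity = standards$intensity, flux = flux))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine here
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope is not positive", call. = FALSE)
  }
  if (is.finite(r2) && r2 < r_squared_min) {
    warning(sprintf("calibration linearity poor: R^2 = %.4f < %.2f",
                    r2, r_squared_min), call. = FALSE)
  }
  calibration_model(response_slope = slope, response_intercept = intercept,
                    transport_efficiency = transport_efficiency,
                    flow = flow, dwell_time = dwell_time, r_squared = r2,
                    reference_material = reference_material,
                    calibration_date = calibration_date)
}

#' Construct a calibration model
#'
#' Container for a day's calibration: ionic response (slope in counts per
#' gram of analyte per dwell, intercept in counts) plus the transport
#' efficiency and flow/dwell constants it was determined under. Built by
#' [ionic_calibration()]; construct directly when the constants come from
#' elsewhere (e.g. a simulation's known truth).
#'
#' @param response_slope counts per gram per dwell (> 0).
#' @param response_intercept counts (default 0).
#' @param transport_efficiency fraction in (0, 1].
#' @param flow sample uptake (g/s).
#' @param dwell_time dwell time (s).
#' @param r_squared fit diagnostic (NA when constructed directly).
#' @param reference_material,calibration_date provenance labels.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(response_slope, response_intercept = 0,
                              transport_efficiency = 1, flow = 1,
                              dwell_time = 1, r_squared = NA_real_,
                              reference_material = NA_character_,
                              calibration_date = NA_character_) {
  check_positive(response_slope, "response_slope")
  check_positive(transport_efficiency, "transport_efficiency")
  if (transport_efficiency > 1) {
    stop("'transport_efficiency' must be <= 1", call. = FALSE)
  }
  check_positive(flow, "flow")
  check_positive(dwell_time, "dwell_time")
  structure(
    list(response_slope = response_slope,
         response_intercept = response_intercept,
         transport_efficiency = transport_efficiency,
         flow = flow, dwell_time = dwell_time, r_squared = r_squared,
         reference_material = reference_material,
         calibration_date = calibration_date),
    class = "calibration_model")
}
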