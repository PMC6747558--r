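#' Acquisition configuration for a time-resolved spICP-MS run
#'
#' Bundles the instrument and run parameters needed to simulate or interpret
#' a time trace. Units are deliberately generic but must be used
#' consistently: `sample_flow` is mass (or volume) of measured dispersion
#' per second, `response_slope` is detector counts per gram of analyte
#' reaching the plasma within one dwell.
#'
#' @param dwell_time dwell (integration) time in seconds per reading.
#' @param n_dwells number of readings in the acquisition.
#' @param sample_flow dispersion uptake in g/s (or mL/s for aqueous work).
#' @param transport_efficiency fraction of nebulized sample reaching the
#'   plasma, in (0, 1].
#' @param response_slope counts per gram of analyte per dwell.
#' @param background_mean mean instrument background in counts per dwell.
#' @param dilution_factor dilution applied between the stock dispersion and
#'   the measured suspension (>= 1).
#' @param split_prob probability that a particle's ion plume straddles two
#'   consecutive dwells (default 0.1, roughly a rise time of 10% of the
#'   dwell).
#' @param sd_flicker optional Gaussian flicker noise (counts per dwell)
#'   added on top of the Poisson counting background; 0 disables it.
#' @return an object of class `acq_config` (a validated list).
#' @seealso [particle_population()], [simulate_trace()]
#' @export
acquisition_config <- function(dwell_time = 3e-3,
                               n_dwells = 20000L,
                               sample_flow = 5.8e-3,
                               transport_efficiency = 0.05,
                               response_slope = 2e19,
                               background_mean = 10,
                               dilution_factor = 1,
                               split_prob = 0.1,
                               sd_flicker = 0) {
  check_positive(dwell_time, "dwell_time")
  check_positive(n_dwells, "n_dwells")
  if (n_dwells < 1 || n_dwells != round(n_dwells)) {
    stop("'n_dwells' must be a positive integer", call. = FALSE)
  }
  check_positive(sample_flow, "sample_flow")
  check_positive(transport_efficiency, "transport_efficiency")
  if (transport_efficiency > 1) {
    stop("'transport_efficiency' must be <= 1", call. = FALSE)
  }
  check_positive(response_slope, "response_slope")
  check_positive(background_mean, "background_mean", strict = FALSE)
  check_positive(dilution_factor, "dilution_factor")
  if (dilution_factor < 1) stop("'dilution_factor' must be >= 1", call. = FALSE)
  check_fraction(split_prob, "split_prob")
  check_positive(sd_flicker, "sd_flicker", strict = FALSE)

  structure(
    list(dwell_time = dwell_time, n_dwells = as.integer(n_dwells),
         sample_flow = sample_flow,
         transport_efficiency = transport_efficiency,
         response_slope = response_slope, background_mean = background_mean,
         dilution_factor = dilution_factor, split_prob = split_prob,
         sd_flicker = sd_flicker),
    class = "acq_config")
}

#' Particle population to be dispersed and measured
#'
#' Describes the nanoparticle size distribution and abundance in the stock
#' dispersion, plus the dissolved (ionic) fraction of the analyte that raises
#' the continuous background.
#'
#' @param distribution `"normal"` or `"lognormal"` number-based size
#'   distribution of the spherical-equivalent diameter.
#' @param mean_nm location parameter: mean diameter (normal) or median
#'   diameter (lognormal), in nm.
#' @param sd_nm scale parameter: standard deviation in nm (normal) or the
#'   log-scale standard deviation `sdlog` (lognormal, dimensionless).
#' @param number_concentration particles per gram of stock dispersion.
#' @param density particle density in g/cm^3 (10.49 for silver).
#' @param ionic_fraction fraction of the *total* analyte mass present as
#'   dissolved ions (in \[0, 1)); the dissolved mass concentration is derived
#'   from the particulate one as `particulate * f / (1 - f)`.
#' @param dissolved_conc optional explicit dissolved analyte concentration
#'   (g analyte per g of stock dispersion); overrides the `ionic_fraction`
#'   derivation, and is the way to simulate dissolved-only standards.
#' @return an object of class `particle_population`.
#' @export
particle_population <- function(distribution = c("normal", "lognormal"),
                                mean_nm,
                                sd_nm,
                                number_concentration,
                                density = 10.49,
                                ionic_fraction = 0,
                                dissolved_conc = NULL) {
  distribution <- match.arg(distribution)
  check_positive(mean_nm, "mean_nm")
  check_positive(sd_nm, "sd_nm", strict = FALSE)
  check_positive(number_concentration, "number_concentration", strict = FALSE)
  check_positive(density, "density")
  check_fraction(ionic_fraction, "ionic_fraction", upper_open = TRUE)
  if (!is.null(dissolved_conc)) {
    check_positive(dissolved_conc, "dissolved_conc", strict = FALSE)
  }
  structure(
    list(distribution = distribution, mean_nm = mean_nm, sd_nm = sd_nm,
         number_concentration = number_concentration, density = density,
         ionic_fraction = ionic_fraction, dissolved_conc = dissolved_conc),
    class = "particle_population")
}

#' Multi-day validation study design
#'
#' Layout and variance components of a precision study: `n_days` analysis
#' days with `n_replicates` independently prepared replicates per day.
#' Standard deviations and bias are relative (e.g. 0.028 for 2.8%).
#'
#' @param n_days number of analysis days (>= 1).
#' @param n_replicates replicates per day (>= 1).
#' @param between_day_sd relative between-day standard deviation.
#' @param within_day_sd relative within-day (repeatability) standard
#'   deviation.
#' @param bias relative bias of the measurement procedure.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_days = 5L, n_replicates = 3L,
                         between_day_sd = 0, within_day_sd = 0, bias = 0) {
  if (n_days < 1 || n_days != round(n_days)) {
    stop("'n_days' must be a positive integer", call. = FALSE)
  }
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("'n_replicates' must be a positive integer", call. = FALSE)
  }
  check_positive(between_day_sd, "between_day_sd", strict = FALSE)
  check_positive(within_day_sd, "within_day_sd", strict = FALSE)
  stopifnot(is.numeric(bias), length(bias) == 1L)
  structure(
    list(n_days = as.integer(n_days), n_replicates = as.integer(n_replicates),
         between_day_sd = between_day_sd, within_day_sd = within_day_sd,
         bias = bias),
    class = "study_design")
}

#' Sample-type presets for the synthetic trace generator
#'
#' Three ready-made (config, population) pairs emulating the sample classes
#' the method is validated on:
#'
#' * `"nm300k"` — an aqueous colloidal AgNP dispersion: normal size
#'   distribution with mode 15.4 nm and half width at half maximum 2.6 nm
#'   (sd = 2.6 / sqrt(2 log 2) ~ 2.208 nm), negligible dissolved silver,
#'   low instrument background.
#' * `"e174"` — a pristine silver food additive: log-normal, right-tailed
#'   size distribution (median ~18.7 nm), a high dissolved-silver
#'   background, and a low particle count near the lower end of the
#'   200--2200 acceptance window.
#' * `"product"` — E174-containing confectionery: log-normal distribution
#'   (median ~22.5 nm), low background, moderate counts.
#'
#' Number concentrations and dilution factors are chosen so a default 60 s
#' acquisition (20000 dwells of 3 ms) lands inside the 200--2200 detected
#' particle window at roughly 500 (nm300k), 250 (e174) and 800 (product)
#' events, with per-dwell arrival rates well below the coincidence regime.
#'
#' @param name one of `"nm300k"`, `"e174"`, `"product"`.
#' @param n_dwells number of dwells (default 60000, a 3-minute run).
#' @return list with elements `config` ([acquisition_config()]) and
#'   `population` ([particle_population()]).
#' @export
sample_preset <- function(name = c("nm300k", "e174", "product"),
                          n_dwells = 60000L) {
  name <- match.arg(name)
  switch(name,
    nm300k = list(
      config = acquisition_config(n_dwells = n_dwells, dilution_factor = 1e5,
                                  background_mean = 50),
      population = particle_population(
        "normal", mean_nm = 15.4, sd_nm = 2.6 / sqrt(2 * log(2)),
        number_concentration = 1e9, density = 10.49, ionic_fraction = 0.001)
    ),
    e174 = list(
      config = acquisition_config(n_dwells = n_dwells, dilution_factor = 1e4,
                                  background_mean = 2),
      population = particle_population(
        "lognormal", mean_nm = 18.7, sd_nm = 0.35,
        number_concentration = 4.8e7, density = 10.49, ionic_fraction = 0.97)
    ),
    product = list(
      config = acquisition_config(n_dwells = n_dwells, dilution_factor = 1e4,
                                  background_mean = 2),
      population = particle_population(
        "lognormal", mean_nm = 22.5, sd_nm = 0.30,
        number_concentration = 1.55e8, density = 10.49, ionic_fraction = 0.2)
    ))
}
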