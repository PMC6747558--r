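#' Simulate a time-resolved spICP-MS intensity trace
#'
#' Generates one intensity reading per dwell: a Poisson counting background
#' (instrument background plus the flux of dissolved analyte, with optional
#' Gaussian flicker) onto which discrete particle pulses are superimposed.
#' Particle arrivals are independent across dwells with per-dwell rate
#' `number_concentration * sample_flow * transport_efficiency * dwell_time /
#' dilution_factor`; each arriving particle draws a diameter from the
#' population's size distribution, is converted to mass, and contributes
#' `response_slope * mass` expected counts (with Poisson counting noise).
#' With probability `split_prob` a pulse straddles two consecutive dwells,
#' its counts partitioned by a uniform random fraction — emulating ion
#' plumes detected over two consecutive dwell times. Two particles arriving
#' in one dwell simply sum (coincidence).
#'
#' All randomness derives from `seed` through fixed per-component
#' sub-streams, so traces are reproducible independently of evaluation
#' order.
#'
#' @param config an [acquisition_config()].
#' @param population a [particle_population()].
#' @param seed integer seed fixing all randomness.
#' @return a `time_trace`: a data.frame with columns `dwell` and `counts`,
#'   carrying the config as attribute `config` and (for testing against
#'   ground truth) attribute `truth`: a list with the arrival dwells, true
#'   particle masses (g) and diameters (nm), and the dissolved background
#'   mean in counts/dwell.
#' @examples
#' p <- sample_preset("nm300k", n_dwells = 5000)
#' tr <- simulate_trace(p$config, p$population, seed = 1)
#' head(tr)
#' @export
simulate_trace <- function(config, population, seed) {
  stopifnot(inherits(config, "acq_config"),
            inherits(population, "particle_population"))
  n <- config$n_dwells
  seeds <- substream_seeds(seed, 4L)

  # expected particle arrivals per dwell
  lambda <- population$number_concentration * config$sample_flow *
    config$transport_efficiency * config$dwell_time / config$dilution_factor
  if (lambda > 0.1) {
    warning(sprintf(
      "expected %.3g particle arrivals per dwell (> 0.1): coincidence regime",
      lambda), call. = FALSE)
  }

  # dissolved analyte raises the continuous background
  dis <- dissolved_concentration(population) / config$dilution_factor
  bg_dissolved <- config$response_slope * dis * config$sample_flow *
    config$dwell_time * config$transport_efficiency
  bg_mean <- config$background_mean + bg_dissolved

  set.seed(seeds[1])
  counts <- stats::rpois(n, bg_mean)
  if (config$sd_flicker > 0) {
    counts <- pmax(0, round(counts + stats::rnorm(n, 0, config$sd_flicker)))
  }

  set.seed(seeds[2])
  arrivals <- stats::rpois(n, lambda)
  idx <- rep.int(seq_len(n), arrivals)

  d_nm <- numeric(0)
  if (length(idx)) {
    set.seed(seeds[3])
    d_nm <- draw_diameters(population, length(idx))
    masses <- sphere_mass(d_nm, population$density)
    pulse_mean <- config$response_slope * masses

    set.seed(seeds[4])
    pulse <- stats::rpois(length(idx), pulse_mean)
    split <- stats::runif(length(idx)) < config$split_prob & idx < n
    frac <- stats::runif(length(idx))
    first <- ifelse(split, round(pulse * frac), pulse)
    second <- pulse - first
    counts[idx] <- counts[idx] + first
    spl <- which(split)
    if (length(spl)) {
      tab <- tapply(second[spl], idx[spl] + 1L, sum)
      at <- as.integer(names(tab))
      counts[at] <- counts[at] + as.integer(tab)
    }
    truth_masses <- masses
  } else {
    truth_masses <- numeric(0)
  }

  structure(
    data.frame(dwell = seq_len(n), counts = as.numeric(counts)),
    config = config,
    truth = list(arrival_dwells = idx, masses = truth_masses,
                 diameters_nm = d_nm, lambda = lambda,
                 background_mean = bg_mean),
    class = c("time_trace", "data.frame"))
}

# internal: dissolved analyte concentration (g/g of stock dispersion)
dissolved_concentration <- function(population) {
  if (!is.null(population$dissolved_conc)) return(population$dissolved_conc)
  f <- population$ionic_fraction
  if (f == 0 || population$number_concentration == 0) return(0)
  particulate <- population$number_concentration *
    mean_particle_mass(population)
  particulate * f / (1 - f)
}

# internal: E[mass] of one particle, from the size distribution's third
# moment (normal: mu^3 + 3 mu sigma^2, negative-diameter mass negligible for
# the narrow distributions used here; lognormal: exp(3 mulog + 4.5 sdlog^2))
mean_particle_mass <- function(population) {
  m3 <- switch(population$distribution,
    normal = population$mean_nm^3 + 3 * population$mean_nm * population$sd_nm^2,
    lognormal = exp(3 * log(population$mean_nm) + 4.5 * population$sd_nm^2))
  pi / 6 * (m3 * 1e-21) * population$density  # nm^3 -> cm^3
}

# internal: draw particle diameters (nm) from the population
draw_diameters <- function(population, n) {
  d <- switch(population$distribution,
    normal = stats::rnorm(n, population$mean_nm, population$sd_nm),
    lognormal = stats::rlnorm(n, log(population$mean_nm), population$sd_nm))
  while (any(d <= 0)) {  # resample the (vanishingly rare) non-physical draws
    bad <- d <= 0
    d[bad] <- switch(population$distribution,
      normal = stats::rnorm(sum(bad), population$mean_nm, population$sd_nm),
      lognormal = stats::rlnorm(sum(bad), log(population$mean_nm),
                                population$sd_nm))
  }
  d
}

#' Simulate a multi-day validation study
#'
#' Produces a day-by-replicate table of measurement results around a known
#' true value: `value = true_value * (1 + bias + day_effect +
#' replicate_effect)`, with the day effect shared by all replicates of a day
#' and both effects mean-zero normal with the design's relative standard
#' deviations. This is the ground-truth generator against which the ANOVA
#' precision decomposition is verified.
#'
#' @param design a [study_design()].
#' @param true_value the true value of the measurand (any unit).
#' @param seed integer seed.
#' @param measurand label stored with the study (e.g. `"median ESD"`).
#' @return a `validation_study`: data.frame with columns `day`, `replicate`,
#'   `measurand`, `value`.
#' @examples
#' simulate_validation_study(study_design(5, 3, 0.028, 0.009), 15.4, seed = 1)
#' @export
simulate_validation_study <- function(design, true_value, seed,
                                      measurand = "measurand") {
  stopifnot(inherits(design, "study_design"))
  check_positive(true_value, "true_value")
  seeds <- substream_seeds(seed, 2L)
  d <- design$n_days
  n <- design$n_replicates
  set.seed(seeds[1])
  day_eff <- stats::rnorm(d, 0, design$between_day_sd)
  set.seed(seeds[2])
  rep_eff <- stats::rnorm(d * n, 0, design$within_day_sd)
  value <- true_value *
    (1 + design$bias + rep(day_eff, each = n) + rep_eff)
  structure(
    data.frame(day = rep(seq_len(d), each = n),
               replicate = rep(seq_len(n), times = d),
               measurand = measurand, value = value),
    true_value = true_value, design = design,
    class = c("validation_study", "data.frame"))
}
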