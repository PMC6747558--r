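#' Convert net pulse intensities to particle masses
#'
#' `mass = (net_intensity - response_intercept) / response_slope`. The slope
#' from [ionic_calibration()] already carries the flow x dwell x
#' transport-efficiency scaling, so a pulse's net counts map directly to the
#' particle mass that produced them. Events whose computed mass is not
#' strictly positive are dropped with a warning reporting how many.
#'
#' @param net_intensity numeric vector of net (background-subtracted) pulse
#'   intensities, or a `particle_events` object.
#' @param model a `calibration_model`.
#' @return numeric vector of masses in g (dropped events removed), with
#'   attribute `n_dropped`.
#' @export
event_mass <- function(net_intensity, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (inherits(net_intensity, "particle_events")) {
    net_intensity <- net_intensity$events$net
  }
  mass <- (net_intensity - model$response_intercept) / model$response_slope
  bad <- !(mass > 0)
  if (any(bad)) {
    warning(sprintf("%d event(s) dropped: non-positive computed mass",
                    sum(bad)), call. = FALSE)
  }
  structure(mass[!bad], n_dropped = sum(bad))
}

#' Equivalent spherical diameter from particle mass
#'
#' `d = (6 m / (pi rho))^(1/3)`, the diameter of the sphere of density
#' `rho` having mass `m`, returned in nm. Exact inverse of [sphere_mass()].
#'
#' @param mass mass in g (vectorized).
#' @param density density in g/cm^3.
#' @return diameter in nm.
#' @examples
#' esd_from_mass(2.0e-17, 10.49)  # ~15.4 nm
#' @export
esd_from_mass <- function(mass, density) {
  stopifnot(all(mass > 0), density > 0)
  (6 * mass / (pi * density))^(1 / 3) * 1e7  # cm -> nm
}

#' Size quantification limit
#'
#' The equivalent spherical diameter of a particle whose pulse sits exactly
#' at the detection threshold `mu + n_sigma * sigma`: particles smaller than
#' this are indistinguishable from background. The threshold intensity is
#' converted to mass through the calibration after intercept subtraction.
#' An optional multiplier (3x or 10x conventions) can be applied; the
#' default applies none.
#'
#' @param background a `background_stats` (from [detect_particles()]).
#' @param model a `calibration_model`.
#' @param density particle density in g/cm^3.
#' @param multiplier optional factor on the threshold-equivalent mass
#'   (default 1).
#' @return size LOQ in nm.
#' @export
size_loq <- function(background, model, density, multiplier = 1) {
  stopifnot(inherits(model, "calibration_model"))
  check_positive(multiplier, "multiplier")
  mass <- (background$threshold - model$response_intercept) /
    model$response_slope * multiplier
  if (mass < 0) {
    stop("detection threshold below calibration intercept", call. = FALSE)
  }
  if (mass == 0) return(.Machine$double.xmin)
  esd_from_mass(mass, density)
}

#' Particle number and mass concentrations
#'
#' Scales the detected event count and summed event masses back to the
#' original sample: `C_p = n_events * dilution_factor / (eta * flow *
#' duration * sample_mass_per_dispersion_mass)` and `C_m` is the sum of the
#' event masses under the same scaling. With flow in g/s and
#' `sample_mass_per_dispersion_mass` in g sample per g dispersion, the
#' results are per gram of original sample; multiply by 1000 for the per-kg
#' convention. QC flag `"count_window"` is raised unless the raw event
#' count lies in the 200--2200 acceptance window.
#'
#' @param events a `particle_events` (after any split-event handling).
#' @param model a `calibration_model`.
#' @param flow sample uptake (g/s).
#' @param duration acquisition time in s (`n_dwells * dwell_time`).
#' @param dilution_factor dilution between original sample dispersion and
#'   measured suspension.
#' @param sample_mass_per_dispersion_mass grams of original sample per gram
#'   of dispersion (1 for a neat dispersion; for prepared foods this single
#'   scalar carries the sub-sample mass and any core-removal correction).
#' @param density density in g/cm^3, used for the median ESD carried in the
#'   result (QC for dilution proportionality).
#' @param count_window acceptable detected-particle window (default
#'   `c(200, 2200)`).
#' @return a `concentration_result`: list with `particle_number_conc`,
#'   `particle_mass_conc`, `n_events`, `n_dropped`, `median_esd`,
#'   `dilution_factor`, `qc_flags`.
#' @export
concentrations <- function(events, model, flow, duration,
                           dilution_factor = 1,
                           sample_mass_per_dispersion_mass = 1,
                           density = 10.49,
                           count_window = c(200, 2200)) {
  stopifnot(inherits(events, "particle_events"),
            inherits(model, "calibration_model"))
  check_positive(flow, "flow")
  check_positive(duration, "duration")
  check_positive(dilution_factor, "dilution_factor")
  check_positive(sample_mass_per_dispersion_mass,
                 "sample_mass_per_dispersion_mass")

  n <- events$n_events
  qc <- character(0)
  if (n < count_window[1] || n > count_window[2]) qc <- c(qc, "count_window")

  scale <- dilution_factor /
    (model$transport_efficiency * flow * duration *
       sample_mass_per_dispersion_mass)
  if (n == 0L) {
    masses <- numeric(0)
    n_dropped <- 0L
    median_esd <- NA_real_
  } else {
    masses <- event_mass(events, model)
    n_dropped <- attr(masses, "n_dropped")
    median_esd <- if (length(masses)) {
      stats::median(esd_from_mass(masses, density))
    } else NA_real_
  }
  structure(
    list(particle_number_conc = length(masses) * scale,
         particle_mass_conc = sum(masses) * scale,
         n_events = n, n_dropped = n_dropped,
         median_esd = median_esd, density = density,
         dilution_factor = dilution_factor, qc_flags = qc),
    class = "concentration_result")
}

#' Dilution-series proportionality check
#'
#' The two measured dilution levels of a sample must back-calculate to the
#' same concentration in the original sample and yield the same particle
#' size; otherwise the dilutions (or the background discrimination) are
#' suspect. Passes when the dilution-corrected number concentrations agree
#' within `tol_conc` (default 20%) and the median ESDs within `tol_size`
#' (default 5%).
#'
#' @param result_a,result_b `concentration_result`s of the same sample at
#'   two different dilution levels.
#' @param tol_conc relative tolerance on the back-calculated number
#'   concentration ratio.
#' @param tol_size relative tolerance on the median ESD ratio.
#' @return a `qc_verdict`: list with `pass`, `conc_ratio`, `size_ratio`,
#'   and the tolerances.
#' @export
dilution_proportionality <- function(result_a, result_b,
                                     tol_conc = 0.20, tol_size = 0.05) {
  stopifnot(inherits(result_a, "concentration_result"),
            inherits(result_b, "concentration_result"))
  if (result_a$dilution_factor == result_b$dilution_factor) {
    stop("the two results must come from different dilution levels",
         call. = FALSE)
  }
  conc_ratio <- result_a$particle_number_conc / result_b$particle_number_conc
  size_ratio <- result_a$median_esd / result_b$median_esd
  pass <- is.finite(conc_ratio) && abs(conc_ratio - 1) <= tol_conc &&
    is.finite(size_ratio) && abs(size_ratio - 1) <= tol_size
  structure(
    list(pass = pass, conc_ratio = conc_ratio, size_ratio = size_ratio,
         tol_conc = tol_conc, tol_size = tol_size),
    class = "qc_verdict")
}

#' Size-distribution container
#'
#' Holds per-particle equivalent spherical diameters together with summary
#' statistics and the below-LOQ correction state.
#'
#' @param esd numeric vector of diameters in nm.
#' @param size_loq size quantification limit in nm (optional).
#' @param below_loq_number_fraction externally determined fraction (by
#'   number) of particles below the size LOQ, e.g. from electron
#'   microscopy of the same sample; in \[0, 1).
#' @return a `size_distribution`: list with `esd`, `median`, `mode`,
#'   `hwhm`, `size_loq`, `below_loq_number_fraction`, `observed_weight`
#'   (the share of the normalized total carried by the observed particles),
#'   `normalized`.
#' @seealso [distribution_summary()], [number_recovery_correction()]
#' @export
size_distribution <- function(esd, size_loq = NA_real_,
                              below_loq_number_fraction = 0) {
  stopifnot(is.numeric(esd), all(esd > 0))
  check_fraction(below_loq_number_fraction, "below_loq_number_fraction",
                 upper_open = TRUE)
  s <- distribution_summary(esd)
  structure(
    list(esd = esd, median = s$median, mode = s$mode, hwhm = s$hwhm,
         size_loq = size_loq,
         below_loq_number_fraction = below_loq_number_fraction,
         observed_weight = 1 - below_loq_number_fraction,
         normalized = FALSE),
    class = "size_distribution")
}

#' Median, mode and half width at half maximum of a size distribution
#'
#' The median is the sample median. The mode and HWHM are read off a
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth):
#' the mode is the abscissa of the density maximum, and the HWHM is half
#' the distance between the two half-maximum crossings around it. With
#' fewer than 50 particles only the median is reliable; mode and HWHM are
#' returned as NA with a warning.
#'
#' @param x numeric vector of diameters (nm) or a `size_distribution`.
#' @param n_grid density grid resolution (default 2048).
#' @return list with `median`, `mode`, `hwhm` (nm).
#' @export
distribution_summary <- function(x, n_grid = 2048) {
  if (inherits(x, "size_distribution")) x <- x$esd
  stopifnot(is.numeric(x), length(x) >= 1)
  med <- stats::median(x)
  if (length(unique(x)) == 1L) {
    # degenerate sample: the mode is that value, the width carries no
    # spread information beyond the bandwidth floor
    warning("all values identical: HWHM is bandwidth-limited", call. = FALSE)
    return(list(median = med, mode = x[1], hwhm = 0))
  }
  if (length(x) < 50L) {
    warning("fewer than 50 particles: mode and HWHM not estimated",
            call. = FALSE)
    return(list(median = med, mode = NA_real_, hwhm = NA_real_))
  }
  dens <- stats::density(x, bw = "nrd0", n = n_grid)
  i_max <- which.max(dens$y)
  mode <- dens$x[i_max]
  half <- dens$y[i_max] / 2
  above <- dens$y >= half
  # contiguous above-half region around the mode
  left <- i_max
  while (left > 1L && above[left - 1L]) left <- left - 1L
  right <- i_max
  while (right < length(above) && above[right + 1L]) right <- right + 1L
  x_left <- interp_crossing(dens$x, dens$y, left, half, lower = TRUE)
  x_right <- interp_crossing(dens$x, dens$y, right, half, lower = FALSE)
  list(median = med, mode = mode, hwhm = (x_right - x_left) / 2)
}

# internal: linear interpolation of the half-maximum crossing at a region edge
interp_crossing <- function(gx, gy, i, half, lower) {
  j <- if (lower) i - 1L else i + 1L
  if (j < 1L || j > length(gx)) return(gx[i])  # half-max runs off the grid
  gx[i] + (gx[j] - gx[i]) * (half - gy[i]) / (gy[j] - gy[i])
}

#' Total number recovery correction
#'
#' Normalized number-based size distributions from spICP-MS miss the
#' particles below the size quantification limit. Given the below-LOQ
#' number fraction determined independently (e.g. from electron microscopy
#' of the same sample), the observed distribution is rescaled so that it
#' represents only `1 - fraction` of the total particle number: the
#' normalized density of the observed portion integrates to
#' `1 - fraction` instead of 1.
#'
#' @param dist a `size_distribution`.
#' @param below_loq_number_fraction fraction in \[0, 1).
#' @return the `size_distribution` with `below_loq_number_fraction`,
#'   `observed_weight = 1 - fraction` and `normalized = TRUE` set.
#' @export
number_recovery_correction <- function(dist, below_loq_number_fraction) {
  stopifnot(inherits(dist, "size_distribution"))
  check_fraction(below_loq_number_fraction, "below_loq_number_fraction",
                 upper_open = TRUE)
  dist$below_loq_number_fraction <- below_loq_number_fraction
  dist$observed_weight <- 1 - below_loq_number_fraction
  dist$normalized <- TRUE
  dist
}
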