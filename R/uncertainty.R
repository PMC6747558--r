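#' Precision components by one-way analysis of variance
#'
#' Decomposes a day-by-replicate validation study into repeatability,
#' between-day, and intermediate-precision standard deviations:
#' `s_r = sqrt(MSW)`, `s_d = sqrt((MSB - MSW) / n)` and
#' `s_ip = sqrt(s_r^2 + s_d^2)`, where MSW and MSB are the within- and
#' between-day mean squares of the one-way ANOVA with day as the grouping
#' factor and `n` is the number of replicates per day (the harmonic mean of
#' the per-day counts for unbalanced designs, taken with a warning). A
#' negative between-day variance estimate (MSB < MSW) is floored at zero
#' and flagged. Relative values are the absolute ones divided by the grand
#' mean, times 100.
#'
#' @param study a `validation_study` from [simulate_validation_study()] /
#'   [read_study()], or any data.frame with columns `day` and `value`.
#' @return a `precision_result`: list with `s_r`, `s_d`, `s_ip` (units of
#'   the measurand), `s_r_rel`, `s_d_rel`, `s_ip_rel` (percent of the grand
#'   mean), `msw`, `msb`, `n_per_day`, `n_days`, `grand_mean`,
#'   `s_d_floored`.
#' @examples
#' st <- simulate_validation_study(study_design(5, 3, 0.028, 0.009), 100, 1)
#' anova_precision(st)
#' @export
anova_precision <- function(study) {
  study <- as.data.frame(study)
  if (!all(c("day", "value") %in% names(study))) {
    stop("study needs columns 'day' and 'value'", call. = FALSE)
  }
  day <- factor(study$day)
  x <- study$value
  d <- nlevels(day)
  if (d < 2L) {
    stop("between-day precision requires at least 2 days", call. = FALSE)
  }
  n_i <- as.vector(table(day))
  if (max(n_i) < 2L) {
    stop("at least one day needs 2 or more replicates", call. = FALSE)
  }
  balanced <- length(unique(n_i)) == 1L
  if (!balanced) {
    warning("unbalanced design: using the harmonic mean of replicates per day",
            call. = FALSE)
  }
  n_h <- d / sum(1 / n_i)

  grand <- mean(x)
  day_means <- tapply(x, day, mean)
  ssw <- sum((x - day_means[day])^2)
  ssb <- sum(n_i * (day_means - grand)^2)
  msw <- ssw / (length(x) - d)
  msb <- ssb / (d - 1)

  s_r <- sqrt(msw)
  floored <- msb <= msw
  s_d <- if (floored) 0 else sqrt((msb - msw) / n_h)
  s_ip <- sqrt(s_r^2 + s_d^2)

  structure(
    list(s_r = s_r, s_d = s_d, s_ip = s_ip,
         s_r_rel = 100 * s_r / grand, s_d_rel = 100 * s_d / grand,
         s_ip_rel = 100 * s_ip / grand,
         msw = msw, msb = msb, n_per_day = n_h, n_days = d,
         grand_mean = grand, s_d_floored = floored),
    class = "precision_result")
}

#' Bias uncertainty for a size measurand
#'
#' Combines the scatter of the trueness-determination experiments with the
#' uncertainty of the reference (electron-microscopy) size determination:
#' `u_delta = sqrt((s_t / sqrt(n_t))^2 + u_ref^2)`. Both inputs must be on
#' the same convention (both absolute, or both relative).
#'
#' @param s_t standard deviation of the trueness experiments.
#' @param n_t number of trueness experiments (>= 1).
#' @param u_ref combined standard uncertainty of the reference size method
#'   (e.g. half the expanded TEM uncertainty of the matching measurand).
#' @return `u_delta`, same convention as the inputs.
#' @export
bias_uncertainty_size <- function(s_t, n_t, u_ref) {
  check_positive(s_t, "s_t", strict = FALSE)
  check_positive(n_t, "n_t")
  check_positive(u_ref, "u_ref", strict = FALSE)
  sqrt((s_t / sqrt(n_t))^2 + u_ref^2)
}

#' Bias uncertainty for a concentration measurand
#'
#' With no independent reference method for particle concentrations, only
#' the trueness-experiment scatter enters: `u_delta = s_t / sqrt(n_t)`.
#'
#' @inheritParams bias_uncertainty_size
#' @return `u_delta`, same convention as `s_t`.
#' @export
bias_uncertainty_concentration <- function(s_t, n_t) {
  check_positive(s_t, "s_t", strict = FALSE)
  check_positive(n_t, "n_t")
  s_t / sqrt(n_t)
}

#' Measurement-uncertainty budget under routine conditions
#'
#' Under routine conditions (n replicates on each of d days) the precision
#' components are divided by the corresponding replication:
#' `u_r = s_r / sqrt(n)`, `u_d = s_d / sqrt(d)`, combined with the bias
#' uncertainty in quadrature, `u_c = sqrt(u_r^2 + u_d^2 + u_delta^2)`, and
#' expanded with coverage factor k: `U = k * u_c` (k = 2 for ~95%
#' coverage). All quantities are usually relative (percent); the algebra is
#' convention-agnostic as long as all three inputs share one.
#'
#' @param s_r repeatability standard deviation (or a `precision_result`,
#'   whose relative percent components are then used).
#' @param s_d between-day standard deviation (ignored when `s_r` is a
#'   `precision_result`).
#' @param u_delta bias uncertainty, same convention.
#' @param n replicates per day under routine conditions.
#' @param d days under routine conditions.
#' @param k coverage factor (default 2).
#' @return an `uncertainty_budget`: list with `u_r`, `u_d`, `u_delta`,
#'   `u_c`, `U`, `U_report` (U rounded to 2 significant figures, the table
#'   convention), `n`, `d`, `k`.
#' @examples
#' routine_budget(0.9, 2.8, 6.0, n = 3, d = 1)$U_report  # 13
#' @export
routine_budget <- function(s_r, s_d = NULL, u_delta, n, d, k = 2) {
  if (inherits(s_r, "precision_result")) {
    pr <- s_r
    s_r <- pr$s_r_rel
    s_d <- pr$s_d_rel
  }
  check_positive(s_r, "s_r", strict = FALSE)
  check_positive(s_d, "s_d", strict = FALSE)
  check_positive(u_delta, "u_delta", strict = FALSE)
  check_positive(n, "n")
  check_positive(d, "d")
  check_positive(k, "k")
  u_r <- s_r / sqrt(n)
  u_d <- s_d / sqrt(d)
  u_c <- sqrt(u_r^2 + u_d^2 + u_delta^2)
  U <- k * u_c
  structure(
    list(u_r = u_r, u_d = u_d, u_delta = u_delta, u_c = u_c, U = U,
         U_report = signif_away(U, 2), n = n, d = d, k = k),
    class = "uncertainty_budget")
}

#' Quadrature decomposition of a combined uncertainty
#'
#' When a combined uncertainty is built from independent stages in
#' quadrature (e.g. `u_c^2 = u_sample_preparation^2 + u_analysis^2`), an
#' unknown component follows by subtraction:
#' `sqrt(u_total^2 - sum(u_known^2))`. Errors when the known components
#' already exceed the total (inconsistent inputs), reporting the deficit.
#'
#' @param u_total the combined (total) uncertainty.
#' @param u_known numeric vector of known components, same convention.
#' @return the remaining component.
#' @examples
#' decompose_uncertainty(16 / 2, 13 / 2)  # sample preparation: ~4.7
#' @export
decompose_uncertainty <- function(u_total, u_known) {
  check_positive(u_total, "u_total", strict = FALSE)
  stopifnot(is.numeric(u_known), all(u_known >= 0))
  rad <- u_total^2 - sum(u_known^2)
  if (rad < 0) {
    stop(sprintf(
      "known components exceed the total: deficit %.4g (squared units)",
      -rad), call. = FALSE)
  }
  sqrt(rad)
}

#' Theoretical particle concentrations of a characterized dispersion
#'
#' Builds the expected particulate mass and number concentrations from the
#' total analyte content and independently determined correction fractions:
#' `C_m = total_content * (1 - ionic_fraction)` (the particulate share of
#' the total analyte mass) and `C_p = C_m / particle_mass *
#' (1 - undetected_number_fraction)` (the detectable particle number, with
#' the per-particle mass taken at the representative diameter). The mass
#' fraction carried by undetectable particles is reported for reference but
#' not applied to `C_m` by default (it is within the rounding of the
#' inputs); set `apply_undetected_mass = TRUE` to subtract it.
#'
#' @param total_content total analyte mass fraction of the dispersion
#'   (g/g, e.g. 0.1016 for 10.16% w/w).
#' @param ionic_fraction fraction of total analyte present as dissolved
#'   ions at the measurement dilution.
#' @param particle_mass representative per-particle mass in g (e.g.
#'   [sphere_mass()] at the median diameter).
#' @param undetected_number_fraction number fraction of particles below the
#'   size LOQ (from electron microscopy).
#' @param undetected_mass_fraction mass fraction carried by those
#'   particles; reported, only applied if requested.
#' @param apply_undetected_mass subtract `undetected_mass_fraction` from
#'   `C_m` (default FALSE).
#' @return list with `C_m_theo_mg_g` (mg analyte per g dispersion),
#'   `C_p_theo_per_g` (particles per g dispersion), and the inputs.
#' @examples
#' theoretical_concentration(0.1016, 0.22, sphere_mass(15.4, 10.49), 0.14)
#' @export
theoretical_concentration <- function(total_content, ionic_fraction,
                                      particle_mass,
                                      undetected_number_fraction = 0,
                                      undetected_mass_fraction = 0,
                                      apply_undetected_mass = FALSE) {
  check_fraction(total_content, "total_content")
  check_fraction(ionic_fraction, "ionic_fraction", upper_open = TRUE)
  check_positive(particle_mass, "particle_mass")
  check_fraction(undetected_number_fraction, "undetected_number_fraction",
                 upper_open = TRUE)
  check_fraction(undetected_mass_fraction, "undetected_mass_fraction",
                 upper_open = TRUE)
  c_m <- total_content * (1 - ionic_fraction)
  if (apply_undetected_mass) c_m <- c_m * (1 - undetected_mass_fraction)
  c_p <- c_m / particle_mass * (1 - undetected_number_fraction)
  list(C_m_theo_mg_g = c_m * 1000, C_p_theo_per_g = c_p,
       total_content = total_content, ionic_fraction = ionic_fraction,
       particle_mass = particle_mass,
       undetected_number_fraction = undetected_number_fraction,
       undetected_mass_fraction = undetected_mass_fraction)
}

#' Recovery against a theoretical value
#'
#' @param measured measured concentration.
#' @param theoretical theoretical concentration (> 0), same units.
#' @return recovery in percent.
#' @examples
#' recovery(1.73e15, 3.4e15)  # ~51
#' @export
recovery <- function(measured, theoretical) {
  check_positive(theoretical, "theoretical")
  100 * measured / theoretical
}
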