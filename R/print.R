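#' @export
print.particle_events <- function(x, ...) {
  bg <- x$background
  cat(sprintf(
    "particle_events: %d events (n_sigma = %g)\n", x$n_events, bg$n_sigma))
  cat(sprintf(
    "  background: mu = %.4g, sigma = %.4g, threshold = %.4g (%d iterations%s)\n",
    bg$mu, bg$sigma, bg$threshold, bg$iterations,
    if (bg$converged) "" else ", NOT converged"))
  if (!is.null(x$split_mode)) {
    cat(sprintf("  split-event handling: %s\n", x$split_mode))
  }
  invisible(x)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("calibration_model\n")
  cat(sprintf("  response: slope = %.4g counts/g/dwell, intercept = %.4g counts\n",
              x$response_slope, x$response_intercept))
  cat(sprintf("  transport efficiency = %.4g, flow = %.4g, dwell = %.4g s\n",
              x$transport_efficiency, x$flow, x$dwell_time))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 = %.5f\n", x$r_squared))
  invisible(x)
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("concentration_result: %d events (dilution %.3g)\n",
              x$n_events, x$dilution_factor))
  cat(sprintf("  C_p = %.4g particles per unit sample mass\n",
              x$particle_number_conc))
  cat(sprintf("  C_m = %.4g g per unit sample mass\n", x$particle_mass_conc))
  if (is.finite(x$median_esd)) {
    cat(sprintf("  median ESD = %.3f nm\n", x$median_esd))
  }
  if (length(x$qc_flags)) {
    cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf(
    "precision_result (%d days, %.3g replicates/day, grand mean %.4g)\n",
    x$n_days, x$n_per_day, x$grand_mean))
  cat(sprintf("  s_r  = %.4g (%.3g%%)\n", x$s_r, x$s_r_rel))
  cat(sprintf("  s_d  = %.4g (%.3g%%)%s\n", x$s_d, x$s_d_rel,
              if (x$s_d_floored) " [floored: MSB <= MSW]" else ""))
  cat(sprintf("  s_ip = %.4g (%.3g%%)\n", x$s_ip, x$s_ip_rel))
  invisible(x)
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("uncertainty_budget (n = %g, d = %g, k = %g)\n",
              x$n, x$d, x$k))
  cat(sprintf("  u_r = %.4g  u_d = %.4g  u_delta = %.4g\n",
              x$u_r, x$u_d, x$u_delta))
  cat(sprintf("  u_c = %.4g  U = %.4g (reported: %g)\n",
              x$u_c, x$U, x$U_report))
  invisible(x)
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("dilution proportionality: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  back-calculated C_p ratio = %.3f (tolerance %.0f%%)\n",
              x$conc_ratio, 100 * x$tol_conc))
  cat(sprintf("  median ESD ratio = %.3f (tolerance %.0f%%)\n",
              x$size_ratio, 100 * x$tol_size))
  invisible(x)
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("size_distribution: %d particles\n", length(x$esd)))
  cat(sprintf("  median = %.3f nm, mode = %.3f nm, HWHM = %.3f nm\n",
              x$median, x$mode, x$hwhm))
  if (is.finite(x$size_loq)) cat(sprintf("  size LOQ = %.3f nm\n", x$size_loq))
  if (x$normalized) {
    cat(sprintf("  normalized: observed particles carry weight %.3f (%.1f%% below LOQ)\n",
                x$observed_weight, 100 * x$below_loq_number_fraction))
  }
  invisible(x)
}
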