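#' Detect particle pulses by the iterative mean + n*sigma threshold
#'
#' Separates discrete particle events from the continuous ionic/instrument
#' background. Starting with every dwell classified as background, the mean
#' `mu` and standard deviation `sigma` of the background-classified dwells
#' are computed, dwells exceeding `mu + n_sigma * sigma` are reclassified as
#' particle events, and the loop repeats until the classification no longer
#' changes (or `max_iter` is reached, with a warning). Ties (a reading
#' exactly at the threshold) stay background: only strict exceedance counts.
#'
#' Because removing high readings can only lower the threshold, the
#' background set shrinks monotonically and the procedure converges to the
#' largest thresholding-stable background partition.
#'
#' @param trace a `time_trace` from [simulate_trace()] / [read_trace()], or
#'   a bare numeric vector of counts.
#' @param n_sigma integer threshold multiplier; 5 by default, 4 for samples
#'   where the particle signal overlaps the background.
#' @param max_iter iteration cap (default 100).
#' @return a `particle_events` object: list with `events` (data.frame of
#'   `dwell`, `raw`, `net = raw - mu`), `background` (a `background_stats`
#'   list: `mu`, `sigma`, `n_sigma`, `threshold`, `iterations`,
#'   `converged`), `n_events`, and the trace's acquisition config (if any)
#'   as `config`.
#' @examples
#' p <- sample_preset("nm300k", n_dwells = 5000)
#' ev <- detect_particles(simulate_trace(p$config, p$population, seed = 1))
#' ev$n_events
#' @export
detect_particles <- function(trace, n_sigma = 5L, max_iter = 100L) {
  counts <- trace_counts(trace)
  if (length(counts) == 0L) stop("trace is empty", call. = FALSE)
  if (!is.numeric(n_sigma) || n_sigma < 1) {
    stop("'n_sigma' must be >= 1", call. = FALSE)
  }

  is_bg <- rep(TRUE, length(counts))
  iter <- 0L
  converged <- FALSE
  mu <- sigma <- threshold <- NA_real_
  trail <- list()
  while (iter < max_iter) {
    iter <- iter + 1L
    if (!any(is_bg)) {
      stop("no background identifiable: all dwells classified as particles",
           call. = FALSE)
    }
    bg <- counts[is_bg]
    mu <- mean(bg)
    sigma <- if (length(bg) > 1L) stats::sd(bg) else 0
    threshold <- mu + n_sigma * sigma
    new_bg <- counts <= threshold
    trail[[iter]] <- c(mu = mu, sigma = sigma, threshold = threshold,
                       n_events = sum(!new_bg))
    if (identical(new_bg, is_bg)) {
      converged <- TRUE
      break
    }
    is_bg <- new_bg
  }
  if (!converged) {
    warning(sprintf("detection did not converge within %d iterations", max_iter),
            call. = FALSE)
  }
  if (!any(is_bg)) {
    stop("no background identifiable: all dwells classified as particles",
         call. = FALSE)
  }

  ev_idx <- which(!is_bg)
  events <- data.frame(dwell = ev_idx, raw = counts[ev_idx],
                       net = counts[ev_idx] - mu)
  structure(
    list(events = events,
         background = structure(
           list(mu = mu, sigma = sigma, n_sigma = n_sigma,
                threshold = threshold, iterations = iter,
                converged = converged),
           class = "background_stats"),
         n_events = nrow(events),
         config = attr(trace, "config", exact = TRUE),
         trail = do.call(rbind, trail)),
    class = "particle_events")
}

# internal: counts vector from a time_trace or numeric input
trace_counts <- function(trace) {
  if (is.data.frame(trace)) {
    if (!"counts" %in% names(trace)) {
      stop("trace data.frame must have a 'counts' column", call. = FALSE)
    }
    trace$counts
  } else if (is.numeric(trace)) {
    as.numeric(trace)
  } else {
    stop("'trace' must be a time_trace, data.frame or numeric vector",
         call. = FALSE)
  }
}

#' Combine or drop particle events split over consecutive dwells
#'
#' An ion plume can straddle two consecutive dwell times, showing up as two
#' adjacent above-threshold dwells. Runs of adjacent events are either
#' summed into one event (`"merge"`, the default — recovers the full pulse
#' intensity), removed entirely (`"discard"` — excludes incomplete events),
#' or left untouched (`"keep"`).
#'
#' @param events a `particle_events` from [detect_particles()].
#' @param mode `"merge"`, `"discard"` or `"keep"`.
#' @return a `particle_events` with the events table adjusted; the chosen
#'   mode is recorded as `split_mode`.
#' @export
merge_split_events <- function(events, mode = c("merge", "discard", "keep")) {
  mode <- match.arg(mode)
  stopifnot(inherits(events, "particle_events"))
  ev <- events$events
  out <- events
  if (mode != "keep" && nrow(ev) > 1L) {
    stopifnot(!is.unsorted(ev$dwell))
    run <- cumsum(c(1L, diff(ev$dwell) != 1L))
    if (mode == "merge") {
      ev <- data.frame(dwell = tapply(ev$dwell, run, min),
                       raw = tapply(ev$raw, run, sum),
                       net = tapply(ev$net, run, sum), row.names = NULL)
    } else {  # discard runs longer than one dwell
      keep <- run %in% which(tabulate(run) == 1L)
      ev <- ev[keep, , drop = FALSE]
      rownames(ev) <- NULL
    }
  }
  out$events <- ev
  out$n_events <- nrow(ev)
  out$split_mode <- mode
  out
}

#' Choose the threshold multiplier n for a sample
#'
#' Both candidate multipliers are applied to the trace. The stricter n = 5
#' is kept when it already yields at least `min_events` detected particles
#' (the lower edge of the dilution-acceptance window) or when relaxing to
#' n = 4 recovers no additional events; otherwise n = 4 is chosen for
#' samples whose particle signal overlaps the background. The decision and
#' both candidate counts are attached as attribute `decision` and reported
#' by `message()` when `quiet = FALSE`.
#'
#' @param trace a time trace or numeric counts vector.
#' @param min_events minimum acceptable event count at n = 5 (default 200).
#' @param quiet suppress the decision message.
#' @return integer 4 or 5, with attribute `decision` (a list with both
#'   candidate counts and the reason).
#' @export
choose_n_sigma <- function(trace, min_events = 200L, quiet = FALSE) {
  ev5 <- detect_particles(trace, n_sigma = 5L)
  ev4 <- detect_particles(trace, n_sigma = 4L)
  if (ev5$n_events >= min_events || ev4$n_events <= ev5$n_events) {
    n <- 5L
    reason <- if (ev5$n_events >= min_events) {
      sprintf("n=5 retains %d events (>= %d)", ev5$n_events, min_events)
    } else {
      "relaxing to n=4 recovers no additional events"
    }
  } else {
    n <- 4L
    reason <- sprintf(
      "n=5 retains only %d events (< %d); n=4 recovers %d",
      ev5$n_events, min_events, ev4$n_events)
  }
  decision <- list(n_sigma = n, count_n5 = ev5$n_events,
                   count_n4 = ev4$n_events, min_events = min_events,
                   reason = reason)
  if (!quiet) {
    message(sprintf("choose_n_sigma: %s -> n = %d", reason, n))
  }
  structure(n, decision = decision)
}
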