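#' Write / read a time trace as delimited text
#'
#' Traces are stored as two tab-separated columns (`dwell`, `counts`)
#' preceded by `# key=value` header lines carrying the acquisition
#' configuration. The round trip is lossless to full double precision.
#'
#' @param trace a `time_trace`.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `time_trace` (without simulation ground truth).
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace), all(c("dwell", "counts") %in% names(trace)))
  config <- attr(trace, "config", exact = TRUE)
  lines <- character(0)
  if (!is.null(config)) {
    keys <- names(config)
    lines <- sprintf("# %s=%s", keys,
                     vapply(config[keys], format_num, character(1)))
  }
  lines <- c(lines, "dwell\tcounts",
             sprintf("%d\t%s", trace$dwell, format_num(trace$counts)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  raw <- readLines(path)
  hdr <- grepl("^#", raw)
  meta <- parse_kv(sub("^#\\s*", "", raw[hdr]))
  body <- raw[!hdr]
  if (length(body) < 2L) stop("trace file has no data rows", call. = FALSE)
  body <- body[-1L]  # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed trace line %d: expected 2 fields",
                 which(!hdr)[-1L][bad[1]] + 0L), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value in trace body", call. = FALSE)
  config <- NULL
  cfg_keys <- c("dwell_time", "n_dwells", "sample_flow",
                "transport_efficiency", "response_slope", "background_mean",
                "dilution_factor", "split_prob", "sd_flicker")
  if (all(cfg_keys %in% names(meta))) {
    config <- do.call(acquisition_config,
                      lapply(meta[cfg_keys], as.numeric))
  }
  structure(data.frame(dwell = m[, 1], counts = m[, 2]),
            config = config, class = c("time_trace", "data.frame"))
}

#' Write / read a detected particle list
#'
#' Events are stored as tab-separated `dwell`, `net_intensity` columns with
#' the background statistics in `# key=value` headers, so a particle list
#' can be re-quantified without the original trace.
#'
#' @param events a `particle_events`.
#' @param path file path.
#' @return `write_particles` returns `path` invisibly; `read_particles`
#'   returns a `particle_events`.
#' @export
write_particles <- function(events, path) {
  stopifnot(inherits(events, "particle_events"))
  bg <- events$background
  lines <- c(
    sprintf("# mu=%s", format_num(bg$mu)),
    sprintf("# sigma=%s", format_num(bg$sigma)),
    sprintf("# n_sigma=%s", format_num(bg$n_sigma)),
    sprintf("# threshold=%s", format_num(bg$threshold)),
    sprintf("# iterations=%d", bg$iterations),
    "dwell\tnet_intensity",
    sprintf("%d\t%s", events$events$dwell, format_num(events$events$net)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  raw <- readLines(path)
  hdr <- grepl("^#", raw)
  meta <- parse_kv(sub("^#\\s*", "", raw[hdr]))
  for (k in c("mu", "sigma", "n_sigma", "threshold")) {
    if (!k %in% names(meta)) {
      stop(sprintf("particle file missing header '%s'", k), call. = FALSE)
    }
  }
  body <- raw[!hdr][-1L]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("malformed particle line: expected 2 fields", call. = FALSE)
    }
    m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
    ev <- data.frame(dwell = m[, 1],
                     raw = m[, 2] + as.numeric(meta$mu), net = m[, 2])
  } else {
    ev <- data.frame(dwell = integer(0), raw = numeric(0), net = numeric(0))
  }
  structure(
    list(events = ev,
         background = structure(
           list(mu = as.numeric(meta$mu), sigma = as.numeric(meta$sigma),
                n_sigma = as.numeric(meta$n_sigma),
                threshold = as.numeric(meta$threshold),
                iterations = as.integer(meta$iterations %||% NA),
                converged = TRUE),
           class = "background_stats"),
         n_events = nrow(ev), config = NULL),
    class = "particle_events")
}

#' Write / read a validation study table
#'
#' Tidy tab-separated text with columns `day`, `replicate`, `measurand`,
#' `value`.
#'
#' @param study a `validation_study` (or compatible data.frame).
#' @param path file path.
#' @return `write_study` returns `path` invisibly; `read_study` a
#'   `validation_study`.
#' @export
write_study <- function(study, path) {
  study <- as.data.frame(study)
  need <- c("day", "replicate", "measurand", "value")
  stopifnot(all(need %in% names(study)))
  utils::write.table(study[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  for (k in c("day", "replicate", "measurand", "value")) {
    if (!k %in% names(df)) {
      stop(sprintf("study file missing column '%s'", k), call. = FALSE)
    }
  }
  if (!is.numeric(df$value) || anyNA(df$value)) {
    stop("study 'value' column must be numeric with no missing entries",
         call. = FALSE)
  }
  structure(df, class = c("validation_study", "data.frame"))
}

#' Read ionic calibration standards
#'
#' Tab- or comma-separated text with columns `concentration` and
#' `intensity` (lines starting with `#` ignored).
#'
#' @param path file path.
#' @return data.frame with columns `concentration`, `intensity`.
#' @export
read_standards <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          comment.char = "#", check.names = FALSE)
  if (ncol(df) == 1L) {
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  }
  for (k in c("concentration", "intensity")) {
    if (!k %in% names(df)) {
      stop(sprintf("standards file missing column '%s'", k), call. = FALSE)
    }
  }
  df
}

#' Serialize / restore a calibration model as key=value text
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   a `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  keys <- names(model)
  writeLines(sprintf("%s=%s", keys,
                     vapply(model[keys], format_num, character(1))), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  meta <- parse_kv(readLines(path))
  num <- function(k) as.numeric(meta[[k]])
  calibration_model(
    response_slope = num("response_slope"),
    response_intercept = num("response_intercept"),
    transport_efficiency = num("transport_efficiency"),
    flow = num("flow"), dwell_time = num("dwell_time"),
    r_squared = num("r_squared"),
    reference_material = meta$reference_material %||% NA_character_,
    calibration_date = meta$calibration_date %||% NA_character_)
}

#' Write a report of named quantities
#'
#' Flat, machine-readable `key\tvalue` lines (full double precision, keys in
#' the order given), preceded by optional `# key=value` metadata. Output is
#' byte-identical for identical inputs, so regenerated reports can be
#' compared directly.
#'
#' @param x a named list (or named vector) of scalars, or a data.frame
#'   (written as a tab-separated table).
#' @param path file path.
#' @param meta optional named list written as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, meta = NULL) {
  lines <- character(0)
  if (!is.null(meta)) {
    lines <- sprintf("# %s=%s", names(meta),
                     vapply(meta, format_num, character(1)))
  }
  if (is.data.frame(x)) {
    tmp <- textConnection("out", "w", local = TRUE)
    utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    close(tmp)
    lines <- c(lines, out)
  } else {
    stopifnot(!is.null(names(x)), all(nzchar(names(x))))
    lines <- c(lines, sprintf("%s\t%s", names(x),
                              vapply(x, format_num, character(1))))
  }
  writeLines(lines, path)
  invisible(path)
}

# internal: full-precision, locale-independent scalar formatting
format_num <- function(x) {
  if (is.numeric(x)) format(x, digits = 17, scientific = NA, trim = TRUE)
  else as.character(x)
}

# internal: parse "key=value" lines into a named list of strings
parse_kv <- function(lines) {
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  ok <- lengths(kv) == 2L
  out <- lapply(kv[ok], function(p) trimws(p[2]))
  names(out) <- vapply(kv[ok], function(p) trimws(p[1]), character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
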