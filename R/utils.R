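#' Round to significant figures, half away from zero
#'
#' Report-style rounding used for uncertainty tables: a fixed number of
#' significant figures with ties rounded away from zero (so 12.5 -> 13),
#' unlike [signif()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of significant figures (default 2, the table
#'   convention for uncertainty reporting).
#' @return numeric vector rounded to `digits` significant figures.
#' @examples
#' signif_away(13.28)   # 13
#' signif_away(12.5)    # 13
#' signif_away(0.0466)  # 0.047
#' @export
signif_away <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    p <- digits - ceiling(log10(abs(x[nz]) * (1 + 1e-15)))
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * 10^p + 0.5) / 10^p
  }
  out
}

# internal: scalar positivity / range checks with a readable error
check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (strict) "strictly positive" else "non-negative"),
         call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (upper_open && x >= 1) || (!upper_open && x > 1)) {
    stop(sprintf("'%s' must be in [0, 1%s", name,
                 if (upper_open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

# internal: derive independent sub-stream seeds from one master seed, so each
# stochastic component of a simulation draws from its own reproducible stream
# regardless of evaluation order. Seeds stay below 2^31.
substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
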