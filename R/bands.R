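#' Frequency band definition
#'
#' A band is a named half-open frequency interval `[low, high)` in Hz. The
#' four analysis bands are theta (4-8 Hz), alpha1 (8-10 Hz), alpha2
#' (10-13 Hz) and beta (13-30 Hz); for regional band-power analyses a
#' conventional delta band (1-4 Hz) is prepended.
#'
#' @param name Band label.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return An object of class `band_definition`.
#' @export
#' @examples
#' band_definition("alpha2", 10, 13)
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low)
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Default analysis bands
#'
#' The four connectivity-analysis bands: theta, alpha1, alpha2 and beta.
#'
#' @return Named list of [band_definition] objects.
#' @export
analysis_bands <- function() {
  list(theta  = band_definition("theta",  4, 8),
       alpha1 = band_definition("alpha1", 8, 10),
       alpha2 = band_definition("alpha2", 10, 13),
       beta   = band_definition("beta",   13, 30))
}

#' Bands used for relative band power (delta through beta)
#'
#' @return Named list of [band_definition] objects covering 1-30 Hz.
#' @export
power_bands <- function() {
  c(list(delta = band_definition("delta", 1, 4)), analysis_bands())
}

check_band_vs_rate <- function(band, rate) {
  if (band$high >= rate / 2)
    stop(sprintf("band '%s' upper edge %g Hz is at or above Nyquist (%g Hz)",
                 band$name, band$high, rate / 2), call. = FALSE)
  invisible(TRUE)
}
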