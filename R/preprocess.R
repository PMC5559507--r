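#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a Butterworth band-pass applied
#' forward-backward (`signal::filtfilt`), i.e. with zero phase shift --
#' essential ahead of phase-based connectivity. The default 4th-order design
#' gives well over 20 dB attenuation one octave outside the passband after
#' the two passes.
#'
#' @param rec An [eeg_recording].
#' @param band A [band_definition]; `band$high` must be below Nyquist.
#' @param order Butterworth order (per pass), default 4.
#' @return A filtered [eeg_recording] with attribute `"band"`.
#' @export
eeg_bandpass <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_definition"))
  check_band_vs_rate(band, rec$rate)
  bf <- signal::butter(order, c(band$low, band$high) / (rec$rate / 2),
                       type = "pass")
  out <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  res <- eeg_recording(out, rec$rate, rec$labels, rec$positions)
  attr(res, "band") <- band
  res
}

# FFT analytic signal of a real vector (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase by sliding-window Hilbert transform
#'
#' The recording is tiled with Hann-tapered windows of `window_s` seconds at
#' 50% overlap; each window's analytic signal contributes its central half,
#' so every interior sample is produced exactly once and window-edge
#' artifacts are discarded. Samples in the first and last quarter window
#' (and any untiled tail) are flagged invalid, as are samples whose analytic
#' amplitude is numerically zero (undefined phase).
#'
#' @param rec An [eeg_recording], typically band-pass filtered.
#' @param window_s Window length in seconds (default 4).
#' @param overlap Window overlap fraction; only 0.5 is supported (the
#'   central-half tiling is defined by it).
#' @return Object of class `phase_tensor`: list with `phase` (channels x
#'   samples, radians in (-pi, pi]), `valid` (logical per sample x channel),
#'   `rate`, `labels` and the `band` attribute of `rec` if present.
#' @export
hilbert_phase <- function(rec, window_s = 4, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!isTRUE(all.equal(overlap, 0.5)))
    stop("only 50% window overlap is supported", call. = FALSE)
  n <- round(window_s * rec$rate)
  if (n %% 2L != 0L) n <- n + 1L
  T <- ncol(rec$data)
  if (T < n)
    stop("recording shorter than one Hilbert window", call. = FALSE)
  hop <- n %/% 2L
  quarter <- n %/% 4L
  # periodic Hann taper: sinusoids on the window's DFT grid stay exactly
  # three-bin, so their analytic phase is recovered to machine precision
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))
  starts <- seq(1L, T - n + 1L, by = hop)
  m <- nrow(rec$data)
  phase <- matrix(NA_real_, m, T)
  valid <- matrix(FALSE, m, T)
  centre <- quarter:(3L * quarter - 1L)  # offsets of the central half
  for (ch in seq_len(m)) {
    x <- rec$data[ch, ]
    for (s in starts) {
      a <- analytic_signal(x[s:(s + n - 1L)] * w)
      idx <- s + centre
      phase[ch, idx] <- Arg(a[centre + 1L])
      valid[ch, idx] <- Mod(a[centre + 1L]) > 1e-12
    }
  }
  structure(list(phase = phase, valid = valid, rate = rec$rate,
                 labels = rec$labels, band = attr(rec, "band")),
            class = "phase_tensor")
}

#' @export
print.phase_tensor <- function(x, ...) {
  cat(sprintf("<phase_tensor> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$phase), ncol(x$phase), x$rate,
              if (is.null(x$band)) "broadband" else x$band$name))
  invisible(x)
}

# Welch power spectral density: Hann-tapered segments, 50% overlap,
# averaged periodograms. Returns list(freq, psd) per channel (psd is a
# channels x freq matrix). Absolute scale is irrelevant for relative power.
welch_psd <- function(data, rate, seg_s = 2) {
  n <- round(seg_s * rate)
  T <- ncol(data)
  if (T < n) n <- T
  hop <- max(1L, n %/% 2L)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  starts <- seq(1L, T - n + 1L, by = hop)
  nf <- n %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * rate / n
  psd <- matrix(0, nrow(data), nf)
  for (s in starts) {
    seg <- data[, s:(s + n - 1L), drop = FALSE] *
      matrix(w, nrow(data), n, byrow = TRUE)
    P <- Mod(t(apply(seg, 1L, fft)))^2
    psd <- psd + P[, seq_len(nf), drop = FALSE]
  }
  list(freq = freq, psd = psd / length(starts))
}

#' Relative band power per channel or region
#'
#' Welch spectral power in each band divided by the power in `total_range`.
#' Frequency bins are assigned half-open (`low <= f < high`), so a band set
#' that tiles `total_range` yields fractions summing to one per channel.
#'
#' @param rec An [eeg_recording].
#' @param bands List of [band_definition]s (default [power_bands()]).
#' @param total_range Length-2 numeric, denominator frequency range in Hz
#'   (default `c(1, 30)`).
#' @param roi_map Optional data frame (`channel`, `roi`); if given, rows are
#'   averaged within regions.
#' @param seg_s Welch segment length in seconds (default 2).
#' @return Data frame of relative power, one row per channel (or ROI), one
#'   column per band.
#' @export
relative_band_power <- function(rec, bands = power_bands(),
                                total_range = c(1, 30), roi_map = NULL,
                                seg_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bands) == 0L) stop("empty band set", call. = FALSE)
  if (all(rec$data == 0))
    stop("all-zero recording: relative power undefined", call. = FALSE)
  sp <- welch_psd(rec$data, rec$rate, seg_s)
  in_total <- sp$freq >= total_range[1] & sp$freq < total_range[2]
  total <- rowSums(sp$psd[, in_total, drop = FALSE])
  if (any(total <= 0))
    stop("channel with zero power in total_range", call. = FALSE)
  rel <- sapply(bands, function(b) {
    sel <- sp$freq >= b$low & sp$freq < b$high
    rowSums(sp$psd[, sel, drop = FALSE]) / total
  })
  rel <- matrix(rel, nrow = nrow(rec$data),
                dimnames = list(rec$labels, vapply(bands, `[[`, "", "name")))
  if (!is.null(roi_map)) {
    keep <- rec$labels %in% roi_map$channel
    roi <- roi_map$roi[match(rec$labels[keep], roi_map$channel)]
    rel <- apply(rel[keep, , drop = FALSE], 2L,
                 function(col) tapply(col, roi, mean))
  }
  as.data.frame(rel)
}
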