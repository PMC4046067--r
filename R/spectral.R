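#' Frequency of an FFT bin on the analysis grid
#'
#' EEG power spectra are computed for consecutive 4-s epochs sampled at
#' 250 Hz.  Although a 4-s epoch holds 1000 samples, the printed spectral
#' resolution of 0.244 Hz implies a 1024-point transform: epochs are
#' zero-padded from 1000 to 1024 points, so bin `k` sits at
#' `k * 250 / 1024` Hz.  The retained analysis grid spans bins 4 through
#' 196 (0.98-47.85 Hz at 2-dp printing precision), 193 bins in total.
#'
#' @param k integer bin index (vectorized), `0 <= k <= 512`.
#' @return frequency in Hz.
#' @examples
#' round(bin_frequency(c(4, 16, 196)), 2)  # 0.98  3.91 47.85
#' @export
bin_frequency <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k != floor(k))) {
    stop("bin index must be integer-valued", call. = FALSE)
  }
  if (any(k < 0 | k > 512)) {
    stop("bin index out of range [0, 512]", call. = FALSE)
  }
  k * 250 / 1024
}

# retained bin indices of the analysis grid
GRID_BINS <- 4:196

#' The retained EEG frequency grid
#'
#' @return data frame with columns `bin` (FFT bin index, 4-196) and
#'   `freq_hz` (bin-center frequency).
#' @export
eeg_bin_grid <- function() {
  data.frame(bin = GRID_BINS, freq_hz = bin_frequency(GRID_BINS))
}

#' Standard EEG frequency bands
#'
#' Band edges as conventionally printed: delta 0.98-3.91 Hz, theta (REMS)
#' 5-9 Hz, upper theta 8.5-11 Hz, beta-2 20-35 Hz, gamma-1 35-48 Hz.
#' Gamma-1 extends past the top retained bin and is clipped to the grid.
#'
#' @return data frame with columns `band`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    band  = c("delta", "theta", "upper_theta", "beta2", "gamma1"),
    lo_hz = c(0.98, 5, 8.5, 20, 35),
    hi_hz = c(3.91, 9, 11, 35, 48),
    stringsAsFactors = FALSE
  )
}

#' Grid bins belonging to a band
#'
#' Membership is by bin-center frequency rounded to the printed 2-dp
#' precision, compared inclusively against `[lo_hz, hi_hz]` (so bin 4 at
#' 0.9766 Hz belongs to the 0.98-Hz delta edge).  Bands are clipped to the
#' retained grid.
#'
#' @param lo_hz,hi_hz inclusive band edges in Hz.
#' @return integer vector of FFT bin indices (subset of 4:196).
#' @export
band_bins <- function(lo_hz, hi_hz) {
  if (!is.numeric(lo_hz) || !is.numeric(hi_hz) || hi_hz <= lo_hz) {
    stop("band edges must satisfy lo < hi", call. = FALSE)
  }
  f <- round(bin_frequency(GRID_BINS), 2)
  bins <- GRID_BINS[f >= lo_hz - 1e-9 & f <= hi_hz + 1e-9]
  if (length(bins) == 0L) {
    stop("band [", lo_hz, ", ", hi_hz, "] contains no grid bins",
         call. = FALSE)
  }
  bins
}

#' Power spectrum of a single 4-s epoch
#'
#' Hanning-windowed, zero-padded (1000 to 1024 points) squared-magnitude
#' periodogram, restricted to the retained grid bins 4-196.  No absolute
#' calibration is applied: every downstream quantity is a ratio or a
#' percentage, so only relative power matters.
#'
#' @param signal numeric vector of exactly 1000 samples (4 s at 250 Hz).
#' @return named numeric vector of length 193; names are bin-center
#'   frequencies in Hz.
#' @export
epoch_psd <- function(signal) {
  if (length(signal) != 1000L) {
    stop("epoch must contain exactly 1000 samples (4 s at 250 Hz)",
         call. = FALSE)
  }
  if (any(!is.finite(signal))) {
    stop("epoch contains non-finite samples", call. = FALSE)
  }
  n <- 1000L
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  x <- c(signal * w, rep(0, 1024 - n))
  p <- Mod(stats::fft(x))^2
  out <- p[GRID_BINS + 1L]
  names(out) <- bin_frequency(GRID_BINS)
  out
}

#' State-conditional normalized mean EEG spectrum
#'
#' Averages the per-epoch power over the artifact-free epochs of one
#' vigilance state inside a protocol window, then expresses each bin as a
#' percentage of the summed power over all 193 retained bins (the output
#' sums to 100).
#'
#' @param frames a `spectral_frame` (see [simulate_spectra()]).
#' @param hyp matching hypnogram.
#' @param state one of `"W"`, `"N"`, `"R"`.
#' @param window protocol window name or `c(start_h, end_h)`.
#' @return named numeric vector of length 193 summing to 100, or `NULL`
#'   (with a warning) when no qualifying epoch exists.
#' @export
state_spectrum <- function(frames, hyp, state, window = "BSL-L") {
  check_frame_hyp(frames, hyp)
  state <- match.arg(state, c("W", "N", "R"))
  sel <- epochs_in_window(hyp, window) & hyp$state == state & !hyp$artifact
  if (!any(sel)) {
    warning("no artifact-free ", state, " epochs in window; returning NULL",
            call. = FALSE)
    return(NULL)
  }
  m <- colMeans(frames$power[sel, , drop = FALSE])
  out <- 100 * m / sum(m)
  names(out) <- frames$freq_hz
  out
}

#' Mean power within a frequency band
#'
#' Mean over the grid bins whose (2-dp rounded) center frequency lies in
#' the closed band interval; accepts either a single spectrum (length-193
#' vector) or an epoch-by-bin matrix, in which case the band mean is
#' returned per epoch.
#'
#' @param x numeric vector of length 193 or matrix with 193 columns.
#' @param lo_hz,hi_hz band edges in Hz.
#' @return scalar (vector input) or per-epoch numeric vector (matrix input).
#' @export
band_power <- function(x, lo_hz, hi_hz) {
  bins <- band_bins(lo_hz, hi_hz)
  idx <- match(bins, GRID_BINS)
  if (is.matrix(x)) {
    if (ncol(x) != length(GRID_BINS)) {
      stop("matrix must have 193 grid columns", call. = FALSE)
    }
    return(rowMeans(x[, idx, drop = FALSE]))
  }
  if (length(x) != length(GRID_BINS)) {
    stop("spectrum must have 193 grid values", call. = FALSE)
  }
  mean(x[idx])
}

#' Theta peak frequency of a REMS spectrum
#'
#' The frequency at which EEG power density is maximal, searched within
#' the REMS theta window (5-9 Hz by default) so broadband delta cannot win
#' the argmax; ties break toward the lower frequency.  Set
#' `global = TRUE` to search the whole retained grid instead.
#'
#' @param spectrum numeric vector of length 193 on the retained grid.
#' @param window numeric `c(lo, hi)` search window in Hz.
#' @param global if `TRUE`, ignore `window` and search all bins.
#' @return peak frequency in Hz, or `NA_real_` (with a warning) on an
#'   empty/NULL spectrum.
#' @export
theta_peak_frequency <- function(spectrum, window = c(5, 9), global = FALSE) {
  if (is.null(spectrum) || length(spectrum) == 0L) {
    warning("empty spectrum; returning NA", call. = FALSE)
    return(NA_real_)
  }
  if (length(spectrum) != length(GRID_BINS)) {
    stop("spectrum must have 193 grid values", call. = FALSE)
  }
  bins <- if (global) GRID_BINS else band_bins(window[1], window[2])
  idx <- match(bins, GRID_BINS)
  v <- spectrum[idx]
  bin_frequency(bins[which.max(v)])  # which.max -> first (lowest) on ties
}

# shared validation: frame and hypnogram on the same epoch grid
check_frame_hyp <- function(frames, hyp) {
  if (!inherits(frames, "spectral_frame")) {
    stop("`frames` must be a spectral_frame", call. = FALSE)
  }
  if (!inherits(hyp, "hypnogram")) {
    stop("`hyp` must be a hypnogram", call. = FALSE)
  }
  if (nrow(frames$power) != nrow(hyp)) {
    stop("spectral frame and hypnogram have mismatched epoch counts",
         call. = FALSE)
  }
  invisible(TRUE)
}
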