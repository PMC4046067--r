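#' Default equal-epoch interval counts per protocol window
#'
#' NREMS delta time courses use 12 (BSL-L), 5 (BSL-D), 9 (Rec-D1),
#' 11 (Rec-L) and 6 (Rec-D2) intervals per 12-h window, each receiving an
#' equal number of NREMS epochs within each subject; the SD-L waking
#' analysis uses 36 intervals of equal waking-epoch counts.
#'
#' @return named integer vector.
#' @export
default_interval_counts <- function() {
  c("BSL-L" = 12L, "BSL-D" = 5L, "Rec-D1" = 9L, "Rec-L" = 11L,
    "Rec-D2" = 6L, "SD-L" = 36L)
}

#' Partition a window's state epochs into equal-count intervals
#'
#' The artifact-free epochs of `state` inside `window` are taken in
#' chronological order and split into `n_intervals` contiguous groups of
#' size `floor(m/n)` or `ceiling(m/n)`; remainder epochs go to the
#' earliest intervals, which keeps early-recovery intervals (where the
#' dynamics are fastest) at least as well sampled.
#'
#' @param hyp a hypnogram.
#' @param window protocol window name or `c(start_h, end_h)`.
#' @param state one of `"W"`, `"N"`, `"R"`.
#' @param n_intervals number of intervals.
#' @return object of class `interval_partition`: list with `window`,
#'   `state`, `n_intervals`, `intervals` (list of epoch-index vectors) and
#'   `mid_zt_h` (mean ZT hour of each interval's epochs).
#' @export
partition_equal_epochs <- function(hyp, window, state, n_intervals) {
  stopifnot(inherits(hyp, "hypnogram"))
  state <- match.arg(state, c("W", "N", "R"))
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("n_intervals must be >= 1", call. = FALSE)
  idx <- which(epochs_in_window(hyp, window) & hyp$state == state &
                 !hyp$artifact)
  m <- length(idx)
  if (m < n_intervals) {
    stop("insufficient data: ", m, " artifact-free ", state,
         " epochs for ", n_intervals, " intervals in window",
         call. = FALSE)
  }
  base <- m %/% n_intervals
  extra <- m %% n_intervals
  sizes <- rep(base, n_intervals) + c(rep(1L, extra),
                                      rep(0L, n_intervals - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_intervals] + 1L)
  intervals <- Map(function(s, e) idx[s:e], starts, ends)
  structure(
    list(window = if (is.character(window)) window else paste(window,
                                                              collapse = "-"),
         state = state, n_intervals = n_intervals, intervals = intervals,
         mid_zt_h = vapply(intervals,
                           function(i) mean(hyp$zt_sec[i]) / 3600,
                           numeric(1))),
    class = "interval_partition"
  )
}

# per-epoch delta band power of a frame
delta_series <- function(frames) {
  band_power(frames$power, 0.98, 3.91)
}

#' NREMS delta-power time course
#'
#' Mean delta power (0.98-3.91 Hz) per equal-NREMS-epoch interval across
#' the five NREMS windows (SD-L is skipped: no NREMS analysis there),
#' individually normalized to the mean delta power in NREMS during the
#' last 4 h of the baseline light period (ZT 8-12, the lowest level
#' reached during baseline).
#'
#' @param frames a `spectral_frame`.
#' @param hyp matching hypnogram.
#' @param interval_counts named interval counts
#'   (default [default_interval_counts()]).
#' @return object of class `delta_timecourse`: data frame with `window`,
#'   `interval`, `mid_zt_h`, `delta_raw`, `delta_pct`; the normalization
#'   reference is stored as attribute `reference`.
#' @export
delta_timecourse <- function(frames, hyp,
                             interval_counts = default_interval_counts()) {
  check_frame_hyp(frames, hyp)
  dser <- delta_series(frames)
  ref_sel <- hyp$zt_sec / 3600 >= 8 & hyp$zt_sec / 3600 < 12 &
    hyp$state == "N" & !hyp$artifact
  if (!any(ref_sel)) stop("no reference NREMS epochs in ZT 8-12",
                          call. = FALSE)
  reference <- mean(dser[ref_sel])
  if (reference <= 0) stop("non-positive normalization reference",
                           call. = FALSE)
  windows <- c("BSL-L", "BSL-D", "Rec-D1", "Rec-L", "Rec-D2")
  rows <- lapply(windows, function(w) {
    part <- partition_equal_epochs(hyp, w, "N", interval_counts[[w]])
    raw <- vapply(part$intervals, function(i) mean(dser[i]), numeric(1))
    data.frame(window = w, interval = seq_along(raw),
               mid_zt_h = part$mid_zt_h, delta_raw = raw,
               delta_pct = 100 * raw / reference)
  })
  out <- do.call(rbind, rows)
  structure(out, reference = reference,
            class = c("delta_timecourse", "data.frame"))
}

#' Immediate delta-power rebound after sleep deprivation
#'
#' Delta power in the first equal-epoch interval of recovery (Rec-D1
#' interval 1) as a percentage of delta power in the interval immediately
#' preceding SD (BSL-L interval 12).
#'
#' @param timecourse a [delta_timecourse()] result.
#' @return rebound in percent.
#' @export
immediate_rebound <- function(timecourse) {
  stopifnot(inherits(timecourse, "delta_timecourse"))
  pre <- timecourse$delta_raw[timecourse$window == "BSL-L" &
                                timecourse$interval ==
                                max(timecourse$interval[
                                  timecourse$window == "BSL-L"])]
  post <- timecourse$delta_raw[timecourse$window == "Rec-D1" &
                                 timecourse$interval == 1L]
  if (length(pre) != 1L || length(post) != 1L) {
    stop("insufficient data: missing BSL-L or Rec-D1 interval",
         call. = FALSE)
  }
  100 * post / pre
}

#' Slow-wave-energy accumulation curve
#'
#' Hourly NREMS delta energy (delta band power summed over that hour's
#' artifact-free NREMS epochs; 0 when the hour holds none), differenced
#' against the same ZT hour of the baseline day, cumulatively summed from
#' SD onset and expressed as a percentage of the total delta energy of
#' the 24-h baseline day.
#'
#' @param frames a `spectral_frame`.
#' @param hyp matching hypnogram.
#' @param baseline_day 1-based baseline day index.
#' @return object of class `swe_curve`: data frame with `hour`,
#'   `swe_diff` and `swe_acc_pct`; baseline total stored as attribute
#'   `baseline_total`.
#' @export
swe_accumulation <- function(frames, hyp, baseline_day = 1L) {
  check_frame_hyp(frames, hyp)
  dser <- delta_series(frames)
  contrib <- ifelse(hyp$state == "N" & !hyp$artifact, dser, 0)
  hour_of <- floor(hyp$zt_sec / 3600)
  energy <- tapply(contrib, hour_of, sum)
  hours <- as.integer(names(energy))
  b0 <- (baseline_day - 1L) * 24L
  base_hours <- b0:(b0 + 23L)
  if (!all(base_hours %in% hours)) stop("baseline day incomplete",
                                        call. = FALSE)
  baseline <- energy[match(base_hours, hours)]
  total <- sum(baseline)
  if (total <= 0) stop("zero baseline delta energy", call. = FALSE)
  post <- hours[hours >= b0 + 24L]
  d <- as.numeric(energy[match(post, hours)] - baseline[(post %% 24L) + 1L])
  structure(
    data.frame(hour = post, swe_diff = 100 * d / total,
               swe_acc_pct = 100 * cumsum(d) / total),
    baseline_total = total,
    class = c("swe_curve", "data.frame")
  )
}

#' Waking-band time course during sleep deprivation
#'
#' Mean power of the waking EEG bands (upper theta 8.5-11 Hz, beta-2
#' 20-35 Hz, gamma-1 35-48 Hz, by default) over the artifact-free waking
#' epochs of the SD period, expressed as a percentage of the mean power
#' in the same band during spontaneous wakefulness in the baseline light
#' period.  `mode = "interval"` uses 36 intervals with equal waking-epoch
#' counts; `mode = "hourly"` uses the 12 clock hours of SD.
#'
#' @param frames a `spectral_frame`.
#' @param hyp matching hypnogram.
#' @param bands data frame with `band`, `lo_hz`, `hi_hz`; defaults to the
#'   three SD bands.
#' @param mode `"interval"` (36 equal-epoch bins) or `"hourly"`.
#' @return data frame with `band`, `interval` (or `hour`), `mid_zt_h`,
#'   `pct_of_baseline`.
#' @export
waking_band_timecourse <- function(frames, hyp,
                                   bands = eeg_bands()[
                                     eeg_bands()$band %in%
                                       c("upper_theta", "beta2", "gamma1"), ],
                                   mode = c("interval", "hourly")) {
  check_frame_hyp(frames, hyp)
  mode <- match.arg(mode)
  base_sel <- epochs_in_window(hyp, "BSL-L") & hyp$state == "W" &
    !hyp$artifact
  if (!any(base_sel)) stop("no baseline waking epochs", call. = FALSE)
  groups <- if (mode == "interval") {
    part <- partition_equal_epochs(hyp, "SD-L", "W", 36L)
    list(idx = part$intervals, mid = part$mid_zt_h,
         key = seq_len(36L), key_name = "interval")
  } else {
    zt_h <- hyp$zt_sec / 3600
    hrs <- 24:35
    idx <- lapply(hrs, function(h) {
      which(zt_h >= h & zt_h < h + 1 & hyp$state == "W" & !hyp$artifact)
    })
    if (any(lengths(idx) == 0L)) {
      stop("insufficient data: SD hour without waking epochs",
           call. = FALSE)
    }
    list(idx = idx, mid = hrs + 0.5, key = hrs, key_name = "hour")
  }
  rows <- lapply(seq_len(nrow(bands)), function(bi) {
    bp <- band_power(frames$power, bands$lo_hz[bi], bands$hi_hz[bi])
    ref <- mean(bp[base_sel])
    vals <- vapply(groups$idx, function(i) mean(bp[i]), numeric(1))
    df <- data.frame(band = bands$band[bi], key = groups$key,
                     mid_zt_h = groups$mid,
                     pct_of_baseline = 100 * vals / ref)
    names(df)[2] <- groups$key_name
    df
  })
  do.call(rbind, rows)
}
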