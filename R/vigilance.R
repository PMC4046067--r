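#' Vigilance-state time budgets
#'
#' Time spent in each vigilance state, expressed as a percentage of total
#' recording time per bin of `bin_h` hours inside a protocol window, plus
#' REMS as a percentage of total sleep time (TST = NREMS + REMS).
#' Artifact-flagged epochs count toward recording time with their scored
#' state (artifacts are excluded only from spectral analyses, not from
#' time budgets).  A bin with zero sleep has an undefined REMS/TST and is
#' reported as `NA`.
#'
#' @param hyp a hypnogram.
#' @param window protocol window name or `c(start_h, end_h)`.
#' @param bin_h bin width in hours (2 or 12 in the protocol; any divisor
#'   of the window length is accepted).
#' @return data frame with one row per bin: `bin_start_h`, `bin_end_h`,
#'   `pct_w`, `pct_n`, `pct_r`, `rems_tst`.
#' @export
state_percentages <- function(hyp, window = "BSL-L", bin_h = 12) {
  stopifnot(inherits(hyp, "hypnogram"))
  b <- window_bounds(window)
  if (bin_h > diff(b)) {
    stop("bin longer than window", call. = FALSE)
  }
  sel <- epochs_in_window(hyp, window)
  if (!any(sel)) stop("window not covered by hypnogram", call. = FALSE)
  zt_h <- hyp$zt_sec[sel] / 3600
  st <- hyp$state[sel]
  starts <- seq(b[1], b[2] - bin_h, by = bin_h)
  out <- lapply(starts, function(s0) {
    in_bin <- zt_h >= s0 & zt_h < s0 + bin_h
    tot <- sum(in_bin)
    cw <- sum(st[in_bin] == "W"); cn <- sum(st[in_bin] == "N")
    cr <- sum(st[in_bin] == "R")
    data.frame(
      bin_start_h = s0, bin_end_h = s0 + bin_h,
      pct_w = 100 * cw / tot, pct_n = 100 * cn / tot,
      pct_r = 100 * cr / tot,
      rems_tst = if (cn + cr > 0) 100 * cr / (cn + cr) else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Accumulated state difference from baseline
#'
#' For each completed hour of the SD + recovery portion (ZT 24 onward),
#' the difference between minutes spent in `state` during that hour and
#' minutes spent in `state` during the same ZT hour of the baseline day,
#' cumulatively summed from SD onset.  Hours not fully covered by the
#' hypnogram are excluded with a warning.
#'
#' @param hyp a hypnogram covering the baseline day and some post-baseline
#'   hours.
#' @param state one of `"W"`, `"N"`, `"R"`.
#' @param baseline_day which recording day (1-based) is the baseline;
#'   the protocol uses day 1.
#' @return data frame with `hour` (ZT hour since recording start),
#'   `diff_min` (that hour's difference) and `acc_min` (running sum).
#' @export
accumulated_state_difference <- function(hyp, state, baseline_day = 1L) {
  stopifnot(inherits(hyp, "hypnogram"))
  state <- match.arg(state, c("W", "N", "R"))
  epoch_min <- 4 / 60
  hour_of <- floor(hyp$zt_sec / 3600)
  per_hour <- tapply(hyp$state == state, hour_of, sum) * epoch_min
  counts <- tapply(hyp$state, hour_of, length)
  hours <- as.integer(names(per_hour))
  full <- counts == 900L                 # 900 4-s epochs per complete hour
  if (any(!full)) {
    warning("excluding ", sum(!full), " incomplete hour(s)", call. = FALSE)
    per_hour <- per_hour[full]; hours <- hours[full]
  }
  b0 <- (baseline_day - 1L) * 24L
  base_hours <- b0:(b0 + 23L)
  if (!all(base_hours %in% hours)) {
    stop("baseline day incomplete", call. = FALSE)
  }
  baseline <- per_hour[match(base_hours, hours)]
  post <- hours[hours >= b0 + 24L]
  if (length(post) == 0L) {
    return(data.frame(hour = integer(0), diff_min = numeric(0),
                      acc_min = numeric(0)))
  }
  d <- per_hour[match(post, hours)] - baseline[(post %% 24L) + 1L]
  data.frame(hour = post, diff_min = as.numeric(d),
             acc_min = cumsum(as.numeric(d)))
}
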