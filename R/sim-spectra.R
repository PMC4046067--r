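#' Trajectory of the homeostatic delta drive (process S)
#'
#' Classical two-process update evaluated per 4-s epoch: during
#' wakefulness S relaxes exponentially toward the upper asymptote with
#' time constant `tau_rise_h`; during sleep (NREMS or REMS) it relaxes
#' toward the lower asymptote with `tau_decay_h`.
#'
#' @param states character/factor vector of epoch states (W/N/R).
#' @param homeostat list with `lower`, `upper`, `tau_rise_h`,
#'   `tau_decay_h`.
#' @param s0 initial value; default starts three-quarters of the way up
#'   (light onset follows the active dark phase, so pressure is high).
#' @param epoch_s epoch length (s).
#' @return numeric vector of S at each epoch (value *entering* the epoch).
#' @export
process_s <- function(states, homeostat, s0 = NULL, epoch_s = 4) {
  ua <- homeostat$upper
  la <- homeostat$lower
  dt <- epoch_s / 3600
  kr <- exp(-dt / homeostat$tau_rise_h)
  kd <- exp(-dt / homeostat$tau_decay_h)
  if (is.null(s0)) s0 <- la + 0.75 * (ua - la)
  n <- length(states)
  s <- numeric(n)
  cur <- s0
  wake <- states == "W"
  for (i in seq_len(n)) {
    s[i] <- cur
    cur <- if (wake[i]) ua - (ua - cur) * kr else la + (cur - la) * kd
  }
  s
}

#' Simulate epoch spectra for a hypnogram
#'
#' Builds the epoch-by-bin power matrix on the fixed 193-bin grid.
#' State-conditional templates: wakefulness carries a 1/f background with
#' a modest active-wake theta bump; NREMS carries the same background
#' outside delta, while the delta bins (0.98-3.91 Hz) are exactly
#' proportional to the homeostatic drive S (so the noiseless NREMS delta
#' series *is* the S trajectory up to one scale factor); REMS carries a
#' theta peak at `params$tpf_hz`.  During SD (ZT 24-36), waking upper
#' theta, beta-2 and gamma-1 bins are multiplied by saturating
#' time-profiled gains `1 + (g-1) * (1-exp(-t/tau))`.  Multiplicative
#' lognormal noise (`config$noise_sd`) is applied to every bin.
#'
#' When `calibrate_rebound` is `TRUE` (default), the delta drive of
#' Rec-D1 NREMS epochs is rescaled by one constant so that the immediate
#' rebound -- first Rec-D1 equal-epoch interval over last BSL-L interval,
#' exactly as [immediate_rebound()] measures it -- equals
#' `100 * params$rebound_gain` in the noiseless generator.  With `FALSE`
#' the delta series stays purely proportional to S everywhere.
#'
#' @param hypnogram a [simulate_hypnogram()] result.
#' @param params matching [genotype_params()].
#' @param config [sim_config()] sharing the epoch grid.
#' @param calibrate_rebound apply the rebound calibration (see above).
#' @return a `spectral_frame`: list with `power` (epochs x 193 matrix),
#'   `freq_hz`, `epoch_s`, `sample_hz`.
#' @export
simulate_spectra <- function(hypnogram, params, config,
                             calibrate_rebound = TRUE) {
  stopifnot(inherits(hypnogram, "hypnogram"),
            inherits(params, "genotype_params"),
            inherits(config, "sim_config"))
  n <- nrow(hypnogram)
  if (n != protocol_n_epochs()) {
    stop("hypnogram does not span the 72-h protocol", call. = FALSE)
  }
  f <- bin_frequency(GRID_BINS)
  nb <- length(f)
  states <- as.character(hypnogram$state)
  s_traj <- process_s(states, params$homeostat, epoch_s = config$epoch_s)

  wake_t <- 1.2 / f^1.1 + 0.25 * exp(-(f - 7.5)^2 / (2 * 0.8^2))
  bg_t   <- 0.9 / f^1.2
  rem_t  <- 0.5 / f^1.05 +
    1.4 * exp(-(f - params$tpf_hz)^2 / (2 * 0.45^2))
  d_idx <- match(band_bins(0.98, 3.91), GRID_BINS)
  delta_scale <- 2

  power <- matrix(0, n, nb)
  iw <- states == "W"; inr <- states == "N"; ir <- states == "R"
  if (any(iw))  power[iw, ]  <- matrix(wake_t, sum(iw), nb, byrow = TRUE)
  if (any(ir))  power[ir, ]  <- matrix(rem_t, sum(ir), nb, byrow = TRUE)
  if (any(inr)) {
    power[inr, ] <- matrix(bg_t, sum(inr), nb, byrow = TRUE)
    power[inr, d_idx] <- delta_scale * s_traj[inr]
  }

  # SD waking-band gains with saturating onset profile
  zt_h <- hypnogram$zt_sec / 3600
  sd_sel <- iw & zt_h >= 24 & zt_h < 36
  if (any(sd_sel)) {
    tvec <- zt_h[sd_sel] - 24
    g <- params$sd_band_gains
    bands <- list(upper_theta = c(8.5, 11), beta2 = c(20, 35),
                  gamma1 = c(35, 48))
    for (bn in names(bands)) {
      idx <- match(band_bins(bands[[bn]][1], bands[[bn]][2]), GRID_BINS)
      fac <- 1 + (g[[bn]] - 1) * (1 - exp(-tvec / g$tau_profile_h))
      power[sd_sel, idx] <- power[sd_sel, idx] * fac
    }
  }

  # rebound calibration on the noiseless delta drive
  if (calibrate_rebound) {
    p_bsl <- try(partition_equal_epochs(hypnogram, "BSL-L", "N", 12L),
                 silent = TRUE)
    p_rec <- try(partition_equal_epochs(hypnogram, "Rec-D1", "N", 9L),
                 silent = TRUE)
    if (inherits(p_bsl, "try-error") || inherits(p_rec, "try-error")) {
      warning("too few NREMS epochs to calibrate the rebound; skipped",
              call. = FALSE)
    } else {
      m0 <- mean(s_traj[p_bsl$intervals[[12L]]])
      m1 <- mean(s_traj[p_rec$intervals[[1L]]])
      cal <- params$rebound_gain * m0 / m1
      rec1 <- inr & zt_h >= 36 & zt_h < 48
      power[rec1, d_idx] <- power[rec1, d_idx] * cal
    }
  }

  if (config$noise_sd > 0) {
    subject <- attr(hypnogram, "subject")
    if (is.null(subject)) subject <- 0L
    noise <- withr_seed(derive_seed(config$seed, subject, 2L),
                        matrix(stats::rnorm(n * nb, 0, config$noise_sd),
                               n, nb))
    power <- power * exp(noise)
  }

  structure(list(power = power, freq_hz = f, epoch_s = 4L,
                 sample_hz = config$sample_hz),
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat("<spectral_frame> ", nrow(x$power), " epochs x ", ncol(x$power),
      " bins (", round(min(x$freq_hz), 2), "-", round(max(x$freq_hz), 2),
      " Hz)\n", sep = "")
  invisible(x)
}
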