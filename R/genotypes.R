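#' Genotype parameter set for the synthetic generator
#'
#' Bundles everything the generator needs to emulate one genotype:
#' vigilance-state occupancy targets per protocol window, semi-Markov bout
#' scales, the two-process homeostat constants, the delta rebound gain at
#' the end of sleep deprivation, the SD waking-band gains, the REMS theta
#' peak frequency, the artifact rate, the between-genotype variance share
#' for grouped-value simulation, and the free-running period model.
#'
#' Occupancy rows must sum to 1 exactly; use [default_genotypes()] for
#' calibrated values (it renormalizes printed percentages).  Bout scales
#' are validated for semi-Markov feasibility: with occupancy fractions
#' `f` and mean bout lengths `L` (epochs), bout rates `r = f/L` must
#' satisfy `r_W <= r_N` (every wake bout is followed by a NREMS bout) and
#' `r_R <= r_N` (REMS is entered only from NREMS), and the implied routing
#' probabilities must lie in `[0, 1]`.
#'
#' @param label genotype name.
#' @param occupancy 6 x 3 matrix (rows = protocol windows in order, cols =
#'   `W`,`N`,`R`) of target time fractions; each row sums to 1.  The SD-L
#'   row is documentary: SD is simulated as forced wakefulness with
#'   `sd_leak` (below), not from its occupancy row.
#' @param bout_scale list with elements `light` and `dark`, each a named
#'   numeric `c(W=,N=,R=)` of mean bout lengths in 4-s epochs.
#' @param homeostat list `list(lower=, upper=, tau_rise_h=, tau_decay_h=)`:
#'   asymptotes and time constants (hours) of the delta-drive process S.
#' @param rebound_gain multiplier applied to the delta drive at SD end;
#'   the immediate rebound equals `100 * rebound_gain` in the noiseless
#'   generator.
#' @param sd_band_gains list `list(upper_theta=, beta2=, gamma1=,
#'   tau_profile_h=)`: peak multiplicative gains of the waking bands during
#'   SD and the time constant (hours) of the saturating onset profile.
#' @param tpf_hz REMS theta-peak frequency (Hz).
#' @param artifact_rate fraction of epochs flagged as artifact, in `[0,1)`.
#' @param icc_fraction between-genotype variance share used by
#'   [simulate_grouped_values()], in `[0,1]`.
#' @param period_hr free-running circadian period in darkness (20-28 h).
#' @param light_slope period increment per unit `log1p(light intensity)`
#'   (h per log-unit of mW/m^2).
#' @param sd_leak per-epoch NREMS leak probability during forced
#'   wakefulness (residual ~1% NREMS during SD).
#' @return an object of class `genotype_params`.
#' @export
genotype_params <- function(label,
                            occupancy,
                            bout_scale,
                            homeostat = list(lower = 0.05, upper = 1,
                                             tau_rise_h = 8,
                                             tau_decay_h = 1.5),
                            rebound_gain = 1.8,
                            sd_band_gains = list(upper_theta = 2.4,
                                                 beta2 = 1.3, gamma1 = 1.3,
                                                 tau_profile_h = 1),
                            tpf_hz = 7.08,
                            artifact_rate = 0.03,
                            icc_fraction = 0.48,
                            period_hr = 23.7,
                            light_slope = 0.12,
                            sd_leak = 0.011) {
  occupancy <- as.matrix(occupancy)
  if (!all(dim(occupancy) == c(6L, 3L))) {
    stop("occupancy must be a 6 x 3 (window x state) matrix", call. = FALSE)
  }
  colnames(occupancy) <- c("W", "N", "R")
  rownames(occupancy) <- protocol_windows()$window
  if (any(occupancy < 0) ||
      any(abs(rowSums(occupancy) - 1) > 1e-6)) {
    stop("occupancy fractions per window must be nonnegative and sum to 1",
         call. = FALSE)
  }
  for (cond in c("light", "dark")) {
    bs <- bout_scale[[cond]]
    if (is.null(bs) || !all(c("W", "N", "R") %in% names(bs)) || any(bs <= 0)) {
      stop("bout_scale$", cond, " must be positive and named W, N, R",
           call. = FALSE)
    }
  }
  with(homeostat, {
    if (tau_rise_h <= 0 || tau_decay_h <= 0 || upper <= lower || lower < 0) {
      stop("homeostat constants invalid: need 0 <= lower < upper, taus > 0",
           call. = FALSE)
    }
  })
  if (artifact_rate < 0 || artifact_rate >= 1) {
    stop("artifact_rate must lie in [0, 1)", call. = FALSE)
  }
  if (icc_fraction < 0 || icc_fraction > 1) {
    stop("icc_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (period_hr < 20 || period_hr > 28) {
    stop("period_hr must lie in [20, 28] h", call. = FALSE)
  }
  if (rebound_gain <= 0) stop("rebound_gain must be > 0", call. = FALSE)
  if (sd_leak < 0 || sd_leak > 0.02) {
    stop("sd_leak must lie in [0, 0.02]", call. = FALSE)
  }
  p <- structure(
    list(label = label, occupancy = occupancy, bout_scale = bout_scale,
         homeostat = homeostat, rebound_gain = rebound_gain,
         sd_band_gains = sd_band_gains, tpf_hz = tpf_hz,
         artifact_rate = artifact_rate, icc_fraction = icc_fraction,
         period_hr = period_hr, light_slope = light_slope,
         sd_leak = sd_leak),
    class = "genotype_params"
  )
  # feasibility of the semi-Markov routing in every non-SD window
  pw <- protocol_windows()
  for (i in seq_len(6L)[-3L]) {
    routing_probs(p, pw$window[i])  # errors if infeasible
  }
  p
}

# Bout routing probabilities for one window.
# Flow balance with R entered only from N and W exiting only to N:
#   a = P(N -> R) = r_R / r_N,  b = P(R -> N) = (r_N - r_W) / r_R.
routing_probs <- function(params, window) {
  pw <- protocol_windows()
  i <- match(window, pw$window)
  f <- params$occupancy[i, ]
  L <- params$bout_scale[[pw$lighting[i]]][c("W", "N", "R")]
  r <- ifelse(f > 0, f / L, 0)
  if (f["R"] > 0 && f["N"] == 0) {
    stop("window ", window, ": REMS occupancy requires NREMS (R entered ",
         "only from N)", call. = FALSE)
  }
  a <- if (r["N"] > 0) r["R"] / r["N"] else 0
  b <- if (r["R"] > 0) (r["N"] - r["W"]) / r["R"] else 0
  tol <- 1e-9
  if (a > 1 + tol || b < -tol || b > 1 + tol || r["W"] > r["N"] + tol &&
      f["N"] > 0) {
    stop("window ", window, ": occupancy/bout_scale combination is ",
         "infeasible for the semi-Markov bout model (need r_W <= r_N, ",
         "r_R <= r_N, r_N <= r_W + r_R)", call. = FALSE)
  }
  list(rates = r, p_n_to_r = min(max(a, 0), 1), p_r_to_n = min(max(b, 0), 1))
}

#' @export
print.genotype_params <- function(x, ...) {
  cat("<genotype_params>", x$label, "\n")
  cat("  occupancy targets (%):\n")
  print(round(100 * x$occupancy, 1))
  cat("  rebound_gain:", x$rebound_gain,
      " tpf:", x$tpf_hz, "Hz",
      " artifact_rate:", x$artifact_rate, "\n")
  cat("  sd gains: upper_theta", x$sd_band_gains$upper_theta,
      " beta2", x$sd_band_gains$beta2,
      " gamma1", x$sd_band_gains$gamma1, "\n")
  cat("  period:", x$period_hr, "h  + ", x$light_slope,
      "h per log-unit light\n")
  invisible(x)
}

#' Shipped genotype calibration defaults
#'
#' Loads the calibration config shipped with the package
#' (`extdata/genotype_params.json`).  The occupancy entries are published
#' group-mean state percentages per 12-h protocol window for the wild-type
#' and the two humanized PER3 VNTR knock-in lines; rows are renormalized
#' to sum to exactly 1 (printed triplets can sum to 100.1%).  Rebound
#' gains, SD band gains, theta peak frequencies and the ICC fraction are
#' likewise calibration values, not fitted quantities.
#'
#' @param path optional path to an alternative JSON config.
#' @return named list of `genotype_params` (WT, Per3-4/4, Per3-5/5).
#' @export
default_genotypes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "genotype_params.json",
                        package = "somnostat")
  }
  cfg <- jsonlite::read_json(path)
  out <- lapply(cfg$genotypes, function(g) {
    occ <- do.call(rbind, lapply(g$occupancy_pct, unlist))
    occ <- occ / rowSums(occ)  # renormalize printed percentages
    genotype_params(
      label = g$label,
      occupancy = occ,
      bout_scale = lapply(cfg$bout_scale, function(b) unlist(b)),
      homeostat = as.list(cfg$homeostat),
      rebound_gain = g$rebound_gain,
      sd_band_gains = as.list(g$sd_band_gains),
      tpf_hz = g$tpf_hz,
      artifact_rate = cfg$artifact_rate,
      icc_fraction = cfg$icc_fraction,
      period_hr = g$period_hr,
      light_slope = cfg$light_slope,
      sd_leak = g$sd_leak
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}
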