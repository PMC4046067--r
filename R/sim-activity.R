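#' Simulate wheel-running activity
#'
#' Generates a 1-min count series per schedule block.  Counts are Poisson
#' around a thresholded sinusoidal activity profile whose period is
#' `period_hr + light_slope * log1p(intensity)` (free-running period
#' lengthens with constant-light intensity, Aschoff's rule for a
#' nocturnal rodent).  A block flagged `ld = TRUE` represents 12:12
#' light-dark entrainment: the period is forced to 24 h and activity is
#' gated to the dark half of the cycle.
#'
#' @param params a [genotype_params()] (uses `period_hr`, `light_slope`).
#' @param light_schedule data frame with columns `intensity` (mW/m^2),
#'   `days`, optional `ld` (logical) and `label`.
#' @param seed integer seed.
#' @param amplitude mean peak count rate per minute.
#' @param baseline dark-phase-independent count floor per minute.
#' @return object of class `activity_series`: data frame with
#'   `minute` (0-based), `counts`, `condition`, `intensity`.
#' @export
simulate_activity <- function(params, light_schedule, seed = 1L,
                              amplitude = 30, baseline = 0.5) {
  stopifnot(inherits(params, "genotype_params"))
  if (any(light_schedule$days <= 0)) {
    stop("block durations must be positive", call. = FALSE)
  }
  if (is.null(light_schedule$ld)) light_schedule$ld <- FALSE
  if (is.null(light_schedule$label)) {
    light_schedule$label <- paste0("LL", light_schedule$intensity)
    light_schedule$label[light_schedule$ld] <- "LD"
  }
  withr_seed(seed, {
    blocks <- lapply(seq_len(nrow(light_schedule)), function(i) {
      blk <- light_schedule[i, ]
      n_min <- round(blk$days * 24 * 60)
      t_h <- (seq_len(n_min) - 1) / 60
      period <- if (blk$ld) 24 else {
        params$period_hr + params$light_slope * log1p(blk$intensity)
      }
      # activity onset at (subjective) dark onset, ZT 12
      prof <- pmax(0, sin(2 * pi * (t_h - 12) / period))
      lam <- baseline + amplitude * prof
      data.frame(counts = stats::rpois(n_min, lam),
                 condition = blk$label, intensity = blk$intensity)
    })
    out <- do.call(rbind, blocks)
    out$minute <- seq_len(nrow(out)) - 1L
    structure(out[, c("minute", "counts", "condition", "intensity")],
              class = c("activity_series", "data.frame"))
  })
}

#' Default constant-light schedule
#'
#' Four 14-d constant-light episodes of increasing intensity
#' (0, 33, 171 and 865 mW/m^2).
#' @return schedule data frame for [simulate_activity()].
#' @export
default_light_schedule <- function() {
  data.frame(intensity = c(0, 33, 171, 865), days = 14,
             ld = FALSE,
             label = c("DD", "LL33", "LL171", "LL865"))
}
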