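#' Protocol windows of the 72-h recording
#'
#' The analysis protocol spans 72 h of contiguous 4-s epochs anchored to
#' zeitgeber time (ZT; ZT 0 = light onset): a 24-h baseline day (12-h light,
#' 12-h dark), a 12-h sleep-deprivation period in light starting at ZT 24,
#' and a 36-h recovery period (dark, light, dark).  All downstream
#' quantities (state budgets, delta time courses, waking-band time courses)
#' are keyed to these six half-open 12-h windows.
#'
#' @return A data frame with columns `window`, `start_h`, `end_h` (hours
#'   since recording start), and `lighting` (`"light"`/`"dark"`).  The six
#'   windows partition `[0, 72)`.
#' @examples
#' protocol_windows()
#' @export
protocol_windows <- function() {
  data.frame(
    window   = c("BSL-L", "BSL-D", "SD-L", "Rec-D1", "Rec-L", "Rec-D2"),
    start_h  = seq(0, 60, by = 12),
    end_h    = seq(12, 72, by = 12),
    lighting = c("light", "dark", "light", "dark", "light", "dark"),
    stringsAsFactors = FALSE
  )
}

#' Resolve a window name or numeric interval to hour bounds
#'
#' @param window either a window name from [protocol_windows()] or a numeric
#'   `c(start_h, end_h)` half-open interval in hours.
#' @return numeric length-2 vector `c(start_h, end_h)`.
#' @keywords internal
window_bounds <- function(window) {
  if (is.character(window)) {
    pw <- protocol_windows()
    i <- match(window, pw$window)
    if (is.na(i)) {
      stop("unknown protocol window: ", window, call. = FALSE)
    }
    return(c(pw$start_h[i], pw$end_h[i]))
  }
  if (!is.numeric(window) || length(window) != 2L || window[2] <= window[1]) {
    stop("window must be a window name or c(start_h, end_h)", call. = FALSE)
  }
  as.numeric(window)
}

# epoch selector: TRUE for epochs whose ZT hour lies in [lo, hi)
epochs_in_window <- function(hyp, window) {
  b <- window_bounds(window)
  zt_h <- hyp$zt_sec / 3600
  zt_h >= b[1] & zt_h < b[2]
}

#' Number of 4-s epochs in the 72-h protocol
#' @keywords internal
protocol_n_epochs <- function(epoch_s = 4) {
  as.integer(72 * 3600 / epoch_s)
}
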