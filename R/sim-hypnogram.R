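#' Simulation configuration
#'
#' @param seed integer master seed; together with a subject id it fully
#'   determines every generated epoch.
#' @param n_subjects subjects per genotype.
#' @param epoch_s epoch length in seconds (fixed at 4 by the protocol).
#' @param sample_hz nominal EEG sampling rate (metadata only).
#' @param noise_sd standard deviation of the multiplicative lognormal
#'   noise applied to every spectral bin (0 = noiseless generator).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_subjects = 8L, epoch_s = 4L,
                       sample_hz = 250L, noise_sd = 0.2) {
  if (epoch_s != 4L) stop("protocol uses 4-s epochs", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 epoch_s = 4L, sample_hz = as.integer(sample_hz),
                 noise_sd = noise_sd),
            class = "sim_config")
}

# deterministic sub-seed per (master seed, subject, stream); < 2^31
derive_seed <- function(seed, subject_id, stream = 0L) {
  as.integer((abs(seed) %% 2147483647 * 7919 +
                subject_id * 104729 + stream * 7561) %% 2147483647)
}

#' Simulate a 72-h hypnogram
#'
#' Generates the 64,800-epoch vigilance-state sequence of one subject
#' under the 72-h protocol.  Outside the SD window states follow a
#' semi-Markov bout model with geometric bout lengths whose stationary
#' occupancy matches the genotype's target fractions for that window;
#' REMS is entered only from NREMS.  During SD-L (ZT 24-36) the subject is
#' held awake apart from isolated NREMS leak epochs
#' (`params$sd_leak`, ~1%); REMS never occurs during SD.  Artifact flags
#' are independent Bernoulli(`params$artifact_rate`) draws; they label
#' epochs for spectral exclusion, they do not alter the scored state.
#'
#' @param params a [genotype_params()] object.
#' @param config a [sim_config()] object.
#' @param subject_id integer; maps to a derived sub-seed.
#' @return a `hypnogram`: data frame with columns `epoch`, `zt_sec`,
#'   `state` (factor W/N/R) and `artifact` (logical), plus attributes
#'   `epoch_s`, `subject`, `genotype`.
#' @export
simulate_hypnogram <- function(params, config, subject_id = 1L) {
  stopifnot(inherits(params, "genotype_params"),
            inherits(config, "sim_config"))
  n_total <- protocol_n_epochs()
  block_n <- n_total / 6L                       # 10,800 epochs per window
  pw <- protocol_windows()
  st <- withr_seed(derive_seed(config$seed, subject_id, 1L), {
    states <- character(0)
    for (i in seq_len(6L)) {
      if (pw$window[i] == "SD-L") {
        blk <- rep("W", block_n)
        leak <- stats::runif(block_n) < params$sd_leak
        blk[leak] <- "N"
        states <- c(states, blk)
      } else {
        states <- c(states, sim_bout_block(params, pw$window[i], block_n))
      }
    }
    artifact <- stats::runif(n_total) < params$artifact_rate
    list(states = states, artifact = artifact)
  })
  hyp <- data.frame(
    epoch = seq_len(n_total),
    zt_sec = (seq_len(n_total) - 1L) * 4L,
    state = factor(st$states, levels = c("W", "N", "R")),
    artifact = st$artifact
  )
  structure(hyp, epoch_s = 4L, subject = subject_id,
            genotype = params$label,
            class = c("hypnogram", "data.frame"))
}

# evaluate `expr` under a locally-set RNG seed, restoring global RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# one 12-h window of the semi-Markov bout chain (geometric bout lengths)
sim_bout_block <- function(params, window, n_epochs) {
  pw <- protocol_windows()
  i <- match(window, pw$window)
  f <- params$occupancy[i, ]
  if (f["W"] >= 1 - 1e-12) return(rep("W", n_epochs))
  L <- params$bout_scale[[pw$lighting[i]]][c("W", "N", "R")]
  rp <- routing_probs(params, window)
  states <- character(0)
  cur <- sample(c("W", "N", "R"), 1L, prob = f)
  filled <- 0L
  while (filled < n_epochs) {
    len <- stats::rgeom(1L, 1 / L[cur]) + 1L
    len <- min(len, n_epochs - filled)
    states <- c(states, rep(cur, len))
    filled <- filled + len
    cur <- switch(cur,
      W = "N",
      N = if (stats::runif(1) < rp$p_n_to_r && f["R"] > 0) "R" else "W",
      R = if (stats::runif(1) < rp$p_r_to_n) "N" else "W"
    )
    # windows with zero occupancy for the next state: reroute
    if (f[cur] == 0) cur <- if (cur == "R") "W" else "N"
    if (f[cur] == 0) cur <- "W"
  }
  states
}
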