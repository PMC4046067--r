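# shared fixtures, all built in code

# hypnogram from a state vector (contiguous 4-s epochs from ZT 0)
make_hypnogram <- function(states, artifact = FALSE) {
  n <- length(states)
  structure(
    data.frame(epoch = seq_len(n), zt_sec = (seq_len(n) - 1L) * 4L,
               state = factor(states, levels = c("W", "N", "R")),
               artifact = rep_len(artifact, n)),
    epoch_s = 4L, class = c("hypnogram", "data.frame"))
}

# full 72-h hypnogram by recycling a state pattern
make_full_hypnogram <- function(pattern = c("W", "N", "N", "R"),
                                artifact = FALSE) {
  make_hypnogram(rep_len(pattern, 64800L), artifact = artifact)
}

# spectral frame from an epoch x 193 power matrix
make_frame <- function(power) {
  structure(list(power = power, freq_hz = somnostat::eeg_bin_grid()$freq_hz,
                 epoch_s = 4L, sample_hz = 250L),
            class = "spectral_frame")
}

constant_frame <- function(n_epochs, value = 1) {
  make_frame(matrix(value, n_epochs, 193L))
}

withr_tempdir <- function() {
  d <- tempfile("somnostat-test-")
  dir.create(d, recursive = TRUE)
  d
}

# compact feasible parameter set for generator tests
toy_params <- function(...) {
  occ <- matrix(c(0.40, 0.45, 0.15,
                  0.75, 0.21, 0.04,
                  0.99, 0.01, 0.00,
                  0.58, 0.33, 0.09,
                  0.40, 0.45, 0.15,
                  0.73, 0.23, 0.04), 6, 3, byrow = TRUE)
  args <- list(...)
  defaults <- list(
    label = "toy", occupancy = occ,
    bout_scale = list(light = c(W = 65, N = 60, R = 25),
                      dark = c(W = 250, N = 48, R = 16)))
  do.call(genotype_params, utils::modifyList(defaults, args))
}
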