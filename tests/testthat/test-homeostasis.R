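test_that("equal-epoch partition sizes and reconstruction", {
  states <- rep("W", 10800)
  states[seq(1, by = 450, length.out = 24)] <- "N"  # 24 N epochs
  hyp <- make_hypnogram(states)
  part <- partition_equal_epochs(hyp, "BSL-L", "N", 12)
  expect_equal(lengths(part$intervals), rep(2L, 12))
  # 25 epochs over 12 intervals: remainder goes to the earliest interval
  states[10000] <- "N"
  part2 <- partition_equal_epochs(make_hypnogram(states), "BSL-L", "N", 12)
  expect_equal(lengths(part2$intervals), c(3L, rep(2L, 11)))
  # reconstruction: concatenated intervals = chronologically sorted epochs
  idx <- which(states == "N")
  expect_equal(unlist(part2$intervals), idx)
  expect_true(all(diff(unlist(part2$intervals)) > 0))
  expect_error(partition_equal_epochs(hyp, "BSL-L", "N", 25),
               "insufficient")
  # artifact epochs never qualify
  hyp3 <- make_hypnogram(states, artifact = seq_along(states) == idx[1])
  part3 <- partition_equal_epochs(hyp3, "BSL-L", "N", 12)
  expect_false(idx[1] %in% unlist(part3$intervals))
})

test_that("delta timecourse is flat at 100 for constant power", {
  hyp <- make_full_hypnogram(c("N", "W", "N", "R"))
  fr <- constant_frame(64800, 5)
  tc <- delta_timecourse(fr, hyp)
  expect_equal(tc$delta_pct, rep(100, nrow(tc)))
  expect_equal(nrow(tc), 12 + 5 + 9 + 11 + 6)
  expect_equal(immediate_rebound(tc), 100)
  expect_true(all(diff(tc$mid_zt_h[tc$window == "BSL-L"]) > 0))
})

test_that("normalized outputs are invariant to a global power rescale", {
  hyp <- make_full_hypnogram(c("N", "W", "N", "R", "W", "N"))
  set.seed(21)
  pw <- matrix(rexp(64800 * 193, rate = 2), 64800, 193)
  fr <- make_frame(pw)
  fr_scaled <- make_frame(pw * 37.5)
  tc <- delta_timecourse(fr, hyp)
  tc2 <- delta_timecourse(fr_scaled, hyp)
  expect_equal(tc2$delta_pct, tc$delta_pct)
  expect_equal(immediate_rebound(tc2), immediate_rebound(tc))
  expect_equal(swe_accumulation(fr_scaled, hyp)$swe_acc_pct,
               swe_accumulation(fr, hyp)$swe_acc_pct)
  wb <- waking_band_timecourse(fr, hyp, mode = "hourly")
  wb2 <- waking_band_timecourse(fr_scaled, hyp, mode = "hourly")
  expect_equal(wb2$pct_of_baseline, wb$pct_of_baseline)
})

test_that("SWE accumulation: identities, telescoping, total loss", {
  # recording equal to baseline at every ZT hour -> zero curve
  day <- rep(c("N", "W", "N", "W"), 5400)
  hyp <- make_hypnogram(rep(day, 3))
  fr <- constant_frame(64800, 2)
  swe <- swe_accumulation(fr, hyp)
  expect_equal(swe$swe_acc_pct, rep(0, 48))
  # telescoping: last value equals the direct non-cumulative total
  set.seed(5)
  hyp2 <- make_full_hypnogram(sample(c("W", "N", "R"), 400, replace = TRUE))
  pw <- matrix(rexp(64800 * 193), 64800, 193)
  fr2 <- make_frame(pw)
  swe2 <- swe_accumulation(fr2, hyp2)
  dser <- band_power(pw, 0.98, 3.91)
  contrib <- ifelse(hyp2$state == "N" & !hyp2$artifact, dser, 0)
  hourly <- tapply(contrib, floor(hyp2$zt_sec / 3600), sum)
  base_total <- sum(hourly[1:24])
  direct <- (sum(hourly[25:72]) - 2 * base_total) / base_total * 100
  expect_equal(tail(swe2$swe_acc_pct, 1), direct)
  # total-loss identity: a post period without NREMS loses exactly the
  # matching baseline share
  day3 <- c(rep("N", 10800), rep("W", 10800))
  hyp3 <- make_hypnogram(c(day3, rep("W", 10800), day3[1:10800],
                           rep("W", 10800)))
  swe3 <- swe_accumulation(constant_frame(54000), hyp3)
  expect_equal(swe3$swe_acc_pct[swe3$hour == 35], -100)  # all N is in light
})

test_that("waking band timecourse: flatness and selectivity", {
  hyp <- make_full_hypnogram(c("W", "N"))
  fr <- constant_frame(64800, 3)
  wb <- waking_band_timecourse(fr, hyp, mode = "hourly")
  expect_equal(wb$pct_of_baseline, rep(100, nrow(wb)))
  expect_equal(sort(unique(wb$hour)), 24:35)
  # doubling only the upper-theta bins during SD elevates only that band
  pw <- fr$power
  sd_wake <- hyp$state == "W" & hyp$zt_sec / 3600 >= 24 &
    hyp$zt_sec / 3600 < 36
  th_cols <- match(band_bins(8.5, 11), 4:196)
  pw[sd_wake, th_cols] <- pw[sd_wake, th_cols] * 2
  wb2 <- waking_band_timecourse(make_frame(pw), hyp, mode = "hourly")
  expect_equal(wb2$pct_of_baseline[wb2$band == "upper_theta"],
               rep(200, 12))
  expect_equal(wb2$pct_of_baseline[wb2$band == "beta2"], rep(100, 12))
  # interval mode: 36 equal-wake-epoch intervals
  wb3 <- waking_band_timecourse(make_frame(pw), hyp, mode = "interval")
  expect_equal(sort(unique(wb3$interval)), 1:36)
  expect_equal(wb3$pct_of_baseline[wb3$band == "gamma1"], rep(100, 36))
})

test_that("generator closed loop: rebound gain and delta decay rate", {
  gset <- default_genotypes()
  sc0 <- sim_config(seed = 11, noise_sd = 0)
  p55 <- gset[["Per3-5/5"]]
  hyp <- simulate_hypnogram(p55, sc0, 4)
  fr <- simulate_spectra(hyp, p55, sc0)
  tc <- delta_timecourse(fr, hyp)
  # noiseless immediate rebound is exactly 100 * rebound_gain
  expect_equal(immediate_rebound(tc), 100 * p55$rebound_gain,
               tolerance = 1e-9)
  # rebound_gain 1 restores the pre-SD level exactly
  p1 <- gset$WT
  p1$rebound_gain <- 1
  fr1 <- simulate_spectra(hyp, p1, sc0)
  expect_equal(immediate_rebound(delta_timecourse(fr1, hyp)), 100,
               tolerance = 1e-9)
  # delta conservation (no rebound calibration): NREMS delta == scale * S
  fr0 <- simulate_spectra(hyp, p55, sc0, calibrate_rebound = FALSE)
  s <- process_s(as.character(hyp$state), p55$homeostat)
  nn <- hyp$state == "N"
  dser <- band_power(fr0$power, 0.98, 3.91)
  expect_equal(dser[nn] / s[nn], rep(2, sum(nn)), tolerance = 1e-12)
  # smaller tau_decay -> faster within-sleep delta decline (all-N day)
  hyp_n <- make_full_hypnogram("N")
  rate_of <- function(tau) {
    p <- p55
    p$homeostat$tau_decay_h <- tau
    frn <- simulate_spectra(hyp_n, p, sc0, calibrate_rebound = FALSE)
    d <- band_power(frn$power, 0.98, 3.91)[1:5000]
    la <- p$homeostat$lower * 2
    -stats::coef(stats::lm(log(d - la * 0.999) ~ seq_along(d)))[2]
  }
  expect_gt(rate_of(0.5), rate_of(3))
})
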