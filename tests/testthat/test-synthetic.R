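test_that("genotype parameter validation catches bad configs", {
  expect_error(toy_params(occupancy = matrix(1 / 3, 5, 3)), "6 x 3")
  bad <- matrix(c(0.5, 0.4, 0.2), 6, 3, byrow = TRUE)  # sums to 1.1
  expect_error(toy_params(occupancy = bad), "sum to 1")
  expect_error(toy_params(artifact_rate = 1), "artifact_rate")
  expect_error(toy_params(period_hr = 30), "period_hr")
  expect_error(toy_params(icc_fraction = 1.2), "icc_fraction")
  # REMS without NREMS is unreachable (R entered only from N)
  occ <- matrix(c(0.8, 0, 0.2), 6, 3, byrow = TRUE)
  expect_error(toy_params(occupancy = occ), "only from N")
  # shipped defaults load and validate
  gset <- default_genotypes()
  expect_named(gset, c("WT", "Per3-4/4", "Per3-5/5"))
  for (g in gset) expect_equal(unname(rowSums(g$occupancy)), rep(1, 6))
})

test_that("hypnogram generator honors protocol structure", {
  sc <- sim_config(seed = 5)
  # degenerate occupancy: wake 1.0 everywhere outside SD
  occ <- matrix(rep(c(1, 0, 0), 6), 6, 3, byrow = TRUE)
  hyp_w <- simulate_hypnogram(toy_params(occupancy = occ, sd_leak = 0),
                              sc, 1)
  expect_equal(nrow(hyp_w), 64800L)
  expect_true(all(hyp_w$state == "W"))
  hyp <- simulate_hypnogram(toy_params(), sc, 1)
  expect_equal(nrow(hyp), 64800L)
  expect_equal(diff(hyp$zt_sec), rep(4L, 64799L))
  # SD block: no REMS, NREMS at most 2%
  sd_sp <- state_percentages(hyp, "SD-L", 12)
  expect_equal(sd_sp$pct_r, 0)
  expect_lte(sd_sp$pct_n, 2)
  # REMS is entered only from NREMS: no R directly after W
  s <- as.character(hyp$state)
  expect_false(any(s[-1] == "R" & s[-length(s)] == "W"))
})

test_that("generator is deterministic in (seed, subject)", {
  sc <- sim_config(seed = 9, noise_sd = 0.1)
  p <- toy_params()
  h1 <- simulate_hypnogram(p, sc, 3)
  h2 <- simulate_hypnogram(p, sc, 3)
  expect_identical(h1, h2)
  h3 <- simulate_hypnogram(p, sc, 4)
  expect_false(identical(h1$state, h3$state))
  f1 <- simulate_spectra(h1, p, sc)
  f2 <- simulate_spectra(h2, p, sc)
  expect_identical(f1$power, f2$power)
  expect_true(all(f1$power > 0))
  rm(f1, f2)
})

test_that("realized occupancy converges to the configured targets", {
  p <- toy_params()
  sc <- sim_config(seed = 2)
  fr <- rowMeans(vapply(1:64, function(i) {
    sp <- state_percentages(simulate_hypnogram(p, sc, i), "BSL-L", 12)
    c(sp$pct_w, sp$pct_n, sp$pct_r) / 100
  }, numeric(3)))
  expect_equal(fr, unname(p$occupancy["BSL-L", ]), tolerance = 0.03)
})

test_that("artifact flags follow the binomial expectation", {
  p <- toy_params(artifact_rate = 0.03)
  hyp <- simulate_hypnogram(p, sim_config(seed = 13), 1)
  n_flag <- sum(hyp$artifact)
  # ~1944 expected; 5 binomial sds ~ 217
  expect_lt(abs(n_flag - 64800 * 0.03), 5 * sqrt(64800 * 0.03 * 0.97))
})

test_that("noiseless spectra are state-deterministic templates", {
  sc0 <- sim_config(seed = 1, noise_sd = 0)
  p <- toy_params(sd_band_gains = list(upper_theta = 1, beta2 = 1,
                                       gamma1 = 1, tau_profile_h = 1))
  hyp <- simulate_hypnogram(p, sc0, 1)
  fr <- simulate_spectra(hyp, p, sc0)
  w_idx <- which(hyp$state == "W")
  ref <- fr$power[w_idx[1], ]
  same <- vapply(w_idx, function(i) all(fr$power[i, ] == ref), logical(1))
  expect_true(all(same))  # gains 1 + noise 0: every wake epoch identical
  # REMS spectrum peaks at the configured theta frequency (bin 29)
  p2 <- toy_params(tpf_hz = 7.08)
  fr2 <- simulate_spectra(hyp, p2, sc0)
  rsp <- state_spectrum(fr2, hyp, "R", "BSL-L")
  expect_equal(theta_peak_frequency(rsp), bin_frequency(29))
  rm(fr, fr2)
})

test_that("dark-period delta runs above the light-period minimum", {
  gset <- default_genotypes()
  sc0 <- sim_config(seed = 3, noise_sd = 0)
  hyp <- simulate_hypnogram(gset$WT, sc0, 2)
  tc <- delta_timecourse(simulate_spectra(hyp, gset$WT, sc0), hyp)
  m <- tapply(tc$delta_pct, tc$window, mean)
  expect_gt(m[["BSL-D"]], m[["BSL-L"]])
  # the normalization reference is the BSL-L minimum region: last
  # baseline-light intervals sit near 100%
  expect_lt(min(tc$delta_pct[tc$window == "BSL-L"]), m[["BSL-D"]])
})

test_that("expression generator plants recoverable fold changes", {
  m0 <- simulate_expression(500, 4, de_fraction = 0, seed = 2)
  expect_equal(nrow(attr(m0, "truth")), 0)
  m1 <- simulate_expression(500, 8, de_fraction = 0.1, fc_log2 = 2,
                            seed = 2)
  m1b <- simulate_expression(500, 8, de_fraction = 0.1, fc_log2 = 2,
                             seed = 2)
  expect_identical(m1, m1b)
  truth <- attr(m1, "truth")
  expect_equal(nrow(truth), 50)
  # planted genes dominate the top of the |fold change| ranking
  g <- attr(m1, "groups")
  lfc <- rowMeans(m1[, g == "B"]) - rowMeans(m1[, g == "A"])
  top <- rownames(m1)[order(-abs(lfc))][1:50]
  expect_gte(length(intersect(top, truth$gene)), 45)
  expect_error(simulate_expression(10, 1), ">= 2 samples")
})

test_that("activity generator obeys schedule and degenerate settings", {
  p <- toy_params()
  expect_error(simulate_activity(p, data.frame(intensity = 0, days = -1)),
               "positive")
  # light_slope 0: the dominant period agrees across blocks (to the
  # 1-min candidate grid, under count noise)
  p0 <- toy_params(light_slope = 0, period_hr = 24)
  act <- simulate_activity(p0, default_light_schedule(), seed = 2,
                           amplitude = 300)
  pp <- period_per_condition(act)
  expect_lte(diff(range(pp$period_h)), 2 / 60)
  # zero amplitude: flat series, no significant peak
  flat <- simulate_activity(p, data.frame(intensity = 0, days = 3),
                            seed = 2, amplitude = 0, baseline = 0)
  pg <- chi_square_periodogram(flat$counts)
  expect_true(is.na(attr(pg, "peak_period_h")))
  expect_false(attr(pg, "peak_significant"))
})
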