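test_that("percentile-shift normalization aligns arrays", {
  m <- matrix(rnorm(200 * 6, 8), 200, 6)
  q <- apply(m, 2, quantile, 0.75)
  norm <- percentile_shift_normalize(m)
  expect_equal(unname(apply(norm, 2, quantile, 0.75)), rep(0, 6))
  # a sample whose 75th percentile is already 0 is unchanged
  m0 <- sweep(m, 2, q, `-`)
  expect_equal(percentile_shift_normalize(m0), m0,
               ignore_attr = TRUE)
  # shift invariance: adding a constant to one array washes out
  m2 <- m
  m2[, 3] <- m2[, 3] + 5.5
  expect_equal(percentile_shift_normalize(m2),
               percentile_shift_normalize(m), ignore_attr = TRUE)
  # planted per-array offsets from the generator align after the shift
  em <- simulate_expression(400, 5, de_fraction = 0, seed = 6,
                            array_offset_sd = 1)
  norm2 <- percentile_shift_normalize(em)
  expect_lt(sd(apply(norm2, 2, median)),
            sd(apply(em, 2, median)) / 5)
  expect_lt(sd(apply(norm2, 2, median)), 0.1)
  expect_error(percentile_shift_normalize(m, percentile = 0), "percentile")
  # linear-scale variant also zeroes the (linear) 75th percentile
  lin <- percentile_shift_normalize(m, scale = "linear")
  expect_equal(unname(apply(2^lin, 2, quantile, 0.75)), rep(1, 6))
})

test_that("rank product matches a direct re-computation and extremes", {
  set.seed(9)
  m <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  m[1, 3:4] <- m[1, 3:4] + 50   # gene 1 most up in every comparison
  grp <- factor(rep(c("A", "B"), each = 2))
  rp <- rank_product(m, grp, n_perm = 50, seed = 3)
  expect_equal(rp$rp_up[1], 1)
  expect_equal(which.min(rp$pfp_up), 1L)
  # oracle: explicit loop over the 4 cross pairs
  ranks <- sapply(list(c(3, 1), c(4, 1), c(3, 2), c(4, 2)), function(pr) {
    rank(-(m[, pr[1]] - m[, pr[2]]))
  })
  expect_equal(rp$rp_up, unname(exp(rowMeans(log(ranks)))))
  expect_equal(rp$rp_down, unname(exp(rowMeans(log(21 - ranks)))))
  expect_error(rank_product(m, factor(rep("A", 4))), "2 groups")
})

test_that("permutation PFP agrees with exhaustive enumeration on 5 genes", {
  set.seed(15)
  m <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("g", 1:5), NULL))
  grp <- factor(rep(c("A", "B"), each = 2))
  rp <- rank_product(m, grp, n_perm = 4000, seed = 8,
                     null_method = "rank")
  # under the rank-permutation null a gene's 4 comparison ranks are
  # i.i.d. uniform on 1..5, so E[# null genes with RP <= q] =
  # 5 * P(geomean of 4 ranks <= q), enumerable over all 5^4 tuples
  tup <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5))
  null_rp <- exp(rowMeans(log(tup)))
  for (i in 1:5) {
    e_exact <- 5 * mean(null_rp <= rp$rp_up[i])
    obs_rank <- rank(rp$rp_up, ties.method = "max")[i]
    pfp_exact <- e_exact / obs_rank
    expect_equal(rp$pfp_up[i], pfp_exact, tolerance = 0.15)
  }
})

test_that("pure-null matrices produce (almost) no PFP discoveries", {
  m <- simulate_expression(800, 4, de_fraction = 0, seed = 4)
  rp <- rank_product(m, n_perm = 60, seed = 5)
  expect_lt(mean(rp$pfp_up < 0.015 | rp$pfp_down < 0.015), 0.02)
})

test_that("dual-criterion classification recovers planted genes", {
  m <- simulate_expression(2000, 8, de_fraction = 0.075, fc_log2 = 2,
                           seed = 10)   # 150 planted: 100 up, 50 down
  norm <- percentile_shift_normalize(m)
  de <- classify_de(norm, n_perm = 60, seed = 11)
  counts <- attr(de, "counts")
  expect_gt(counts[["up"]], counts[["down"]])
  # every planted gene should be recovered ...
  truth <- attr(m, "truth")
  expect_gte(length(intersect(de$gene[de$de], truth$gene)), 140)
  # ... with counts near 100 up / 50 down; the down side runs a little
  # high because anchoring the 75th percentile under asymmetric (mostly
  # up) DE pushes null genes slightly down
  expect_true(counts[["up"]] >= 90 && counts[["up"]] <= 120)
  expect_true(counts[["down"]] >= 45 && counts[["down"]] <= 85)
  # the dual criterion is exactly the union of the two single criteria
  expect_equal(de$de,
               de$p_adj < 0.05 | de$pfp_up < 0.015 | de$pfp_down < 0.015)
  # null calibration: BH keeps false discoveries near zero
  m0 <- simulate_expression(2000, 8, de_fraction = 0, seed = 12)
  de0 <- classify_de(percentile_shift_normalize(m0), n_perm = 60,
                     seed = 13)
  expect_lt(sum(de0$de), 2000 * 0.01)
  # BH monotonicity: adjusted p is monotone in raw p
  ord <- order(de$p)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-12))
  # single gene, identical groups: never DE
  one <- matrix(rep(1:4, each = 1), 1, 4)
  rownames(one) <- "g1"
  one[1, ] <- c(2, 3, 2, 3)
  de1 <- classify_de(one, factor(c("A", "B", "A", "B")), n_perm = 20,
                     seed = 1)
  expect_false(de1$de)
})

test_that("fold-change ranking orders, breaks ties and truncates", {
  res <- structure(
    data.frame(gene = c("a", "b", "c", "d"),
               lfc = c(3, -2, 2, 0.5), p = c(0.001, 0.01, 0.005, 0.2),
               p_adj = c(0.004, 0.04, 0.02, 0.4),
               pfp_up = NA_real_, pfp_down = NA_real_,
               de = c(TRUE, TRUE, TRUE, FALSE),
               direction = c("up", "down", "up", "none")),
    counts = c(up = 2, down = 1), class = c("de_result", "data.frame"))
  rk <- fold_change_ranking(res, top_n = 2)
  expect_equal(rk$gene, c("a", "c"))  # |3| then tie |2| -> smaller p_adj
  expect_message(fold_change_ranking(res, top_n = 10), "only 3")
  # planted-truth enrichment beyond the hypergeometric null
  m <- simulate_expression(1000, 8, de_fraction = 0.05, fc_log2 = 2,
                           seed = 14)
  de <- classify_de(percentile_shift_normalize(m), n_perm = 40, seed = 15)
  top <- fold_change_ranking(de, top_n = 50)
  hits <- length(intersect(top$gene, attr(m, "truth")$gene))
  # null expectation 50 * 50/1000 = 2.5; demand overwhelming enrichment
  expect_gte(hits, 40)
})

test_that("rank product is invariant to per-sample shifts and seeds", {
  set.seed(33)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("g", 1:50), NULL))
  grp <- factor(rep(c("A", "B"), each = 3))
  r1 <- rank_product(m, grp, n_perm = 30, seed = 21)
  # additive per-sample offsets shift every within-pair difference by a
  # constant and leave all fold-change ranks unchanged
  m2 <- sweep(m, 2, rnorm(6, 0, 4), `+`)
  r2 <- rank_product(m2, grp, n_perm = 30, seed = 21)
  expect_equal(r2$rp_up, r1$rp_up)
  expect_equal(r2$pfp_up, r1$pfp_up)
  # fixed seed -> bit-identical output
  expect_identical(rank_product(m, grp, n_perm = 30, seed = 21), r1)
})
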