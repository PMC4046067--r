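#' Intraclass correlation between groups
#'
#' One-way random-effects method-of-moments estimate of the ratio of the
#' between-group variance to the total variance.  With mean squares MSB
#' (between) and MSW (within) and the standard unbalanced-design
#' coefficient `n0`, the between component is
#' `sigma2_b = max(0, (MSB - MSW) / n0)` and
#' `ICC = sigma2_b / (sigma2_b + MSW)`.  The 95% confidence interval uses
#' the F-distribution pivot of the one-way design, truncated to `[0, 1]`.
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups,
#'   >= 2 values each), or a list with `values`/`group`.
#' @param conf_level confidence level for the interval.
#' @return object of class `icc_result`: list with `icc`, `ci` (lo, hi),
#'   `var_between`, `var_within`, `msb`, `msw`, `group_sizes`.
#' @export
icc_between_groups <- function(values_by_group, conf_level = 0.95) {
  g <- values_by_group
  if (!is.list(g) || length(g) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(g)
  if (any(sizes < 2L)) stop("every group needs >= 2 values", call. = FALSE)
  k <- length(g)
  n_tot <- sum(sizes)
  all_v <- unlist(g, use.names = FALSE)
  gm <- vapply(g, mean, numeric(1))
  grand <- mean(all_v)
  msb <- sum(sizes * (gm - grand)^2) / (k - 1)
  msw <- sum(unlist(Map(function(v, m) (v - m)^2, g, gm))) / (n_tot - k)
  n0 <- (n_tot - sum(sizes^2) / n_tot) / (k - 1)
  vb <- max(0, (msb - msw) / n0)
  icc <- if (vb + msw > 0) vb / (vb + msw) else 0
  a <- 1 - conf_level
  if (msw > 0) {
    f_obs <- msb / msw
    fl <- f_obs / stats::qf(1 - a / 2, k - 1, n_tot - k)
    fu <- f_obs * stats::qf(1 - a / 2, n_tot - k, k - 1)
    ci <- c((fl - 1) / (fl + n0 - 1), (fu - 1) / (fu + n0 - 1))
    ci <- pmin(pmax(ci, 0), 1)
  } else {
    ci <- c(icc, icc)
  }
  structure(list(icc = icc, ci = ci, var_between = vb, var_within = msw,
                 msb = msb, msw = msw, group_sizes = sizes),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f  [%.3f, %.3f]  (between %.3f, within %.3f)\n",
              x$icc, x$ci[1], x$ci[2], x$var_between, x$var_within))
  invisible(x)
}

#' Tie-corrected Kruskal-Wallis H
#'
#' @param values_by_group list of numeric vectors.
#' @return list with `H`, `df`, `p` (asymptotic chi-square).  When every
#'   value is identical the test is degenerate and `H = 0`, `p = 1` by
#'   convention.
#' @export
kruskal_wallis <- function(values_by_group) {
  g <- values_by_group
  if (length(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  all_v <- unlist(g, use.names = FALSE)
  k <- length(g)
  if (length(unique(all_v)) == 1L) {
    return(list(H = 0, df = k - 1, p = 1))
  }
  n <- length(all_v)
  r <- rank(all_v)
  sizes <- lengths(g)
  grp <- rep(seq_along(g), sizes)
  rs <- tapply(r, grp, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(all_v)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  list(H = h, df = k - 1, p = stats::pchisq(h, k - 1, lower.tail = FALSE))
}

#' Per-bin Kruskal-Wallis over genotype spectra
#'
#' Applies the tie-corrected Kruskal-Wallis test independently at every
#' frequency bin of the retained grid.
#'
#' @param spectra_by_genotype named list of subject-by-bin matrices (193
#'   grid columns each).
#' @return data frame with one row per bin: `bin`, `freq_hz`, `H`, `p`.
#' @export
per_bin_kruskal_wallis <- function(spectra_by_genotype) {
  mats <- spectra_by_genotype
  if (length(mats) < 2L) stop("need >= 2 genotypes", call. = FALSE)
  nb <- unique(vapply(mats, ncol, integer(1)))
  if (length(nb) != 1L) stop("bin counts differ across groups",
                             call. = FALSE)
  grid <- eeg_bin_grid()
  if (nb != nrow(grid)) stop("matrices must have 193 grid columns",
                             call. = FALSE)
  res <- vapply(seq_len(nb), function(j) {
    kw <- kruskal_wallis(lapply(mats, function(m) m[, j]))
    c(kw$H, kw$p)
  }, numeric(2))
  data.frame(bin = grid$bin, freq_hz = grid$freq_hz,
             H = res[1, ], p = res[2, ])
}

#' Student-Newman-Keuls post hoc test on ranks
#'
#' Stepwise range test applied after a Kruskal-Wallis comparison: values
#' are jointly rank-transformed (set `on_ranks = FALSE` for the classical
#' parametric SNK on raw values), group means are ordered, and pairs are
#' compared against studentized-range critical values whose stretch
#' parameter equals the number of means spanned.  Non-significant spans
#' block all comparisons nested inside them (the defining SNK step-down
#' rule).
#'
#' @param values_by_group named list of numeric vectors.
#' @param alpha family significance level.
#' @param on_ranks compare rank-transformed values (default) or raw.
#' @return data frame with `group1`, `group2`, `stretch`, `q`, `q_crit`,
#'   `significant`.
#' @export
snk_posthoc <- function(values_by_group, alpha = 0.05, on_ranks = TRUE) {
  g <- values_by_group
  k <- length(g)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(g))) names(g) <- paste0("g", seq_len(k))
  if (on_ranks) {
    sizes <- lengths(g)
    r <- rank(unlist(g, use.names = FALSE))
    g <- split(r, rep(seq_len(k), sizes))
    names(g) <- names(values_by_group)
    if (is.null(names(values_by_group))) names(g) <- paste0("g", seq_len(k))
  }
  sizes <- lengths(g)
  n_tot <- sum(sizes)
  means <- vapply(g, mean, numeric(1))
  msw <- sum(unlist(Map(function(v, m) (v - m)^2, g, means))) /
    (n_tot - k)
  ord <- order(means)
  means <- means[ord]; sizes <- sizes[ord]
  labs <- names(g)[ord]
  df_err <- n_tot - k
  blocked <- matrix(FALSE, k, k)
  out <- list()
  for (stretch in k:2) {
    for (i in seq_len(k - stretch + 1L)) {
      j <- i + stretch - 1L
      if (blocked[i, j]) next
      nh <- 2 / (1 / sizes[i] + 1 / sizes[j])   # harmonic pair size
      se <- sqrt(msw / nh)
      q <- if (se > 0) abs(means[j] - means[i]) / se else 0
      qc <- stats::qtukey(1 - alpha, stretch, df_err)
      sig <- q > qc
      out[[length(out) + 1L]] <- data.frame(
        group1 = labs[i], group2 = labs[j], stretch = stretch,
        q = q, q_crit = qc, significant = sig)
      if (!sig) {
        for (a_ in i:j) for (b_ in i:j) blocked[a_, b_] <- TRUE
        blocked[i, j] <- FALSE  # keep this comparison reported
      }
    }
  }
  do.call(rbind, out)
}

#' Paired return-to-baseline test
#'
#' One-sample t test of per-subject final accumulated differences (e.g.
#' the last slow-wave-energy accumulation value) against zero: does the
#' cohort remain below its baseline at the end of recovery?
#'
#' @param accumulated_values numeric vector, one final accumulated value
#'   per subject.
#' @param alternative passed to [stats::t.test()].
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
paired_return_to_baseline <- function(accumulated_values,
                                      alternative = "two.sided") {
  x <- accumulated_values
  if (length(x) < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (stats::sd(x) == 0) {
    if (mean(x) == 0) {
      return(list(t = 0, df = length(x) - 1L, p = 1, mean = 0))
    }
    stop("degenerate input: zero variance with non-zero mean",
         call. = FALSE)
  }
  tt <- stats::t.test(x, mu = 0, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(x))
}

#' Simulate grouped values with a target intraclass correlation
#'
#' Two-genotype grouped-value model: fixed group effects `+/- d` plus
#' i.i.d. Gaussian within-group noise, on a unit total-variance scale.
#' Because the one-way method-of-moments ICC estimator is biased at
#' `k = 2` groups, the separation `d` is calibrated (deterministically,
#' through the noncentral-F representation of the estimator) so that the
#' *expected value of the estimator* equals `icc_fraction`; published
#' ICCs are estimates from this very estimator, so calibration on the
#' estimator scale is what reproduces them.
#'
#' @param icc_fraction target expected ICC estimate, in `[0, 1)`.
#' @param n_per_group values per group.
#' @param seed integer seed.
#' @return list of two numeric vectors (`A`, `B`).
#' @export
simulate_grouped_values <- function(icc_fraction = 0.48, n_per_group = 8L,
                                    seed = 1L) {
  if (icc_fraction < 0 || icc_fraction >= 1) {
    stop("icc_fraction must lie in [0, 1)", call. = FALSE)
  }
  d <- icc_group_separation(icc_fraction, n_per_group)
  sw <- sqrt(1 - icc_fraction)
  withr_seed(seed, {
    list(A = -d + stats::rnorm(n_per_group, 0, sw),
         B =  d + stats::rnorm(n_per_group, 0, sw))
  })
}

# E[ICC-hat] for fixed effects +/-d at k=2:
#   F = MSB/MSW ~ noncentral F(1, N-2; lambda = 2 n d^2 / sw^2),
#   ICC-hat = max(0, F-1)/(F + n - 1);  solve lambda for the target mean.
icc_group_separation <- function(icc_fraction, n_per_group) {
  if (icc_fraction == 0) return(0)
  n <- n_per_group
  nn <- 2L * n
  e_icc <- function(lambda) {
    stats::integrate(function(x) {
      pmax(0, x - 1) / (x + n - 1) * stats::df(x, 1, nn - 2, ncp = lambda)
    }, 0, Inf, rel.tol = 1e-9, subdivisions = 2000L)$value
  }
  lo <- 1e-8
  if (e_icc(lo) >= icc_fraction) {
    # truncation at 0 gives the estimator a positive null mean; fractions
    # below that floor are not reachable with any separation
    stop("icc_fraction below the estimator's null expectation (",
         round(e_icc(lo), 3), ") for this group size", call. = FALSE)
  }
  sol <- stats::uniroot(function(l) e_icc(l) - icc_fraction,
                        c(lo, 300), tol = 1e-9, extendInt = "upX")
  sw2 <- 1 - icc_fraction
  sqrt(sol$root * sw2 / (2 * n))
}
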