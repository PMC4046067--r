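#' Simulate a log2 expression matrix with planted fold changes
#'
#' Per-gene lognormal (Gaussian on the log2 scale) baselines, i.i.d.
#' within-group noise, per-array scaling offsets (so percentile-shift
#' normalization is nontrivial), and a planted differentially expressed
#' subset shifted by `+/- fc_log2` in group B.  Truth labels are recorded
#' in the `"truth"` attribute.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (two groups, `A` and `B`).
#' @param de_fraction fraction of genes planted as DE, in `[0, 1]`.
#' @param fc_log2 absolute planted log2 fold change.
#' @param seed integer seed.
#' @param prop_up fraction of planted genes shifted up (the remainder
#'   down); published contrasts show more up- than down-regulated
#'   transcripts, so cohort emulations typically use 2/3.
#' @param noise_sd within-group log2 noise sd.
#' @param array_offset_sd sd of the per-array additive (log2) offset.
#' @return log2 matrix (genes x samples) with attributes `groups`
#'   (factor) and `truth` (data frame `gene`, `direction`).
#' @export
simulate_expression <- function(n_genes, n_per_group, de_fraction = 0.01,
                                fc_log2 = 1, seed = 1L, prop_up = 2 / 3,
                                noise_sd = 0.25, array_offset_sd = 0.3) {
  if (n_per_group < 2L) stop("need >= 2 samples per group", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  }
  withr_seed(seed, {
    n_s <- 2L * n_per_group
    mu <- stats::rnorm(n_genes, 7, 1.5)
    x <- matrix(mu, n_genes, n_s) +
      matrix(stats::rnorm(n_genes * n_s, 0, noise_sd), n_genes, n_s)
    offs <- stats::rnorm(n_s, 0, array_offset_sd)
    x <- sweep(x, 2, offs, `+`)
    groups <- factor(rep(c("A", "B"), each = n_per_group))
    n_de <- round(n_genes * de_fraction)
    truth <- data.frame(gene = character(0), direction = character(0))
    if (n_de > 0) {
      de_idx <- sample.int(n_genes, n_de)
      n_up <- round(n_de * prop_up)
      dir <- rep(c(1, -1), c(n_up, n_de - n_up))
      x[de_idx, groups == "B"] <- x[de_idx, groups == "B"] + dir * fc_log2
      truth <- data.frame(gene = sprintf("gene%05d", de_idx),
                          direction = ifelse(dir > 0, "up", "down"))
    }
    rownames(x) <- sprintf("gene%05d", seq_len(n_genes))
    colnames(x) <- paste0(rep(c("A", "B"), each = n_per_group),
                          seq_len(n_per_group))
    structure(x, groups = groups, truth = truth)
  })
}

#' Percentile-shift normalization
#'
#' Subtracts each sample's chosen intensity percentile (75th by default)
#' from that sample's log2 values, so the percentile aligns at 0 across
#' arrays.  A linear-scale division variant is available via
#' `scale = "linear"` (values are exponentiated, divided by the sample
#' percentile, and re-logged).
#'
#' @param matrix log2 genes-by-samples matrix.
#' @param percentile percentile in `(0, 100)`.
#' @param scale `"log2"` (subtraction, default) or `"linear"`.
#' @return normalized matrix (attributes preserved).
#' @export
percentile_shift_normalize <- function(matrix, percentile = 75,
                                       scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie in (0, 100)", call. = FALSE)
  }
  out <- if (scale == "log2") {
    q <- apply(matrix, 2, stats::quantile, probs = percentile / 100,
               names = FALSE, type = 7)  # linear interpolation
    sweep(matrix, 2, q, `-`)
  } else {
    lin <- 2^matrix
    q <- apply(lin, 2, stats::quantile, probs = percentile / 100,
               names = FALSE, type = 7)
    log2(sweep(lin, 2, q, `/`))
  }
  attr(out, "groups") <- attr(matrix, "groups")
  attr(out, "truth") <- attr(matrix, "truth")
  out
}

#' Rank-product analysis with permutation PFP
#'
#' For every cross-group sample pair the genes are ranked by log2 fold
#' change (rank 1 = strongest change in the tested direction); the rank
#' product is the geometric mean of a gene's ranks over all pairs.  The
#' null distribution comes from `n_perm` within-comparison rank
#' permutations; the percentage of false prediction at a gene is the
#' expected number of null genes at or below its RP divided by its
#' observed-positive rank.
#'
#' @param matrix log2 genes-by-samples matrix.
#' @param groups two-level factor of sample groups (defaults to the
#'   matrix's `groups` attribute).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed (mandatory for reproducibility).
#' @param null_method `"sample"` (default) draws null rank products by
#'   permuting sample labels and recomputing the full statistic, which
#'   preserves the correlation among cross pairs sharing a sample;
#'   `"rank"` draws independent within-comparison rank permutations.
#'   The rank null understates the tails of the observed null when all
#'   `n1 * n2` cross pairs are used (pairs sharing a sample are
#'   positively correlated), so `"sample"` is the calibrated default.
#' @return data frame with `gene`, `rp_up`, `rp_down`, `pfp_up`,
#'   `pfp_down`.
#' @export
rank_product <- function(matrix, groups = attr(matrix, "groups"),
                         n_perm = 100L, seed = 1L,
                         null_method = c("sample", "rank")) {
  groups <- as.factor(groups)
  null_method <- match.arg(null_method)
  if (nlevels(groups) != 2L) stop("need exactly 2 groups", call. = FALSE)
  if (min(table(groups)) < 2L) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  n_g <- nrow(matrix)
  n_c <- length(ia) * length(ib)
  rp <- rp_statistic(matrix, ia, ib)
  null_rp <- withr_seed(seed, {
    if (null_method == "rank") {
      as.numeric(vapply(seq_len(n_perm), function(p) {
        r <- vapply(seq_len(n_c), function(j) sample.int(n_g),
                    integer(n_g))
        exp(rowMeans(log(base::matrix(r, n_g, n_c))))
      }, numeric(n_g)))
    } else {
      unlist(lapply(seq_len(n_perm), function(p) {
        perm <- sample.int(ncol(matrix))
        np <- rp_statistic(matrix[, perm, drop = FALSE], ia, ib)
        c(np$rp_up, np$rp_down)
      }))
    }
  })
  # the sample null pools both directions (they share one distribution)
  null_scale <- if (null_method == "rank") n_perm else 2 * n_perm
  null_sorted <- sort(null_rp)
  pfp <- function(x) {
    ord_rank <- rank(x, ties.method = "max")
    exp_fp <- findInterval(x, null_sorted) / null_scale
    exp_fp / ord_rank
  }
  data.frame(gene = rownames(matrix) %||% sprintf("gene%05d", seq_len(n_g)),
             rp_up = rp$rp_up, rp_down = rp$rp_down,
             pfp_up = pfp(rp$rp_up), pfp_down = pfp(rp$rp_down))
}

# rank-product statistic over all cross-group sample pairs
# (fold change of B over A; rank 1 = strongest in the tested direction)
rp_statistic <- function(mat, ia, ib) {
  n_g <- nrow(mat)
  pairs <- expand.grid(a = ia, b = ib)
  n_c <- nrow(pairs)
  lr_up <- base::matrix(0, n_g, n_c)
  for (j in seq_len(n_c)) {
    d <- mat[, pairs$b[j]] - mat[, pairs$a[j]]
    lr_up[, j] <- rank(-d, ties.method = "average")
  }
  list(rp_up = exp(rowMeans(log(lr_up))),
       rp_down = exp(rowMeans(log(n_g + 1 - lr_up))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorized pooled-variance unpaired t test (rows = genes)
row_t_test <- function(matrix, groups, welch = FALSE) {
  ia <- groups == levels(groups)[1]
  ib <- groups == levels(groups)[2]
  na <- sum(ia); nb <- sum(ib)
  ma <- rowMeans(matrix[, ia, drop = FALSE])
  mb <- rowMeans(matrix[, ib, drop = FALSE])
  va <- apply(matrix[, ia, drop = FALSE], 1, stats::var)
  vb <- apply(matrix[, ib, drop = FALSE], 1, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    tt <- (mb - ma) / sqrt(se2)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (mb - ma) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(tt))
  }
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[!is.finite(tt)] <- 1  # degenerate zero-variance, zero-difference rows
  list(lfc = mb - ma, t = tt, p = p)
}

# vectorized one-way ANOVA F test (rows = genes)
row_anova <- function(matrix, groups) {
  k <- nlevels(groups)
  n <- ncol(matrix)
  gm <- rowMeans(matrix)
  ssb <- 0; ssw <- 0
  for (lv in levels(groups)) {
    sel <- groups == lv
    m <- rowMeans(matrix[, sel, drop = FALSE])
    ssb <- ssb + sum(sel) * (m - gm)^2
    ssw <- ssw + rowSums((matrix[, sel, drop = FALSE] - m)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[!is.finite(f)] <- 1
  list(f = f, p = p)
}

#' Dual-criterion differential-expression classification
#'
#' Each gene is tested parametrically (unpaired pooled-variance t test
#' for 2 groups, one-way ANOVA for more; asymptotic p values with
#' Benjamini-Hochberg correction across genes) and, for two-group
#' contrasts, by rank product.  A gene is differentially expressed when
#' its BH-adjusted p is below `alpha` *or* its PFP (in either direction)
#' is below `pfp_threshold`; direction follows the sign of the group mean
#' difference.
#'
#' @param matrix normalized log2 genes-by-samples matrix.
#' @param groups factor of sample groups (default: `groups` attribute).
#' @param alpha BH-adjusted significance level.
#' @param pfp_threshold rank-product PFP cutoff.
#' @param n_perm,seed rank-product permutation settings.
#' @param welch use Welch instead of pooled-variance t.
#' @return object of class `de_result`: data frame with `gene`, `lfc`,
#'   `p`, `p_adj`, `pfp_up`, `pfp_down`, `de`, `direction`; up/down
#'   counts in attribute `counts`.
#' @export
classify_de <- function(matrix, groups = attr(matrix, "groups"),
                        alpha = 0.05, pfp_threshold = 0.015,
                        n_perm = 100L, seed = 1L, welch = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  two <- nlevels(groups) == 2L
  par_res <- if (two) row_t_test(matrix, groups, welch = welch) else
    row_anova(matrix, groups)
  p_adj <- stats::p.adjust(par_res$p, method = "BH")
  if (two) {
    rp <- rank_product(matrix, groups, n_perm = n_perm, seed = seed)
    pfp_up <- rp$pfp_up; pfp_down <- rp$pfp_down
    lfc <- par_res$lfc
  } else {
    pfp_up <- pfp_down <- rep(NA_real_, nrow(matrix))
    lv_means <- sapply(levels(groups), function(lv) {
      rowMeans(matrix[, groups == lv, drop = FALSE])
    })
    lfc <- apply(lv_means, 1, function(v) max(v) - min(v))
  }
  de <- p_adj < alpha |
    (!is.na(pfp_up) & pfp_up < pfp_threshold) |
    (!is.na(pfp_down) & pfp_down < pfp_threshold)
  direction <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none"))
  direction[!de] <- "none"
  out <- data.frame(
    gene = rownames(matrix) %||% sprintf("gene%05d", seq_len(nrow(matrix))),
    lfc = lfc, p = par_res$p, p_adj = p_adj,
    pfp_up = pfp_up, pfp_down = pfp_down, de = de, direction = direction)
  structure(out,
            counts = c(up = sum(direction == "up"),
                       down = sum(direction == "down")),
            class = c("de_result", "data.frame"))
}

#' Rank differentially expressed genes by absolute fold change
#'
#' DE-flagged genes sorted by decreasing `|log2 fold change|`; ties break
#' by smaller adjusted p, then gene id; truncated to the top `top_n`.
#'
#' @param results a [classify_de()] result.
#' @param top_n table length.
#' @return data frame of the top-ranked DE genes with a `rank` column.
#' @export
fold_change_ranking <- function(results, top_n = 200L) {
  stopifnot(inherits(results, "de_result"))
  de <- results[results$de, , drop = FALSE]
  if (nrow(de) < top_n) {
    message("only ", nrow(de), " DE genes available (top_n = ", top_n, ")")
  }
  ord <- order(-abs(de$lfc), de$p_adj, de$gene)
  de <- de[ord, , drop = FALSE]
  de <- utils::head(de, top_n)
  de$rank <- seq_len(nrow(de))
  rownames(de) <- NULL
  de
}
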