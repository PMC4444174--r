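#' Log-likelihood-ratio goodness-of-fit statistic G
#'
#' `G = 2 * sum(o_i * log(o_i / e_i))` over cells with positive observed
#' counts; zero-count cells contribute nothing. Observed and expected totals
#' must agree.
#'
#' @param counts non-negative integer observed counts.
#' @param expected positive expected counts summing to `sum(counts)`.
#' @return The G statistic, or `NA_real_` when all counts are zero.
#' @export
g_statistic <- function(counts, expected) {
  stopifnot(length(counts) == length(expected), all(counts >= 0),
            all(expected > 0))
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  if (abs(n - sum(expected)) > 1e-6 * max(1, n))
    stop("expected counts must sum to the observed total")
  pos <- counts > 0
  2 * sum(counts[pos] * log(counts[pos] / expected[pos]))
}

#' Williams' small-sample correction for G
#'
#' Divides G by `q = 1 + (k^2 - 1) / (6 * n * (k - 1))`, the standard
#' correction for goodness-of-fit G tests with small expected counts. `q > 1`
#' for finite `n`, so the corrected statistic is always smaller than the raw
#' one; `q -> 1` as `n` grows.
#'
#' @param G raw G statistic.
#' @param n total count.
#' @param k number of cells.
#' @return A list with `q` and `G_adj = G / q`.
#' @export
williams_correct <- function(G, n, k) {
  stopifnot(n >= 1, k >= 2)
  q <- 1 + (k^2 - 1) / (6 * n * (k - 1))
  list(q = q, G_adj = G / q)
}

#' Monte-Carlo G test against a discrete uniform distribution
#'
#' Tests whether per-individual counts could have arisen from a discrete
#' uniform distribution over the `k` individuals, using the
#' Williams-corrected G statistic and a Monte-Carlo null: `B` multinomial
#' draws of size `n` from the uniform distribution, each reduced to its
#' corrected G. The p-value uses the add-one estimator
#' `(1 + #{G_sim >= G_obs}) / (B + 1)`, so it is never exactly zero; the
#' simulated statistics receive the same correction as the observed one.
#'
#' @param counts non-negative integer counts, one per individual.
#' @param B number of Monte-Carlo simulations (default 2000).
#' @param seed integer seed, recorded in the result.
#' @return A list of class `"g_test"`: `G_raw`, `williams_q`, `G_adj`, `df`
#'   (`k - 1`), `p_mc`, `n`, `k`, `n_simulations`, `seed`.
#' @export
mc_uniform_test <- function(counts, B = 2000L, seed = 1L) {
  if (B < 1) stop("B must be at least 1")
  k <- length(counts)
  n <- sum(counts)
  expected <- rep(n / k, k)
  G <- g_statistic(counts, expected)
  wc <- williams_correct(G, n, k)
  set.seed(seed)
  sim <- stats::rmultinom(B, size = n, prob = rep(1 / k, k))
  logterm <- sim * log(sim / (n / k))
  logterm[sim == 0] <- 0
  G_sim <- 2 * colSums(logterm) / wc$q
  p <- (1 + sum(G_sim >= wc$G_adj)) / (B + 1)
  structure(list(G_raw = G, williams_q = wc$q, G_adj = wc$G_adj,
                 df = k - 1L, p_mc = p, n = n, k = k,
                 n_simulations = as.integer(B), seed = as.integer(seed)),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo uniformity G test: G = %.1f (raw %.2f, Williams q = %.4f), df = %d, p = %.4g (B = %d)\n",
    x$G_adj, x$G_raw, x$williams_q, x$df, x$p_mc, x$n_simulations))
  invisible(x)
}

#' Per-individual chance-level tests with Holm correction
#'
#' After a significant uniformity test, asks which individuals depart from
#' the chance value `n / k`: an exact two-sided binomial test of each
#' individual's count out of `n` against success probability `1 / k`,
#' followed by Holm step-down correction across the `k` tests. Two-sided
#' because both above-chance (candidate leaders) and below-chance individuals
#' are of interest.
#'
#' @param counts non-negative integer counts.
#' @param n total number of trials (default `sum(counts)`).
#' @param alpha family-wise error level for the significance flags.
#' @param ids optional individual labels.
#' @return A data frame of class `"posthoc"`: observed and expected counts,
#'   raw and Holm-adjusted p-values, significance flag, and direction
#'   (`"above"`/`"below"` chance).
#' @export
posthoc_chance_tests <- function(counts, n = sum(counts), alpha = 0.05,
                                 ids = NULL) {
  k <- length(counts)
  stopifnot(k >= 2, all(counts >= 0), all(counts <= n))
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(k))
  p_raw <- vapply(counts, function(x)
    stats::binom.test(x, n, p = 1 / k)$p.value, 0)
  p_holm <- holm_adjust(p_raw)
  out <- data.frame(id = ids, observed = as.integer(counts),
                    expected = n / k, p_raw = p_raw, p_holm = p_holm,
                    significant = p_holm < alpha,
                    direction = ifelse(counts >= n / k, "above", "below"),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("posthoc", "data.frame")
  out
}

#' Holm step-down adjustment of p-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "holm"`: monotone,
#' capped at 1, identity for a single p-value.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "holm")
}

#' Tie-aware Spearman rank correlation
#'
#' Computes `rs` as the Pearson correlation of mid-rank vectors (the standard
#' tie treatment). The p-value is an exact two-sided permutation test over
#' all `n!` orderings when `n <= 9`, and the usual t approximation on
#' `n - 2` degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return A list: `rs`, `p`, `n`, `method` (`"exact"` or
#'   `"t-approximation"`). `rs` is `NA` when either rank vector is constant.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rs = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  rs <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rs_perm <- as.vector(rxc %*% matrix(ryc[perms], nrow = n)) / denom
    p <- mean(abs(rs_perm) >= abs(rs) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rs = rs, p = min(p, 1), n = n, method = method)
}

# n x n! matrix of permutation indices, built iteratively.
all_permutations <- function(n) {
  p <- matrix(1L, nrow = 1)
  for (m in 2:n) {
    old <- p
    p <- matrix(0L, nrow = m, ncol = ncol(old) * m)
    for (pos in seq_len(m)) {
      cols <- seq.int((pos - 1) * ncol(old) + 1, pos * ncol(old))
      p[pos, cols] <- m
      p[-pos, cols] <- old
    }
  }
  p
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis comparison of two or more groups (delegates
#' to [stats::kruskal.test()]), used to compare joining-process durations
#' across first movers.
#'
#' @param groups list of numeric vectors, each non-empty.
#' @return A list: `H`, `df`, `p`, `n` (total observations).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 0L) >= 1))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1, n = length(values)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(values))
}
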