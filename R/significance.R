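#' Pearson correlation with t-test on replicate-mean profiles
#'
#' Ordinary whole-interval correlation between the two profiles, reported
#' alongside the local similarity score. Significance uses the classical
#' result that `t = r * sqrt((n - 2) / (1 - r^2))` follows a t
#' distribution with `n - 2` degrees of freedom under the null of no
#' correlation; the p-value is two-sided. Inputs are the per-time-point
#' replicate means (not normal scores).
#'
#' @param x,y Numeric profiles of equal length `n >= 3`.
#' @return List with elements `r` and `p`. A zero-variance profile makes
#'   the correlation undefined; zero (with p-value 1) is returned with a
#'   warning.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a profile; correlation undefined, returning r = 0")
    return(list(r = 0, p = 1))
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 0))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Permutation p-value for a local similarity score
#'
#' Reshuffles the time order of the X profile uniformly at random,
#' recomputes the score magnitude, and reports the fraction of permuted
#' magnitudes at least as large as the observed one:
#' \deqn{p = \frac{1}{L}\sum_{\ell=1}^{L}
#'       I\{S_{max}(X^{(\ell)}, Y) \ge S_{max}(X, Y)\}.}
#' Comparison is on the non-negative magnitude, which already covers both
#' association signs (the score maximizes over positive and negative
#' configurations), so the test is two-sided by construction. Shuffling
#' the summarized, normalized profile is equivalent to shuffling the raw
#' replicate columns: per-time-point summarization commutes with a
#' permutation of time points and the rank-based normalization is
#' order-invariant.
#'
#' @param zx,zy Normalized profiles.
#' @param observed Observed score magnitude (`magnitude` from
#'   [local_similarity()]).
#' @param delay_limit Delay limit used for the observed score.
#' @param n_perm Number of permutations `L`; `0` returns `NA`.
#' @param seed Optional integer seed for a reproducible permutation
#'   stream; the caller's RNG state is preserved.
#' @param conservative If `TRUE`, use the `(count + 1) / (L + 1)` estimator
#'   instead of the plain proportion. The plain proportion can report
#'   `p = 0`; the conservative variant cannot.
#' @return Permutation p-value in `[0, 1]`, or `NA` if `n_perm = 0`.
#' @export
permutation_pvalue <- function(zx, zy, observed, delay_limit, n_perm,
                               seed = NULL, conservative = FALSE) {
  if (n_perm < 1) return(NA_real_)
  check_ls_inputs(zx, zy, delay_limit)
  n <- length(zx)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(l) {
      ls_score(zx[sample.int(n)], zy, delay_limit)[["magnitude"]] >= observed
    }, logical(1)))
  })
  if (conservative) (hits + 1) / (n_perm + 1) else hits / n_perm
}

#' Bootstrap percentile confidence interval for the LS score
#'
#' For each of `B` bootstrap rounds the `m` replicates are independently
#' resampled with replacement at every time point of X and of Y; the
#' resampled series are re-summarized, re-normalized and re-scored, and
#' the `1 - alpha` percentile interval of the `B` signed scores is
#' returned, using order statistics at positions `ceiling(B * alpha / 2)`
#' and `ceiling(B * (1 - alpha / 2))`. With a single replicate every
#' resample reproduces the original series, so the interval degenerates
#' to the observed score with zero width.
#'
#' @param x,y Replicated series: `n x m` numeric matrices without missing
#'   values.
#' @param method Summarizing function passed to
#'   [summarize_replicates()].
#' @param delay_limit Delay limit for the score.
#' @param n_boot Number of bootstrap rounds `B`; `0` returns `c(NA, NA)`.
#' @param alpha Type-I level of the interval (default 0.05 for a 95% CI).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(x, y, method = "simple", delay_limit = 3,
                         n_boot = 100, alpha = 0.05, seed = NULL) {
  if (n_boot < 1) return(c(low = NA_real_, high = NA_real_))
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y),
            ncol(x) == ncol(y), alpha > 0, alpha < 1)
  if (anyNA(x) || anyNA(y))
    stop("replicated series contain missing values; impute first")
  n <- nrow(x); m <- ncol(x)
  scores <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xb <- resample_replicates(x, n, m)
      yb <- resample_replicates(y, n, m)
      ls_score(ls_profile(xb, method), ls_profile(yb, method),
               delay_limit)[["score"]]
    }, numeric(1))
  })
  scores <- sort(scores)
  c(low = scores[max(1L, ceiling(n_boot * alpha / 2))],
    high = scores[ceiling(n_boot * (1 - alpha / 2))])
}

resample_replicates <- function(x, n, m) {
  if (m == 1L) return(x)
  idx <- matrix(sample.int(m, n * m, replace = TRUE), n, m)
  matrix(x[cbind(rep.int(seq_len(n), m), as.vector(idx))], n, m)
}

#' Storey q-values for a set of p-values
#'
#' Estimates the proportion of true nulls `pi0` by evaluating
#' `pi0(lambda) = #\{p > lambda\} / (N (1 - lambda))` on the grid
#' `lambda = 0, 0.05, ..., 0.90`, smoothing with a cubic polynomial and
#' taking the fitted value at the largest lambda, clamped into (0, 1].
#' The q-value of the i-th smallest p-value is then
#' `min_{j >= i} pi0 * N * p_(j) / j`, capped at 1. The q-value estimates
#' the proportion of false positives incurred when that pair is declared
#' significant.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (no `NA`).
#' @return Numeric vector of q-values in input order.
#' @export
storey_qvalues <- function(p) {
  if (length(p) < 1L) stop("no p-values supplied")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  n <- length(p)
  lambda <- seq(0, 0.90, by = 0.05)
  pi0_grid <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::lm(pi0_grid ~ lambda + I(lambda^2) + I(lambda^3))
  pi0 <- stats::predict(fit, data.frame(lambda = max(lambda)))[[1L]]
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  ord <- order(p)
  qs <- pi0 * n * p[ord] / seq_len(n)
  qs <- pmin(rev(cummin(rev(qs))), 1)
  out <- numeric(n)
  out[ord] <- qs
  out
}
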