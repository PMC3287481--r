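#' Collapse replicates per time point with a summarizing function
#'
#' Reduces the `m` replicate measurements at each time point to a single
#' value. Four summarizing functions are supported:
#' \describe{
#'   \item{`simple`}{arithmetic mean of the replicates;}
#'   \item{`sd`}{mean divided by the replicate standard deviation
#'     (SD-weighted average), using the unbiased `m - 1` denominator;}
#'   \item{`med`}{median of the replicates;}
#'   \item{`mad`}{median divided by the median absolute deviation
#'     `MAD = median(|x - median(x)|)` (no consistency constant).}
#' }
#' The ratio forms (`sd`, `mad`) down-weight time points whose replicates
#' disagree, and require `m >= 2`. Time points where all replicates are
#' identical have zero dispersion; the divisor is then clamped below at
#' `1e-12` with a warning rather than failing, since repeated identical
#' counts are common in real abundance data.
#'
#' @param x An `n x m` numeric matrix (rows = time points, columns =
#'   replicates) with no missing values.
#' @param method Summarizing function: `"simple"`, `"sd"`, `"med"` or
#'   `"mad"`.
#' @return Numeric vector of length `n`.
#' @seealso [normal_score()]
#' @export
summarize_replicates <- function(x, method = c("simple", "sd", "med", "mad")) {
  method <- match.arg(method)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x))
    stop("missing values present; run fill_missing() first")
  m <- ncol(x)
  if (m < 2L && method %in% c("sd", "mad"))
    stop(sprintf("method '%s' is undefined for m = 1 replicate", method))
  switch(method,
    simple = rowMeans(x),
    med = apply(x, 1L, stats::median),
    sd = {
      s <- apply(x, 1L, stats::sd)
      rowMeans(x) / clamp_dispersion(s, "SD")
    },
    mad = {
      med <- apply(x, 1L, stats::median)
      s <- apply(abs(x - med), 1L, stats::median)
      med / clamp_dispersion(s, "MAD")
    })
}

clamp_dispersion <- function(s, what) {
  zero <- s < 1e-12
  if (any(zero)) {
    warning(sprintf("%s is zero at %d time point(s); clamped at 1e-12",
                    what, sum(zero)))
    s[zero] <- 1e-12
  }
  s
}

#' Rank-based normal-score normalization
#'
#' Maps a summarized profile onto standard-normal quantiles:
#' `z_i = qnorm(r_i / (n + 1))` where `r_i` is the (mid-)rank of value `i`
#' among the `n` values. The transform depends on the input only through
#' its ranks, so it is invariant under strictly increasing transformations
#' and enforces marginal normality regardless of the raw data scale. The
#' divisor `n + 1` keeps all arguments strictly inside (0, 1); ties receive
#' average ranks, so a constant profile maps to all zeros.
#'
#' @param x Numeric vector of length `n >= 2` with finite values.
#' @return Numeric vector of normal scores, mean zero for tie-free input.
#' @export
normal_score <- function(x) {
  if (length(x) < 2L)
    stop("normal_score needs at least 2 values")
  if (!all(is.finite(x)))
    stop("normal_score requires finite input values")
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

# Summarize + normalize in one step: the scored profile fed to the DP.
ls_profile <- function(x, method = "simple") {
  normal_score(summarize_replicates(x, method))
}
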