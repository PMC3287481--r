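#' Delay-limited local similarity score between two normalized profiles
#'
#' Finds the pair of equal-length, equally shifted windows (offset at most
#' `delay_limit`) maximizing the running sum of products of the two
#' normalized profiles, in the spirit of a Smith-Waterman alignment with
#' the product `zx[i] * zy[j]` as the match score. Two tables are kept:
#' `P` accumulates the products (positive association) and `N` the negated
#' products (negative association); both reset to zero whenever the
#' running sum would go negative:
#' \deqn{P_{i,j} = \max(0, P_{i-1,j-1} + z^x_i z^y_j), \quad
#'       N_{i,j} = \max(0, N_{i-1,j-1} - z^x_i z^y_j)}
#' over cells with \eqn{|i - j| \le D}. The score magnitude is
#' `max(P_max, N_max) / n` and the sign is `+1` if `P_max >= N_max`, else
#' `-1`. The reported interval is the run of the winning cell, obtained by
#' tracing back along its diagonal to the most recent reset; when several
#' cells attain the maximum, the first in row-major order wins.
#'
#' @param zx,zy Normalized profiles (see [normal_score()]) of equal length
#'   `n`.
#' @param delay_limit Maximum absolute offset `D` between aligned time
#'   points, `0 <= D <= n - 1`. Sample sizes `n > 5 + D` are recommended;
#'   shifting and trimming reduce the effective sample size.
#' @return An object of class `lsa_result`: list with elements `score`
#'   (signed), `magnitude`, `sign`, `p_max`, `n_max`, `xs`, `ys` (1-based
#'   starts of the aligned windows in X and Y), `length`, and `delay`
#'   (`xs - ys`). A zero score reports `xs = ys = 1`, `length = 0`.
#' @seealso [brute_force_ls()] for an exhaustive reference implementation.
#' @export
local_similarity <- function(zx, zy, delay_limit) {
  check_ls_inputs(zx, zy, delay_limit)
  n <- length(zx)
  P <- matrix(0, n + 1L, n + 1L)
  N <- matrix(0, n + 1L, n + 1L)
  PL <- matrix(0L, n + 1L, n + 1L)  # run length ending at each cell
  NL <- matrix(0L, n + 1L, n + 1L)
  bp <- 0; bp_cell <- c(0L, 0L, 0L)
  bn <- 0; bn_cell <- c(0L, 0L, 0L)
  for (i in seq_len(n)) {
    for (j in max(1L, i - delay_limit):min(n, i + delay_limit)) {
      s <- zx[i] * zy[j]
      p <- P[i, j] + s
      if (p > 0) {
        P[i + 1L, j + 1L] <- p
        PL[i + 1L, j + 1L] <- PL[i, j] + 1L
        if (p > bp) {
          bp <- p
          bp_cell <- c(i, j, PL[i + 1L, j + 1L])
        }
      }
      q <- N[i, j] - s
      if (q > 0) {
        N[i + 1L, j + 1L] <- q
        NL[i + 1L, j + 1L] <- NL[i, j] + 1L
        if (q > bn) {
          bn <- q
          bn_cell <- c(i, j, NL[i + 1L, j + 1L])
        }
      }
    }
  }
  sgn <- if (bp >= bn) 1 else -1
  win <- if (sgn > 0) bp_cell else bn_cell
  mag <- max(bp, bn) / n
  if (mag == 0) {
    xs <- 1L; ys <- 1L; len <- 0L
  } else {
    len <- win[3L]
    xs <- win[1L] - len + 1L
    ys <- win[2L] - len + 1L
  }
  structure(list(score = sgn * mag, magnitude = mag, sign = sgn,
                 p_max = bp, n_max = bn, xs = xs, ys = ys,
                 length = len, delay = xs - ys),
            class = "lsa_result")
}

#' @export
print.lsa_result <- function(x, ...) {
  cat(sprintf(
    "local similarity: LS = %.4f (sign %+d), X[%d..%d] ~ Y[%d..%d], delay %d\n",
    x$score, x$sign, x$xs, x$xs + max(x$length - 1L, 0L),
    x$ys, x$ys + max(x$length - 1L, 0L), x$delay))
  invisible(x)
}

# Fast score-only variant used in permutation/bootstrap/benchmark inner
# loops: per-diagonal maximum subarray via cumulative sums (the max(0, .)
# recurrence along a diagonal equals the best contiguous window sum).
ls_score <- function(zx, zy, delay_limit) {
  n <- length(zx)
  bp <- 0; bn <- 0
  for (d in -delay_limit:delay_limit) {
    s <- if (d >= 0) zx[(1 + d):n] * zy[seq_len(n - d)]
         else zx[seq_len(n + d)] * zy[(1 - d):n]
    cs <- cumsum(s)
    prefmin <- cummin(c(0, cs[-length(cs)]))
    bp <- max(bp, cs - prefmin)
    cs <- -cs
    prefmin <- cummin(c(0, cs[-length(cs)]))
    bn <- max(bn, cs - prefmin)
  }
  sgn <- if (bp >= bn) 1 else -1
  mag <- max(bp, bn) / n
  c(score = sgn * mag, magnitude = mag, sign = sgn)
}

#' Exhaustive local similarity by window enumeration
#'
#' Reference implementation that enumerates every offset `d` in
#' `[-delay_limit, delay_limit]` and every contiguous window on that
#' diagonal, scoring window sums of products (positive branch) and of
#' negated products (negative branch). Quadratic in `n` per diagonal;
#' intended for validating [local_similarity()] on small inputs.
#'
#' @inheritParams local_similarity
#' @return An `lsa_result`, combined exactly as in [local_similarity()]
#'   (ties broken by row-major order of the window's last cell).
#' @export
brute_force_ls <- function(zx, zy, delay_limit) {
  check_ls_inputs(zx, zy, delay_limit)
  n <- length(zx)
  bp <- 0; bp_win <- c(1L, 1L, 0L)
  bn <- 0; bn_win <- c(1L, 1L, 0L)
  # scan in row-major order of the window's end cell so that ties keep the
  # first-found window, matching the DP's tie rule
  for (i_end in seq_len(n)) {
    for (j_end in max(1L, i_end - delay_limit):min(n, i_end + delay_limit)) {
      for (len in seq_len(min(i_end, j_end))) {
        xi <- (i_end - len + 1L):i_end
        yi <- (j_end - len + 1L):j_end
        tot <- sum(zx[xi] * zy[yi])
        if (tot > bp) {
          bp <- tot
          bp_win <- c(xi[1L], yi[1L], len)
        }
        if (-tot > bn) {
          bn <- -tot
          bn_win <- c(xi[1L], yi[1L], len)
        }
      }
    }
  }
  sgn <- if (bp >= bn) 1 else -1
  win <- if (sgn > 0) bp_win else bn_win
  mag <- max(bp, bn) / n
  if (mag == 0) win <- c(1L, 1L, 0L)
  structure(list(score = sgn * mag, magnitude = mag, sign = sgn,
                 p_max = bp, n_max = bn, xs = win[1L], ys = win[2L],
                 length = win[3L], delay = win[1L] - win[2L]),
            class = "lsa_result")
}

check_ls_inputs <- function(zx, zy, delay_limit) {
  if (length(zx) != length(zy))
    stop("profiles differ in length: ", length(zx), " vs ", length(zy))
  if (anyNA(zx) || anyNA(zy))
    stop("profiles contain missing values; impute with fill_missing() first")
  if (length(delay_limit) != 1L || delay_limit < 0 ||
      delay_limit > length(zx) - 1L)
    stop("delay_limit must be a single value in [0, n - 1]")
  invisible(TRUE)
}
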