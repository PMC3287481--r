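#' Analysis configuration for the all-pairs pipeline
#'
#' Bundles the user parameters of a run. Defaults follow common practice
#' for abundance time courses: delay limit 3 time units, simple averaging,
#' 1000 permutations, 100 bootstrap rounds, 95% intervals, and 0.05
#' significance thresholds on both the permutation p-value and the
#' q-value.
#'
#' @param delay_limit Maximum association delay `D` in time units.
#' @param transform Replicate summarizing function (see
#'   [summarize_replicates()]).
#' @param fill Missing-value policy (see [fill_missing()]); `"none"`
#'   refuses missing values downstream.
#' @param n_perm Permutations per pair (`0` disables the test).
#' @param n_boot Bootstrap rounds per pair (`0` disables the CI).
#' @param alpha Type-I level for bootstrap intervals.
#' @param p_max,q_max Reporting thresholds used when filtering output and
#'   building networks.
#' @param seed Run-level integer seed. Every pair derives its own
#'   deterministic substream from it, keyed by the pair's index, so
#'   results do not depend on evaluation order.
#' @return List of class `lsa_config`.
#' @export
analysis_config <- function(delay_limit = 3, transform = "simple",
                            fill = "none", n_perm = 1000, n_boot = 100,
                            alpha = 0.05, p_max = 0.05, q_max = 0.05,
                            seed = 1L) {
  stopifnot(delay_limit >= 0, n_perm >= 0, n_boot >= 0,
            alpha > 0, alpha < 1, p_max > 0, p_max <= 1,
            q_max > 0, q_max <= 1)
  transform <- match.arg(transform, c("simple", "sd", "med", "mad"))
  fill <- match.arg(fill, c("none", "zero", "linear", "quadratic",
                            "cubic", "nearest"))
  structure(list(delay_limit = as.integer(delay_limit),
                 transform = transform, fill = fill,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 alpha = alpha, p_max = p_max, q_max = q_max,
                 seed = as.integer(seed)),
            class = "lsa_config")
}

#' Analyze a single pair of replicated series
#'
#' Runs the per-pair pipeline: summarize replicates, normalize, compute
#' the delay-limited local similarity with its aligned interval, attach a
#' permutation p-value, a bootstrap confidence interval (when `m > 1` and
#' `n_boot > 0`), and the Pearson correlation of the replicate-mean
#' profiles. Q-value columns are left `NA`; they are only defined across
#' the full set of pairs and are filled by [analyze_all()].
#'
#' @param x,y Replicated series: `n x m` numeric matrices with no missing
#'   values.
#' @param config An [analysis_config()].
#' @param x_id,y_id Factor labels for the output record.
#' @param pair_seed Integer seed for this pair's permutation and bootstrap
#'   streams (derived from the run seed by [analyze_all()]).
#' @return One-row data frame with columns
#'   `X Y LS lowCI upCI Xs Ys Len D P PCC Ppcc Q Qpcc`.
#' @export
analyze_pair <- function(x, y, config = analysis_config(), x_id = "X",
                         y_id = "Y", pair_seed = config$seed) {
  stopifnot(inherits(config, "lsa_config"), is.matrix(x), is.matrix(y),
            nrow(x) == nrow(y), ncol(x) == ncol(y))
  if (anyNA(x) || anyNA(y))
    stop(sprintf(
      "pair (%s, %s): missing values reached scoring; use a fill method",
      x_id, y_id))
  m <- ncol(x)
  zx <- ls_profile(x, config$transform)
  zy <- ls_profile(y, config$transform)
  ls <- local_similarity(zx, zy, config$delay_limit)
  p <- permutation_pvalue(zx, zy, ls$magnitude, config$delay_limit,
                          config$n_perm, seed = pair_seed)
  ci <- if (m > 1L && config$n_boot > 0L) {
    bootstrap_ci(x, y, config$transform, config$delay_limit,
                 config$n_boot, config$alpha,
                 seed = derive_seed(pair_seed, 1L))
  } else c(low = NA_real_, high = NA_real_)
  pcc <- pearson_test(rowMeans(x), rowMeans(y))
  data.frame(X = x_id, Y = y_id, LS = ls$score,
             lowCI = ci[["low"]], upCI = ci[["high"]],
             Xs = ls$xs, Ys = ls$ys, Len = ls$length, D = ls$delay,
             P = p, PCC = pcc$r, Ppcc = pcc$p,
             Q = NA_real_, Qpcc = NA_real_,
             stringsAsFactors = FALSE)
}

#' All-pairs local similarity analysis
#'
#' Applies [analyze_pair()] to every unordered pair of factors (X is the
#' earlier input row), then computes Storey q-values twice across the full
#' table: over all permutation p-values (`Q`) and over all Pearson
#' p-values (`Qpcc`). The unfiltered table is always returned; apply
#' [filter_records()] or the thresholds in the network step to select
#' significant pairs. A run with `T` factors produces `T * (T - 1) / 2`
#' records and costs on the order of `O(T^2 (B + L) n)` score evaluations.
#'
#' @param dataset An `lsa_dataset` with at least two factors.
#' @param config An [analysis_config()]. The `fill` policy is applied to
#'   each factor before scoring.
#' @param verbose Emit a progress message every 1000 pairs.
#' @return Data frame with one row per pair and the 14 standard columns.
#' @export
analyze_all <- function(dataset, config = analysis_config(),
                        verbose = FALSE) {
  stopifnot(inherits(dataset, "lsa_dataset"),
            inherits(config, "lsa_config"))
  ids <- dataset$factor_ids
  nf <- length(ids)
  if (nf < 2L) stop("need at least 2 factors")
  filled <- lapply(stats::setNames(ids, ids), function(id)
    fill_missing(dataset$series[[id]], config$fill, .label = id))
  pairs <- which(upper.tri(matrix(0, nf, nf)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  records <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    # substream keyed by the factor labels so every (X, Y) record is
    # reproducible regardless of evaluation order or input row order
    pair_seed <- pair_label_seed(config$seed, ids[i], ids[j])
    records[[k]] <- analyze_pair(filled[[i]], filled[[j]], config,
                                 x_id = ids[i], y_id = ids[j],
                                 pair_seed = pair_seed)
    if (verbose && k %% 1000L == 0L)
      message(sprintf("analyzed %d / %d pairs", k, nrow(pairs)))
  }
  out <- do.call(rbind, records)
  if (config$n_perm > 0L) out$Q <- storey_qvalues(out$P)
  out$Qpcc <- storey_qvalues(out$Ppcc)
  rownames(out) <- NULL
  out
}
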