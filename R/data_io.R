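#' Read a replicated time-series abundance matrix
#'
#' Parses a tab-delimited matrix in which each row is one factor (an OTU, a
#' gene, an environmental variable) and the data columns hold `n_spots`
#' time points with `n_reps` replicates each, grouped by time point
#' (t1r1 ... t1r_m, t2r1 ..., i.e. time-major). The first row is a header
#' and the first field of every data row is the factor label.
#'
#' @param path Path to the tab-delimited input file.
#' @param n_spots Number of time points (n).
#' @param n_reps Number of replicates per time point (m).
#' @param missing_token Cell content flagging a missing value, matched
#'   case-insensitively. Empty cells are always treated as missing.
#' @return An object of class `lsa_dataset`: a list with elements
#'   `factor_ids`, `n`, `m`, and `series`, the latter a named list of
#'   `n x m` numeric matrices (rows = time points, columns = replicates)
#'   with `NA` marking missing measurements.
#' @seealso [write_matrix()], [fill_missing()], [analyze_all()]
#' @export
read_matrix <- function(path, n_spots, n_reps, missing_token = "na") {
  stopifnot(length(n_spots) == 1L, n_spots >= 2, length(n_reps) == 1L,
            n_reps >= 1)
  if (!file.exists(path))
    stop("cannot open input file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("input file has no data rows: ", path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  want <- 1L + n_spots * n_reps
  ids <- vapply(fields, `[`, character(1), 1L)
  bad <- which(lengths(fields) != want)
  if (length(bad))
    stop(sprintf(
      "row for factor '%s' has %d data fields, expected %d (n = %d x m = %d)",
      ids[bad[1L]], lengths(fields)[bad[1L]] - 1L, want - 1L,
      n_spots, n_reps))
  if (anyDuplicated(ids))
    stop("duplicate factor label: ", ids[anyDuplicated(ids)])
  series <- lapply(seq_along(fields), function(r) {
    cells <- fields[[r]][-1L]
    miss <- !nzchar(cells) | tolower(cells) == tolower(missing_token)
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !miss)
    if (length(bad)) {
      i <- (bad[1L] - 1L) %/% n_reps + 1L
      j <- (bad[1L] - 1L) %% n_reps + 1L
      stop(sprintf("non-numeric cell '%s' at factor '%s', time %d, replicate %d",
                   cells[bad[1L]], ids[r], i, j))
    }
    vals[miss] <- NA_real_
    matrix(vals, nrow = n_spots, ncol = n_reps, byrow = TRUE)
  })
  names(series) <- ids
  structure(list(factor_ids = ids, n = as.integer(n_spots),
                 m = as.integer(n_reps), series = series),
            class = "lsa_dataset")
}

#' @export
print.lsa_dataset <- function(x, ...) {
  cat(sprintf("lsa_dataset: %d factors, %d time points x %d replicates\n",
              length(x$factor_ids), x$n, x$m))
  miss <- sum(vapply(x$series, function(s) sum(is.na(s)), numeric(1)))
  if (miss > 0) cat(sprintf("  %d missing measurements\n", miss))
  invisible(x)
}

#' Write a replicated dataset back to the tab-delimited matrix format
#'
#' Inverse of [read_matrix()]: columns are time-major (`t1r1 ... t1rm,
#' t2r1, ...`) and missing values are written as the missing token.
#'
#' @param dataset An `lsa_dataset`.
#' @param path Output file path.
#' @param missing_token Token written for missing cells.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(dataset, path, missing_token = "na") {
  stopifnot(inherits(dataset, "lsa_dataset"))
  hdr <- c("factor",
           paste0("t", rep(seq_len(dataset$n), each = dataset$m),
                  "r", rep(seq_len(dataset$m), dataset$n)))
  rows <- vapply(dataset$factor_ids, function(id) {
    v <- as.vector(t(dataset$series[[id]]))  # time-major flattening
    cells <- vapply(v, function(x)
      if (is.na(x)) missing_token else format(x, digits = 17), character(1))
    paste(c(id, cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(hdr, collapse = "\t"), rows), path)
  invisible(path)
}

#' Impute missing values in a replicated series
#'
#' Each replicate column is interpolated independently along the time axis.
#' Interior gaps are filled by the requested method; leading and trailing
#' gaps are always filled by the nearest observed value (constant
#' extrapolation), since extrapolating polynomials is unstable.
#'
#' @param x An `n x m` numeric matrix with `NA` for missing values, or an
#'   `lsa_dataset` (every factor is filled).
#' @param method One of `"none"` (leave missing values in place; downstream
#'   scoring refuses them), `"zero"` (zero-order hold: previous observed
#'   value), `"linear"`, `"quadratic"` (local second-order Lagrange
#'   interpolation through the three nearest observed points), `"cubic"`
#'   (natural cubic spline), or `"nearest"` (nearest observed time point,
#'   earlier point on ties).
#' @param .label Factor label used in error messages.
#' @return Object of the same shape with missing values imputed (except
#'   under `"none"`).
#' @export
fill_missing <- function(x, method = c("none", "zero", "linear", "quadratic",
                                       "cubic", "nearest"), .label = "series") {
  method <- match.arg(method)
  if (inherits(x, "lsa_dataset")) {
    x$series <- lapply(stats::setNames(x$factor_ids, x$factor_ids),
                       function(id) fill_missing(x$series[[id]], method,
                                                 .label = id))
    return(x)
  }
  stopifnot(is.matrix(x))
  if (method == "none" || !anyNA(x)) return(x)
  for (r in seq_len(ncol(x))) {
    v <- x[, r]
    if (!anyNA(v)) next
    obs <- which(!is.na(v))
    min_obs <- switch(method, zero = 1L, nearest = 1L, linear = 2L,
                      quadratic = 3L, cubic = 4L)
    if (length(obs) < min_obs)
      stop(sprintf(
        "factor '%s', replicate %d: %d observed point(s), need >= %d for method '%s'",
        .label, r, length(obs), min_obs, method))
    gap <- which(is.na(v))
    v[gap] <- interp_column(obs, v[obs], gap, method)
    # constant extrapolation outside the observed range
    v[gap[gap < min(obs)]] <- v[min(obs)]
    v[gap[gap > max(obs)]] <- v[max(obs)]
    x[, r] <- v
  }
  x
}

# Interior interpolation of a single replicate column.
interp_column <- function(xs, ys, at, method) {
  switch(method,
    zero = stats::approx(xs, ys, xout = at, method = "constant",
                         rule = 2)$y,
    linear = stats::approx(xs, ys, xout = at, rule = 2)$y,
    nearest = ys[vapply(at, function(t) {
      d <- abs(xs - t)
      which(d == min(d))[1L]  # earlier point wins ties
    }, integer(1))],
    quadratic = vapply(at, function(t) {
      near <- order(abs(xs - t))[1:3]
      xi <- xs[near]; yi <- ys[near]
      sum(yi * vapply(1:3, function(k) {
        prod((t - xi[-k]) / (xi[k] - xi[-k]))
      }, numeric(1)))
    }, numeric(1)),
    cubic = stats::splinefun(xs, ys, method = "natural")(at))
}

results_columns <- c("X", "Y", "LS", "lowCI", "upCI", "Xs", "Ys", "Len",
                     "D", "P", "PCC", "Ppcc", "Q", "Qpcc")

#' Write the pairwise association result table
#'
#' Writes one row per factor pair with the fixed 14-column layout
#' `X Y LS lowCI upCI Xs Ys Len D P PCC Ppcc Q Qpcc`, tab-delimited with a
#' header row. `lowCI`/`upCI` are left empty when the bootstrap was
#' disabled (single replicate or zero bootstrap rounds).
#'
#' @param records Data frame of pair records as produced by
#'   [analyze_all()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(results_columns, names(records))
  if (length(missing_cols))
    stop("records lack required columns: ",
         paste(missing_cols, collapse = ", "))
  utils::write.table(records[, results_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a tab-delimited result table.
#' @return Data frame with the 14 standard columns; empty CI cells become
#'   `NA`.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "",
                          colClasses = c(X = "character", Y = "character"))
  missing_cols <- setdiff(results_columns, names(df))
  if (length(missing_cols))
    stop("result table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Filter a result table by significance thresholds
#'
#' @param records Data frame of pair records.
#' @param p_max,q_max Keep records with permutation `P <= p_max` and
#'   q-value `Q <= q_max`.
#' @return The filtered data frame.
#' @export
filter_records <- function(records, p_max = 0.05, q_max = 0.05) {
  stopifnot(is.data.frame(records))
  keep <- !is.na(records$P) & records$P <= p_max &
          !is.na(records$Q) & records$Q <= q_max
  records[keep, , drop = FALSE]
}
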