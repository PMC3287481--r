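# Shared fixture builders; all data is generated in code.

# A small well-formed replicated dataset built directly from matrices.
make_dataset <- function(series, n, m) {
  structure(list(factor_ids = names(series), n = as.integer(n),
                 m = as.integer(m), series = series),
            class = "lsa_dataset")
}

random_dataset <- function(n_factors = 4, n = 10, m = 2, seed = 1) {
  set.seed(seed)
  series <- lapply(seq_len(n_factors), function(i)
    matrix(rnorm(n * m), n, m))
  names(series) <- paste0("f", seq_len(n_factors))
  make_dataset(series, n, m)
}

# Write a dataset in the on-disk TSV dialect by hand (independent of
# write_matrix) for parser tests.
write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Minimal pair-record data frame for network tests.
make_records <- function(X, Y, LS, Xs, Ys, Len, P = 0, Q = 0) {
  if (length(X) == 0)
    return(data.frame(X = character(0), Y = character(0), LS = numeric(0),
                      lowCI = numeric(0), upCI = numeric(0),
                      Xs = integer(0), Ys = integer(0), Len = integer(0),
                      D = integer(0), P = numeric(0), PCC = numeric(0),
                      Ppcc = numeric(0), Q = numeric(0),
                      Qpcc = numeric(0), stringsAsFactors = FALSE))
  data.frame(X = X, Y = Y, LS = LS, lowCI = NA_real_, upCI = NA_real_,
             Xs = Xs, Ys = Ys, Len = Len, D = Xs - Ys, P = P,
             PCC = 0, Ppcc = 1, Q = Q, Qpcc = 1,
             stringsAsFactors = FALSE)
}

ls_profile_for_test <- function(x) {
  normal_score(summarize_replicates(x, "simple"))
}

# Independent re-evaluation of the cubic-grid pi0 estimator, used to pin
# the step-up part of the q-value computation.
attr_pi0 <- function(p) {
  lambda <- seq(0, 0.90, by = 0.05)
  grid <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- lm(grid ~ poly(lambda, 3, raw = TRUE))
  min(max(unname(predict(fit, data.frame(lambda = 0.90)))[1],
          .Machine$double.eps), 1)
}
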