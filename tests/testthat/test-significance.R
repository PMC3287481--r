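test_that("pearson test matches the closed-form t reference", {
  # exact linearity
  x <- c(1, 5, 2, 8, 3)
  p1 <- pearson_test(x, 2 * x + 1)
  expect_equal(p1$r, 1)
  expect_equal(p1$p, 0)

  # n = 4: t = r sqrt(2 / (1 - r^2)) with 2 df gives p = 1 - |r| exactly
  p2 <- pearson_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(p2$r, 0.8)
  expect_equal(p2$p, 0.2, tolerance = 1e-12)

  # orthogonal profiles: t = 0, p = 1
  x3 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  y3 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  p3 <- pearson_test(x3, y3)
  expect_equal(p3$r, 0)
  expect_equal(p3$p, 1)
})

test_that("pearson test reproduces a from-scratch textbook implementation", {
  set.seed(202)
  for (case in 1:40) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_test(x, y)
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(got$r, r, tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
    # and the packaged t-test agrees
    ct <- cor.test(x, y)
    expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate profiles yield r = 0 with a warning", {
  expect_warning(out <- pearson_test(rep(2, 6), rnorm(6)), "variance")
  expect_equal(out$r, 0)
  expect_equal(out$p, 1)
})

test_that("permutation p-value is 1 for a constant factor and NA when disabled", {
  zc <- rep(0, 10)
  zy <- normal_score(rnorm(10))
  expect_equal(permutation_pvalue(zc, zy, 0, 3, 100, seed = 1), 1)
  expect_true(is.na(permutation_pvalue(zc, zy, 0, 3, 0)))
})

test_that("permutation p-values are reproducible and seed-streamed", {
  set.seed(31)
  zx <- normal_score(rnorm(15)); zy <- normal_score(rnorm(15))
  obs <- local_similarity(zx, zy, 2)$magnitude
  p1 <- permutation_pvalue(zx, zy, obs, 2, 200, seed = 99)
  p2 <- permutation_pvalue(zx, zy, obs, 2, 200, seed = 99)
  expect_identical(p1, p2)
  # the conservative estimator can never report exactly zero
  pc <- permutation_pvalue(zx, zy, obs, 2, 50, seed = 99,
                           conservative = TRUE)
  expect_true(pc >= 1 / 51)
  # calling with a seed must not disturb the caller's RNG stream
  set.seed(5); a <- rnorm(1)
  set.seed(5); permutation_pvalue(zx, zy, obs, 2, 20, seed = 1)
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("a strongly delayed pair is significant, unlike its Pearson test", {
  p <- simulate_delayed_pair(n = 20, m = 5, rho = 0.8, delay = 3,
                             seed = 404)
  zx <- normal_score(summarize_replicates(p$x, "simple"))
  zy <- normal_score(summarize_replicates(p$y, "simple"))
  obs <- local_similarity(zx, zy, 3)$magnitude
  pval <- permutation_pvalue(zx, zy, obs, 3, 500, seed = 404)
  expect_lt(pval, 0.05)
})

test_that("bootstrap interval is degenerate for a single replicate", {
  p <- simulate_delayed_pair(n = 15, m = 1, seed = 8)
  obs <- local_similarity(normal_score(p$x[, 1]), normal_score(p$y[, 1]),
                          3)$score
  for (B in c(1, 10, 73)) {
    ci <- bootstrap_ci(p$x, p$y, "simple", 3, n_boot = B, seed = 2)
    expect_equal(unname(ci[1]), obs)
    expect_equal(unname(ci[2]), obs)
  }
  expect_true(all(is.na(bootstrap_ci(p$x, p$y, n_boot = 0))))
})

test_that("bootstrap interval brackets the observed score and is seed-stable", {
  p <- simulate_delayed_pair(n = 20, m = 5, seed = 13)
  obs <- local_similarity(ls_profile_for_test(p$x), ls_profile_for_test(p$y),
                          3)$score
  ci <- bootstrap_ci(p$x, p$y, "simple", 3, n_boot = 200, seed = 21)
  expect_lt(ci[["low"]], ci[["high"]])
  expect_true(obs >= ci[["low"]] - 0.1 && obs <= ci[["high"]] + 0.1)
  expect_identical(ci, bootstrap_ci(p$x, p$y, "simple", 3, n_boot = 200,
                                    seed = 21))
})

test_that("bootstrap interval covers the noise-free limiting score", {
  # the replicate mean converges to the latent series as m grows, so the
  # latent-series score is the large-replicate limit of the estimate
  set.seed(60)
  n_sims <- 120
  covered <- 0
  for (s in 1:n_sims) {
    x <- rnorm(20)
    y <- c(0.8 * x[4:20] + sqrt(1 - 0.64) * rnorm(17), rnorm(3))
    truth <- local_similarity(normal_score(x), normal_score(y), 3)$score
    p <- list(x = x + matrix(rnorm(100, 0, 0.1), 20, 5),
              y = y + matrix(rnorm(100, 0, 0.1), 20, 5))
    ci <- bootstrap_ci(p$x, p$y, "simple", 3, n_boot = 100, alpha = 0.05)
    if (truth >= ci[["low"]] && truth <= ci[["high"]]) covered <- covered + 1
  }
  expect_gt(covered / n_sims, 0.75)
})

test_that("q-values behave per Storey's estimator", {
  expect_equal(storey_qvalues(rep(1, 20)), rep(1, 20))
  expect_true(storey_qvalues(0.02) <= 0.02)  # pi0 clamped at 1, N = 1

  # a signal block against a null background, against an independent
  # step-up evaluation with the same pi0
  p <- c(rep(0.001, 10), rep(0.5, 990))
  q <- storey_qvalues(p)
  expect_true(all(q[1:10] < 0.05))
  pi0 <- attr_pi0(p)
  ord <- order(p)
  brute <- numeric(1000)
  for (i in seq_along(ord)) {
    js <- i:1000
    brute[ord[i]] <- min(pmin(pi0 * 1000 * p[ord[js]] / js, 1))
  }
  expect_equal(q, brute, tolerance = 1e-12)

  # monotone in p and bounded by 1
  set.seed(17)
  pv <- runif(300)^2
  qv <- storey_qvalues(pv)
  expect_true(all(qv <= 1))
  expect_true(all(diff(qv[order(pv)]) >= -1e-12))

  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(storey_qvalues(c(0.5, NA)), "\\[0, 1\\]")
})
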