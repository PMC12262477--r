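test_that("static FC reproduces exact correlation structure", {
  set.seed(51)
  x <- rnorm(200)
  ts <- make_ts(rbind(x, x + 0, -x), c("A", "B", "C"))
  fc <- static_fc(ts)
  expect_equal(unname(fc$weights["A", "B"]), 1)
  expect_equal(unname(fc$weights["A", "C"]), -1)
  expect_error(static_fc(make_ts(rbind(x, rep(1, 200)))), "zero-variance")
})

test_that("long independent series have near-zero FC", {
  set.seed(52)
  ts <- make_ts(matrix(rnorm(3 * 10000), 3, 10000))
  fc <- static_fc(ts)
  expect_lt(max(abs(offdiag(fc$weights))), 0.1)
})

test_that("FCD has the combinatorial length and piles near 1 when stationary", {
  t <- seq(0, 500, by = 1)
  phases <- c(0, 0.7, 1.9, 3.1)
  x <- t(sapply(phases, function(ph) sin(2 * pi * 0.04 * t + ph)))
  ts <- make_ts(x, dt = 1)
  d <- fcd_distribution(ts, window = 50, step = 10)
  w <- length(seq(1, ncol(x) - 50 + 1, by = 10))
  expect_length(d, w * (w - 1) / 2)
  expect_gt(min(d), 0.9)
  expect_error(fcd_distribution(ts, window = 400), "2 x window")
  expect_error(fcd_distribution(ts, window = 4), ">= 5")
})

test_that("KS distance matches analytic values and the reference test", {
  set.seed(53)
  u <- runif(1e5)
  expect_equal(ks_distance(u, u), 0)
  expect_equal(ks_distance(runif(100), runif(100) + 5), 1)
  v <- runif(1e5) + 0.5
  expect_lt(abs(ks_distance(u, v) - 0.5), 0.01)
  # agreement with the reference implementation on arbitrary samples
  a <- rnorm(500)
  b <- rnorm(700, 0.3)
  expect_equal(ks_distance(a, b),
               unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
  expect_error(ks_distance(numeric(0), u), "nonempty")
})

test_that("composite fit is exactly 1 on self-comparison", {
  set.seed(54)
  g <- generate_synthetic_sc(10, 0.4, seed = 54)
  p <- hopf_params(omega = 2 * pi * 0.05, G = 0.5, duration = 300,
                   seed = 55)
  ts <- simulate_hopf(weighted_digraph(g$weights / max(g$weights),
                                       g$region_ids, "SC"), p)
  fit <- composite_fit(ts, ts)
  expect_equal(fit$fc_correlation, 1)
  expect_equal(fit$fcd_ks, 0)
  expect_equal(fit$fit, 1)
})

test_that("composite fit is invariant under positive affine rescaling", {
  set.seed(56)
  x <- matrix(rnorm(6 * 240), 6, 240)
  x <- x + 0.5 * x[rep(1, 6), ]   # shared structure
  a <- make_ts(x)
  b <- make_ts(x + matrix(rnorm(6 * 240, sd = 0.4), 6, 240))
  f0 <- composite_fit(a, b)
  a2 <- make_ts(3.2 * x + 17)
  b2 <- make_ts(3.2 * b$values + 17)
  f1 <- composite_fit(a2, b2)
  expect_equal(f1$fit, f0$fit, tolerance = 1e-10)
})

test_that("region permutation destroys the composite fit", {
  set.seed(57)
  g <- generate_synthetic_sc(12, 0.3, seed = 57)
  p <- hopf_params(omega = 2 * pi * runif(12, 0.04, 0.07), G = 1,
                   duration = 400, seed = 58)
  ts <- simulate_hopf(weighted_digraph(g$weights / max(g$weights),
                                       g$region_ids, "SC"), p)
  perm <- make_ts(ts$values[c(5, 9, 1, 12, 3, 7, 2, 10, 4, 11, 6, 8), ],
                  ts$region_ids, ts$dt)
  self <- composite_fit(ts, ts)$fit
  shuf <- composite_fit(ts, perm)$fit
  expect_equal(self, 1)
  expect_lt(shuf, 0.3)
})

test_that("time-delay projection recovers constructed shifts", {
  set.seed(59)
  base <- as.vector(stats::filter(rnorm(1300), rep(1, 5) / 5,
                                  sides = 1))[101:1300]
  x <- rbind(base[4:1103], base[1:1100])   # second region lags by 3 samples
  ts <- make_ts(x, c("lead", "lag"), dt = 0.5)
  td <- time_delay_projection(ts, max_lag = 10)
  expect_lt(abs((td[["lag"]] - td[["lead"]]) - 3 * 0.5), 0.5 * 0.5)
  expect_equal(unname(td[["lead"]] + td[["lag"]]), 0, tolerance = 1e-9)

  same <- make_ts(rbind(base[1:800], base[1:800]), c("a", "b"))
  td0 <- time_delay_projection(same, max_lag = 5)
  expect_equal(unname(td0), c(0, 0), tolerance = 1e-9)
})

test_that("a three-stage cascade is ordered earliest to latest", {
  set.seed(60)
  base <- as.vector(stats::filter(rnorm(1500), rep(1, 7) / 7,
                                  sides = 1))[101:1500]
  x <- rbind(base[5:1204], base[3:1202], base[1:1200])
  ts <- make_ts(x, c("first", "second", "third"), dt = 1)
  td <- time_delay_projection(ts, max_lag = 8)
  expect_true(td[["first"]] < td[["second"]])
  expect_true(td[["second"]] < td[["third"]])
  expect_error(time_delay_projection(ts, max_lag = 400), "duration/4")
})

test_that("directionality F1 handles identity and full reversal", {
  set.seed(61)
  n <- 10
  w <- matrix(0, n, n)
  slots <- which(row(w) != col(w) & upper.tri(w))
  picked <- sample(slots, 13)
  w[picked] <- runif(13) + 0.5   # antisymmetric support: no reciprocal edges
  truth <- weighted_digraph(w, paste0("R", 1:n), "ground_truth")
  dens <- 13 / (n * (n - 1))
  expect_equal(f1_directionality(truth, truth, dens), 1)
  flipped <- weighted_digraph(t(w), paste0("R", 1:n), "ground_truth")
  expect_equal(f1_directionality(flipped, truth, dens), 0)
  expect_error(f1_directionality(truth, truth, 1.5), "sparsity")
})

test_that("F1 equals a brute-force confusion-table count", {
  set.seed(62)
  for (r in 1:50) {
    n <- 10
    est <- weighted_digraph(zero_diag(matrix(rnorm(n * n), n)),
                            paste0("R", 1:n), "EC")
    tw <- zero_diag(matrix(rbinom(n * n, 1, 0.2) * runif(n * n), n))
    if (all(tw == 0)) next
    truth <- weighted_digraph(tw, paste0("R", 1:n), "ground_truth")
    s <- 0.15
    got <- f1_directionality(est, truth, s)
    # brute force, cell by cell
    off <- which(row(tw) != col(tw))
    k <- ceiling(s * length(off))
    thr <- sort(abs(est$weights[off]), decreasing = TRUE)[k]
    tp <- fp <- fn <- 0
    for (cell in off) {
      pred <- abs(est$weights[cell]) >= thr
      act <- tw[cell] != 0
      if (pred && act) tp <- tp + 1
      if (pred && !act) fp <- fp + 1
      if (!pred && act) fn <- fn + 1
    }
    want <- if (tp == 0) 0 else {
      p <- tp / (tp + fp)
      rr <- tp / (tp + fn)
      2 * p * rr / (p + rr)
    }
    expect_equal(got, want)
  }
})

test_that("the true graph maximizes F1 over random perturbations", {
  set.seed(63)
  n <- 10
  tw <- zero_diag(matrix(rbinom(n * n, 1, 0.15) * runif(n * n, 0.5, 1), n))
  truth <- weighted_digraph(tw, paste0("R", 1:n), "ground_truth")
  dens <- sum(tw != 0) / (n * (n - 1))
  base <- f1_directionality(truth, truth, dens)
  worse <- vapply(seq_len(200), function(i) {
    pert <- tw + matrix(rnorm(n * n, sd = 2), n)
    f1_directionality(weighted_digraph(zero_diag(pert),
                                       paste0("R", 1:n), "EC"),
                      truth, dens)
  }, numeric(1))
  expect_true(all(worse <= base))
})
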