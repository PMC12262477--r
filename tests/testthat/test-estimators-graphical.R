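# Patel's tau -----------------------------------------------------------

test_that("tau is zero for identical regions (symmetric joint table)", {
  set.seed(21)
  x <- rnorm(500)
  e <- estimate_patel_tau(make_ts(rbind(x, x + 0, x), c("A", "B", "C")))
  expect_equal(unname(e$graph$weights["B", "A"]), 0)
  expect_equal(unname(e$graph$weights["A", "B"]), 0)
})

test_that("tau matches a brute-force evaluation on a printed 2x2 table", {
  # construct binarizable series with a known joint table: Y=1 implies X=1,
  # X has extra events.  With q = 0.5 both thresholds sit inside the zero
  # mass, so active == positive.
  x <- rep(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 50)   # P(X=1) = 0.3
  y <- rep(c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0), 50)   # P(Y=1) = 0.1, subset of X
  x <- x * rep(seq(1, 2, length.out = 500))       # break ties among positives
  y <- y * rep(seq(1, 2, length.out = 500))
  e <- estimate_patel_tau(make_ts(rbind(x, y), c("X", "Y")), q = 0.5)
  # brute force from the table: t1 = 0.1, P(X)=0.3, P(Y)=0.1
  p_x_given_y <- 0.1 / 0.1   # 1
  p_y_given_x <- 0.1 / 0.3
  tau_hand <- sign(p_y_given_x - p_x_given_y) *
    (1 - min(p_x_given_y, p_y_given_x) / max(p_x_given_y, p_y_given_x))
  expect_lt(tau_hand, 0)     # Y ascendant under the sufficiency convention
  expect_equal(unname(e$graph$weights["X", "Y"]), abs(tau_hand))
  expect_equal(unname(e$graph$weights["Y", "X"]), 0)
})

test_that("tau vanishes on independent binarized series", {
  set.seed(23)
  n <- 10000
  x <- rbinom(n, 1, 0.3) * rexp(n)
  y <- rbinom(n, 1, 0.3) * rexp(n)
  e <- estimate_patel_tau(make_ts(rbind(x, y), c("X", "Y")))
  expect_lt(max(abs(e$graph$weights)), 0.05)
})

test_that("constant regions are rejected (no activation variability)", {
  x <- rbind(rep(1, 100), rnorm(100))
  expect_error(estimate_patel_tau(make_ts(x)), "activation variability")
})

# DirectLiNGAM -----------------------------------------------------------

test_that("LiNGAM recovers direction and coefficient of a uniform-noise pair", {
  correct <- 0
  coefs <- numeric(40)
  for (r in 1:40) {
    set.seed(3000 + r)
    n <- 5000
    x <- runif(n) - 0.5
    e <- (runif(n) - 0.5) * 0.4
    y <- 0.8 * x + e
    est <- estimate_direct_lingam(make_ts(rbind(x, y), c("X", "Y")))
    w <- est$graph$weights
    if (abs(w["Y", "X"]) > abs(w["X", "Y"])) correct <- correct + 1
    coefs[r] <- w["Y", "X"]
  }
  expect_gte(correct, 36)            # >= 90%
  expect_lt(abs(mean(coefs) - 0.8), 0.05)
})

test_that("Gaussian pairs are unidentifiable: orientation at chance", {
  xy <- 0
  for (r in 1:60) {
    set.seed(3100 + r)
    x <- rnorm(1000)
    y <- 0.8 * x + rnorm(1000, sd = 0.6)
    est <- estimate_direct_lingam(make_ts(rbind(x, y), c("X", "Y")))
    w <- est$graph$weights
    if (abs(w["Y", "X"]) > abs(w["X", "Y"])) xy <- xy + 1
  }
  # binomial 99.9% band around 0.5 for 60 replicates
  expect_gte(xy, 18)
  expect_lte(xy, 42)
})

test_that("LiNGAM recovers the order of a three-node chain", {
  ok <- 0
  for (r in 1:20) {
    set.seed(3200 + r)
    n <- 3000
    x <- runif(n) - 0.5
    y <- 0.8 * x + (runif(n) - 0.5) * 0.4
    z <- 0.8 * y + (runif(n) - 0.5) * 0.4
    est <- estimate_direct_lingam(make_ts(rbind(x, y, z), c("X", "Y", "Z")))
    ord <- est$params$causal_order
    if (identical(ord, c("X", "Y", "Z"))) ok <- ok + 1
  }
  expect_gte(ok, 18)   # >= 90%
})

test_that("LiNGAM requires more samples than regions", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(estimate_direct_lingam(make_ts(x)), "more samples")
})

# Skew graph -------------------------------------------------------------

test_that("skew graph orients a positively skewed driver", {
  correct <- 0
  for (r in 1:40) {
    set.seed(3300 + r)
    n <- 3000
    x <- rexp(n) - 1
    y <- x + rnorm(n, sd = 0.5)
    est <- estimate_skew_graph(make_ts(rbind(x, y), c("X", "Y")))
    w <- est$graph$weights
    if (abs(w["Y", "X"]) > abs(w["X", "Y"])) correct <- correct + 1
  }
  expect_gte(correct, 36)
})

test_that("symmetric Gaussian pairs keep adjacency but orient at chance", {
  xy <- 0
  adj <- 0
  for (r in 1:60) {
    set.seed(3400 + r)
    x <- rnorm(1500)
    y <- 0.7 * x + rnorm(1500, sd = 0.7)
    est <- estimate_skew_graph(make_ts(rbind(x, y), c("X", "Y")))
    w <- est$graph$weights
    if (any(w != 0)) adj <- adj + 1
    if (abs(w["Y", "X"]) > abs(w["X", "Y"])) xy <- xy + 1
  }
  expect_equal(adj, 60)
  expect_gte(xy, 18)
  expect_lte(xy, 42)
})

test_that("independent regions produce no skew-graph edges at alpha 0.01", {
  clean <- 0
  for (r in 1:40) {
    set.seed(3500 + r)
    x <- matrix(rnorm(4 * 800), 4, 800)
    est <- estimate_skew_graph(make_ts(x), alpha = 0.01)
    if (all(est$graph$weights == 0)) clean <- clean + 1
  }
  expect_gte(clean, 36)   # >= 95% nominal with binomial slack at 40 reps
})

test_that("skew graph refuses more regions than samples", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(estimate_skew_graph(region_ts(x, paste0("R", 1:10), 1)),
               "ill-posed")
})

# shared estimator invariants -------------------------------------------

test_that("every estimator emits zero diagonals and finite weights", {
  set.seed(37)
  x <- matrix(rnorm(5 * 400), 5, 400)
  ts <- make_ts(x)
  for (e in list(estimate_var_l2(ts, 0.01), estimate_mvgc(ts),
                 estimate_patel_tau(ts), estimate_direct_lingam(ts),
                 estimate_skew_graph(ts))) {
    expect_equal(diag(e$graph$weights), rep(0, 5), ignore_attr = TRUE)
    expect_true(all(is.finite(e$graph$weights)))
  }
})
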