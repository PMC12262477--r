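test_that("top-fraction thresholding keeps the exact count and ties", {
  set.seed(81)
  n <- 20
  w <- zero_diag(matrix(rnorm(n * n), n))
  g <- weighted_digraph(w, paste0("R", 1:n), "EC")
  gt <- threshold_top_fraction(g, 0.15)
  expect_equal(sum(gt$weights != 0), ceiling(0.15 * n * (n - 1)))  # 57
  # retained values keep their signs and magnitudes
  kept <- gt$weights[gt$weights != 0]
  expect_true(all(kept %in% w))

  expect_identical(threshold_top_fraction(g, 1)$weights, g$weights)

  tied <- weighted_digraph(zero_diag(matrix(2, 4, 4)),
                           paste0("R", 1:4), "EC")
  expect_message(all_kept <- threshold_top_fraction(tied, 0.25), "tied")
  expect_equal(sum(all_kept$weights != 0), 12)
  expect_error(threshold_top_fraction(
    weighted_digraph(matrix(0, 3, 3), kind = "EC"), 0.5), "all-zero")
})

test_that("noiseless planted hierarchies are recovered exactly", {
  b <- c(0, 1, 2)
  g <- plant_hierarchy_network(3, b, 0, 1, seed = 82)
  h <- estimate_hierarchy(g, fraction = 1)
  expect_lt(max(abs(h$beta - (b - mean(b)))), 1e-10)
  expect_lt(h$residual_rms, 1e-10)
  expect_equal(h$n_components, 1)
  expect_lt(abs(mean(h$beta)), 1e-10)
})

test_that("a single edge solves to symmetric anchored levels", {
  w <- matrix(0, 2, 2)
  w[2, 1] <- 1   # A -> B with weight 1: beta_B - beta_A = 1
  g <- weighted_digraph(w, c("A", "B"), "EC")
  h <- estimate_hierarchy(g, fraction = 1)
  expect_equal(unname(h$beta), c(-0.5, 0.5), tolerance = 1e-12)
})

test_that("noisy planted hierarchies are recovered with high fidelity", {
  cors <- vapply(1:20, function(s) {
    set.seed(8200 + s)
    b <- rnorm(50)
    g <- plant_hierarchy_network(50, b, noise_sd = 0.25 * diff(range(b)),
                                 density = 0.3, seed = 8300 + s)
    h <- estimate_hierarchy(g, fraction = 1)
    cor(h$beta, b)
  }, numeric(1))
  expect_gte(median(cors), 0.95)
})

test_that("hierarchy estimation is shift/scale equivariant and flips on transpose", {
  set.seed(83)
  b <- rnorm(12)
  g <- plant_hierarchy_network(12, b, 0.05, 0.6, seed = 84)
  h <- estimate_hierarchy(g, fraction = 1)

  g_shift <- plant_hierarchy_network(12, b + 5, 0.05, 0.6, seed = 84)
  h_shift <- estimate_hierarchy(g_shift, fraction = 1)
  expect_equal(h_shift$beta, h$beta, tolerance = 1e-8)

  g_scaled <- weighted_digraph(3 * g$weights, g$region_ids, g$kind)
  h_scaled <- estimate_hierarchy(g_scaled, fraction = 1)
  expect_equal(h_scaled$beta, 3 * h$beta, tolerance = 1e-8)

  g_rev <- weighted_digraph(t(g$weights), g$region_ids, g$kind)
  h_rev <- estimate_hierarchy(g_rev, fraction = 1)
  expect_equal(h_rev$beta, -h$beta, tolerance = 1e-8)
})

test_that("negative edges genuinely change the estimated hierarchy", {
  set.seed(85)
  b <- seq(-1, 1, length.out = 10)
  g <- plant_hierarchy_network(10, b, 0.1, 0.8, seed = 86)
  mixed <- g$weights
  h_full <- estimate_hierarchy(weighted_digraph(mixed, g$region_ids, "EC"),
                               fraction = 1)
  pos_only <- mixed
  pos_only[pos_only < 0] <- 0
  h_pos <- estimate_hierarchy(weighted_digraph(pos_only, g$region_ids,
                                               "EC"), fraction = 1)
  expect_gt(max(abs(h_full$beta - h_pos$beta), na.rm = TRUE), 1e-6)
})

test_that("stability normalization matches the hand-computed 2x2 case", {
  g <- weighted_digraph(matrix(c(0, 1, 1, 0), 2), c("A", "B"), "SC")
  gn <- normalize_stable(g, c = 1)
  expect_equal(unname(gn$weights),
               matrix(c(-1, 0.5, 0.5, -1), 2), tolerance = 1e-12)
  ev <- eigen(gn$weights, only.values = TRUE)$values
  expect_equal(sort(Re(ev)), c(-1.5, -0.5), tolerance = 1e-12)

  z <- normalize_stable(weighted_digraph(matrix(0, 3, 3), kind = "EC"))
  expect_equal(unname(z$weights), -diag(3))
})

test_that("normalized systems are always Hurwitz stable", {
  worst <- -Inf
  for (r in 1:100) {
    set.seed(8700 + r)
    n <- sample(5:30, 1)
    w <- matrix(rnorm(n * n, sd = runif(1, 0.1, 3)), n)
    gn <- normalize_stable(weighted_digraph(zero_diag(w),
                                            paste0("R", 1:n), "EC"))
    worst <- max(worst,
                 max(Re(eigen(gn$weights, only.values = TRUE)$values)))
  }
  expect_lt(worst, 0)
})

test_that("impulse propagation matches scalar decay and the analytic limit", {
  gn <- weighted_digraph(-diag(3), paste0("R", 1:3), "system")
  r <- propagate_impulse(gn, "R2")
  expect_equal(unname(r), c(0, 1, 0), tolerance = 1e-12)

  sys <- weighted_digraph(random_stable_system(8, seed = 88),
                          paste0("R", 1:8), "system")
  ana <- propagate_impulse(sys, "R1")
  tau <- 1 / abs(max(Re(eigen(sys$weights, only.values = TRUE)$values)))
  fin <- propagate_impulse(sys, "R1", horizon = 40 * tau)
  expect_lt(max(abs(fin - ana)), 1e-6)
})

test_that("analytic propagation agrees with a dense ODE-solver oracle", {
  skip_if_not_installed("deSolve")
  w <- random_stable_system(10, seed = 89)
  sys <- weighted_digraph(w, paste0("R", 1:10), "system")
  ana <- propagate_impulse(sys, c("R3", "R7"))
  x0 <- rep(0, 10)
  x0[c(3, 7)] <- 0.5
  tau <- 1 / abs(max(Re(eigen(w, only.values = TRUE)$values)))
  # carry the running integral as additional ODE state so the solver, not
  # a quadrature rule, controls its accuracy
  sol <- deSolve::ode(y = c(x0, rep(0, 10)),
                      times = c(0, 60 * tau),
                      func = function(t, y, p) {
                        x <- y[1:10]
                        list(c(as.vector(w %*% x), x))
                      },
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  integral <- sol[nrow(sol), 12:21]
  expect_lt(max(abs(unname(ana) - unname(integral))), 1e-5)
})

test_that("module flow aggregates exactly and isolates blocks", {
  part <- module_partition(setNames(c("M1", "M1", "M2", "M2", "M2"),
                                    paste0("R", 1:5)))
  gn <- weighted_digraph(-diag(5), paste0("R", 1:5), "system")
  fl <- module_flow(gn, part)
  expect_equal(unname(diag(fl$flow)), c(1, 1))  # unit seed mass conserved
  expect_equal(sum(fl$flow) - sum(diag(fl$flow)), 0)

  # block-structured coupling inside M1 only: flow into M2 stays ~0
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 0.4
  sysw <- normalize_stable(weighted_digraph(w, paste0("R", 1:5), "EC"))
  fl2 <- module_flow(sysw, part)
  expect_lt(abs(fl2$flow["M2", "M1"]), 1e-10)
  expect_gt(fl2$flow["M1", "M1"], 0)

  # aggregation equals brute-force per-region propagation
  sys <- weighted_digraph(random_stable_system(5, seed = 90),
                          paste0("R", 1:5), "system")
  fl3 <- module_flow(sys, part)
  resp_m2 <- propagate_impulse(sys, c("R3", "R4", "R5"))
  expect_equal(unname(fl3$flow["M1", "M2"]), sum(resp_m2[1:2]))
})

test_that("state contrasts flag constructed outliers and only those", {
  part <- module_partition(setNames(paste0("M", 1:10), paste0("R", 1:10)))
  mk_flow <- function(po, ne) {
    structure(list(flow = po + ne, flow_pos = po, flow_neg = ne,
                   partition = part, horizon = "analytic",
                   normalization = list()),
              class = "flow_graph")
  }
  set.seed(91)
  base_p <- matrix(runif(100), 10, 10,
                   dimnames = list(part$module_order, part$module_order))
  base_n <- -matrix(runif(100), 10, 10,
                    dimnames = dimnames(base_p))
  fa <- mk_flow(base_p, base_n)
  pb <- base_p + matrix(rnorm(100, sd = 0.01), 10)
  pb[, 4] <- pb[, 4] + 10   # module M4's positive outflow jumps
  fb <- mk_flow(pb, base_n + matrix(rnorm(100, sd = 0.01), 10))
  tab <- compare_states(fa, fb)
  pos <- tab[tab$stream == "positive", ]
  expect_true(pos$sig_two_tailed[pos$module == "M4"])
  expect_false(any(pos$sig_one_tailed[pos$module != "M4"]))

  expect_error(compare_states(fa, fa), "no variation")
})

test_that("state-contrast flags are calibrated under a null", {
  part <- module_partition(setNames(paste0("M", 1:27), paste0("R", 1:27)))
  mk_flow <- function(po, ne) {
    dimnames(po) <- dimnames(ne) <- list(part$module_order,
                                         part$module_order)
    structure(list(flow = po + ne, flow_pos = po, flow_neg = ne,
                   partition = part, horizon = "analytic",
                   normalization = list()),
              class = "flow_graph")
  }
  hits <- 0
  total <- 0
  for (r in 1:150) {
    set.seed(9200 + r)
    fa <- mk_flow(matrix(runif(27^2), 27), -matrix(runif(27^2), 27))
    fb <- mk_flow(matrix(runif(27^2), 27), -matrix(runif(27^2), 27))
    tab <- compare_states(fa, fb)
    hits <- hits + sum(tab$sig_one_tailed[tab$stream == "positive"])
    total <- total + 27
  }
  # flags fire at |z| >= 1.645, i.e. ~10% two-sided exceedance under the
  # null; binomial 99.9% band (z-scores within a 27-module draw are
  # weakly dependent, so the band is indicative but generous)
  p_nom <- 2 * (1 - pnorm(qnorm(0.95)))
  ci <- qbinom(c(0.0005, 0.9995), total, p_nom)
  expect_gte(hits, ci[1] - 10)
  expect_lte(hits, ci[2] + 10)
})
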