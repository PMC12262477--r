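# Shared fixtures: all built in code, no data files.

make_ts <- function(values, ids = NULL, dt = 1) {
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(values)))
  region_ts(values, ids, dt)
}

# random stable VAR transition matrix with given spectral radius
random_stable_A <- function(p, radius = 0.8, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(p * p, sd = 0.5), p, p)
  a * radius / max(Mod(eigen(a, only.values = TRUE)$values))
}

# simulate a lag-1 VAR driven by Gaussian noise
simulate_var <- function(a, n, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  p <- nrow(a)
  x <- matrix(0, p, n)
  x[, 1] <- rnorm(p)
  for (t in 2:n) x[, t] <- a %*% x[, t - 1] + rnorm(p, sd = noise_sd)
  x
}

# random stable (Hurwitz) system matrix: shifted to negative real parts
random_stable_system <- function(n, seed = 1) {
  set.seed(seed)
  w <- matrix(rnorm(n * n, sd = 0.4), n, n)
  lmax <- max(Re(eigen(w, only.values = TRUE)$values))
  w - diag(lmax + 0.5, n)
}

# small signed digraph used across tests
toy_signed_graph <- function() {
  weighted_digraph(matrix(c(0, 2, -1,
                            0, 0, 3,
                            -2, 0, 0), 3, 3, byrow = TRUE),
                   c("A", "B", "C"), "EC")
}
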