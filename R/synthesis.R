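## Synthetic connectomes: connected weighted graphs with heavy-tailed
## weights, degree-preserving directed rewiring to plant ground-truth
## directionality, and planted-hierarchy networks for recovery tests.

#' Generate a synthetic structural-connectivity stand-in
#'
#' Builds a connected, symmetric weighted graph at the requested edge
#' density with heavy-tailed weights, mimicking a group-averaged
#' diffusion-MRI structural connectome before directionality is induced.
#' Real connectomes are modular, with heterogeneous local density and
#' edge weights coupled to topology (within-community connections are
#' denser and stronger); the generator reproduces this with `n_modules`
#' communities whose within-module connection propensity follows a
#' gradient, weak between-module links concentrated on adjacent modules,
#' and within-module weights boosted over between-module ones.  A chain
#' spanning structure (within and across modules) guarantees
#' connectedness; the remaining pairs are drawn without replacement with
#' propensity-proportional probability so the edge count is exact.
#'
#' @param n_regions number of regions (>= 10).
#' @param density fraction of the `n*(n-1)` directed slots that are
#'   nonzero, in (0,1).  Densities below the spanning-tree minimum
#'   cannot produce a connected graph and raise an error.
#' @param weight_dist `"lognormal"` or `"pareto"`.
#' @param meanlog,sdlog lognormal parameters (defaults 0, 1).
#' @param pareto_alpha Pareto tail exponent (default 1.45, the heavy-tail
#'   regime typical of cortical connectivity strength).
#' @param n_modules number of communities (default 5).
#' @param seed integer seed; generation is bit-reproducible under it.
#' @return A [weighted_digraph()] of kind `"SC"` (symmetric), with the
#'   module membership in `meta$modules`.
#' @export
generate_synthetic_sc <- function(n_regions = 100, density = 0.15,
                                  weight_dist = c("lognormal", "pareto"),
                                  meanlog = 0, sdlog = 1,
                                  pareto_alpha = 1.45, n_modules = 5,
                                  seed = 1) {
  weight_dist <- match.arg(weight_dist)
  if (n_regions < 10L) stop("n_regions must be >= 10")
  if (density <= 0 || density >= 1) stop("density must be in (0,1)")
  n <- n_regions
  n_pairs <- round(density * n * (n - 1) / 2)
  if (n_pairs < n - 1L) {
    stop("density ", density, " too low to connect ", n,
         " regions (needs >= ", (n - 1), " pairs, got ", n_pairs, ")")
  }
  set.seed(seed)
  k <- n_modules
  sizes <- rep(n %/% k, k)
  sizes[1] <- sizes[1] + n %% k
  memb <- rep(seq_len(k), sizes)
  ## connection propensity: within-module gradient, adjacent-module
  ## bridges, sparse long-range background
  pw <- seq(0.35, 0.95, length.out = k)
  prob <- matrix(0.015, n, n)
  for (m in seq_len(k)) prob[memb == m, memb == m] <- pw[m]
  for (m in seq_len(k - 1L)) {
    prob[memb == m, memb == m + 1L] <- 0.06
    prob[memb == m + 1L, memb == m] <- 0.06
  }
  ## chain spanning structure: consecutive regions (module-ordered), so
  ## the graph is connected regardless of the random draw
  a <- matrix(FALSE, n, n)
  a[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- TRUE
  a <- a | t(a)
  need <- n_pairs - (n - 1L)
  iu <- which(upper.tri(a) & !a)
  if (need > 0L) {
    pick <- sample(iu, need, prob = prob[iu])
    a[pick] <- TRUE
    a <- a | t(a)
  }
  wu <- which(upper.tri(a) & a)
  m_edges <- length(wu)
  vals <- switch(weight_dist,
                 lognormal = stats::rlnorm(m_edges, meanlog, sdlog),
                 pareto = stats::runif(m_edges)^(-1 / pareto_alpha))
  ## weight-topology coupling: within-module edges are stronger, scaled
  ## with the module's density level
  ri <- ((wu - 1L) %% n) + 1L
  ci <- ((wu - 1L) %/% n) + 1L
  boost <- ifelse(memb[ri] == memb[ci], 1 + 2 * pw[memb[ri]], 0.5)
  w <- matrix(0, n, n)
  w[wu] <- vals * boost
  w <- w + t(w)
  weighted_digraph(w, paste0("R", seq_len(n)), "SC",
                   meta = list(modules = memb))
}

## weak connectivity of the binary support
is_connected_digraph <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w != 0, mode = "directed")
  igraph::is_connected(g, mode = "weak")
}

#' Induce directionality by degree-preserving edge rewiring
#'
#' Performs directed edge swaps (a->b, c->d become a->d, c->b) on the
#' binary support, rejecting swaps that would create a self-loop or a
#' duplicate edge, until the requested fraction of edges has been
#' reassigned; weights travel with their source stub (a->d inherits the
#' weight of a->b).  Binary in- and out-degree sequences are preserved
#' exactly by construction.  Weak connectedness is checked every 10
#' accepted swaps, rolling the batch back on failure.  Applied to a
#' symmetric structural matrix this plants directed ground truth while
#' retaining the network's topological fingerprint (clustering, strength).
#'
#' @param g a connected [weighted_digraph()].
#' @param fraction fraction of directed edges to reassign, in (0,1]
#'   (default 0.2).
#' @param seed integer seed.
#' @return A [weighted_digraph()] of kind `"ground_truth"` with metadata
#'   `n_reassigned`.
#' @export
rewire_directed <- function(g, fraction = 0.2, seed = 1) {
  stopifnot(inherits(g, "weighted_digraph"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0,1]")
  w <- zero_diag(g$weights)
  if (!is_connected_digraph(w)) stop("input graph must be connected")
  n_edges <- sum(w != 0)
  budget <- ceiling(fraction * n_edges / 2)  # each swap reassigns 2 edges
  set.seed(seed)
  done <- 0L
  attempts <- 0L
  max_attempts <- 100L * budget
  batch <- 0L
  w_checkpoint <- w
  while (done < budget) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("rewiring budget unreachable: ", done, "/", budget,
           " swaps in ", attempts, " attempts (graph too constrained)")
    }
    idx <- which(w != 0)
    e <- sample(idx, 2L)
    ## w[i,j] is edge j -> i: source = column, target = row
    t1 <- ((e[1] - 1L) %% nrow(w)) + 1L
    s1 <- ((e[1] - 1L) %/% nrow(w)) + 1L
    t2 <- ((e[2] - 1L) %% nrow(w)) + 1L
    s2 <- ((e[2] - 1L) %/% nrow(w)) + 1L
    ## swap targets: s1->t1, s2->t2  =>  s1->t2, s2->t1
    if (s1 == t2 || s2 == t1) next               # self-loop
    if (w[t2, s1] != 0 || w[t1, s2] != 0) next   # duplicate edge
    w[t2, s1] <- w[t1, s1]
    w[t1, s2] <- w[t2, s2]
    w[t1, s1] <- 0
    w[t2, s2] <- 0
    done <- done + 1L
    batch <- batch + 1L
    if (batch >= 10L || done >= budget) {
      if (is_connected_digraph(w)) {
        w_checkpoint <- w
      } else {
        w <- w_checkpoint
        done <- done - batch
      }
      batch <- 0L
    }
  }
  weighted_digraph(w, g$region_ids, "ground_truth",
                   meta = list(n_reassigned = 2L * done,
                               fraction = fraction))
}

#' Plant a hierarchy-structured directed network
#'
#' On a random connected directed edge set at the requested density, the
#' edge weight from source j to target i is `beta[i] - beta[j]` plus
#' Gaussian noise: the generative model of the incidence-matrix hierarchy
#' estimator, used as its recovery fixture.  The planted levels are
#' attached as metadata.
#'
#' @param n number of regions.
#' @param beta numeric vector of planted per-region hierarchy levels.
#' @param noise_sd Gaussian noise standard deviation on edge weights.
#' @param density fraction of the `n*(n-1)` directed slots carrying edges;
#'   `1` gives the complete digraph.
#' @param seed integer seed.
#' @return A [weighted_digraph()] of kind `"ground_truth"` with
#'   `meta$planted_beta`.
#' @export
plant_hierarchy_network <- function(n, beta, noise_sd = 0, density = 1,
                                    seed = 1) {
  if (length(beta) != n) stop("beta must have length n")
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (density <= 0 || density > 1) stop("density must be in (0,1]")
  set.seed(seed)
  slots <- which(row(diag(n)) != col(diag(n)))
  if (density < 1) {
    repeat {
      keep <- sample(slots, max(round(density * length(slots)), n))
      w0 <- matrix(0, n, n)
      w0[keep] <- 1
      if (is_connected_digraph(w0)) break
    }
  } else {
    keep <- slots
  }
  w <- matrix(0, n, n)
  ri <- ((keep - 1L) %% n) + 1L   # targets
  ci <- ((keep - 1L) %/% n) + 1L  # sources
  w[keep] <- beta[ri] - beta[ci] + stats::rnorm(length(keep), 0, noise_sd)
  weighted_digraph(w, paste0("R", seq_len(n)), "ground_truth",
                   meta = list(planted_beta = beta))
}

#' Planted two-node burst system for orientation checks
#'
#' The reference linear non-Gaussian two-node model used to test edge
#' orientation: the source emits sparse positive bursts
#' (Bernoulli(`burst_rate`) x Exp(1), an event-like activation profile)
#' and the target is a linear readout with dense Gaussian noise,
#' `y = coef * x + noise_sd * N(0,1)`.  All pairwise orientation methods
#' in the package (DirectLiNGAM, Patel's tau, the skew graph) are expected
#' to recover `X -> Y` from this system; the zero-inflated source is
#' essential for Patel's tau, which has no directional power on strictly
#' continuous equal-rate signals.
#'
#' @param n number of samples (timepoints).
#' @param burst_rate Bernoulli rate of source bursts (default 0.2).
#' @param coef linear coupling (default 0.8).
#' @param noise_sd target noise scale (default 0.2).
#' @param seed integer seed.
#' @return A [region_ts()] with regions `X` (source) and `Y` (target).
#' @export
synth_burst_pair <- function(n = 5000, burst_rate = 0.2, coef = 0.8,
                             noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, burst_rate) * stats::rexp(n)
  y <- coef * x + noise_sd * stats::rnorm(n)
  region_ts(rbind(x, y), c("X", "Y"), dt = 1)
}
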