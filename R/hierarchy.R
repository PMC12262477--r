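## Signal-flow hierarchy: incidence-matrix least-squares hierarchy levels,
## eigenvalue-normalized stable linear propagation, module-level flow
## aggregation, and state contrasts.

#' Keep the strongest fraction of edges
#'
#' Retains the top `fraction` of off-diagonal entries by absolute weight
#' (signed values kept) and zeroes the rest.  Ties at the cutoff are all
#' kept, so the retained count may slightly exceed the nominal fraction
#' (a message is emitted when it does).
#'
#' @param g a [weighted_digraph()] with at least one nonzero entry.
#' @param fraction retention fraction in (0,1]; 1 returns the input
#'   unchanged.
#' @return A [weighted_digraph()] of the same kind.
#' @export
threshold_top_fraction <- function(g, fraction = 0.15) {
  stopifnot(inherits(g, "weighted_digraph"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0,1]")
  if (fraction == 1) return(g)
  off <- row(g$weights) != col(g$weights)
  av <- abs(g$weights[off])
  if (all(av == 0)) stop("all-zero matrix cannot be thresholded")
  k <- ceiling(fraction * sum(off))
  thr <- sort(av, decreasing = TRUE)[k]
  keep <- abs(g$weights) >= thr & off
  n_kept <- sum(keep)
  if (n_kept > k) {
    message(n_kept - k, " tied entr(ies) at the cutoff kept beyond the ",
            "nominal count ", k)
  }
  w <- g$weights
  w[!keep] <- 0
  weighted_digraph(zero_diag(w), g$region_ids, g$kind, g$meta)
}

#' Estimate hierarchy levels from a signed EC
#'
#' Models every retained edge value as the hierarchy difference of its
#' endpoints, `E[EC_ij] = beta_i - beta_j` (identity link), stacks the
#' edges into a signed incidence system `Y = X beta` (one row per edge:
#' +1 at the target, -1 at the source) and solves it by minimum-norm least
#' squares via the pseudoinverse of the incidence Gram matrix.  Levels are
#' anchored to mean zero within each weakly connected component of the
#' retained edge graph; levels are not comparable across components (a
#' warning is emitted when more than one exists).
#'
#' @param g a [weighted_digraph()] (typically an integrated EC).
#' @param fraction edge-retention fraction passed to
#'   [threshold_top_fraction()] before fitting (default 0.15); use 1 to
#'   fit all edges.
#' @return A `hierarchy_map`: list with `beta` (named levels),
#'   `retained_fraction`, `n_components`, `residual_rms`, `n_edges`.
#' @export
estimate_hierarchy <- function(g, fraction = 0.15) {
  gt <- threshold_top_fraction(g, fraction)
  w <- gt$weights
  n <- nrow(w)
  idx <- which(w != 0 & row(w) != col(w))
  if (!length(idx)) stop("no edges retained")
  ti <- ((idx - 1L) %% n) + 1L   # targets
  si <- ((idx - 1L) %/% n) + 1L  # sources
  y <- w[idx]
  ## incidence Gram matrix: XtX = D - (A + At) on the undirected support,
  ## a graph Laplacian; min-norm solution via pseudoinverse
  p <- length(idx)
  X <- matrix(0, p, n)
  X[cbind(seq_len(p), ti)] <- 1
  X[cbind(seq_len(p), si)] <- X[cbind(seq_len(p), si)] - 1
  beta <- as.vector(MASS::ginv(crossprod(X)) %*% crossprod(X, y))
  und <- igraph::graph_from_adjacency_matrix((w != 0) | t(w != 0),
                                             mode = "undirected")
  comp <- igraph::components(und)$membership
  iso <- !(seq_len(n) %in% c(ti, si))
  for (cmp in unique(comp)) {
    sel <- comp == cmp & !iso
    if (any(sel)) beta[sel] <- beta[sel] - mean(beta[sel])
  }
  beta[iso] <- NA_real_
  ncomp <- length(unique(comp[!iso]))
  if (ncomp > 1L) {
    warning("retained edge graph has ", ncomp, " components; hierarchy ",
            "levels are only comparable within a component")
  }
  resid <- y - (beta[ti] - beta[si])
  structure(list(beta = stats::setNames(beta, gt$region_ids),
                 retained_fraction = fraction, n_components = ncomp,
                 residual_rms = sqrt(mean(resid^2)), n_edges = p),
            class = "hierarchy_map")
}

#' @export
print.hierarchy_map <- function(x, ...) {
  cat(sprintf(paste0("<hierarchy_map> %d regions, %d edges (top %.0f%%), ",
                     "%d component(s), residual RMS %.4f\n"),
              length(x$beta), x$n_edges, 100 * x$retained_fraction,
              x$n_components, x$residual_rms))
  invisible(x)
}

#' Normalize an EC matrix to a stable linear system
#'
#' Returns `g / (lambda_max + c) - I`, where `lambda_max` is the largest
#' real part among the eigenvalues of the weight matrix and `I` the
#' identity.  Every eigenvalue of the result has strictly negative real
#' part, so the linear system `x' = W x` is guaranteed to decay.
#'
#' @param g a [weighted_digraph()].
#' @param c stability margin added to the leading eigenvalue (default 1).
#' @return A [weighted_digraph()] of kind `"system"` with metadata
#'   `lambda_max` and `c`.  Note the diagonal is `-1` plus any original
#'   diagonal, so the result is a system matrix, not an EC in the
#'   zero-diagonal sense.
#' @export
normalize_stable <- function(g, c = 1) {
  stopifnot(inherits(g, "weighted_digraph"))
  lmax <- max(Re(eigen(g$weights, only.values = TRUE)$values))
  if (lmax + c <= 0) {
    stop("lambda_max + c must be positive (got ", signif(lmax + c, 4), ")")
  }
  w <- g$weights / (lmax + c) - diag(nrow(g$weights))
  weighted_digraph(w, g$region_ids, "system",
                   meta = list(lambda_max = lmax, c = c,
                               normalized_stable = TRUE))
}

#' Propagate a seed impulse through a stable linear system
#'
#' Places unit mass uniformly over `seed_regions` and reads out the
#' time-integral of the state of `x' = W x`: for `horizon = "analytic"`
#' the closed form `-W^{-1} x(0)` (the integral to infinity), otherwise
#' the finite-horizon integral `W^{-1}(e^{hW} - I) x(0)` via the matrix
#' exponential.  The finite-horizon value converges to the analytic one as
#' the horizon grows.
#'
#' @param g_norm a stable [weighted_digraph()] (all eigenvalue real parts
#'   negative), e.g. from [normalize_stable()].
#' @param seed_regions character vector of region ids (or integer indices)
#'   receiving the impulse.
#' @param horizon `"analytic"` (default) or a positive time.
#' @return Named numeric vector: integrated response per region.
#' @export
propagate_impulse <- function(g_norm, seed_regions, horizon = "analytic") {
  stopifnot(inherits(g_norm, "weighted_digraph"))
  w <- g_norm$weights
  if (max(Re(eigen(w, only.values = TRUE)$values)) >= 0) {
    stop("system is not stable; apply normalize_stable() first")
  }
  n <- nrow(w)
  if (is.character(seed_regions)) {
    seed_idx <- match(seed_regions, g_norm$region_ids)
    if (anyNA(seed_idx)) {
      stop("unknown seed region(s): ",
           paste(seed_regions[is.na(seed_idx)], collapse = ", "))
    }
  } else {
    seed_idx <- as.integer(seed_regions)
  }
  x0 <- rep(0, n)
  x0[seed_idx] <- 1 / length(seed_idx)
  resp <- if (identical(horizon, "analytic")) {
    -solve(w, x0)
  } else {
    h <- as.numeric(horizon)
    if (!is.finite(h) || h <= 0) stop("horizon must be positive")
    eh <- as.matrix(Matrix::expm(h * w))
    solve(w, (eh - diag(n)) %*% x0)
  }
  stats::setNames(as.vector(resp), g_norm$region_ids)
}

#' Module-level signal flow
#'
#' Seeds each module in turn with a unit impulse (mass split uniformly
#' over its regions), propagates it through the stable system, and sums
#' the per-region integrated responses within each target module.  Signed
#' responses are kept, and the positive and negative parts are also
#' accumulated separately, since excitatory and suppressive flow streams
#' are interpreted separately.
#'
#' @param g_norm a stable [weighted_digraph()].
#' @param partition a [module_partition()] covering all regions.
#' @param horizon propagation horizon (default `"analytic"`).
#' @return A `flow_graph`: list with `flow`, `flow_pos`, `flow_neg`
#'   (module x module matrices, rows = target modules, columns = seeded
#'   source modules), `partition`, `horizon`, `normalization`.
#' @export
module_flow <- function(g_norm, partition, horizon = "analytic") {
  stopifnot(inherits(g_norm, "weighted_digraph"),
            inherits(partition, "module_partition"))
  if (!setequal(names(partition$assignment), g_norm$region_ids)) {
    stop("partition does not cover exactly the graph's regions")
  }
  mods <- partition$module_order
  memb <- partition$assignment[g_norm$region_ids]
  k <- length(mods)
  flow <- flow_pos <- flow_neg <-
    matrix(0, k, k, dimnames = list(mods, mods))
  for (m in mods) {
    resp <- propagate_impulse(g_norm, g_norm$region_ids[memb == m], horizon)
    for (tm in mods) {
      r <- resp[memb == tm]
      flow[tm, m] <- sum(r)
      flow_pos[tm, m] <- sum(r[r > 0])
      flow_neg[tm, m] <- sum(r[r < 0])
    }
  }
  structure(list(flow = flow, flow_pos = flow_pos, flow_neg = flow_neg,
                 partition = partition, horizon = horizon,
                 normalization = g_norm$meta[c("lambda_max", "c")]),
            class = "flow_graph")
}

#' Contrast module flows between two states
#'
#' For each module, summarizes outgoing flow separately for the positive
#' and negative streams (column sums of `flow_pos` and `flow_neg`),
#' computes the state difference Delta = B - A, standardizes it as
#' z-scores across modules within each stream, and flags modules at the
#' one-tailed (|z| >= 1.645, alpha = 0.05) and two-tailed (|z| >= 1.96,
#' alpha = 0.025 per tail) thresholds.
#'
#' @param flow_a,flow_b `flow_graph` objects over the same partition
#'   (state A = baseline, state B = contrast).
#' @return A data.frame with columns `module`, `stream`, `delta`, `z`,
#'   `sig_one_tailed`, `sig_two_tailed`.
#' @export
compare_states <- function(flow_a, flow_b) {
  stopifnot(inherits(flow_a, "flow_graph"), inherits(flow_b, "flow_graph"))
  if (!identical(flow_a$partition$module_order,
                 flow_b$partition$module_order)) {
    stop("flow graphs use different partitions")
  }
  mods <- flow_a$partition$module_order
  rows <- lapply(c(positive = "flow_pos", negative = "flow_neg"),
                 function(f) colSums(flow_b[[f]]) - colSums(flow_a[[f]]))
  out <- do.call(rbind, lapply(names(rows), function(stream) {
    d <- rows[[stream]]
    s <- stats::sd(d)
    if (!is.finite(s) || s == 0) {
      stop("no variation in the ", stream, " flow deltas across modules")
    }
    z <- (d - mean(d)) / s
    data.frame(module = mods, stream = stream, delta = unname(d),
               z = unname(z),
               sig_one_tailed = abs(z) >= stats::qnorm(0.95),
               sig_two_tailed = abs(z) >= stats::qnorm(0.975),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
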