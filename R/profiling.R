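## Descriptive profiling of a signed EC: weighted degrees, signed-edge
## ratios, heavy-tail index, tracer-style feedforward/feedback sign
## profiles, and the directed weighted clustering coefficient.

#' Signed degree profile of a weighted digraph
#'
#' Weighted in-degree (strength) of region i is its row sum
#' `sum_j EC[i, j]`; weighted out-degree of region j is its column sum
#' `sum_i EC[i, j]`.  The positive (negative) ratio of a region's in- or
#' out-connections is the count of positive (negative) entries in its row
#' or column divided by N, the matrix dimension -- the denominator is N
#' rather than N-1 by definition of the profile.
#'
#' @param g a [weighted_digraph()].
#' @return A `degree_profile` data.frame with columns `region`,
#'   `in_strength`, `out_strength`, `pos_in_ratio`, `neg_in_ratio`,
#'   `pos_out_ratio`, `neg_out_ratio`.
#' @export
signed_degree_profile <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  w <- g$weights
  n <- nrow(w)
  out <- data.frame(
    region = g$region_ids,
    in_strength = rowSums(w),
    out_strength = colSums(w),
    pos_in_ratio = rowSums(w > 0) / n,
    neg_in_ratio = rowSums(w < 0) / n,
    pos_out_ratio = colSums(w > 0) / n,
    neg_out_ratio = colSums(w < 0) / n,
    row.names = NULL)
  class(out) <- c("degree_profile", "data.frame")
  out
}

#' Hill tail-index estimator
#'
#' Estimates the tail exponent of a heavy-tailed positive sample from the
#' top `top_fraction` order statistics:
#' `alpha = k / sum_{i=1..k} log(x_(i) / x_(k+1))` with `x_(1) >= ...`
#' the decreasing order statistics.  Values below 2 indicate a
#' heavy-tailed distribution (infinite variance regime).
#'
#' @param weights positive numeric values (>= 50 required).
#' @param top_fraction fraction of the sample treated as the tail
#'   (default 0.1).
#' @return Scalar tail-index estimate.
#' @export
tail_index <- function(weights, top_fraction = 0.1) {
  x <- weights[is.finite(weights) & weights > 0]
  if (length(x) < 50L) stop("need >= 50 positive values, got ", length(x))
  x <- sort(x, decreasing = TRUE)
  k <- max(2L, floor(top_fraction * length(x)))
  if (k >= length(x)) k <- length(x) - 1L
  k / sum(log(x[1:k] / x[k + 1L]))
}

#' Feedforward/feedback sign profile against a tracer-style matrix
#'
#' Classifies edges with a defined tracer value (e.g. the fraction of
#' supragranular labeled neurons, range 0-1) as feedforward
#' (value > threshold) or feedback (value < threshold); values exactly at
#' the threshold are dropped as ties, and unmeasured pairs (NaN) are
#' skipped.  Within each class, the proportions of positive and negative
#' EC entries are reported.
#'
#' @param ec a [weighted_digraph()] of kind `"EC"`.
#' @param sln_like a [weighted_digraph()] (kind `"SLN"`) over the same
#'   regions; NaN marks unmeasured pairs.
#' @param threshold feedforward/feedback cut (default 0.5).
#' @return A data.frame with columns `class` (`FF`/`FB`), `n_edges`,
#'   `prop_positive`, `prop_negative`, `prop_zero`.
#' @export
pathway_sign_profile <- function(ec, sln_like, threshold = 0.5) {
  check_same_regions(ec$region_ids, sln_like$region_ids,
                     "EC and tracer matrices")
  off <- row(ec$weights) != col(ec$weights)
  sv <- sln_like$weights[off]
  ev <- ec$weights[off]
  defined <- is.finite(sv)
  if (!any(defined)) stop("no defined tracer edges")
  cls <- ifelse(sv > threshold, "FF", ifelse(sv < threshold, "FB", NA))
  keep <- defined & !is.na(cls)
  if (!any(keep)) stop("all tracer values tie at the threshold")
  out <- do.call(rbind, lapply(c("FF", "FB"), function(cl) {
    sel <- keep & cls == cl
    n <- sum(sel)
    data.frame(class = cl, n_edges = n,
               prop_positive = if (n) mean(ev[sel] > 0) else NA_real_,
               prop_negative = if (n) mean(ev[sel] < 0) else NA_real_,
               prop_zero = if (n) mean(ev[sel] == 0) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Directed weighted clustering coefficient (Fagiolo)
#'
#' Per-node clustering for weighted digraphs: with `W` the weight matrix
#' scaled to \[0, 1\] by its maximum and `Wr = W^(1/3)` elementwise,
#' \deqn{C_i = \frac{[(Wr + Wr^T)^3]_{ii} / 2}
#'   {d^{tot}_i (d^{tot}_i - 1) - 2 d^{bi}_i}}
#' where `d_tot` is the total binary degree (in + out) and `d_bi` the
#' number of bilateral (reciprocated) neighbors.  Nodes with fewer than
#' two neighbors get 0.
#'
#' @param g a [weighted_digraph()]; weights are used in absolute value.
#' @return Named numeric vector of clustering coefficients.
#' @export
weighted_clustering <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  w <- abs(zero_diag(g$weights))
  mx <- max(w)
  if (mx == 0) {
    return(stats::setNames(rep(0, nrow(w)), g$region_ids))
  }
  wr <- (w / mx)^(1 / 3)
  a <- (w != 0) * 1
  s <- wr + t(wr)
  num <- diag(s %*% s %*% s) / 2
  dtot <- rowSums(a) + colSums(a)
  dbi <- diag(a %*% a)
  den <- dtot * (dtot - 1) - 2 * dbi
  cc <- ifelse(den > 0, num / den, 0)
  stats::setNames(cc, g$region_ids)
}
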