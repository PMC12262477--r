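## Validation metrics: static FC, sliding-window FC dynamics (FCD) and its
## Kolmogorov-Smirnov distance, the composite fit r - KS, time-delay
## projection, and directionality F1 against a ground-truth network.

#' Static functional connectivity
#'
#' Pearson correlation matrix across regions.
#'
#' @param ts a [region_ts()] with >= 3 timepoints.
#' @return A symmetric [weighted_digraph()] of kind `"FC"`.
#' @export
static_fc <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  v <- apply(ts$values, 1, stats::sd)
  if (any(v == 0)) {
    stop("zero-variance region(s): ",
         paste(ts$region_ids[v == 0], collapse = ", "))
  }
  weighted_digraph(stats::cor(t(ts$values)), ts$region_ids, "FC")
}

#' Functional connectivity dynamics distribution
#'
#' Computes FC within sliding windows, then the Pearson correlation between
#' the vectorized upper-triangular window-FCs for every pair of windows
#' (the FCD matrix); returns the upper-triangular FCD entries as the
#' empirical distribution.  For `w` windows the distribution has length
#' `w*(w-1)/2`.
#'
#' @param ts a [region_ts()] with duration >= 2 windows.
#' @param window window length in samples (default 30).
#' @param step window step in samples (default 3).
#' @return Numeric vector of FCD entries in \[-1, 1\].
#' @export
fcd_distribution <- function(ts, window = 30, step = 3) {
  stopifnot(inherits(ts, "region_ts"))
  if (window < 5) stop("window must be >= 5 samples")
  n <- ncol(ts$values)
  if (n < 2 * window) stop("duration must be >= 2 x window")
  starts <- seq(1L, n - window + 1L, by = step)
  ut <- upper.tri(matrix(0, nrow(ts$values), nrow(ts$values)))
  vecs <- vapply(starts, function(s) {
    fc <- suppressWarnings(
      stats::cor(t(ts$values[, s:(s + window - 1L), drop = FALSE])))
    fc[!is.finite(fc)] <- 0
    fc[ut]
  }, numeric(sum(ut)))
  fcd <- suppressWarnings(stats::cor(vecs))
  fcd[!is.finite(fcd)] <- 0
  fcd[upper.tri(fcd)]
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' Sup-norm distance between the empirical CDFs; a metric on empirical
#' distributions, in \[0, 1\].
#'
#' @param d1,d2 nonempty numeric vectors.
#' @return Scalar in \[0, 1\].
#' @export
ks_distance <- function(d1, d2) {
  if (!length(d1) || !length(d2)) stop("both samples must be nonempty")
  grid <- sort(c(d1, d2))
  c1 <- findInterval(grid, sort(d1)) / length(d1)
  c2 <- findInterval(grid, sort(d2)) / length(d2)
  max(abs(c1 - c2))
}

#' Composite fit between empirical and simulated signals
#'
#' The model-fitting score `fit = r - KS`: Pearson correlation between the
#' off-diagonal static FCs minus the Kolmogorov-Smirnov distance between
#' the FCD distributions.  Higher is better; a simulation identical to the
#' data scores exactly 1 (r = 1, KS = 0), and the score is invariant under
#' any common positive affine rescaling of either signal set.  When
#' `max_lag` is given, the correlation of the time-delay projections is
#' reported alongside (not part of the score).
#'
#' @param empirical_ts,simulated_ts [region_ts()] objects over the same
#'   regions.
#' @param window,step FCD windowing (defaults 30 and 3 samples).
#' @param max_lag optional lag bound (samples) to add the time-delay
#'   comparison.
#' @return A `fit_report` list: `fc_correlation`, `fcd_ks`, `fit`,
#'   `td_correlation` (NA unless `max_lag` given).
#' @export
composite_fit <- function(empirical_ts, simulated_ts, window = 30,
                          step = 3, max_lag = NULL) {
  check_same_regions(empirical_ts$region_ids, simulated_ts$region_ids,
                     "empirical and simulated series")
  fc_e <- static_fc(empirical_ts)$weights
  fc_s <- static_fc(simulated_ts)$weights
  r <- stats::cor(offdiag(fc_e), offdiag(fc_s))
  ks <- ks_distance(fcd_distribution(empirical_ts, window, step),
                    fcd_distribution(simulated_ts, window, step))
  td <- NA_real_
  if (!is.null(max_lag)) {
    td <- stats::cor(time_delay_projection(empirical_ts, max_lag),
                     time_delay_projection(simulated_ts, max_lag))
  }
  structure(list(fc_correlation = r, fcd_ks = ks, fit = r - ks,
                 td_correlation = td),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> FC r = %.3f, FCD KS = %.3f, fit = %.3f",
              x$fc_correlation, x$fcd_ks, x$fit))
  if (!is.na(x$td_correlation)) {
    cat(sprintf(", TD r = %.3f", x$td_correlation))
  }
  cat("\n")
  invisible(x)
}

#' Time-delay projection
#'
#' For every region pair, the lagged cross-covariance is evaluated over
#' +/- `max_lag` samples and the lag of its absolute extremum is refined by
#' parabolic interpolation; extrema pinned at the window edge are censored.
#' The pairwise lag matrix is antisymmetric by construction (the lag of
#' (j,i) is minus the lag of (i,j)); a region's projection value is its row
#' mean over uncensored pairs, in seconds.  Earlier (leading) regions get
#' negative values.
#'
#' @param ts a [region_ts()] with duration much larger than `max_lag`
#'   (at least 4x).
#' @param max_lag lag bound in samples (default 10).
#' @return Named numeric vector, one mean lag (s) per region.
#' @export
time_delay_projection <- function(ts, max_lag = 10) {
  stopifnot(inherits(ts, "region_ts"))
  n <- ncol(ts$values)
  if (max_lag >= n / 4) stop("max_lag must be < duration/4")
  p <- nrow(ts$values)
  x <- t(scale(t(ts$values)))   # per-region standardization
  lags <- (-max_lag):max_lag
  lagmat <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      cc <- vapply(lags, function(l) {
        if (l >= 0) {
          mean(x[i, 1:(n - l)] * x[j, (1 + l):n])
        } else {
          mean(x[i, (1 - l):n] * x[j, 1:(n + l)])
        }
      }, numeric(1))
      k <- which.max(abs(cc))
      if (k == 1L || k == length(lags)) next  # censored: edge extremum
      ## parabolic refinement around the extremum
      y0 <- cc[k - 1L]; y1 <- cc[k]; y2 <- cc[k + 1L]
      den <- y0 - 2 * y1 + y2
      shift <- if (abs(den) < .Machine$double.eps) 0 else
        0.5 * (y0 - y2) / den
      lag_ij <- (lags[k] + shift) * ts$dt
      ## positive lag: j follows i (i leads); store antisymmetrically
      lagmat[i, j] <- lag_ij
      lagmat[j, i] <- -lag_ij
    }
  }
  diag(lagmat) <- 0
  td <- apply(lagmat, 1, function(r) mean(r[is.finite(r)]))
  ## row mean of lags at which OTHERS follow region i; negate so that
  ## regions leading the network get negative (early) values
  stats::setNames(-td, ts$region_ids)
}

#' Directionality F1 score against a ground-truth network
#'
#' Binarizes the estimate by retaining the top `sparsity` fraction of
#' off-diagonal absolute weights and the truth by its nonzero entries
#' (tract-tracing semantics: an absent projection is a structural zero),
#' then scores the directed edge labels: F1 = 2PR/(P+R).
#'
#' @param estimate,truth [weighted_digraph()] objects over the same
#'   regions; `truth` must have at least one edge.
#' @param sparsity retention fraction in (0,1), e.g. 0.15 or 0.30.
#' @return Scalar in \[0, 1\].
#' @export
f1_directionality <- function(estimate, truth, sparsity = 0.15) {
  check_same_regions(estimate$region_ids, truth$region_ids,
                     "estimate and truth")
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0,1)")
  off <- row(estimate$weights) != col(estimate$weights)
  tv <- truth$weights[off] != 0
  if (!any(tv)) stop("truth has no edges")
  av <- abs(estimate$weights[off])
  k <- ceiling(sparsity * sum(off))
  thr <- sort(av, decreasing = TRUE)[k]
  ev <- av >= thr & av > 0
  tp <- sum(ev & tv)
  fp <- sum(ev & !tv)
  fn <- sum(!ev & tv)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
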