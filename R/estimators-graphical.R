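## Graphical-model estimators.  These treat timepoints as i.i.d. samples
## and infer directionality from contemporaneous statistical structure:
## conditional activation probabilities (Patel's tau), non-Gaussianity
## (DirectLiNGAM), and skewness of the joint distribution (skew graph).

#' Patel's tau: pairwise conditional-activation directionality
#'
#' Binarizes each region at its `q`-quantile (active = above) and, for each
#' pair, compares the conditional activation probabilities P(X|Y) and
#' P(Y|X) from the 2x2 joint-activation table.  The asymmetry
#' \deqn{\tau = \mathrm{sign}(P(Y|X)-P(X|Y)) \left(1 -
#'   \frac{\min(P(X|Y),P(Y|X))}{\max(P(X|Y),P(Y|X))}\right)}
#' lies in \[-1, 1\]; tau > 0 marks X as ascendant (activation of X is
#' reliably followed by activation of Y, while Y also activates on its own)
#' and is stored as an X -> Y edge of weight tau; tau < 0 as Y -> X of
#' weight |tau|.  Applied to the full series without subsampling.
#'
#' Directional power requires unequal activation rates, which quantile
#' binarization only produces for zero-inflated (event-like) signals: for
#' strictly continuous data every region is active exactly `1 - q` of the
#' time and tau is ~0 by construction.
#'
#' @param ts a [region_ts()].
#' @param q binarization quantile in (0,1); default 0.75.
#' @return An `ec_estimate` with weights in \[0, 1\].
#' @export
estimate_patel_tau <- function(ts, q = 0.75) {
  stopifnot(inherits(ts, "region_ts"))
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0,1)")
  x <- ts$values
  p <- nrow(x)
  act <- matrix(FALSE, p, ncol(x))
  for (i in seq_len(p)) {
    thr <- stats::quantile(x[i, ], q, names = FALSE)
    act[i, ] <- x[i, ] > thr
    if (!any(act[i, ])) {
      stop("region ", ts$region_ids[i],
           " has no activation variability after binarization")
    }
  }
  w <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      tau <- patel_tau_pair(act[i, ], act[j, ])
      if (tau > 0) {        # i ascendant: i -> j
        w[j, i] <- tau
      } else if (tau < 0) { # j ascendant: j -> i
        w[i, j] <- -tau
      }
    }
  }
  ec_estimate(w, ts$region_ids, "patel_tau", list(q = q))
}

## tau for one binarized pair; positive means x ascendant to y.
patel_tau_pair <- function(x, y) {
  t1 <- mean(x & y)       # joint activation
  px <- t1 + mean(x & !y) # P(x=1)
  py <- t1 + mean(!x & y) # P(y=1)
  if (t1 == 0 || px == 0 || py == 0) return(0)
  p_x_given_y <- t1 / py
  p_y_given_x <- t1 / px
  hi <- max(p_x_given_y, p_y_given_x)
  lo <- min(p_x_given_y, p_y_given_x)
  sign(p_y_given_x - p_x_given_y) * (1 - lo / hi)
}

## --- DirectLiNGAM ---------------------------------------------------------
## The pairwise exogeneity sweep lives in src/lingam.cpp
## (lingam_exogeneity_scores); the recursion and the final coefficient
## regressions stay here.

#' DirectLiNGAM: linear non-Gaussian acyclic causal discovery
#'
#' Assumes a linear acyclic data-generating model with non-Gaussian noise,
#' under which the causal order is identifiable.  The order is found by
#' repeatedly selecting the most exogenous variable -- the one whose
#' regression residuals are least dependent on it, scored by a
#' mutual-information difference computed from a maximum-entropy
#' approximation -- regressing its influence out of the remaining
#' variables, and recursing.  Signed connection coefficients are then
#' estimated by ordinary least squares of each variable on its causal
#' predecessors.
#'
#' With purely Gaussian data the direction of an edge is unidentifiable and
#' the assigned orientation is arbitrary (chance level across seeds).
#'
#' @param ts a [region_ts()]; timepoints are treated as i.i.d. samples.
#' @param order_samples maximum number of samples used by the
#'   exogeneity-scoring sweep of the order search (default 1024, evenly
#'   spaced); the pairwise statistic is well saturated at this size while
#'   the sweep is quadratic in regions and linear in samples.  Connection
#'   coefficients are always estimated on the full series.
#' @return An `ec_estimate` with signed coefficients on the identified
#'   acyclic order (rows = targets).
#' @export
estimate_direct_lingam <- function(ts, order_samples = 1024) {
  stopifnot(inherits(ts, "region_ts"))
  p <- nrow(ts$values)
  n <- ncol(ts$values)
  if (n <= p) stop("DirectLiNGAM needs more samples than regions")
  x <- t(ts$values)                      # samples x regions
  x <- scale(x, center = TRUE, scale = FALSE)
  score_rows <- if (n > order_samples) {
    unique(round(seq(1L, n, length.out = order_samples)))
  } else {
    seq_len(n)
  }
  order_idx <- integer(0)
  remaining <- seq_len(p)
  xc <- x
  while (length(remaining) > 1L) {
    xm <- xc[score_rows, remaining, drop = FALSE]
    sds <- apply(xm, 2, stats::sd)
    if (any(sds == 0)) {
      ## a residual collapsed to constant: treat it as maximally exogenous
      root_pos <- which(sds == 0)[1]
    } else {
      root_pos <- which.min(lingam_exogeneity_scores(xm))
    }
    root <- remaining[root_pos]
    order_idx <- c(order_idx, root)
    remaining <- remaining[-root_pos]
    ## regress the root out of the remaining variables (columns stay
    ## centered: residuals of centered variables are centered)
    v <- sum(xc[, root]^2)
    if (v > 0) {
      b <- crossprod(xc[, remaining, drop = FALSE], xc[, root]) / v
      xc[, remaining] <- xc[, remaining, drop = FALSE] -
        outer(xc[, root], as.vector(b))
    }
  }
  order_idx <- c(order_idx, remaining)
  ## coefficients: OLS of each variable on its causal predecessors
  w <- matrix(0, p, p)
  for (k in 2:p) {
    tgt <- order_idx[k]
    pred <- order_idx[seq_len(k - 1L)]
    fit <- stats::lm.fit(cbind(1, x[, pred, drop = FALSE]), x[, tgt])
    w[tgt, pred] <- fit$coefficients[-1]
  }
  w[!is.finite(w)] <- 0
  ec_estimate(zero_diag(w), ts$region_ids, "direct_lingam",
              list(causal_order = ts$region_ids[order_idx]))
}

## --- Skew graph -----------------------------------------------------------

#' Skewness-oriented partial-correlation graph
#'
#' Two-step estimator in the spirit of fast adjacency-plus-skewness search:
#' (1) adjacency: region pairs whose partial correlation given all other
#' regions exceeds `adjacency_threshold` in magnitude and is significant at
#' level `alpha`; (2) orientation: for each adjacent pair, the normalized
#' second moment E\[XY|cond\] / sqrt(E\[X^2|cond\] E\[Y^2|cond\]) of the
#' mean-centered pair is computed conditional on positivity of each member;
#' the member whose conditioning yields the larger conditional correlation
#' is taken as the source.  The stored weight is the signed full Pearson
#' correlation of the pair.
#'
#' Orientation exploits skewness of the joint distribution; for symmetric
#' (e.g. Gaussian) pairs the assigned direction is at chance while the
#' adjacency is still detected.
#'
#' @param ts a [region_ts()]; needs more samples than regions (the partial
#'   correlation is otherwise ill-posed -- use a smaller parcellation or a
#'   shrinkage estimate upstream).
#' @param adjacency_threshold minimum |partial correlation| (default 0.05).
#' @param alpha significance level of the partial-correlation t-test.
#' @return An `ec_estimate` with signed correlation weights.
#' @export
estimate_skew_graph <- function(ts, adjacency_threshold = 0.05,
                                alpha = 0.05) {
  stopifnot(inherits(ts, "region_ts"))
  p <- nrow(ts$values)
  n <- ncol(ts$values)
  if (n <= p + 2L) {
    stop("partial correlation ill-posed: more regions than samples ",
         "(use shrinkage or a smaller parcellation)")
  }
  x <- t(ts$values)
  x <- scale(x, center = TRUE, scale = FALSE)
  cv <- stats::cov(x)
  prec <- tryCatch(solve(cv), error = function(e) MASS::ginv(cv))
  dp <- sqrt(diag(prec))
  pcor <- -prec / outer(dp, dp)
  diag(pcor) <- 1
  df <- n - p
  w <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      pc <- pcor[i, j]
      tstat <- pc * sqrt(df / max(1 - pc^2, .Machine$double.eps))
      pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
      if (abs(pc) < adjacency_threshold || pval >= alpha) next
      xi <- x[, i]
      xj <- x[, j]
      ci <- cond_corr(xi, xj, xi > 0)
      cj <- cond_corr(xi, xj, xj > 0)
      r <- stats::cor(xi, xj)
      if (is.na(ci) || is.na(cj)) next
      if (ci >= cj) {
        w[j, i] <- r          # i is the source: i -> j
      } else {
        w[i, j] <- r          # j is the source: j -> i
      }
    }
  }
  ec_estimate(w, ts$region_ids, "skew_graph",
              list(adjacency_threshold = adjacency_threshold, alpha = alpha))
}

## Uncentered conditional correlation of already mean-centered signals:
## the left-right orientation statistic.  Centering within the conditioned
## subsample would discard exactly the skewness the rule exploits.
cond_corr <- function(x, y, keep) {
  if (sum(keep) < 3L) return(NA_real_)
  xk <- x[keep]
  yk <- y[keep]
  den <- sqrt(mean(xk^2) * mean(yk^2))
  if (den == 0) return(NA_real_)
  mean(xk * yk) / den
}
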