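## Dynamical-systems estimators: lag-1 vector autoregression with L2
## (ridge) regularization, and multivariate Granger causality built on the
## same lag-1 model.

## Internal: lag-1 design/response pair in samples x regions layout.
var_design <- function(ts) {
  x <- t(ts$values)                       # samples x regions
  n <- nrow(x)
  list(X = x[-n, , drop = FALSE], Y = x[-1, , drop = FALSE])
}

#' Ridge-regularized lag-1 vector autoregression
#'
#' Fits the model x(t+1) = A x(t) + e by the closed-form ridge solution of
#' the normal equations, A = (X'X + lambda I)^-1 X'Y transposed to the
#' rows-as-targets convention, and zeroes the diagonal (self-lags are not
#' connectivity).  Signs of the coefficients are preserved.
#'
#' @param ts a [region_ts()] with at least `regions + 2` timepoints.
#' @param lambda nonnegative ridge strength.  With `lambda = 0` a singular
#'   design raises an error advising `lambda > 0`.
#' @return An `ec_estimate`: list with `graph` ([weighted_digraph()],
#'   kind `"EC"`), `estimator_name`, `params`.
#' @examples
#' a <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2)
#' x <- matrix(0, 2, 500); x[, 1] <- rnorm(2)
#' for (t in 2:500) x[, t] <- a %*% x[, t - 1] + rnorm(2, sd = 0.1)
#' e <- estimate_var_l2(region_ts(x, c("A", "B"), 1), lambda = 0.01)
#' @export
estimate_var_l2 <- function(ts, lambda = 0.01) {
  stopifnot(inherits(ts, "region_ts"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a nonnegative scalar")
  }
  p <- nrow(ts$values)
  if (ncol(ts$values) < p + 2L) {
    stop("need at least regions + 2 timepoints for a lag-1 VAR")
  }
  d <- var_design(ts)
  xtx <- crossprod(d$X) + diag(lambda, p)
  if (lambda == 0 && rcond(xtx) < .Machine$double.eps * 100) {
    stop("singular lag-1 design with lambda = 0; use lambda > 0")
  }
  a <- solve(xtx, crossprod(d$X, d$Y))    # columns: target regions
  w <- zero_diag(t(a))                    # rows = targets
  ec_estimate(w, ts$region_ids, "var_l2", list(lambda = lambda, lag = 1))
}

#' Multivariate Granger causality (lag-1)
#'
#' For every ordered pair source j -> target i, compares a full lag-1 model
#' of the target (its own past plus the source's past) against a restricted
#' model containing only the target's own history.  The edge weight is the
#' F-statistic of the comparison where its p-value falls below `alpha`, and
#' zero otherwise.
#'
#' MVGC is provided for completeness but excluded from the integrated EC by
#' default (see [optimize_weights()] callers): its estimates are the least
#' robust to regional hemodynamic variation.
#'
#' @param ts a [region_ts()].
#' @param alpha significance level for retaining an edge (default 0.05).
#' @return An `ec_estimate` whose weights are thresholded F-statistics.
#' @export
estimate_mvgc <- function(ts, alpha = 0.05) {
  stopifnot(inherits(ts, "region_ts"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0,1)")
  }
  p <- nrow(ts$values)
  if (ncol(ts$values) < p + 2L) {
    stop("need at least regions + 2 timepoints for a lag-1 model")
  }
  d <- var_design(ts)
  n <- nrow(d$X)
  w <- matrix(0, p, p)
  for (i in seq_len(p)) {
    y <- d$Y[, i]
    xi <- d$X[, i]
    rss0 <- sum(stats::lm.fit(cbind(1, xi), y)$residuals^2)
    for (j in seq_len(p)[-i]) {
      fit1 <- stats::lm.fit(cbind(1, xi, d$X[, j]), y)
      rss1 <- sum(fit1$residuals^2)
      df2 <- n - 3L
      if (rss1 <= .Machine$double.eps * rss0 || df2 < 1L) {
        ## degenerate regression (e.g. duplicated signals): no evidence
        ## assignable to the source beyond numerical noise
        next
      }
      f <- (rss0 - rss1) / (rss1 / df2)
      pval <- stats::pf(f, 1, df2, lower.tail = FALSE)
      if (is.finite(f) && pval < alpha) w[i, j] <- f
    }
  }
  ec_estimate(w, ts$region_ids, "mvgc",
              list(alpha = alpha, lag = 1, excluded_from_iec = TRUE))
}
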