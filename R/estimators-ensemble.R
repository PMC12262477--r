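## Subsampling ensemble: stabilizes inherently binary graphical estimates
## by averaging signed edge indicators over random half-samples.

#' Subsampling ensemble of a graphical estimator
#'
#' Runs a graphical estimator on `count` random timepoint subsamples of
#' size ceiling(N/2), drawn without replacement, and averages the signed
#' adjacency indicators (+1 edge present with positive weight, -1 present
#' with negative weight, 0 absent).  The resulting weights lie in \[-1, 1\]
#' and are interpretable as signed empirical edge frequencies.
#'
#' Subsampling destroys temporal order, which is acceptable for the
#' targeted estimators (they treat samples as i.i.d.); dynamical estimators
#' such as the VAR always see the full ordered series and are not accepted
#' here (nor is Patel's tau, which is used without subsampling).
#'
#' @param ts a [region_ts()].
#' @param estimator `"lingam"`, `"skew"`, or a function `ts -> ec_estimate`
#'   (the latter mainly for testing).
#' @param count number of subsamples (default 100).
#' @param seed integer seed controlling the subsample draws.
#' @param ... passed on to the estimator.
#' @return An `ec_estimate` named `ensemble_<estimator>`.
#' @export
ensemble_subsample <- function(ts, estimator, count = 100, seed = 1, ...) {
  stopifnot(inherits(ts, "region_ts"))
  if (count < 1L) stop("count must be >= 1")
  fn <- if (is.function(estimator)) {
    estimator
  } else {
    switch(match.arg(estimator, c("lingam", "skew")),
           lingam = function(ts, ...) estimate_direct_lingam(ts, ...),
           skew   = function(ts, ...) estimate_skew_graph(ts, ...))
  }
  name <- if (is.function(estimator)) "custom" else estimator
  n <- ncol(ts$values)
  m <- ceiling(n / 2)
  p <- nrow(ts$values)
  acc <- matrix(0, p, p)
  failures <- character(0)
  ok <- 0L
  set.seed(seed)
  for (k in seq_len(count)) {
    idx <- sort(sample.int(n, m, replace = FALSE))
    sub <- region_ts(ts$values[, idx, drop = FALSE], ts$region_ids, ts$dt)
    est <- tryCatch(fn(sub, ...), error = function(e) e)
    if (inherits(est, "error")) {
      failures <- c(failures, conditionMessage(est))
      next
    }
    acc <- acc + sign(est$graph$weights)
    ok <- ok + 1L
  }
  if (length(failures) > 0.2 * count) {
    stop("estimator failed on ", length(failures), "/", count,
         " subsamples; first error: ", failures[1])
  }
  w <- if (ok > 0) acc / ok else acc
  ec_estimate(zero_diag(w), ts$region_ids, paste0("ensemble_", name),
              list(count = count, subsample_size = m, seed = seed,
                   n_failed = length(failures)))
}
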