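## ec_estimate: the common return type of every estimator, plus the plug-in
## entry point for EC matrices computed by external toolchains.

#' Construct an EC estimate
#'
#' Wraps a weight matrix (rows = targets, columns = sources) as the common
#' estimator return type.  The diagonal must be zero and all weights finite.
#'
#' @param weights square numeric matrix, or a [weighted_digraph()].
#' @param region_ids region labels (ignored when `weights` is a digraph).
#' @param estimator_name label identifying the producing algorithm.
#' @param params named list of hyperparameters used.
#' @return An object of class `ec_estimate` with fields `graph`,
#'   `estimator_name`, `params`.
#' @export
ec_estimate <- function(weights, region_ids = NULL, estimator_name,
                        params = list()) {
  g <- if (inherits(weights, "weighted_digraph")) {
    weighted_digraph(weights$weights, weights$region_ids, "EC", weights$meta)
  } else {
    weighted_digraph(weights, region_ids, "EC")
  }
  if (any(!is.finite(g$weights))) stop("EC estimate has non-finite weights")
  structure(list(graph = g, estimator_name = as.character(estimator_name),
                 params = params),
            class = "ec_estimate")
}

#' @export
print.ec_estimate <- function(x, ...) {
  cat(sprintf("<ec_estimate:%s> %d regions\n", x$estimator_name,
              length(x$graph$region_ids)))
  invisible(x)
}

#' Register an externally computed EC matrix
#'
#' Ingests an EC matrix produced outside the package (e.g. rDCM or a
#' Tetrad-family graphical algorithm) so it can participate in integration
#' alongside native estimates.
#'
#' @param path TSV matrix file in the package convention
#'   (rows = targets); set `transposed = TRUE` if the file stores the
#'   sources-as-rows convention, in which case it is transposed on load.
#' @param name estimator label to attach.
#' @param region_ids optional region label sequence of the current session;
#'   if given, the file must match it exactly.
#' @param transposed whether the file uses columns-as-targets.
#' @return An `ec_estimate`.
#' @export
register_external_ec <- function(path, name, region_ids = NULL,
                                 transposed = FALSE) {
  g <- read_matrix(path, kind = "EC")
  w <- if (isTRUE(transposed)) t(g$weights) else g$weights
  if (!is.null(region_ids)) {
    check_same_regions(g$region_ids, region_ids, "external EC and session")
  }
  ec_estimate(w, g$region_ids, name, list(source = path,
                                          transposed = isTRUE(transposed)))
}
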