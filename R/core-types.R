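## Core domain types: region_ts, weighted_digraph, module_partition.
## All constructors validate eagerly; downstream code can assume invariants.

DIGRAPH_KINDS <- c("EC", "SC", "ground_truth", "SLN", "FC", "system")

#' Region-by-time signal container
#'
#' Holds a regions x timepoints matrix of real-valued activations (e.g.
#' parcellated BOLD signals) together with its region labels and sampling
#' interval.  This is the input type consumed by every estimator and metric.
#'
#' @param values numeric matrix, regions in rows, timepoints in columns.
#' @param region_ids character vector of unique region labels, one per row.
#' @param dt sampling interval in seconds (positive scalar).
#' @return An object of class `region_ts` with fields `values`,
#'   `region_ids`, `dt`.
#' @examples
#' ts <- region_ts(matrix(rnorm(20), 2, 10), c("A", "B"), dt = 0.72)
#' dim(ts$values)
#' @export
region_ts <- function(values, region_ids = rownames(values), dt = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(region_ids)) {
    region_ids <- paste0("R", seq_len(nrow(values)))
  }
  region_ids <- as.character(region_ids)
  if (nrow(values) < 2L) {
    stop("region_ts requires >=2 regions, got ", nrow(values))
  }
  if (ncol(values) < 3L) {
    stop("region_ts requires >=3 timepoints, got ", ncol(values))
  }
  if (length(region_ids) != nrow(values)) {
    stop("length(region_ids) must equal nrow(values)")
  }
  if (anyDuplicated(region_ids)) {
    stop("region_ids must be unique")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("region_ts values must be finite with no missing entries")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive scalar (seconds)")
  }
  dimnames(values) <- list(region_ids, NULL)
  structure(list(values = values, region_ids = region_ids, dt = dt),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %d regions x %d timepoints, dt = %g s\n",
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' Weighted directed graph over labeled regions
#'
#' A square signed weight matrix with **rows = targets, columns = sources**:
#' `weights[i, j]` is the edge j -> i.  Carrier type for effective
#' connectivity (EC), structural connectivity (SC), planted ground truth and
#' tracer-style (SLN-like) matrices.
#'
#' @param weights square numeric matrix.
#' @param region_ids character labels, one per row/column, unique.
#' @param kind one of `"EC"`, `"SC"`, `"ground_truth"`, `"SLN"`, `"FC"`.
#'   For `EC` and `ground_truth` the diagonal must be zero (self-loops are
#'   undefined for effective connectivity).
#' @param meta optional named list of metadata (e.g. a planted hierarchy).
#' @return An object of class `weighted_digraph`.
#' @examples
#' g <- weighted_digraph(matrix(c(0, 1, -1, 0), 2, 2), c("A", "B"), "EC")
#' @export
weighted_digraph <- function(weights, region_ids = rownames(weights),
                             kind = "EC", meta = list()) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  kind <- match.arg(kind, DIGRAPH_KINDS)
  if (nrow(weights) != ncol(weights)) {
    stop("non-square weight matrix: ", nrow(weights), " x ", ncol(weights))
  }
  if (is.null(region_ids)) {
    region_ids <- paste0("R", seq_len(nrow(weights)))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != nrow(weights) || anyDuplicated(region_ids) ||
      any(!nzchar(region_ids))) {
    stop("region_ids must be unique non-empty labels matching the matrix size")
  }
  if (anyNA(weights) && kind != "SLN") {
    stop("weights must not contain missing values (NaN allowed only for SLN)")
  }
  if (kind %in% c("EC", "ground_truth") && any(diag(weights) != 0)) {
    stop("diagonal must be zero for kind=", kind)
  }
  dimnames(weights) <- list(region_ids, region_ids)
  structure(list(weights = weights, region_ids = region_ids, kind = kind,
                 meta = meta),
            class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  nz <- sum(x$weights != 0, na.rm = TRUE) - sum(diag(x$weights) != 0,
                                                na.rm = TRUE)
  cat(sprintf("<weighted_digraph:%s> %d regions, %d off-diagonal edges\n",
              x$kind, length(x$region_ids), nz))
  invisible(x)
}

#' Region-to-module partition
#'
#' Maps every region to exactly one module label; used to aggregate
#' signal-flow results over cortical modules or zones.
#'
#' @param assignment named character vector: `names()` are region ids,
#'   values are module labels.
#' @param module_order optional ordered vector of module labels; defaults to
#'   first-appearance order.  Must cover every assigned label.
#' @return An object of class `module_partition`.
#' @export
module_partition <- function(assignment, module_order = NULL) {
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be a named vector (names = region ids)")
  }
  if (anyDuplicated(names(assignment))) {
    stop("each region must be assigned to exactly one module")
  }
  if (is.null(module_order)) {
    module_order <- unique(unname(assignment))
  }
  module_order <- as.character(module_order)
  if (!setequal(module_order, unique(unname(assignment))) ||
      anyDuplicated(module_order)) {
    stop("module_order must cover exactly the assigned module labels")
  }
  structure(list(assignment = assignment, module_order = module_order),
            class = "module_partition")
}

## Fail-fast guard used by every cross-object operation: label sequences
## must be identical, not merely set-equal (silent reindexing is refused).
check_same_regions <- function(a_ids, b_ids, what = "objects") {
  if (length(a_ids) != length(b_ids) || !all(a_ids == b_ids)) {
    stop("region label sequences of the ", what,
         " differ; refusing to reindex silently")
  }
  invisible(TRUE)
}

## Off-diagonal entries of a square matrix as a vector (column-major).
offdiag <- function(m) m[row(m) != col(m)]

zero_diag <- function(m) {
  diag(m) <- 0
  m
}
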