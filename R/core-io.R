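## TSV I/O for matrices, time series and partitions.  TSV is the canonical
## interchange format: labeled, human-diffable, lossless to ~15 significant
## digits (full double round-trip within 1e-12 relative error).

#' Read a labeled square matrix from TSV
#'
#' Expects a header row and a leading label column carrying identical
#' ordered region labels; the body must be numeric and square.  For
#' `kind = "EC"` a nonzero diagonal is forced to zero with a warning
#' (self-influence is undefined for effective connectivity).
#'
#' @param path path to a tab-separated file.
#' @param kind matrix kind passed to [weighted_digraph()].
#' @return A [weighted_digraph()].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, kind = "EC") {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) != ncol(df)) {
    stop("non-square matrix body in ", path, ": ",
         nrow(df), " rows x ", ncol(df), " columns")
  }
  if (!all(rownames(df) == colnames(df))) {
    stop("row and column labels disagree in ", path)
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop("non-numeric cell(s) in matrix body of ", path)
  }
  if (kind %in% c("EC", "ground_truth") && any(diag(m) != 0, na.rm = TRUE)) {
    warning("nonzero diagonal in ", kind, " matrix ", path,
            "; forcing diagonal to zero")
    diag(m) <- 0
  }
  weighted_digraph(m, rownames(df), kind)
}

#' Write a labeled square matrix to TSV
#'
#' Inverse of [read_matrix()]: `read_matrix(write_matrix(g, f))` reproduces
#' weights to <= 1e-12 relative error and labels exactly.
#'
#' @param g a [weighted_digraph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(g, path) {
  stopifnot(inherits(g, "weighted_digraph"))
  m <- format(g$weights, digits = 17, trim = TRUE, scientific = NA)
  df <- data.frame(region = g$region_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("region", g$region_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region-by-time series from TSV
#'
#' Rows are regions with a leading label column; remaining columns are
#' timepoints.
#'
#' @param path path to a tab-separated file.
#' @param dt sampling interval in seconds.
#' @return A [region_ts()].
#' @export
read_timeseries <- function(path, dt = 1) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell(s) in time series ", path)
  if (anyNA(m)) stop("missing value(s) in time series ", path)
  region_ts(m, rownames(df), dt)
}

#' Write a region-by-time series to TSV
#'
#' @param ts a [region_ts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  m <- format(ts$values, digits = 17, trim = TRUE, scientific = NA)
  df <- data.frame(region = ts$region_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("region", paste0("t", seq_len(ncol(ts$values))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region-to-module partition table
#'
#' Two-column TSV (`region`, `module`); module order is first appearance.
#'
#' @param path path to a tab-separated file.
#' @return A [module_partition()].
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("partition table needs columns region, module")
  module_partition(stats::setNames(as.character(df[[2]]),
                                   as.character(df[[1]])))
}

#' Write a module partition table
#' @param p a [module_partition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "module_partition"))
  df <- data.frame(region = names(p$assignment),
                   module = unname(p$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Thin wrapper over `yaml::read_yaml()`; returns a plain named list.  The
#' configuration records the run seed and any estimator hyperparameters so
#' that an analysis can be replayed exactly.
#'
#' @param path path to a YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
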