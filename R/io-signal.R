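#' Per-probe signal tables
#'
#' A `signal_table` pairs an ordered probe list with a matrix of
#' log2(ChIP/input) values, one column per array. It is the peak
#' caller's input. Probe coordinates follow the BED convention (0-based
#' half-open), matching the on-disk format.
#'
#' @param probes data frame with columns `probe_id`, `scaffold`, `start`,
#'   `end` (0-based half-open).
#' @param values numeric matrix, one row per probe, named columns (one
#'   per array). No missing values allowed.
#' @return object of class `signal_table`: list with elements `probes`
#'   (sorted by scaffold then start) and `values` (rows permuted to
#'   match).
#' @export
signal_table <- function(probes, values) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "scaffold", "start", "end") %in% names(probes)))
  values <- as.matrix(values)
  if (is.null(colnames(values)) || any(!nzchar(colnames(values)))) {
    stop("signal value columns must be named by array", call. = FALSE)
  }
  if (nrow(values) != nrow(probes)) stop("one value row per probe required", call. = FALSE)
  if (any(!is.finite(values))) stop("missing or non-finite signal values", call. = FALSE)
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe_id: ", probes$probe_id[duplicated(probes$probe_id)][1], call. = FALSE)
  }
  validate_intervals0(probes$start, probes$end, what = "probe")
  ord <- order(probes$scaffold, probes$start, probes$end)
  probes <- probes[ord, c("probe_id", "scaffold", "start", "end"), drop = FALSE]
  rownames(probes) <- NULL
  structure(list(probes = probes, values = values[ord, , drop = FALSE]),
            class = "signal_table")
}

#' @export
print.signal_table <- function(x, ...) {
  cat("signal_table:", nrow(x$probes), "probes x", ncol(x$values), "array(s) [",
      paste(colnames(x$values), collapse = ", "), "]\n")
  invisible(x)
}

#' Array names of a signal table
#' @param x a `signal_table`.
#' @export
array_names <- function(x) colnames(x$values)

#' Read a probe-signal table
#'
#' Tab-delimited with header: `probe_id`, `scaffold`, `start`, `end`
#' (0-based half-open), then one named column of log2(ChIP/input) values
#' per array. Rows are sorted by genome position on read; duplicate
#' probe ids, ragged rows and missing values are rejected.
#'
#' @param path input TSV.
#' @return a [signal_table()].
#' @export
read_signal_table <- function(path) {
  if (!file.exists(path)) stop("signal table not found: ", path, call. = FALSE)
  nf <- unique(utils::count.fields(path, sep = "\t", quote = ""))
  if (length(nf) != 1L) stop("ragged signal table (rows differ in field count): ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "scaffold", "start", "end")
  if (!all(need %in% names(df)) || ncol(df) < 5L) {
    stop("signal table must have probe_id, scaffold, start, end + >=1 array column", call. = FALSE)
  }
  arrays <- setdiff(names(df), need)
  vals <- as.matrix(df[, arrays, drop = FALSE])
  storage.mode(vals) <- "double"
  signal_table(df[, need], vals)
}

#' Write a probe-signal table
#' @param x a `signal_table`.
#' @param path output TSV path.
#' @export
write_signal_table <- function(x, path) {
  stopifnot(inherits(x, "signal_table"))
  df <- cbind(x$probes, as.data.frame(x$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# probe midpoints (0-based, possibly half-integer)
probe_mid0 <- function(x) (x$probes$start + x$probes$end) / 2
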