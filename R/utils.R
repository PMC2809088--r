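# Shared validators and small helpers. Internal coordinates are GRanges
# (1-based closed); files use BED (0-based half-open). Conversions live in
# the I/O layer only.

# Validate a set of 0-based half-open intervals against a scaffold length.
validate_intervals0 <- function(start0, end0, scaffold_len = NULL, what = "interval") {
  if (any(start0 < 0)) stop(what, ": negative start coordinate", call. = FALSE)
  if (any(start0 >= end0)) stop(what, ": start >= end (half-open intervals must be non-empty)", call. = FALSE)
  if (!is.null(scaffold_len) && any(end0 > scaffold_len)) {
    stop(what, ": interval end beyond scaffold length", call. = FALSE)
  }
  invisible(TRUE)
}

# GRanges from BED-style (0-based half-open) coordinate columns.
granges0 <- function(scaffold, start0, end0, ..., seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start0 + 1L, end0), ...)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# BED-style start/end from a GRanges.
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Named scaffold lengths of a genome
#' @param genome a `genome` object.
#' @return integer vector of scaffold lengths named by scaffold.
#' @export
scaffold_lengths <- function(genome) {
  stopifnot(is(genome$sequences, "DNAStringSet"))
  setNames(Biostrings::width(genome$sequences), names(genome$sequences))
}
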