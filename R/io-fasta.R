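#' Read a (soft-masked) genome FASTA
#'
#' Reads scaffold sequences, records soft-masked (lowercase) runs as the
#' repeat mask, and returns uppercase sequences. An explicit BED mask can
#' be supplied in addition; the union of both masks applies, so a genome
#' can be masked either way (or both).
#'
#' @param path FASTA file. Lowercase bases are interpreted as soft-masked
#'   repeat sequence.
#' @param mask_bed optional BED3+ file of additional masked intervals
#'   (0-based half-open, as BED always is).
#' @return A `genome` object: a list with `sequences` (an uppercase
#'   [Biostrings::DNAStringSet]) and `mask` (a [GenomicRanges::GRanges] of
#'   masked intervals, sorted and reduced, with seqlengths set).
#' @export
read_fasta <- function(path, mask_bed = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(raw) && (is.null(names(raw)) || any(!nzchar(names(raw))))) {
    stop("malformed FASTA header (empty name) in ", path, call. = FALSE)
  }
  # first whitespace-delimited token of the header is the scaffold name
  names(raw) <- sub("\\s.*$", "", names(raw))
  chars <- as.character(raw)
  bad <- grepl("[^ACGTNacgtn]", chars)
  if (any(bad)) {
    stop("non-ACGTN character in FASTA record '", names(raw)[which(bad)[1]],
         "' of ", path, call. = FALSE)
  }
  masks <- lapply(chars, function(s) {
    m <- gregexpr("[acgtn]+", s)[[1]]
    if (m[1] == -1L) return(IRanges::IRanges())
    IRanges::IRanges(start = as.integer(m), width = attr(m, "match.length"))
  })
  lens <- setNames(nchar(chars), names(raw))
  mask <- GenomicRanges::GRanges(
    rep(names(raw), vapply(masks, length, 1L)),
    unlist(IRanges::IRangesList(masks), use.names = FALSE)
  )
  genome <- list(sequences = Biostrings::DNAStringSet(toupper(chars)), mask = mask)
  names(genome$sequences) <- names(raw)
  if (!is.null(mask_bed)) {
    extra <- read_bed(mask_bed)
    genome$mask <- c(genome$mask, GenomicRanges::granges(extra))
  }
  GenomeInfoDb::seqlevels(genome$mask) <- names(lens)
  GenomeInfoDb::seqlengths(genome$mask) <- lens
  genome$mask <- GenomicRanges::reduce(GenomicRanges::sort(genome$mask))
  class(genome) <- "genome"
  genome
}

#' Write a genome FASTA with the mask as lowercase
#'
#' Inverse of [read_fasta()]: masked intervals are written soft-masked so
#' a write/read round trip is the identity.
#'
#' @param genome a `genome` object from [read_fasta()] or [simulate_genome()].
#' @param path output FASTA path.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  chars <- as.character(genome$sequences)
  mask <- genome$mask
  for (nm in names(chars)) {
    m <- mask[GenomeInfoDb::seqnames(mask) == nm]
    if (!length(m)) next
    s <- strsplit(chars[[nm]], "")[[1]]
    idx <- unlist(mapply(seq.int, GenomicRanges::start(m), GenomicRanges::end(m),
                         SIMPLIFY = FALSE))
    s[idx] <- tolower(s[idx])
    chars[[nm]] <- paste0(s, collapse = "")
  }
  out <- Biostrings::BStringSet(chars)
  Biostrings::writeXStringSet(out, path, width = width)
  invisible(path)
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$sequences), "scaffold(s),",
      sum(Biostrings::width(x$sequences)), "bp,",
      sum(GenomicRanges::width(x$mask)), "bp masked\n")
  invisible(x)
}
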