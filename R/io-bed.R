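#' Read regions from a BED file
#'
#' BED3/BED5/BED6 reader. Column 4 (name) is mapped to the region
#' `source` tag and column 5 to `score`; missing columns give `source =
#' "other"` and `score = NA`.
#'
#' @param path BED file (0-based half-open, as BED always is).
#' @return [GenomicRanges::GRanges] with metadata columns `source`
#'   (character) and `score` (numeric).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  src <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name) else rep(NA_character_, length(gr))
  src[is.na(src) | src == "."] <- "other"
  score <- if (!is.null(mcols(gr)$score)) as.numeric(mcols(gr)$score) else rep(NA_real_, length(gr))
  mcols(gr) <- S4Vectors::DataFrame(source = src, score = score)
  gr
}

#' Write regions to a BED file
#'
#' Writes BED5: coordinates (0-based half-open), the `source` tag in
#' column 4 and `score` in column 5. Scores already inside `[0, 1000]`
#' are written untouched (so write/read round-trips are exact); scores
#' outside that range are min-max rescaled into it, as the BED score
#' column demands.
#'
#' @param regions [GenomicRanges::GRanges], optionally with `source` and
#'   `score` metadata columns. Regions must lie within their scaffolds
#'   when seqlengths are set.
#' @param path output file. An empty input writes an empty file.
#' @export
write_bed <- function(regions, path) {
  stopifnot(is(regions, "GRanges"))
  sl <- GenomeInfoDb::seqlengths(regions)
  if (length(sl) && !all(is.na(sl))) {
    lim <- sl[as.character(GenomeInfoDb::seqnames(regions))]
    if (any(!is.na(lim) & GenomicRanges::end(regions) > lim) ||
        any(GenomicRanges::start(regions) < 1L)) {
      stop("region outside scaffold bounds", call. = FALSE)
    }
  }
  if (!length(regions)) {
    file.create(path)
    return(invisible(path))
  }
  src <- mcols(regions)$source
  if (is.null(src)) src <- rep(".", length(regions))
  score <- mcols(regions)$score
  if (is.null(score)) score <- rep(0, length(regions))
  score[is.na(score)] <- 0
  if (any(score < 0) || any(score > 1000)) {
    rng <- range(score)
    score <- if (diff(rng) == 0) rep(0, length(score)) else (score - rng[1]) / diff(rng) * 1000
  }
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(regions)),
                   start = start0(regions), end = end0(regions),
                   name = as.character(src), score = score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
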