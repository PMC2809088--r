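#' Read gene models from GFF3 or BED12
#'
#' GFF3 coordinates (1-based closed) and BED12 coordinates (0-based
#' half-open) are both converted to the internal GRanges representation,
#' so the same gene encoded in either dialect yields the same model. For
#' GFF3, rows of type `gene` are used when present (otherwise all rows);
#' the `ID` attribute (or `Name`) becomes the gene id. For BED12 the name
#' column is the gene id and block structure is ignored (only the span
#' and strand matter for promoter work).
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"bed12"`.
#' @return [GenomicRanges::GRanges] with strand and a `gene_id` metadata
#'   column. The transcription start site is derived from strand: see
#'   [gene_tss()].
#' @export
read_genes <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("gene file not found: ", path, call. = FALSE)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(mcols(gr)$type) && any(mcols(gr)$type == "gene")) {
      gr <- gr[mcols(gr)$type == "gene"]
    }
    id <- mcols(gr)$ID
    if (is.null(id)) id <- mcols(gr)$Name
    if (is.null(id)) id <- paste0("gene_", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    id <- mcols(gr)$name
    if (is.null(id)) id <- paste0("gene_", seq_along(gr))
  }
  if (any(GenomicRanges::strand(gr) == "*")) {
    stop("gene record without strand (+/- required to place the TSS)", call. = FALSE)
  }
  mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(id))
  gr
}

#' Transcription start sites of gene models
#'
#' The TSS is the 5'-most transcribed base: the span start on the `+`
#' strand and the span end on the `-` strand.
#'
#' @param genes GRanges from [read_genes()].
#' @param base `"1"` for 1-based positions (GRanges convention) or `"0"`
#'   for 0-based (BED convention).
#' @return integer vector of TSS positions, named by gene id.
#' @export
gene_tss <- function(genes, base = c("1", "0")) {
  base <- match.arg(base)
  pos <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                GenomicRanges::start(genes), GenomicRanges::end(genes))
  if (base == "0") pos <- pos - 1L
  setNames(as.integer(pos), mcols(genes)$gene_id)
}

#' Read EST alignments from BED12
#'
#' Each BED12 record holds the aligned blocks of one EST on one scaffold;
#' an EST split across scaffolds appears as several records sharing a
#' name. Blocks are returned in genome coordinates.
#'
#' @param path BED12 file.
#' @return [GenomicRanges::GRanges] of aligned blocks with an `est_id`
#'   metadata column.
#' @export
read_ests <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!length(gr)) {
    out <- GenomicRanges::GRanges()
    mcols(out)$est_id <- character(0)
    return(out)
  }
  ids <- as.character(mcols(gr)$name)
  if (!is.null(mcols(gr)$blocks)) {
    bl <- mcols(gr)$blocks  # record-relative, 1-based
    abs_blocks <- IRanges::shift(bl, GenomicRanges::start(gr) - 1L)
    n <- lengths(abs_blocks)
    out <- GenomicRanges::GRanges(
      rep(as.character(GenomeInfoDb::seqnames(gr)), n),
      unlist(abs_blocks, use.names = FALSE)
    )
    mcols(out)$est_id <- rep(ids, n)
  } else {
    out <- GenomicRanges::granges(gr)
    mcols(out)$est_id <- ids
  }
  GenomicRanges::sort(out)
}
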