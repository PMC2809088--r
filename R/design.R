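#' Array design parameters
#'
#' @param extend bp added on each side of every seed region (default
#'   2 kb, the promoter-design convention).
#' @param probe_budget maximum probes manufacturable on one array
#'   (default 2.1 million, one high-density array).
#' @param background_scaffolds scaffold names whose complete tile path is
#'   included to measure genomic background signal.
#' @return list of class `design_params`.
#' @export
design_params <- function(extend = 2000L, probe_budget = 2100000L,
                          background_scaffolds = character(0)) {
  stopifnot(extend >= 0, probe_budget > 0)
  structure(list(extend = as.integer(extend),
                 probe_budget = as.integer(probe_budget),
                 background_scaffolds = background_scaffolds),
            class = "design_params")
}

.concat_tags <- function(tags, rev) {
  vapply(rev, function(i) paste(unique(unlist(strsplit(tags[i], ",", fixed = TRUE))),
                                collapse = ","), character(1))
}

#' Extend regions on both sides and merge overlaps
#'
#' Each region is widened by `extend` bp up- and downstream, clipped to
#' its scaffold, and overlapping or touching results are merged (source
#' tags of merged regions are concatenated). The result is sorted,
#' non-overlapping, and idempotent under re-merge.
#'
#' @param regions GRanges, optionally with a `source` tag column.
#' @param extend bp per side.
#' @param scaffold_lengths named integer vector; every region's scaffold
#'   must be present.
#' @return merged GRanges with a `source` column.
#' @export
extend_and_merge <- function(regions, extend = 2000L, scaffold_lengths) {
  sc <- as.character(GenomeInfoDb::seqnames(regions))
  unknown <- setdiff(unique(sc), names(scaffold_lengths))
  if (length(unknown)) {
    stop("region(s) on unknown scaffold: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!length(regions)) return(regions)
  src <- mcols(regions)$source
  if (is.null(src)) src <- rep("other", length(regions))
  gr <- GenomicRanges::GRanges(
    sc,
    IRanges::IRanges(pmax(1L, GenomicRanges::start(regions) - extend),
                     pmin(unname(scaffold_lengths[sc]),
                          GenomicRanges::end(regions) + extend))
  )
  GenomeInfoDb::seqlevels(gr) <- names(scaffold_lengths)
  GenomeInfoDb::seqlengths(gr) <- scaffold_lengths
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)  # revmap -> input indices
  mcols(red) <- S4Vectors::DataFrame(
    source = .concat_tags(src, as.list(mcols(red)$revmap))
  )
  red
}

#' Promoter regions around gene transcription start sites
#'
#' One region `[tss - extend, tss + extend)` per gene (BED coordinates),
#' clipped to the scaffold; strand determines which gene end is the TSS.
#'
#' @param genes GRanges from [read_genes()].
#' @param extend bp per side.
#' @param scaffold_lengths named integer vector for clipping.
#' @return GRanges with `source = "gene_tss"` and `gene_id`.
#' @export
tss_regions <- function(genes, extend = 2000L, scaffold_lengths) {
  tss1 <- gene_tss(genes, base = "1")
  sc <- as.character(GenomeInfoDb::seqnames(genes))
  gr <- GenomicRanges::GRanges(
    sc,
    IRanges::IRanges(pmax(1L, tss1 - extend),
                     pmin(unname(scaffold_lengths[sc]), tss1 + extend - 1L))
  )
  GenomeInfoDb::seqlevels(gr) <- names(scaffold_lengths)
  GenomeInfoDb::seqlengths(gr) <- scaffold_lengths
  mcols(gr) <- S4Vectors::DataFrame(source = "gene_tss",
                                    gene_id = mcols(genes)$gene_id)
  gr
}

#' Assemble a promoter tile-path design
#'
#' Merges already-extended peak regions, gene TSS regions and
#' (pre-computed) EST TSS regions into one non-overlapping region set,
#' adds the complete tile path of any background scaffolds, tiles the
#' regions with isothermal probes, removes multi-mapping probes, and
#' checks the probe budget. Exceeding the budget is an error carrying
#' the overshoot and a per-source probe breakdown — shrink the design by
#' calling peaks at more stringent thresholds rather than silently
#' trimming.
#'
#' @param peak_regions,gene_regions,est_regions GRanges (any may be
#'   empty/NULL); peak regions default to source tag `h3k4me3_peak`,
#'   EST regions to `est_tss`.
#' @param params a [design_params()].
#' @param genome a `genome` object (sequence for tiling, mask applied).
#' @param tiling a [tiling_params()].
#' @return object of class `array_design`: list with `regions`, `probes`,
#'   `n_probes`, `n_regions`, `median_region_len`, `per_source`.
#' @export
assemble_design <- function(peak_regions = NULL, gene_regions = NULL,
                            est_regions = NULL, params = design_params(),
                            genome, tiling = tiling_params()) {
  sl <- scaffold_lengths(genome)
  tag_default <- function(gr, tag) {
    if (is.null(gr) || !length(gr)) return(NULL)
    if (is.null(mcols(gr)$source)) src <- rep(tag, length(gr))
    else src <- ifelse(is.na(mcols(gr)$source) | mcols(gr)$source %in% c(".", "other"),
                       tag, mcols(gr)$source)
    out <- GenomicRanges::granges(gr)
    mcols(out) <- S4Vectors::DataFrame(source = src)
    out
  }
  parts <- list(tag_default(peak_regions, "h3k4me3_peak"),
                tag_default(gene_regions, "gene_tss"),
                tag_default(est_regions, "est_tss"))
  bg <- params$background_scaffolds
  if (length(bg)) {
    unknown <- setdiff(bg, names(sl))
    if (length(unknown)) stop("unknown background scaffold(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    bgr <- GenomicRanges::GRanges(bg, IRanges::IRanges(1L, unname(sl[bg])))
    mcols(bgr) <- S4Vectors::DataFrame(source = "background")
    parts <- c(parts, list(bgr))
  }
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) stop("nothing to design: all region sets empty", call. = FALSE)
  all_regions <- suppressWarnings(do.call(c, parts))
  regions <- extend_and_merge(all_regions, extend = 0L, scaffold_lengths = sl)
  probes <- tile_regions(genome, regions, tiling)
  if (!is.null(probes) && nrow(probes)) {
    probes <- filter_multimapping(probes, count_exact_matches(probes, genome))
  }
  n_probes <- if (is.null(probes)) 0L else nrow(probes)
  # per-source breakdown: a probe counts toward its region's (merged) tag
  per_source <- integer(0)
  if (n_probes) {
    pr <- granges0(probes$scaffold, probes$start, probes$end)
    hit <- GenomicRanges::findOverlaps(pr, regions, select = "first")
    per_source <- table(mcols(regions)$source[hit])
    per_source <- setNames(as.integer(per_source), names(per_source))
  }
  design <- structure(list(regions = regions, probes = probes,
                           n_probes = n_probes, n_regions = length(regions),
                           median_region_len = median(GenomicRanges::width(regions)),
                           per_source = per_source, params = params),
                      class = "array_design")
  if (n_probes > params$probe_budget) {
    stop(structure(class = c("budget_error", "error", "condition"),
                   list(message = sprintf(
                          "design exceeds probe budget: %d probes for budget %d (overshoot %d); per-source: %s",
                          n_probes, params$probe_budget, n_probes - params$probe_budget,
                          paste(names(per_source), per_source, sep = "=", collapse = ", ")),
                        call = NULL, design = design)))
  }
  design
}

#' @export
print.array_design <- function(x, ...) {
  cat("array_design:", x$n_regions, "regions,", x$n_probes, "probes,",
      "median region", x$median_region_len, "bp\n")
  invisible(x)
}

#' Check a design against its probe budget
#'
#' @param design an `array_design`.
#' @param params a [design_params()] (defaults to the design's own).
#' @return list with `pass`, `n_probes`, `budget`, `headroom` (negative
#'   = overshoot) and, on failure, a `suggestion` on how to shrink the
#'   design.
#' @export
check_budget <- function(design, params = design$params) {
  headroom <- params$probe_budget - design$n_probes
  out <- list(pass = headroom >= 0, n_probes = design$n_probes,
              budget = params$probe_budget, headroom = headroom)
  if (!out$pass) {
    out$suggestion <- paste("over budget by", -headroom, "probes;",
                            "raise the peak-calling thresholds (more stringent",
                            "FDR) or drop lowest-score peak-only regions")
  }
  out
}
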