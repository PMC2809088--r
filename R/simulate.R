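#' Simulation parameters
#'
#' The simulator emulates the statistical structure of a tile-path
#' ChIP-chip experiment on a draft genome: background log2 ratios near
#' zero, promoter-proximal enriched plateaus on a fraction of gene TSSs,
#' noisy replicate arrays with low biological variance, repeat-masked
#' sequence, and ESTs whose aligned blocks split across scaffold pairs.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_len_bp length of each scaffold, bp.
#' @param gc_fraction genome GC content (fraction).
#' @param mask_fraction approximate fraction of each scaffold that is
#'   repeat-masked.
#' @param n_genes genes placed per genome (uniform, both strands,
#'   non-overlapping, off the mask).
#' @param gene_width_bp gene span width, bp.
#' @param enriched_gene_fraction fraction of genes whose TSS carries an
#'   enriched plateau.
#' @param enrichment_mean mean log2 ratio inside enriched regions.
#' @param noise_sd per-probe biological noise sd, log2 units.
#' @param replicate_noise_sd extra per-replicate technical noise sd.
#' @param enriched_width_bp width of the enriched plateau centered on
#'   the TSS.
#' @param n_replicates number of replicate arrays.
#' @param n_split_est_pairs planted scaffold pairs joined by ESTs.
#' @param ests_per_pair ESTs supporting each planted pair.
#' @param seed mandatory RNG seed; the whole fixture is a deterministic
#'   function of it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_scaffolds = 4L, scaffold_len_bp = 100000L,
                       gc_fraction = 0.4, mask_fraction = 0.2,
                       n_genes = 40L, gene_width_bp = 2000L,
                       enriched_gene_fraction = 0.5,
                       enrichment_mean = 2.0, noise_sd = 0.5,
                       replicate_noise_sd = 0.25,
                       enriched_width_bp = 1000L, n_replicates = 2L,
                       n_split_est_pairs = 4L, ests_per_pair = 3L,
                       seed) {
  if (missing(seed)) stop("sim_params: seed is mandatory", call. = FALSE)
  stopifnot(gc_fraction >= 0, gc_fraction <= 1,
            mask_fraction >= 0, mask_fraction < 1,
            enriched_gene_fraction >= 0, enriched_gene_fraction <= 1,
            noise_sd > 0, replicate_noise_sd >= 0, n_replicates >= 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a masked genome with gene models
#'
#' Bases are i.i.d. at the requested GC content; the repeat mask is laid
#' down as random blocks to approximately `mask_fraction` coverage;
#' genes are placed uniformly on both strands, non-overlapping and clear
#' of the mask (bounded retries; placement failure is an error).
#'
#' @param params a [sim_params()].
#' @return list with `genome` (a `genome` object) and `genes` (GRanges
#'   with `gene_id`).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    L <- params$scaffold_len_bp
    scn <- sprintf("scaffold_%d", seq_len(params$n_scaffolds))
    base_p <- c(A = (1 - params$gc_fraction) / 2, C = params$gc_fraction / 2,
                G = params$gc_fraction / 2, T = (1 - params$gc_fraction) / 2)
    seqs <- vapply(scn, function(s) {
      paste0(sample(names(base_p), L, replace = TRUE, prob = base_p), collapse = "")
    }, character(1))
    mask_block <- 300L
    masks <- lapply(scn, function(s) {
      n_blk <- ceiling(params$mask_fraction * L / mask_block)
      if (n_blk == 0L) return(IRanges::IRanges())
      st <- sort(sample.int(L - mask_block, n_blk))
      IRanges::reduce(IRanges::IRanges(st, width = mask_block))
    })
    mask <- GenomicRanges::GRanges(rep(scn, vapply(masks, length, 1L)),
                                   unlist(IRanges::IRangesList(masks), use.names = FALSE))
    genome <- list(sequences = Biostrings::DNAStringSet(seqs), mask = mask)
    names(genome$sequences) <- scn
    GenomeInfoDb::seqlevels(genome$mask) <- scn
    GenomeInfoDb::seqlengths(genome$mask) <- setNames(rep(L, length(scn)), scn)
    class(genome) <- "genome"

    # genes may not overlap each other; their promoter window (TSS +/-
    # 500 bp) must be mask-free so the tiler can cover it (gene bodies
    # crossing repeats are normal and allowed)
    gw <- params$gene_width_bp
    placed <- GenomicRanges::GRanges()
    GenomeInfoDb::seqlevels(placed) <- scn
    for (g in seq_len(params$n_genes)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        sc <- sample(scn, 1L)
        s1 <- sample.int(L - gw, 1L)
        strand_g <- sample(c("+", "-"), 1L)
        cand <- GenomicRanges::GRanges(factor(sc, levels = scn),
                                       IRanges::IRanges(s1, width = gw),
                                       strand = strand_g)
        tss_pos <- if (strand_g == "+") s1 else s1 + gw - 1L
        prom <- GenomicRanges::GRanges(factor(sc, levels = scn),
                                       IRanges::IRanges(max(1L, tss_pos - 500L),
                                                        min(L, tss_pos + 500L)))
        if (!IRanges::overlapsAny(cand, placed, ignore.strand = TRUE) &&
            !IRanges::overlapsAny(prom, mask)) { ok <- TRUE; break }
      }
      if (!ok) stop("simulate_genome: could not place gene ", g,
                    " after 500 tries (mask too dense?)", call. = FALSE)
      placed <- c(placed, cand)
    }
    mcols(placed)$gene_id <- sprintf("gene_%03d", seq_along(placed))
    GenomeInfoDb::seqlengths(placed) <- setNames(rep(L, length(scn)), scn)
    list(genome = genome, genes = GenomicRanges::sort(placed))
  })
}

#' Simulate replicate probe signals with planted promoter enrichment
#'
#' A fraction of gene TSSs receives a flat enriched plateau of width
#' `enriched_width_bp` centered on the TSS. Each probe draws one
#' biological value — `N(0, noise_sd)` in background,
#' `N(enrichment_mean, noise_sd)` when its midpoint lies in a plateau —
#' and each replicate array adds independent `N(0, replicate_noise_sd)`.
#' Plateaus covering no probe are dropped from the truth with a warning.
#'
#' @param probes probe data frame from [tile_genome()] (or any data
#'   frame with `probe_id`, `scaffold`, `start`, `end`).
#' @param genes gene GRanges from [simulate_genome()].
#' @param params a [sim_params()].
#' @return list with `signal` (a [signal_table()], arrays `rep1..repN`)
#'   and `truth` (list: `enriched_regions` GRanges, `enriched_gene_ids`).
#' @export
simulate_signals <- function(probes, genes, params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed + 1L, {
    n_enr <- round(params$enriched_gene_fraction * length(genes))
    enr_idx <- if (n_enr > 0L) sort(sample.int(length(genes), n_enr)) else integer(0)
    tss0 <- gene_tss(genes, base = "0")
    half <- params$enriched_width_bp %/% 2L
    sl <- GenomeInfoDb::seqlengths(genes)
    regions <- GenomicRanges::GRanges()
    if (length(enr_idx)) {
      sc <- as.character(GenomeInfoDb::seqnames(genes))[enr_idx]
      s1 <- pmax(1L, tss0[enr_idx] - half + 1L)
      e1 <- tss0[enr_idx] + half
      if (length(sl) && !all(is.na(sl))) e1 <- pmin(unname(sl[sc]), e1)
      regions <- GenomicRanges::GRanges(sc, IRanges::IRanges(s1, e1))
      mcols(regions) <- S4Vectors::DataFrame(
        source = "h3k4me3_peak", gene_id = mcols(genes)$gene_id[enr_idx])
    }
    mid0 <- (probes$start + probes$end) / 2
    pgr <- GenomicRanges::GRanges(probes$scaffold,
                                  IRanges::IRanges(floor(mid0) + 1L, width = 1L))
    inside <- IRanges::overlapsAny(pgr, regions)
    covered <- IRanges::overlapsAny(regions, pgr)
    if (any(!covered)) {
      warning(sum(!covered), " enriched region(s) contain no probe; dropped from truth")
      keep_genes <- mcols(regions)$gene_id[covered]
      regions <- regions[covered]
    } else keep_genes <- mcols(regions)$gene_id
    n <- nrow(probes)
    base <- rnorm(n, mean = ifelse(inside, params$enrichment_mean, 0),
                  sd = params$noise_sd)
    vals <- vapply(seq_len(params$n_replicates), function(r) {
      base + rnorm(n, 0, params$replicate_noise_sd)
    }, numeric(n))
    colnames(vals) <- sprintf("rep%d", seq_len(params$n_replicates))
    list(signal = signal_table(probes[, c("probe_id", "scaffold", "start", "end")], vals),
         truth = list(enriched_regions = regions,
                      enriched_gene_ids = as.character(keep_genes)))
  })
}

#' Simulate ESTs split across scaffold pairs
#'
#' For each planted pair, `ests_per_pair` ESTs carry a 5' block adjacent
#' to an enriched gene TSS on one scaffold and a second block on a
#' partner scaffold. Decoy ESTs aligned to one or three scaffolds — and
#' decoy two-scaffold ESTs far from any enriched region — are added so
#' the linkage filter has something to reject.
#'
#' @param genes gene GRanges.
#' @param truth the `truth` element of [simulate_signals()] (supplies
#'   enriched gene ids and regions).
#' @param scaffold_lens named integer vector of scaffold lengths.
#' @param params a [sim_params()].
#' @return list with `ests` (block GRanges with `est_id`, as
#'   [read_ests()] returns) and `planted_links` (data frame `scaffold_a`,
#'   `scaffold_b`, `gene_id`, `est_ids`).
#' @export
simulate_split_ests <- function(genes, truth, scaffold_lens, params) {
  stopifnot(inherits(params, "sim_params"), length(scaffold_lens) >= 2L)
  with_seed(params$seed + 2L, {
    scn <- names(scaffold_lens)
    enr <- genes[mcols(genes)$gene_id %in% truth$enriched_gene_ids]
    n_pairs <- min(params$n_split_est_pairs, length(enr))
    tss0 <- gene_tss(enr, base = "0")
    blocks <- list(); est_ids <- character(0)
    links <- list()
    used_pairs <- character(0)
    avoid <- GenomicRanges::trim(suppressWarnings(truth$enriched_regions + 1500L))
    rand_block <- function(sc, width = 400L) {
      for (try in seq_len(100L)) {
        s1 <- sample.int(scaffold_lens[[sc]] - width, 1L)
        cand <- GenomicRanges::GRanges(factor(sc, levels = scn),
                                       IRanges::IRanges(s1, width = width))
        if (!length(avoid) || !IRanges::overlapsAny(cand, avoid)) return(cand)
      }
      stop("simulate_split_ests: no decoy placement found", call. = FALSE)
    }
    add_block <- function(id, gr) {
      blocks[[length(blocks) + 1L]] <<- gr
      est_ids <<- c(est_ids, rep(id, length(gr)))
    }
    for (i in seq_len(n_pairs)) {
      sc_a <- as.character(GenomeInfoDb::seqnames(enr))[i]
      partners <- setdiff(scn, sc_a)
      sc_b <- NULL
      for (p in sample(partners)) {
        if (!paste(sort(c(sc_a, p)), collapse = "|") %in% used_pairs) { sc_b <- p; break }
      }
      if (is.null(sc_b)) next
      used_pairs <- c(used_pairs, paste(sort(c(sc_a, sc_b)), collapse = "|"))
      ids <- sprintf("est_pair%d_%d", i, seq_len(params$ests_per_pair))
      for (j in seq_along(ids)) {
        s1 <- max(1L, tss0[i] - 100L - 20L * j)
        b5 <- GenomicRanges::GRanges(factor(sc_a, levels = scn),
                                     IRanges::IRanges(s1, width = 300L))
        add_block(ids[j], b5)
        add_block(ids[j], rand_block(sc_b))
      }
      links[[length(links) + 1L]] <- data.frame(
        scaffold_a = sort(c(sc_a, sc_b))[1], scaffold_b = sort(c(sc_a, sc_b))[2],
        gene_id = mcols(enr)$gene_id[i],
        est_ids = paste(sort(ids), collapse = ","), stringsAsFactors = FALSE)
    }
    # decoys: single-scaffold, three-scaffold, and peak-free two-scaffold ESTs
    for (d in seq_len(3L)) add_block(sprintf("est_single%d", d), rand_block(sample(scn, 1L)))
    if (length(scn) >= 3L) {
      for (d in seq_len(2L)) {
        id <- sprintf("est_triple%d", d)
        for (sc in sample(scn, 3L)) add_block(id, rand_block(sc))
      }
    }
    for (d in seq_len(2L)) {
      id <- sprintf("est_far%d", d)
      for (sc in sample(scn, 2L)) add_block(id, rand_block(sc))
    }
    ests <- do.call(c, blocks)
    mcols(ests)$est_id <- est_ids
    list(ests = GenomicRanges::sort(ests),
         planted_links = if (length(links)) do.call(rbind, links) else
           data.frame(scaffold_a = character(0), scaffold_b = character(0),
                      gene_id = character(0), est_ids = character(0)))
  })
}
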