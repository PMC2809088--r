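#' Associate peaks with nearby genes
#'
#' A gene is associated with a peak when the gap between the peak
#' interval and the gene — anchored either at the TSS (a single base)
#' or at the full gene span — is at most `max_dist` bp (inclusive;
#' distance 0 when overlapping). Both anchorings appear in promoter
#' reporting with different denominators, hence the flag.
#'
#' @param peaks peak GRanges.
#' @param genes gene GRanges from [read_genes()].
#' @param max_dist association cutoff, bp (inclusive).
#' @param anchor `"tss"` (distance to the TSS base) or `"gene"`
#'   (distance to the whole gene interval).
#' @return data frame, one row per peak: `peak_id`
#'   (`scaffold:start-end`, BED coordinates), `n_genes`, `gene_ids`
#'   (comma-separated, nearest first), `min_distance` (NA when no gene
#'   qualifies).
#' @export
associate_peaks <- function(peaks, genes, max_dist = 1000L,
                            anchor = c("tss", "gene")) {
  anchor <- match.arg(anchor)
  target <- if (anchor == "tss") {
    tss1 <- gene_tss(genes, base = "1")
    GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(genes)),
                           IRanges::IRanges(tss1, width = 1L))
  } else GenomicRanges::granges(genes)
  p <- GenomicRanges::granges(peaks)
  GenomicRanges::strand(target) <- "*"
  hits <- GenomicRanges::findOverlaps(p, target, maxgap = max_dist,
                                      ignore.strand = TRUE)
  d <- GenomicRanges::distance(p[queryHits(hits)], target[subjectHits(hits)],
                               ignore.strand = TRUE)
  out <- data.frame(
    peak_id = sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(p)),
                      start0(p), end0(p)),
    n_genes = rep(0L, length(p)), gene_ids = rep("", length(p)),
    min_distance = rep(NA_integer_, length(p)),
    stringsAsFactors = FALSE
  )
  if (length(hits)) {
    ids <- mcols(genes)$gene_id
    sp <- split(data.frame(g = ids[subjectHits(hits)], d = d), queryHits(hits))
    for (q in names(sp)) {
      i <- as.integer(q)
      rec <- sp[[q]][order(sp[[q]]$d), ]
      out$n_genes[i] <- nrow(rec)
      out$gene_ids[i] <- paste(rec$g, collapse = ",")
      out$min_distance[i] <- rec$d[1]
    }
  }
  out
}

#' Fraction of peaks with a nearby gene
#'
#' @param associations output of [associate_peaks()].
#' @return the fraction, with attributes `n_associated` and `n_peaks`
#'   carrying the exact counts.
#' @export
fraction_near_genes <- function(associations) {
  n <- nrow(associations)
  if (n == 0L) stop("fraction undefined: zero peaks", call. = FALSE)
  k <- sum(associations$n_genes > 0L)
  structure(k / n, n_associated = k, n_peaks = n)
}

#' Fraction of one peak set overlapped by another
#'
#' A peak of `peaks_a` counts as detected in `peaks_b` when it shares at
#' least `min_overlap` bp with the union of `peaks_b`.
#'
#' @param peaks_a,peaks_b GRanges.
#' @param min_overlap minimum shared bp (default 1).
#' @return list with `fraction`, `n_overlapping`, `n_total`.
#' @export
overlap_fraction <- function(peaks_a, peaks_b, min_overlap = 1L) {
  hit <- IRanges::overlapsAny(peaks_a, GenomicRanges::reduce(peaks_b),
                              minoverlap = min_overlap)
  list(fraction = if (length(peaks_a)) mean(hit) else NA_real_,
       n_overlapping = sum(hit), n_total = length(peaks_a))
}

#' Permutation test for peak-set overlap
#'
#' The observed count of `peaks_a` overlapping `peaks_b` (>= 1 bp) is
#' compared with counts obtained after placing each `peaks_a` interval
#' uniformly at random within its own scaffold (lengths preserved, no
#' non-overlap constraint), conditioning on the observed peak-length and
#' scaffold distribution. `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param peaks_a,peaks_b GRanges.
#' @param scaffold_lengths named integer vector covering `peaks_a`
#'   scaffolds.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `p_value`, `observed`, `perm_counts`.
#' @export
overlap_significance <- function(peaks_a, peaks_b, scaffold_lengths,
                                 n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  b <- GenomicRanges::reduce(GenomicRanges::granges(peaks_b))
  obs <- sum(IRanges::overlapsAny(peaks_a, b))
  sc <- as.character(GenomeInfoDb::seqnames(peaks_a))
  w <- GenomicRanges::width(peaks_a)
  maxs <- unname(scaffold_lengths[sc]) - w + 1L
  if (any(is.na(maxs)) || any(maxs < 1L)) {
    stop("peaks_a wider than (or on scaffolds missing from) scaffold_lengths",
         call. = FALSE)
  }
  # all permutations drawn at once; one overlap query per batch
  perm_counts <- with_seed(seed, {
    n <- length(w)
    counts <- numeric(n_perm)
    batch <- max(1L, min(n_perm, 50000L %/% max(1L, n)))
    done <- 0L
    while (done < n_perm) {
      k <- min(batch, n_perm - done)
      s1 <- 1L + floor(runif(n * k) * rep(maxs, k))
      gr <- GenomicRanges::GRanges(rep(sc, k), IRanges::IRanges(s1, width = rep(w, k)))
      hit <- IRanges::overlapsAny(gr, b)
      counts[done + seq_len(k)] <- rowsum(as.numeric(hit), rep(seq_len(k), each = n))
      done <- done + k
    }
    counts
  })
  list(p_value = (1 + sum(perm_counts >= obs)) / (1 + n_perm),
       observed = obs, perm_counts = perm_counts)
}

#' Mean probe signal per peak
#'
#' Arithmetic mean of the values of probes whose interval midpoint lies
#' inside the peak. Peaks containing no probe midpoint are returned as
#' `NA` with a warning so they can be excluded from downstream
#' correlation.
#'
#' @param peaks peak GRanges.
#' @param st a [signal_table()].
#' @param array array name.
#' @return numeric vector, one mean log2 ratio per peak (NA = no probe).
#' @export
per_peak_mean_signal <- function(peaks, st, array) {
  v <- .array_values(st, array)
  mid <- probe_mid0(st)
  sc <- st$probes$scaffold
  ps <- as.character(GenomeInfoDb::seqnames(peaks))
  p0 <- start0(peaks); p1 <- end0(peaks)
  out <- vapply(seq_along(peaks), function(i) {
    sel <- sc == ps[i] & mid >= p0[i] & mid < p1[i]
    if (!any(sel)) return(NA_real_)
    mean(v[sel])
  }, numeric(1))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " peak(s) contain no probe midpoint; returned NA")
  }
  out
}

#' Correlate two per-peak signal tracks
#'
#' @param values_a,values_b equal-length numeric vectors (length >= 3,
#'   finite; pairs with NA in either are dropped).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` (coefficient), `p` (two-sided p-value), `n`.
#' @export
correlate_tracks <- function(values_a, values_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(values_a) == length(values_b))
  ok <- is.finite(values_a) & is.finite(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(a, b, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Average signal profile around transcription start sites
#'
#' Probe values are assigned to bins by their midpoint's offset from the
#' gene's TSS (offsets negated on the minus strand so downstream of
#' transcription is always positive); per-gene bin means are averaged
#' across genes.
#'
#' @param st a [signal_table()].
#' @param array array name.
#' @param genes gene GRanges.
#' @param flank_bp half-width of the profile window (multiple of
#'   `bin_bp`).
#' @param bin_bp bin width.
#' @return data frame: `bin_mid` (bp offset of bin midpoint from TSS),
#'   `mean_signal`, `n_genes` contributing to the bin.
#' @export
tss_profile <- function(st, array, genes, flank_bp = 5000L, bin_bp = 250L) {
  stopifnot(flank_bp %% bin_bp == 0L)
  v <- .array_values(st, array)
  mid <- probe_mid0(st)
  sc <- st$probes$scaffold
  nb <- 2L * flank_bp / bin_bp
  tss0 <- gene_tss(genes, base = "0")
  gsc <- as.character(GenomeInfoDb::seqnames(genes))
  neg <- as.character(GenomicRanges::strand(genes)) == "-"
  sums <- counts <- matrix(0, nrow = length(genes), ncol = nb)
  for (g in seq_along(genes)) {
    off <- mid[sc == gsc[g]] - tss0[g]
    val <- v[sc == gsc[g]]
    if (neg[g]) off <- -off
    keep <- off >= -flank_bp & off < flank_bp
    if (!any(keep)) next
    bins <- floor((off[keep] + flank_bp) / bin_bp) + 1L
    sums[g, ] <- vapply(seq_len(nb), function(bb) sum(val[keep][bins == bb]), numeric(1))
    counts[g, ] <- tabulate(bins, nbins = nb)
  }
  gene_means <- sums / counts  # NaN where a gene has no probe in a bin
  data.frame(
    bin_mid = seq(-flank_bp + bin_bp / 2, flank_bp - bin_bp / 2, by = bin_bp),
    mean_signal = colMeans(gene_means, na.rm = TRUE),
    n_genes = colSums(counts > 0)
  )
}

#' Link orphan promoter scaffolds to gene-body scaffolds via ESTs
#'
#' In draft assemblies the 5' end (with its promoter peak) and the body
#' of one gene can sit on different scaffolds. ESTs are filtered on two
#' criteria: (1) aligned blocks on exactly two scaffolds; (2) a peak
#' within `max_dist` bp of one of the EST's blocks on at least one of
#' them. Unordered scaffold pairs supported by at least two passing ESTs
#' become links.
#'
#' @param ests block GRanges from [read_ests()] (metadata column
#'   `est_id`).
#' @param peaks peak GRanges.
#' @param max_dist bp, inclusive (0 = overlap).
#' @return data frame: `scaffold_a`, `scaffold_b` (lexicographic order),
#'   `n_ests`, `est_ids` (comma-separated), `peak_id`, `peak_side`
#'   (`"a"`/`"b"`, taken from the first supporting EST's nearest peak).
#' @export
link_orphan_scaffolds <- function(ests, peaks, max_dist = 1000L) {
  empty <- data.frame(scaffold_a = character(0), scaffold_b = character(0),
                      n_ests = integer(0), est_ids = character(0),
                      peak_id = character(0), peak_side = character(0),
                      stringsAsFactors = FALSE)
  if (!length(ests) || !length(peaks)) return(empty)
  pk <- GenomicRanges::granges(peaks)
  pid <- sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(pk)),
                 start0(pk), end0(pk))
  hits <- GenomicRanges::findOverlaps(ests, pk, maxgap = max_dist,
                                      ignore.strand = TRUE)
  near <- rep(NA_integer_, length(ests))   # nearest qualifying peak per block
  if (length(hits)) {
    d <- GenomicRanges::distance(ests[queryHits(hits)], pk[subjectHits(hits)],
                                 ignore.strand = TRUE)
    o <- order(queryHits(hits), d)
    first <- !duplicated(queryHits(hits)[o])
    near[queryHits(hits)[o][first]] <- subjectHits(hits)[o][first]
  }
  esc <- as.character(GenomeInfoDb::seqnames(ests))
  recs <- lapply(split(seq_along(ests), mcols(ests)$est_id), function(idx) {
    scs <- unique(esc[idx])
    if (length(scs) != 2L) return(NULL)                      # criterion 1
    pk_hit <- idx[!is.na(near[idx])]
    if (!length(pk_hit)) return(NULL)                        # criterion 2
    scs <- sort(scs)
    list(a = scs[1], b = scs[2],
         peak = near[pk_hit[1]],
         side = if (esc[pk_hit[1]] == scs[1]) "a" else "b")
  })
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs)) return(empty)
  key <- vapply(recs, function(r) paste(r$a, r$b, sep = "|"), character(1))
  groups <- split(names(recs), key)
  groups <- groups[vapply(groups, length, 1L) >= 2L]         # >= 2 ESTs per pair
  if (!length(groups)) return(empty)
  out <- do.call(rbind, lapply(names(groups), function(k) {
    ids <- sort(groups[[k]])
    r <- recs[[ids[1]]]
    data.frame(scaffold_a = r$a, scaffold_b = r$b, n_ests = length(ids),
               est_ids = paste(ids, collapse = ","),
               peak_id = pid[r$peak], peak_side = r$side,
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(out$n_ests >= 2L))  # invariant of the filter
  out[order(out$scaffold_a, out$scaffold_b), , drop = FALSE]
}
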