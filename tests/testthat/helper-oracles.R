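# Fixture builders and independent oracles. Oracles deliberately use
# naive enumeration / direct formulas, not the package's code paths.

# signal_table with evenly spaced 50 bp probes and given value matrix
make_signal <- function(values, scaffold = "s1", spacing = 100L, probe_len = 50L,
                        start0 = 0L) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("a", seq_len(ncol(values)))
  n <- nrow(values)
  st <- start0 + spacing * (seq_len(n) - 1L)
  signal_table(
    data.frame(probe_id = sprintf("%s:%d-%d", scaffold, st, st + probe_len),
               scaffold = scaffold, start = st, end = st + probe_len,
               stringsAsFactors = FALSE),
    values
  )
}

# brute force: enumerate every w-window, test it, union overlapping
# qualifying windows into peaks; returns BED-style data frame
oracle_sliding <- function(st, values, w, t, gap) {
  p <- st$probes
  n <- nrow(p)
  qual_win <- list()
  for (i in seq_len(max(0L, n - w + 1L))) {
    idx <- i:(i + w - 1L)
    if (length(unique(p$scaffold[idx])) != 1L) next
    if (any(diff(p$start[idx]) > gap)) next
    if (any(values[idx] < t)) next
    qual_win[[length(qual_win) + 1L]] <- c(i, i + w - 1L)
  }
  if (!length(qual_win)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0)))
  }
  m <- do.call(rbind, qual_win)
  m <- m[order(m[, 1]), , drop = FALSE]
  peaks <- list(m[1, ])
  for (r in seq_len(nrow(m))[-1]) {
    last <- peaks[[length(peaks)]]
    if (m[r, 1] <= last[2]) {  # windows share probes -> union
      peaks[[length(peaks)]] <- c(last[1], max(last[2], m[r, 2]))
    } else peaks[[length(peaks) + 1L]] <- m[r, ]
  }
  do.call(rbind, lapply(peaks, function(pk) {
    data.frame(scaffold = p$scaffold[pk[1]], start = p$start[pk[1]],
               end = p$end[pk[2]], n_probes = pk[2] - pk[1] + 1L,
               stringsAsFactors = FALSE)
  }))
}

peaks_to_df <- function(gr) {
  data.frame(scaffold = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             n_probes = S4Vectors::mcols(gr)$n_probes,
             stringsAsFactors = FALSE)
}

# Independent nearest-neighbor Tm: own copy of the unified parameter
# table, dimer counting instead of positional summation.
oracle_tm <- function(s, na_conc = 0.05, probe_conc = 2.5e-7) {
  H <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
         GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
         CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  S <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
         GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
         CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  s <- toupper(s)
  n <- nchar(s)
  dimers <- substring(s, 1:(n - 1), 2:n)
  cnt <- table(dimers)
  dh <- sum(H[names(cnt)] * as.integer(cnt))
  ds <- sum(S[names(cnt)] * as.integer(cnt))
  for (term in c(substr(s, 1, 1), substr(s, n, n))) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_conc)
  1000 * dh / (ds + 1.987 * log(probe_conc / 4)) - 273.15
}

random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# naive sliding string scan, both strands, palindromes counted once
oracle_match_count <- function(probe, scaffold_seqs) {
  hits <- function(pat) {
    sum(vapply(scaffold_seqs, function(g) {
      k <- nchar(pat); n <- nchar(g)
      if (n < k) return(0L)
      sum(vapply(1:(n - k + 1), function(i) substr(g, i, i + k - 1) == pat, logical(1)))
    }, numeric(1)))
  }
  rc <- revcomp_chr(probe)
  hits(probe) + if (rc == probe) 0L else hits(rc)
}

# random sorted non-overlapping regions on one scaffold
random_regions <- function(n, scaffold = "s1", max_pos = 100000L, width_range = c(100L, 2000L)) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s0 <- sort(sample.int(max_pos, n))
  GenomicRanges::GRanges(scaffold, IRanges::IRanges(s0 + 1L, width = w))
}

expect_same_ranges <- function(a, b) {
  expect_equal(as.character(GenomeInfoDb::seqnames(a)), as.character(GenomeInfoDb::seqnames(b)))
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_equal(GenomicRanges::end(a), GenomicRanges::end(b))
}
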