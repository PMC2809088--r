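mk_genes <- function(scaffold, tss0, strand = "+", width = 2000L) {
  strand <- rep(strand, length.out = length(tss0))
  start1 <- ifelse(strand == "+", tss0 + 1L, tss0 + 1L - width + 1L)
  g <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start1, width = width),
                              strand = strand)
  S4Vectors::mcols(g)$gene_id <- paste0("g", seq_along(g))
  g
}

test_that("peak-gene association respects the inclusive 1 kb boundary", {
  peak <- GenomicRanges::GRanges("s1", IRanges::IRanges(1001, 1500))  # [1000,1500)
  near <- mk_genes("s1", 2400L)   # gap 900
  far <- mk_genes("s1", 2501L)    # gap 1001
  at <- mk_genes("s1", 2500L)     # gap 1000, inclusive
  expect_equal(associate_peaks(peak, near)$n_genes, 1L)
  expect_equal(associate_peaks(peak, near)$min_distance, 900L)
  expect_equal(associate_peaks(peak, far)$n_genes, 0L)
  expect_equal(associate_peaks(peak, at)$n_genes, 1L)
})

test_that("association equals an all-pairs distance scan and is translation invariant", {
  set.seed(61)
  for (rep in 1:15) {
    peaks <- random_regions(10, max_pos = 50000L, width_range = c(200L, 800L))
    genes <- mk_genes("s1", sample(0:50000, 15))
    got <- associate_peaks(peaks, genes, 1000L, anchor = "tss")
    tssv <- gene_tss(genes, base = "0")
    for (i in seq_along(peaks)) {
      p0 <- GenomicRanges::start(peaks)[i] - 1L
      p1 <- GenomicRanges::end(peaks)[i]
      d <- ifelse(tssv < p0, p0 - tssv - 1L, ifelse(tssv >= p1, tssv - p1, 0L))
      expect_equal(got$n_genes[i], sum(d <= 1000L))
      if (any(d <= 1000L)) expect_equal(got$min_distance[i], min(d[d <= 1000L]))
    }
    shift_pk <- GenomicRanges::shift(peaks, 7000L)
    shift_gn <- GenomicRanges::shift(genes, 7000L)
    expect_equal(associate_peaks(shift_pk, shift_gn, 1000L)$n_genes, got$n_genes)
  }
})

test_that("the near-gene fraction carries exact counts", {
  set.seed(62)
  peaks <- GenomicRanges::GRanges("s1", IRanges::IRanges(seq(1, 91000, 10000), width = 500))
  genes <- mk_genes("s1", c(200L, 10300L, 20900L, 50100L))  # near peaks 1,2,3,6
  fr <- fraction_near_genes(associate_peaks(peaks, genes))
  expect_equal(as.numeric(fr), 4 / 10)
  expect_equal(attr(fr, "n_associated"), 4L)
  expect_equal(attr(fr, "n_peaks"), 10L)
  all_assoc <- associate_peaks(peaks, mk_genes("s1", GenomicRanges::start(peaks) + 9L))
  expect_equal(as.numeric(fraction_near_genes(all_assoc)), 1.0)
  expect_error(fraction_near_genes(associate_peaks(peaks[0], genes)), "zero peaks")
})

test_that("overlap fraction honors the half-open 1 bp boundary", {
  a <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 100))     # [0,100)
  b1 <- GenomicRanges::GRanges("s1", IRanges::IRanges(100, 200))  # [99,200): shares 1 bp
  b2 <- GenomicRanges::GRanges("s1", IRanges::IRanges(101, 200))  # [100,200): touches only
  expect_equal(overlap_fraction(a, b1)$fraction, 1.0)
  expect_equal(overlap_fraction(a, b2)$fraction, 0.0)
  expect_equal(overlap_fraction(a, a)$fraction, 1.0)
})

test_that("overlap fraction equals a quadratic intersection oracle", {
  set.seed(63)
  for (rep in 1:15) {
    a <- random_regions(sample(5:20, 1), max_pos = 30000L)
    b <- random_regions(sample(5:20, 1), max_pos = 30000L)
    got <- overlap_fraction(a, b)
    ov <- vapply(seq_along(a), function(i) {
      any(pmin(GenomicRanges::end(a)[i], GenomicRanges::end(b)) -
            pmax(GenomicRanges::start(a)[i], GenomicRanges::start(b)) + 1L >= 1L)
    }, logical(1))
    expect_equal(got$fraction, mean(ov))
    expect_equal(got$n_overlapping, sum(ov))
  }
})

test_that("the overlap permutation test behaves at the extremes", {
  set.seed(64)
  sl <- c(s1 = 1000000L, s2 = 1000000L)
  a <- suppressWarnings(c(random_regions(50, "s1", 990000L, c(300L, 600L)),
                          random_regions(50, "s2", 990000L, c(300L, 600L))))
  res <- overlap_significance(a, a, sl, n_perm = 199L, seed = 3)
  expect_equal(res$observed, 100L)
  expect_lt(res$p_value, 0.05)  # random placement cannot tie perfect overlap here
  empty <- GenomicRanges::GRanges()
  res0 <- overlap_significance(a, empty, sl, n_perm = 100L, seed = 3)
  expect_equal(res0$p_value, 1.0)
})

test_that("per-peak mean signal averages probes by midpoint, flagging empty peaks", {
  st <- make_signal(cbind(a1 = c(1, 2, 3, 9)))  # probes at [0,50), [100,150), ...
  peak <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 250))
  expect_equal(per_peak_mean_signal(peak, st, "a1"), 2.0)
  single <- GenomicRanges::GRanges("s1", IRanges::IRanges(301, 350))
  expect_equal(per_peak_mean_signal(single, st, "a1"), 9)
  off <- GenomicRanges::GRanges("s1", IRanges::IRanges(400, 450))
  expect_warning(v <- per_peak_mean_signal(off, st, "a1"), "no probe")
  expect_true(is.na(v))
})

test_that("per-peak means match a brute-force probe scan", {
  set.seed(65)
  st <- make_signal(cbind(a1 = rnorm(80)))
  peaks <- random_regions(12, max_pos = 7000L, width_range = c(100L, 1200L))
  got <- suppressWarnings(per_peak_mean_signal(peaks, st, "a1"))
  for (i in seq_along(peaks)) {
    mids <- (st$probes$start + st$probes$end) / 2
    sel <- mids >= GenomicRanges::start(peaks)[i] - 1L & mids < GenomicRanges::end(peaks)[i]
    if (any(sel)) expect_equal(got[i], mean(st$values[sel, 1])) else expect_true(is.na(got[i]))
  }
})

test_that("track correlation matches the closed-form coefficients", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_tracks(x, x, "pearson")$r, 1.0)
  y <- exp(x)
  expect_equal(correlate_tracks(x, y, "spearman")$r, 1.0)
  expect_lt(correlate_tracks(x, y, "pearson")$r, 1.0)
  expect_error(correlate_tracks(x, rep(1, 5)), "zero variance")
  set.seed(66)
  for (rep in 1:20) {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30)
    got <- correlate_tracks(a, b, "pearson")
    r_hand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(got$r, r_hand, tolerance = 1e-12)
    tstat <- r_hand * sqrt(28 / (1 - r_hand^2))
    expect_equal(got$p, 2 * stats::pt(-abs(tstat), 28), tolerance = 1e-10)
  }
})

test_that("TSS profiles are flat on constant signal and strand-oriented", {
  st <- make_signal(cbind(a1 = rep(1.5, 100)))
  genes <- mk_genes("s1", c(3000L, 6000L))
  prof <- tss_profile(st, "a1", genes, flank_bp = 2000L, bin_bp = 500L)
  expect_true(all(abs(prof$mean_signal - 1.5) < 1e-12))

  # enrichment only in [TSS, TSS+500) for a + and a - strand gene
  v <- rep(0, 200)
  st2 <- make_signal(cbind(a1 = v))
  tss_p <- 5000L; tss_m <- 15000L
  mids <- (st2$probes$start + st2$probes$end) / 2
  v[mids >= tss_p & mids < tss_p + 500] <- 3
  v[mids > tss_m - 500 & mids <= tss_m] <- 3   # downstream of a - strand TSS
  st2 <- make_signal(cbind(a1 = v))
  genes2 <- c(mk_genes("s1", tss_p, "+"), mk_genes("s1", tss_m, "-"))
  prof2 <- tss_profile(st2, "a1", genes2, flank_bp = 1000L, bin_bp = 250L)
  up <- prof2$mean_signal[prof2$bin_mid < 0]
  down <- prof2$mean_signal[prof2$bin_mid > 0 & prof2$bin_mid < 500]
  expect_true(all(down > 1))
  expect_true(all(up < 0.5))
})

test_that("TSS profile equals a per-gene binning oracle", {
  set.seed(67)
  st <- make_signal(cbind(a1 = rnorm(300)))
  genes <- mk_genes("s1", sample(2000:25000, 6), sample(c("+", "-"), 6, TRUE))
  flank <- 2000L; bin <- 500L
  got <- tss_profile(st, "a1", genes, flank, bin)
  nb <- 2L * flank / bin
  acc <- matrix(NA_real_, length(genes), nb)
  mids <- (st$probes$start + st$probes$end) / 2
  tssv <- gene_tss(genes, base = "0")
  for (g in seq_along(genes)) {
    off <- mids - tssv[g]
    if (as.character(GenomicRanges::strand(genes))[g] == "-") off <- -off
    for (bb in seq_len(nb)) {
      lo <- -flank + (bb - 1L) * bin
      sel <- off >= lo & off < lo + bin
      if (any(sel)) acc[g, bb] <- mean(st$values[sel, 1])
    }
  }
  expect_equal(got$mean_signal, colMeans(acc, na.rm = TRUE))
  expect_equal(got$n_genes, colSums(!is.na(acc)))
})

mk_est <- function(id, ...) {
  blocks <- list(...)
  gr <- do.call(c, lapply(blocks, function(b) {
    GenomicRanges::GRanges(b[[1]], IRanges::IRanges(as.integer(b[[2]]), as.integer(b[[3]])))
  }))
  S4Vectors::mcols(gr)$est_id <- id
  gr
}

test_that("orphan linkage applies the two-scaffold and >=2-EST rules", {
  peaks <- GenomicRanges::GRanges("s5", IRanges::IRanges(1001, 1500))
  ests <- suppressWarnings(c(
    mk_est("e1", list("s5", 1701, 2000), list("s9", 501, 900)),   # peak 200 bp away
    mk_est("e2", list("s5", 1801, 2100), list("s9", 3001, 3400)),
    mk_est("e3", list("s5", 1701, 2000), list("s9", 501, 900), list("s2", 1, 300)),
    mk_est("e4", list("s7", 1701, 2000), list("s9", 501, 900))    # no peak nearby
  ))
  links <- link_orphan_scaffolds(ests, peaks, 1000L)
  expect_equal(nrow(links), 1L)
  expect_equal(links$scaffold_a, "s5")
  expect_equal(links$scaffold_b, "s9")
  expect_equal(links$n_ests, 2L)
  expect_setequal(strsplit(links$est_ids, ",")[[1]], c("e1", "e2"))
  expect_equal(links$peak_side, "a")

  # one supporting EST is not enough
  links1 <- link_orphan_scaffolds(ests[S4Vectors::mcols(ests)$est_id == "e1"], peaks, 1000L)
  expect_equal(nrow(links1), 0L)
})

test_that("orphan linkage equals a brute-force filter-and-group oracle", {
  set.seed(68)
  scn <- paste0("sc", 1:6)
  for (rep in 1:10) {
    n_est <- 25
    ests <- suppressWarnings(do.call(c, lapply(seq_len(n_est), function(i) {
      k <- sample(1:3, 1)
      scs <- sample(scn, k)
      do.call(c, lapply(scs, function(sc) {
        s0 <- sample.int(20000L, 1)
        b <- GenomicRanges::GRanges(sc, IRanges::IRanges(s0, s0 + 299L))
        S4Vectors::mcols(b)$est_id <- paste0("e", i)
        b
      }))
    })))
    peaks <- suppressWarnings(do.call(c, lapply(sample(scn, 3), function(sc) {
      random_regions(3, sc, 20000L, c(200L, 600L))
    })))
    got <- link_orphan_scaffolds(ests, peaks, 1000L)
    # oracle
    esc <- as.character(GenomeInfoDb::seqnames(ests))
    psc <- as.character(GenomeInfoDb::seqnames(peaks))
    pass <- list()
    for (id in unique(S4Vectors::mcols(ests)$est_id)) {
      idx <- which(S4Vectors::mcols(ests)$est_id == id)
      scs <- unique(esc[idx])
      if (length(scs) != 2) next
      ok <- FALSE
      for (i in idx) {
        same <- which(psc == esc[i])
        for (j in same) {
          gap <- max(0L, max(GenomicRanges::start(peaks)[j] - GenomicRanges::end(ests)[i] - 1L,
                             GenomicRanges::start(ests)[i] - GenomicRanges::end(peaks)[j] - 1L))
          if (gap <= 1000L) ok <- TRUE
        }
      }
      if (ok) pass[[id]] <- paste(sort(scs), collapse = "|")
    }
    tab <- table(unlist(pass))
    want <- sort(names(tab[tab >= 2]))
    expect_equal(paste(got$scaffold_a, got$scaffold_b, sep = "|"), want)
  }
})
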