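#' Isothermal tiling parameters
#'
#' Defaults reproduce a standard high-density tile-path recipe: variable
#' probe length 50-75 bp chosen toward a common 76 degree C melting
#' temperature, one probe anchored every 100 bp (start-to-start) outside
#' repeat-masked sequence.
#'
#' @param min_len,max_len probe length bounds, bp.
#' @param target_tm target melting temperature, degrees C.
#' @param spacing anchor spacing, bp start-to-start.
#' @param na_conc,probe_conc salt and strand concentrations (molar)
#'   passed to [compute_tm()].
#' @return list of class `tiling_params`.
#' @export
tiling_params <- function(min_len = 50L, max_len = 75L, target_tm = 76,
                          spacing = 100L, na_conc = 0.05, probe_conc = 2.5e-7) {
  stopifnot(min_len <= max_len, spacing >= 1, min_len >= 8)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 target_tm = target_tm, spacing = as.integer(spacing),
                 na_conc = na_conc, probe_conc = probe_conc),
            class = "tiling_params")
}

# Tile one character sequence. `masked` is a logical vector (TRUE = do
# not cover); coordinates in the output are offset by `offset0` so the
# same core serves whole scaffolds and design sub-regions. At each
# fixed-grid anchor the candidate length minimizing |Tm - target| wins;
# ties go to the shorter probe; anchors with no mask-free candidate are
# skipped.
.tile_seq <- function(chars, masked, scaffold, params, offset0 = 0L) {
  L <- length(chars)
  empty <- data.frame(probe_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0), length = integer(0),
                      tm = numeric(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  if (L < params$min_len) return(empty)
  masked <- masked | chars == "N"
  dim_dh <- unname(.nn_dh[paste0(chars[-L], chars[-1])])
  dim_ds <- unname(.nn_ds[paste0(chars[-L], chars[-1])])
  im <- which(masked)
  salt <- 0.368 * log(params$na_conc)
  conc <- .gas_const * log(params$probe_conc / 4)
  anchors <- seq.int(1L, L, by = params$spacing)
  res <- vector("list", length(anchors))
  k <- 0L
  for (a in anchors) {
    lmax <- min(params$max_len, L - a + 1L)
    if (lmax < params$min_len) next
    # longest mask-free run starting at the anchor
    nxt <- im[findInterval(a - 0.5, im) + 1L]
    if (!is.na(nxt)) lmax <- min(lmax, nxt - a)
    if (lmax < params$min_len) next
    lens <- params$min_len:lmax
    cd_h <- cumsum(dim_dh[a:(a + lmax - 2L)])
    cd_s <- cumsum(dim_ds[a:(a + lmax - 2L)])
    dh <- (cd_h[lens - 1L] + .nn_init_dh[chars[a]]) + .nn_init_dh[chars[a + lens - 1L]]
    ds <- (cd_s[lens - 1L] + .nn_init_ds[chars[a]]) + .nn_init_ds[chars[a + lens - 1L]]
    tm <- 1000 * dh / (ds + salt * (lens - 1L) + conc) - 273.15
    best <- which.min(abs(tm - params$target_tm))  # first index = shortest on ties
    l <- lens[best]
    k <- k + 1L
    res[[k]] <- list(start = a - 1L + offset0, len = l, tm = unname(tm[best]),
                     seq = paste0(chars[a:(a + l - 1L)], collapse = ""))
  }
  if (k == 0L) return(empty)
  res <- res[seq_len(k)]
  start <- vapply(res, `[[`, integer(1), "start")
  len <- vapply(res, `[[`, integer(1), "len")
  data.frame(
    probe_id = sprintf("%s:%d-%d", scaffold, start, start + len),
    scaffold = scaffold, start = start, end = start + len, length = len,
    tm = vapply(res, `[[`, numeric(1), "tm"),
    sequence = vapply(res, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE
  )
}

.mask_logical <- function(genome, scaffold) {
  L <- Biostrings::width(genome$sequences)[match(scaffold, names(genome$sequences))]
  masked <- logical(L)
  m <- genome$mask[GenomeInfoDb::seqnames(genome$mask) == scaffold]
  for (i in seq_along(m)) masked[GenomicRanges::start(m)[i]:GenomicRanges::end(m)[i]] <- TRUE
  masked
}

#' Tile one scaffold with isothermal probes
#'
#' Candidate anchors sit on a fixed grid every `spacing` bp from the
#' scaffold start; at each anchor, probe lengths between `min_len` and
#' `max_len` are scored by [compute_tm()] and the length closest to the
#' target Tm is selected (ties: shorter probe). Anchors whose every
#' candidate would overlap the repeat mask (or run off the scaffold) are
#' skipped; emitted probes never intersect masked bases. Output is
#' deterministic, sorted, with probe ids `"<scaffold>:<start>-<end>"`
#' in BED (0-based half-open) coordinates.
#'
#' @param genome a `genome` from [read_fasta()] or [simulate_genome()].
#' @param scaffold scaffold name.
#' @param params a [tiling_params()].
#' @return data frame: `probe_id`, `scaffold`, `start`, `end` (0-based
#'   half-open), `length`, `tm`, `sequence`.
#' @export
tile_scaffold <- function(genome, scaffold, params = tiling_params()) {
  stopifnot(scaffold %in% names(genome$sequences))
  chars <- strsplit(as.character(genome$sequences[[scaffold]]), "", fixed = TRUE)[[1]]
  .tile_seq(chars, .mask_logical(genome, scaffold), scaffold, params)
}

#' Tile every scaffold of a genome
#' @inheritParams tile_scaffold
#' @return probe data frame as in [tile_scaffold()], all scaffolds.
#' @export
tile_genome <- function(genome, params = tiling_params()) {
  out <- lapply(names(genome$sequences), function(s) tile_scaffold(genome, s, params))
  do.call(rbind, out)
}

# Tile only within given regions (used by the array designer). Anchors
# restart at each region start; probes must fit inside the region.
tile_regions <- function(genome, regions, params = tiling_params()) {
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    sc <- as.character(GenomeInfoDb::seqnames(regions)[i])
    a <- GenomicRanges::start(regions)[i]
    b <- GenomicRanges::end(regions)[i]
    chars <- strsplit(as.character(Biostrings::subseq(genome$sequences[[sc]], a, b)),
                      "", fixed = TRUE)[[1]]
    masked <- .mask_logical(genome, sc)[a:b]
    out[[i]] <- .tile_seq(chars, masked, sc, params, offset0 = a - 1L)
  }
  probes <- do.call(rbind, out)
  if (is.null(probes)) return(NULL)
  probes[order(probes$scaffold, probes$start), , drop = FALSE]
}

#' Count exact genome matches of probe sequences
#'
#' Counts exact occurrences of each probe sequence, on either strand,
#' across all scaffolds. A probe tiled from the genome always counts at
#' least 1. Palindromic probes are counted once per site (forward and
#' reverse-complement hits at one site are the same duplex).
#'
#' @param sequences character vector of probe sequences, named by
#'   probe id (a probe data frame from [tile_scaffold()] is also
#'   accepted).
#' @param genome a `genome` object.
#' @return named integer vector of match counts.
#' @export
count_exact_matches <- function(sequences, genome) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$probe_id)
  }
  subj <- genome$sequences
  uniq <- unique(unname(sequences))
  cnt <- vapply(uniq, function(s) {
    p <- Biostrings::DNAString(s)
    rc <- Biostrings::reverseComplement(p)
    n <- sum(Biostrings::vcountPattern(p, subj))
    if (as.character(rc) != s) n <- n + sum(Biostrings::vcountPattern(rc, subj))
    as.integer(n)
  }, integer(1))
  setNames(cnt[match(unname(sequences), uniq)], names(sequences))
}

#' Drop probes that match the genome more than once
#'
#' Non-unique probes are removed before peak detection so that repeated
#' sequence cannot seed spurious enrichment. Order is preserved.
#'
#' @param x a probe data frame (with `probe_id`) or a [signal_table()].
#' @param match_counts named integer vector from [count_exact_matches()];
#'   every probe in `x` must have a count.
#' @return filtered object of the same type (`match_count` column added
#'   for probe data frames).
#' @export
filter_multimapping <- function(x, match_counts) {
  ids <- if (inherits(x, "signal_table")) x$probes$probe_id else x$probe_id
  cnt <- match_counts[ids]
  if (any(is.na(cnt))) {
    stop("no match count for probe(s): ",
         paste(head(ids[is.na(cnt)], 3), collapse = ", "), call. = FALSE)
  }
  keep <- cnt == 1L
  if (inherits(x, "signal_table")) {
    signal_table(x$probes[keep, , drop = FALSE], x$values[keep, , drop = FALSE])
  } else {
    out <- x[keep, , drop = FALSE]
    out$match_count <- unname(cnt[keep])
    rownames(out) <- NULL
    out
  }
}
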