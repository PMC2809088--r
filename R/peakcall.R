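#' Peak-calling parameters
#'
#' Defaults follow the multi-window sliding-window scheme: windows of 3,
#' 4 and 5 consecutive probes (small/high peaks through broader/lower
#' ones), per-window log2-ratio thresholds calibrated against randomized
#' probes to a theoretical FDR below 10%, single-probe peaks removed, and
#' peaks within 1.5 kb merged.
#'
#' @param window_lengths integer vector of window sizes (consecutive
#'   probes), each >= 2.
#' @param thresholds optional named numeric vector (names = window
#'   lengths) of log2-ratio thresholds; left `NULL` when
#'   [calibrate_threshold()] will supply them.
#' @param fdr_target target theoretical FDR (randomized/real peak count
#'   ratio), in (0, 1).
#' @param threshold_grid strictly increasing candidate thresholds for
#'   calibration (log2 units).
#' @param max_probe_gap bp; consecutive probes whose starts lie further
#'   apart than this break a window (prevents windows spanning masked
#'   deserts).
#' @param merge_gap bp; peaks separated by at most this gap are merged.
#' @param min_probes_per_peak peaks with fewer probes are discarded.
#' @param rng_seed seed for the probe randomization.
#' @return list of class `peak_call_params`.
#' @export
peak_call_params <- function(window_lengths = c(3L, 4L, 5L), thresholds = NULL,
                             fdr_target = 0.10,
                             threshold_grid = seq(0.1, 4.0, by = 0.1),
                             max_probe_gap = 500L, merge_gap = 1500L,
                             min_probes_per_peak = 2L, rng_seed = 1L) {
  stopifnot(all(window_lengths >= 2L), fdr_target > 0, fdr_target < 1,
            all(diff(threshold_grid) > 0))
  structure(list(window_lengths = as.integer(window_lengths),
                 thresholds = thresholds, fdr_target = fdr_target,
                 threshold_grid = threshold_grid,
                 max_probe_gap = as.integer(max_probe_gap),
                 merge_gap = as.integer(merge_gap),
                 min_probes_per_peak = as.integer(min_probes_per_peak),
                 rng_seed = as.integer(rng_seed)),
            class = "peak_call_params")
}

.array_values <- function(st, array) {
  if (!array %in% colnames(st$values)) {
    stop("unknown array: ", array, " (have: ",
         paste(colnames(st$values), collapse = ", "), ")", call. = FALSE)
  }
  st$values[, array]
}

# Maximal runs of >= window_len consecutive probes (same scaffold,
# adjacent starts <= max_probe_gap apart) all at or above threshold.
# Returns first/last probe row index per run. Every qualifying sliding
# window lies inside exactly one such run, and the union of overlapping
# qualifying windows is the run itself.
.sw_runs <- function(st, values, window_len, threshold, max_probe_gap) {
  p <- st$probes
  n <- nrow(p)
  if (n == 0L) return(data.frame(i1 = integer(0), i2 = integer(0)))
  qual <- values >= threshold
  brk <- c(TRUE, p$scaffold[-1] != p$scaffold[-n] |
                 (p$start[-1] - p$start[-n]) > max_probe_gap)
  run_id <- cumsum(brk | c(TRUE, qual[-1] != qual[-n]))
  keep <- qual
  r <- rle(run_id[keep])
  if (!length(r$lengths)) return(data.frame(i1 = integer(0), i2 = integer(0)))
  idx <- which(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$lengths >= window_len
  data.frame(i1 = idx[starts[ok]], i2 = idx[ends[ok]])
}

.runs_to_peaks <- function(st, values, runs) {
  p <- st$probes
  if (!nrow(runs)) {
    gr <- GenomicRanges::GRanges()
    mcols(gr) <- S4Vectors::DataFrame(n_probes = integer(0),
                                      mean_signal = numeric(0),
                                      max_signal = numeric(0))
    return(gr)
  }
  stats <- t(mapply(function(i1, i2) {
    v <- values[i1:i2]
    c(mean(v), max(v))
  }, runs$i1, runs$i2))
  gr <- granges0(p$scaffold[runs$i1], p$start[runs$i1], p$end[runs$i2])
  mcols(gr) <- S4Vectors::DataFrame(n_probes = runs$i2 - runs$i1 + 1L,
                                    mean_signal = stats[, 1],
                                    max_signal = stats[, 2])
  gr
}

#' Sliding-window peak detection on one array
#'
#' A window of `window_len` consecutive probes qualifies when every probe
#' value is at or above `threshold` (probes on one scaffold with adjacent
#' starts at most `max_probe_gap` apart). Overlapping qualifying windows
#' are unioned, so each maximal qualifying run yields one peak spanning
#' its first probe start to its last probe end.
#'
#' @param st a [signal_table()].
#' @param array array (column) name.
#' @param window_len window size in probes (>= 2).
#' @param threshold log2-ratio threshold.
#' @param max_probe_gap bp gap between adjacent probe starts that breaks
#'   a window.
#' @return [GenomicRanges::GRanges] of peaks with `n_probes`,
#'   `mean_signal`, `max_signal`.
#' @export
sliding_window_detect <- function(st, array, window_len, threshold,
                                  max_probe_gap = 500L) {
  stopifnot(inherits(st, "signal_table"), window_len >= 2L)
  v <- .array_values(st, array)
  .runs_to_peaks(st, v, .sw_runs(st, v, window_len, threshold, max_probe_gap))
}

# merge runs whose bp intervals overlap or touch; merged index range is
# contiguous because a sub-threshold probe between two runs keeps their
# intervals apart
.merge_runs <- function(st, runs) {
  if (!nrow(runs)) return(runs)
  p <- st$probes
  o <- order(p$scaffold[runs$i1], p$start[runs$i1], p$end[runs$i2])
  runs <- runs[o, , drop = FALSE]
  sc <- p$scaffold[runs$i1]
  s0 <- p$start[runs$i1]
  e0 <- p$end[runs$i2]
  out_i1 <- integer(0); out_i2 <- integer(0)
  cur1 <- runs$i1[1]; cur2 <- runs$i2[1]; cur_sc <- sc[1]; cur_end <- e0[1]
  for (j in seq_len(nrow(runs))[-1]) {
    if (sc[j] == cur_sc && s0[j] <= cur_end) {
      cur1 <- min(cur1, runs$i1[j]); cur2 <- max(cur2, runs$i2[j])
      cur_end <- max(cur_end, e0[j])
    } else {
      out_i1 <- c(out_i1, cur1); out_i2 <- c(out_i2, cur2)
      cur1 <- runs$i1[j]; cur2 <- runs$i2[j]; cur_sc <- sc[j]; cur_end <- e0[j]
    }
  }
  data.frame(i1 = c(out_i1, cur1), i2 = c(out_i2, cur2))
}

#' Multi-window peak detection
#'
#' Runs [sliding_window_detect()] for every configured window length
#' (each with its own threshold), unions the detections, merges
#' overlapping peaks, and recomputes per-peak statistics from the
#' constituent probes. Small high peaks are caught by the short window,
#' broader lower peaks by the longer windows.
#'
#' @param st a [signal_table()].
#' @param array array name.
#' @param params a [peak_call_params()] with `thresholds` set for every
#'   window length (names = window lengths).
#' @return peaks as in [sliding_window_detect()].
#' @export
detect_multi_window <- function(st, array, params) {
  stopifnot(inherits(params, "peak_call_params"))
  th <- params$thresholds
  missing <- setdiff(as.character(params$window_lengths), names(th))
  if (length(missing)) {
    stop("no threshold configured for window length(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- .array_values(st, array)
  runs <- do.call(rbind, lapply(params$window_lengths, function(w) {
    .sw_runs(st, v, w, th[[as.character(w)]], params$max_probe_gap)
  }))
  .runs_to_peaks(st, v, .merge_runs(st, runs))
}

#' Randomize probe values of one array
#'
#' Permutes the named array's values uniformly at random across probe
#' positions (coordinates and all other arrays untouched). This is the
#' null model for threshold calibration: any peak structure surviving
#' randomization is positional coincidence.
#'
#' @param st a [signal_table()].
#' @param array array name.
#' @param seed RNG seed; a fixed seed reproduces the permutation.
#' @return a new [signal_table()].
#' @export
randomize_probes <- function(st, array, seed) {
  v <- .array_values(st, array)
  perm <- with_seed(seed, sample.int(length(v)))
  st$values[, array] <- v[perm]
  st
}

#' Calibrate a detection threshold against randomized probes
#'
#' Detection is run at increasing thresholds on both the real and the
#' (once-)randomized signals; the theoretical FDR at a threshold is the
#' randomized peak count divided by the real peak count. The smallest
#' grid threshold whose ratio falls below `fdr_target` is returned
#' together with the evaluated trace.
#'
#' @param st a [signal_table()].
#' @param array array name.
#' @param window_len window size in probes.
#' @param params a [peak_call_params()] (supplies grid, target,
#'   `max_probe_gap` and `rng_seed`).
#' @return list with `threshold`, `fdr_estimate`, and `trace` (data frame
#'   of threshold, n_real, n_random, ratio for every evaluated
#'   threshold).
#' @export
calibrate_threshold <- function(st, array, window_len, params = peak_call_params()) {
  grid <- params$threshold_grid
  if (!length(grid)) stop("empty threshold grid", call. = FALSE)
  v <- .array_values(st, array)
  vr <- .array_values(randomize_probes(st, array, params$rng_seed), array)
  trace <- data.frame(threshold = numeric(0), n_real = integer(0),
                      n_random = integer(0), ratio = numeric(0))
  for (t in grid) {
    n_real <- nrow(.sw_runs(st, v, window_len, t, params$max_probe_gap))
    n_rand <- nrow(.sw_runs(st, vr, window_len, t, params$max_probe_gap))
    ratio <- if (n_real > 0L) n_rand / n_real else NA_real_
    trace <- rbind(trace, data.frame(threshold = t, n_real = n_real,
                                     n_random = n_rand, ratio = ratio))
    if (n_real == 0L) {
      stop(sprintf(paste0("calibration failed: no real peaks left at threshold %g ",
                          "before reaching FDR target %g (best ratio %.3g)"),
                   t, params$fdr_target, suppressWarnings(min(trace$ratio, na.rm = TRUE))),
           call. = FALSE)
    }
    if (ratio < params$fdr_target) {
      return(list(threshold = t, fdr_estimate = ratio, trace = trace))
    }
  }
  stop(sprintf("calibration failed: no grid threshold reaches FDR target %g (best ratio %.3g)",
               params$fdr_target, min(trace$ratio, na.rm = TRUE)), call. = FALSE)
}

#' Remove peaks supported by a single probe
#'
#' @param peaks peak GRanges with an `n_probes` column.
#' @param min_probes minimum probes per peak to keep (default 2).
#' @return filtered peaks.
#' @export
remove_single_probe_peaks <- function(peaks, min_probes = 2L) {
  if (is.null(mcols(peaks)$n_probes)) stop("peaks lack n_probes", call. = FALSE)
  peaks[mcols(peaks)$n_probes >= min_probes]
}

#' Merge nearby peaks
#'
#' Adjacent peaks on one scaffold whose inter-interval gap is at most
#' `merge_gap` bp (inclusive) are merged transitively. Probe counts sum,
#' mean signal is recomputed probe-weighted, max signal is the maximum.
#'
#' @param peaks peak GRanges (sorted or not).
#' @param merge_gap bp, inclusive.
#' @return merged peaks, sorted.
#' @export
merge_peaks_within <- function(peaks, merge_gap = 1500L) {
  if (length(peaks) < 2L) return(peaks)
  peaks <- GenomicRanges::sort(peaks)
  # 1-based closed: gap between [.,e] and [s,.] is s - e - 1
  red <- GenomicRanges::reduce(peaks, min.gapwidth = merge_gap + 1L, with.revmap = TRUE)
  rev <- mcols(red)$revmap
  np <- mcols(peaks)$n_probes
  mn <- mcols(peaks)$mean_signal
  mx <- mcols(peaks)$max_signal
  mcols(red) <- S4Vectors::DataFrame(
    n_probes = vapply(rev, function(i) sum(np[i]), integer(1)),
    mean_signal = vapply(rev, function(i) sum(np[i] * mn[i]) / sum(np[i]), numeric(1)),
    max_signal = vapply(rev, function(i) max(mx[i]), numeric(1))
  )
  red
}

#' Replicate-consensus peak calling
#'
#' Averages probe values across the named replicate arrays, runs the
#' multi-window detection on the averaged track, removes single-probe
#' peaks and merges peaks within the merge gap — the full post-processing
#' chain of the sliding-window method.
#'
#' @param st a [signal_table()].
#' @param arrays character vector of array names to average (>= 1).
#' @param params a [peak_call_params()] with thresholds set.
#' @return peak GRanges.
#' @export
consensus_peaks <- function(st, arrays, params) {
  if (!length(arrays)) stop("no arrays named for consensus", call. = FALSE)
  for (a in arrays) .array_values(st, a)  # validates names
  cons <- rowMeans(st$values[, arrays, drop = FALSE])
  st2 <- signal_table(st$probes, matrix(cons, ncol = 1,
                                        dimnames = list(NULL, "consensus")))
  peaks <- detect_multi_window(st2, "consensus", params)
  peaks <- remove_single_probe_peaks(peaks, params$min_probes_per_peak)
  merge_peaks_within(peaks, params$merge_gap)
}
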