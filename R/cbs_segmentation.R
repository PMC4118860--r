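# Circular binary segmentation with permutation split p-values and the
# 2-SD breakpoint undo (merge) rule applied to delta profiles.

#' CBS parameters
#'
#' @param alpha_split permutation p-value required to accept a split
#'   (default 0.01).
#' @param n_perm_split permutations per split test (default 1000).
#' @param undo_sd undo a breakpoint whose flanking segment means differ by
#'   fewer than this many noise SDs (default 2).
#' @param min_width minimum probes on each side of a candidate arc
#'   (default 2).
#' @param seed RNG seed for the split permutations.
#' @return a `cbs_params` list.
#' @export
cbs_params <- function(alpha_split = 0.01, n_perm_split = 1000L, undo_sd = 2,
                       min_width = 2L, seed = 1L) {
  stopifnot(alpha_split > 0, alpha_split < 1, undo_sd >= 0, min_width >= 1,
            n_perm_split >= 10)
  structure(list(alpha_split = alpha_split,
                 n_perm_split = as.integer(n_perm_split),
                 undo_sd = undo_sd, min_width = as.integer(min_width),
                 seed = as.integer(seed)),
            class = "cbs_params")
}

#' Robust noise SD of a probe signal
#'
#' `1.4826 * median(|x[i+1] - x[i]|) / sqrt(2)`: the MAD of first differences
#' scaled to the SD of Gaussian noise. First differences straddle true
#' copy-number steps at only a handful of probes, so the estimate is robust
#' to real segment structure.
#'
#' @param values numeric probe signal (>= 3 values).
#' @return estimated per-probe noise SD (0 for a constant signal).
#' @export
estimate_noise_sd <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  1.4826 * median(abs(diff(values))) / sqrt(2)
}

# genomic tiling boundaries: midpoints between adjacent probes, extended by
# half the local spacing at chromosome ends (0-based half-open, clipped at 0)
tiling_bounds <- function(positions) {
  n <- length(positions)
  if (n == 1) return(c(max(0, positions - 1), positions + 1))
  mid <- floor((positions[-n] + positions[-1]) / 2)
  c(max(0, floor(positions[1] - (positions[2] - positions[1]) / 2)),
    mid,
    ceiling(positions[n] + (positions[n] - positions[n - 1]) / 2))
}

make_segments <- function(values, positions, breaks, chrom, sample_id) {
  # breaks: sorted 0-based probe-index cut points (excluding 0 and n)
  n <- length(values)
  edges <- c(0L, breaks, n)
  bounds <- tiling_bounds(positions)
  segs <- lapply(seq_len(length(edges) - 1L), function(k) {
    a <- edges[k] + 1L
    b <- edges[k + 1L]
    data.frame(sample_id = sample_id, chrom = chrom,
               start = bounds[a], end = bounds[b + 1L],
               n_probes = b - a + 1L, mean = mean(values[a:b]),
               start_idx = a - 1L, end_idx = b,
               stringsAsFactors = FALSE)
  })
  segment_set(do.call(rbind, segs))
}

#' Circular binary segmentation of one chromosome
#'
#' Recursively finds, on the circularized interval, the arc maximizing the
#' pooled-variance two-sample t-statistic between in-arc and out-of-arc
#' probes; the split is accepted if its permutation p-value (shuffling probe
#' values within the interval) is below `alpha_split`, and the resulting
#' sub-intervals are segmented recursively. Intervals shorter than
#' `2 * min_width` are returned unsplit. Equal maxima are broken towards the
#' smallest arc indices.
#'
#' @param values ordered probe log2 values of one chromosome.
#' @param positions probe midpoints (bp), strictly increasing.
#' @param p a [cbs_params()]. The caller controls the RNG state; set a seed
#'   for reproducible permutation p-values.
#' @param chrom,sample_id labels for the output rows.
#' @return a [segment_set()] tiling the chromosome (states unset).
#' @export
cbs_segment <- function(values, positions, p = cbs_params(),
                        chrom = "chr1", sample_id = "sample") {
  stopifnot(length(values) == length(positions), all(diff(positions) > 0))
  n <- length(values)
  breaks <- integer(0)
  split_interval <- function(lo, hi) {
    # lo, hi: 1-based inclusive probe range
    len <- hi - lo + 1L
    if (len < 2L * p$min_width) return(invisible(NULL))
    res <- .cbs_split_pvalue(values[lo:hi], p$min_width, p$n_perm_split,
                             p$alpha_split)
    if (res$i < 0 || res$p >= p$alpha_split) return(invisible(NULL))
    cuts <- unique(c(res$i, res$j))
    cuts <- cuts[cuts > 0 & cuts < len]
    if (!length(cuts)) return(invisible(NULL))
    abs_cuts <- lo - 1L + cuts
    breaks <<- sort(unique(c(breaks, abs_cuts)))
    edges <- c(lo - 1L, abs_cuts, hi)
    for (k in seq_len(length(edges) - 1L)) {
      split_interval(edges[k] + 1L, edges[k + 1L])
    }
    invisible(NULL)
  }
  split_interval(1L, n)
  make_segments(values, positions, breaks, chrom, sample_id)
}

#' SD-based breakpoint undo
#'
#' Iteratively removes the breakpoint whose flanking segment means are
#' closest, as long as that gap is below `undo_sd * noise_sd`; the two
#' adjacent segments are merged and their mean recomputed from the probes.
#' Removal proceeds smallest gap first until every remaining gap is at least
#' `undo_sd` noise SDs.
#'
#' @param segs a [segment_set()] for one chromosome, tiling `values`.
#' @param values the probe values the segments were fitted on.
#' @param undo_sd required separation in noise SDs (default 2).
#' @param noise_sd noise SD, typically [estimate_noise_sd()] of the whole
#'   profile. With `noise_sd = 0`, only breakpoints between segments with
#'   identical means are undone.
#' @return the merged [segment_set()].
#' @export
sd_undo <- function(segs, values, undo_sd = 2, noise_sd) {
  stopifnot(length(unique(segs$chrom)) <= 1)
  segs <- segs[order(segs$start), , drop = FALSE]
  if (sum(segs$n_probes) != length(values)) {
    stop("segments do not tile the values")
  }
  threshold <- undo_sd * noise_sd
  repeat {
    if (nrow(segs) < 2) break
    gaps <- abs(diff(segs$mean))
    k <- which.min(gaps)
    if (!(gaps[k] < threshold || (gaps[k] == 0 && undo_sd > 0))) break
    a <- segs[k, ]; b <- segs[k + 1, ]
    merged <- a
    merged$end <- b$end
    merged$end_idx <- b$end_idx
    merged$n_probes <- a$n_probes + b$n_probes
    merged$mean <- mean(values[(a$start_idx + 1):b$end_idx])
    segs <- rbind(segs[seq_len(k - 1), , drop = FALSE], merged,
                  segs[setdiff(seq_len(nrow(segs)), seq_len(k + 1)), ,
                       drop = FALSE])
  }
  rownames(segs) <- NULL
  class(segs) <- c("segment_set", "data.frame")
  segs
}

#' Segment a genome-wide profile chromosome by chromosome
#'
#' Runs [cbs_segment()] then [sd_undo()] per chromosome. The noise SD for the
#' undo rule is estimated once from the whole profile ([estimate_noise_sd()])
#' unless supplied. Each chromosome gets its own deterministic RNG stream
#' derived from `p$seed`, so segmentation is reproducible and insensitive to
#' which chromosomes are present.
#'
#' @param values genome-wide probe values aligned to `grid`.
#' @param grid a [probe_grid()].
#' @param p a [cbs_params()].
#' @param sample_id output label.
#' @param noise_sd optional noise SD override.
#' @return a [segment_set()] tiling every chromosome.
#' @export
segment_profile <- function(values, grid, p = cbs_params(),
                            sample_id = "sample", noise_sd = NULL) {
  stopifnot(length(values) == nrow(grid))
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(values)
  chroms <- grid_chroms(grid)
  parts <- lapply(seq_along(chroms), function(ci) {
    idx <- grid$chrom == chroms[ci]
    set.seed(child_seed(p$seed, ci))
    segs <- cbs_segment(values[idx], grid$pos[idx], p,
                        chrom = chroms[ci], sample_id = sample_id)
    sd_undo(segs, values[idx], p$undo_sd, noise_sd)
  })
  out <- do.call(rbind, parts)
  class(out) <- c("segment_set", "data.frame")
  out
}
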