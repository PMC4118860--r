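# Pairwise tumour/metastasis "delta profile" analysis: per-pair quantile
# normalization, subtraction, CBS segmentation with SD-undo, segment
# counting and thresholding, subtype comparison, and the search for
# recurrent overlapping delta segments across patients.

#' Delta-pipeline parameters
#'
#' @param abs_delta_threshold log2 cut-off for a delta segment to count as a
#'   real tumour/metastasis difference (default 0.2).
#' @param min_probes minimum probes for the filtered segment count
#'   (default 10).
#' @param state_threshold log2 cut-off for gain/loss calls in the individual
#'   normalized samples (default 0.2; gain above, loss below the negative).
#' @param overlap_abs_threshold |log2| cut-off for a delta segment to enter
#'   the recurrent-overlap search (default 0.1).
#' @param high_noise_multiplier pairs whose delta noise SD exceeds this
#'   multiple of the cohort median are flagged and excluded from group
#'   statistics (default 3).
#' @param cbs a [cbs_params()] for segmenting the delta profiles.
#' @return a `delta_params` list.
#' @export
delta_params <- function(abs_delta_threshold = 0.2, min_probes = 10L,
                         state_threshold = 0.2, overlap_abs_threshold = 0.1,
                         high_noise_multiplier = 3, cbs = cbs_params()) {
  stopifnot(abs_delta_threshold > 0, min_probes >= 1, state_threshold > 0,
            overlap_abs_threshold > 0, high_noise_multiplier >= 1)
  structure(list(abs_delta_threshold = abs_delta_threshold,
                 min_probes = as.integer(min_probes),
                 state_threshold = state_threshold,
                 overlap_abs_threshold = overlap_abs_threshold,
                 high_noise_multiplier = high_noise_multiplier,
                 cbs = cbs),
            class = "delta_params")
}

#' Two-sample quantile normalization
#'
#' Forces the two profiles onto an identical value distribution: the rank-k
#' value in each sample is replaced by the mean of the two samples' rank-k
#' values; ties receive the average of the replacement values over the tied
#' ranks.
#'
#' @param tumour,lnm numeric log2 vectors on the same grid, no missing values.
#' @return list with normalized `tumour` and `lnm` vectors.
#' @export
quantile_normalize_pair <- function(tumour, lnm) {
  if (length(tumour) != length(lnm)) stop("grid mismatch between the pair")
  stopifnot(all(is.finite(tumour)), all(is.finite(lnm)))
  m <- limma::normalizeQuantiles(cbind(tumour, lnm), ties = TRUE)
  list(tumour = m[, 1], lnm = m[, 2])
}

#' Delta values of a normalized pair
#'
#' @param tumour,lnm normalized log2 vectors (see [quantile_normalize_pair()]).
#' @return metastasis minus tumour, per probe.
#' @export
make_delta <- function(tumour, lnm) {
  if (length(tumour) != length(lnm)) stop("grid mismatch between the pair")
  lnm - tumour
}

#' Build a delta profile for one pair
#'
#' Quantile-normalizes the pair, subtracts tumour from metastasis and
#' estimates the delta noise SD.
#'
#' @param tumour,lnm raw log2 vectors aligned to `grid`.
#' @param grid a [probe_grid()].
#' @param patient_id label.
#' @return a `delta_profile`: normalized sample vectors, `delta`, `noise_sd`,
#'   `segments` (unset until [segment_delta()]).
#' @export
delta_profile <- function(tumour, lnm, grid, patient_id = "patient") {
  stopifnot(length(tumour) == nrow(grid))
  norm <- quantile_normalize_pair(tumour, lnm)
  delta <- make_delta(norm$tumour, norm$lnm)
  structure(list(patient_id = patient_id, grid = grid,
                 tumour = norm$tumour, lnm = norm$lnm, delta = delta,
                 noise_sd = estimate_noise_sd(delta), segments = NULL),
            class = "delta_profile")
}

# per-segment mean of a genome-wide vector over the segment's probes
segment_sample_means <- function(segs, values, grid) {
  chroms <- grid_chroms(grid)
  offsets <- setNames(cumsum(c(0, head(tabulate(factor(grid$chrom, chroms)),
                                       -1))), chroms)
  vapply(seq_len(nrow(segs)), function(k) {
    off <- offsets[[segs$chrom[k]]]
    mean(values[(off + segs$start_idx[k] + 1):(off + segs$end_idx[k])])
  }, numeric(1))
}

state_call <- function(means, threshold) {
  ifelse(means > threshold, "gain", ifelse(means < -threshold, "loss",
                                           "neutral"))
}

#' Segment a delta profile and annotate its segments
#'
#' Segments the delta values per chromosome with [cbs_segment()] plus
#' [sd_undo()], using the noise SD of the whole delta profile. Each segment
#' is annotated with the segment-mean state of the individual normalized
#' tumour and metastasis samples ("gain" above `state_threshold`, "loss"
#' below its negative) and with `passes_threshold` / `passes_min_probes`
#' flags.
#'
#' @param dprof a [delta_profile()].
#' @param dp a [delta_params()].
#' @return the `delta_profile` with its `segments` filled in.
#' @export
segment_delta <- function(dprof, dp = delta_params()) {
  segs <- segment_profile(dprof$delta, dprof$grid, dp$cbs,
                          sample_id = dprof$patient_id,
                          noise_sd = dprof$noise_sd)
  segs$state <- state_call(segs$mean, dp$abs_delta_threshold)
  segs$tumour_mean <- segment_sample_means(segs, dprof$tumour, dprof$grid)
  segs$lnm_mean <- segment_sample_means(segs, dprof$lnm, dprof$grid)
  segs$tumour_state <- state_call(segs$tumour_mean, dp$state_threshold)
  segs$lnm_state <- state_call(segs$lnm_mean, dp$state_threshold)
  segs$passes_threshold <- abs(segs$mean) > dp$abs_delta_threshold
  segs$passes_min_probes <- segs$n_probes >= dp$min_probes
  dprof$segments <- segs
  dprof
}

#' Count qualifying delta segments
#'
#' @param dprof a segmented [delta_profile()].
#' @param dp a [delta_params()].
#' @return named vector: `n_above_threshold` (segments with |mean| above
#'   `abs_delta_threshold`) and `n_above_threshold_min_probes` (those also
#'   spanning at least `min_probes` probes).
#' @export
count_delta_segments <- function(dprof, dp = delta_params()) {
  if (is.null(dprof$segments)) stop("delta profile is not segmented")
  s <- dprof$segments
  c(n_above_threshold = sum(s$passes_threshold),
    n_above_threshold_min_probes = sum(s$passes_threshold & s$passes_min_probes))
}

#' Compare delta-segment counts between subtypes
#'
#' Two-sided Wilcoxon rank-sum test of per-patient counts, TNBC vs ER+.
#' Exact null enumeration when both groups have at most 10 observations and
#' no ties; normal approximation with tie correction otherwise. When every
#' count is identical the test is degenerate and `p = 1` is returned.
#'
#' @param counts numeric per-patient counts.
#' @param subtypes "TNBC"/"ERpos" per patient.
#' @return list with `W`, `p_value` and `method`.
#' @export
compare_subtype_counts <- function(counts, subtypes) {
  x <- counts[subtypes == "TNBC"]
  y <- counts[subtypes == "ERpos"]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 patients per subtype")
  if (length(unique(c(x, y))) == 1L) {
    return(list(W = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all counts identical)"))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(W = unname(wt$statistic), p_value = wt$p.value, method = wt$method)
}

# union-find over 1..n
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Recurrent overlapping delta segments across patients
#'
#' Candidate segments are delta segments whose |mean| exceeds
#' `overlap_abs_threshold`. Overlap groups are connected components of the
#' interval-overlap graph whose edges join candidates of different patients
#' sharing at least 1 bp (`method = "pairwise"` restricts groups to mutually
#' overlapping pairs instead of transitive chains). Each group is annotated
#' with its members' directions (sign of the delta-segment mean) and
#' `consistent_direction` — all members changing the same way, the signature
#' of a recurrent (non-random) difference.
#'
#' @param dprofs list of segmented [delta_profile()]s (>= 2 patients).
#' @param dp a [delta_params()].
#' @param method "components" (default) or "pairwise".
#' @return list of overlap groups: `chrom`, `start`, `end` (intersection of
#'   member spans; NA if transitive chaining empties it), `members`
#'   data.frame and `consistent_direction`.
#' @export
find_overlaps <- function(dprofs, dp = delta_params(),
                          method = c("components", "pairwise")) {
  method <- match.arg(method)
  if (length(dprofs) < 2) stop("need >= 2 patients")
  cand <- do.call(rbind, lapply(dprofs, function(d) {
    if (is.null(d$segments)) stop("unsegmented delta profile: ", d$patient_id)
    s <- d$segments[abs(d$segments$mean) > dp$overlap_abs_threshold, ,
                    drop = FALSE]
    if (!nrow(s)) return(NULL)
    data.frame(patient_id = d$patient_id, chrom = s$chrom, start = s$start,
               end = s$end, mean = s$mean, n_probes = s$n_probes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) < 2) return(list())
  gr <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start + 1, cand$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  e <- cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  e <- e[cand$patient_id[e[, 1]] != cand$patient_id[e[, 2]], , drop = FALSE]
  if (!nrow(e)) return(list())
  if (method == "pairwise") {
    comp_sets <- lapply(seq_len(nrow(e)), function(k) e[k, ])
  } else {
    comp <- uf_components(nrow(cand), e)
    in_graph <- sort(unique(as.vector(e)))
    comp_sets <- split(in_graph, comp[in_graph])
  }
  groups <- lapply(comp_sets, function(idx) {
    members <- cand[idx, , drop = FALSE]
    rownames(members) <- NULL
    istart <- max(members$start)
    iend <- min(members$end)
    if (istart >= iend) { istart <- NA_real_; iend <- NA_real_ }
    signs <- sign(members$mean)
    list(chrom = members$chrom[1], start = istart, end = iend,
         members = members,
         n_patients = length(unique(members$patient_id)),
         consistent_direction = all(signs == signs[1]))
  })
  groups[order(vapply(groups, function(g) chrom_rank(g$chrom), integer(1)),
               vapply(groups, function(g) {
                 if (is.na(g$start)) min(g$members$start) else g$start
               }, numeric(1)))]
}

#' Run the full pairwise delta analysis on a cohort
#'
#' For every tumour/metastasis pair: quantile-normalize, subtract, estimate
#' the delta noise SD; pairs whose noise SD exceeds
#' `high_noise_multiplier` times the cohort median are flagged as poor
#' hybridizations and excluded from group statistics. Remaining delta
#' profiles are segmented and counted, subtype counts compared by Wilcoxon
#' rank-sum, and recurrent overlapping delta segments collected.
#'
#' @param cohort a [cn_cohort()] with paired samples.
#' @param dp a [delta_params()].
#' @return list with `profiles` (segmented delta profiles of included pairs),
#'   `counts` (per patient: counts, noise SD, excluded flag), `wilcoxon`
#'   (on the min-probes-filtered counts, plus the unfiltered variant) and
#'   `overlaps`.
#' @export
delta_pipeline <- function(cohort, dp = delta_params()) {
  pairs <- pair_table(cohort$samples)
  dprofs <- lapply(seq_len(nrow(pairs)), function(i) {
    delta_profile(cohort$values[, pairs$tumour_id[i]],
                  cohort$values[, pairs$lnm_id[i]],
                  cohort$grid, pairs$patient_id[i])
  })
  noise <- vapply(dprofs, `[[`, numeric(1), "noise_sd")
  excluded <- noise > dp$high_noise_multiplier * median(noise)
  if (any(excluded)) {
    message("excluding high-noise pair(s) from group statistics: ",
            paste(pairs$patient_id[excluded], collapse = ", "),
            " (delta noise SD > ", dp$high_noise_multiplier, "x cohort median)")
  }
  dprofs[!excluded] <- lapply(dprofs[!excluded], segment_delta, dp = dp)
  counts <- data.frame(patient_id = pairs$patient_id, subtype = pairs$subtype,
                       noise_sd = noise, excluded = excluded,
                       n_segments = NA_integer_,
                       n_segments_min_probes = NA_integer_,
                       stringsAsFactors = FALSE)
  for (i in which(!excluded)) {
    ct <- count_delta_segments(dprofs[[i]], dp)
    counts$n_segments[i] <- ct[["n_above_threshold"]]
    counts$n_segments_min_probes[i] <- ct[["n_above_threshold_min_probes"]]
  }
  inc <- counts[!counts$excluded, ]
  wil <- list(
    filtered = compare_subtype_counts(inc$n_segments_min_probes, inc$subtype),
    unfiltered = compare_subtype_counts(inc$n_segments, inc$subtype))
  overlaps <- if (sum(!excluded) >= 2) {
    find_overlaps(dprofs[!excluded], dp)
  } else {
    list()
  }
  list(profiles = dprofs[!excluded], counts = counts, wilcoxon = wil,
       overlaps = overlaps)
}
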