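# Domain containers and file I/O for probe-level copy-number data.
#
# Coordinate conventions: all internal coordinates are 0-based half-open;
# probes are points (midpoints). SEG files are written 1-based inclusive,
# BED files 0-based half-open.

#' Natural ordering of chromosome names
#'
#' Orders chromosome labels so that numeric chromosomes sort numerically
#' (chr1 < chr2 < chr10) and non-numeric ones (chrX, chrY) follow
#' alphabetically. No genome build is assumed; names are opaque strings.
#'
#' @param chrom character vector of chromosome names.
#' @return integer ranks usable with `order()`.
#' @export
chrom_rank <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  ord <- order(!is.finite(num), num, u)
  match(as.character(chrom), u[ord])
}

#' Construct a probe grid
#'
#' A probe grid is the ordered set of genomic probe midpoints defining an
#' array platform. Probes are sorted by (chromosome, position); positions
#' must be strictly increasing within a chromosome and probe ids unique.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of probe midpoints (basepairs).
#' @return a `probe_grid`: a data.frame with columns `probe_id`, `chrom`,
#'   `pos`, sorted in natural chromosome order.
#' @export
probe_grid <- function(probe_id, chrom, pos) {
  stopifnot(length(probe_id) == length(chrom), length(chrom) == length(pos))
  probe_id <- as.character(probe_id)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (anyDuplicated(probe_id)) {
    stop("duplicate probe ids: ", paste(head(probe_id[duplicated(probe_id)], 3),
                                        collapse = ", "))
  }
  if (any(!is.finite(pos))) stop("non-finite probe positions")
  o <- order(chrom_rank(chrom), pos)
  g <- data.frame(probe_id = probe_id[o], chrom = chrom[o], pos = pos[o],
                  stringsAsFactors = FALSE)
  for (ch in unique(g$chrom)) {
    p <- g$pos[g$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  class(g) <- c("probe_grid", "data.frame")
  g
}

grid_chroms <- function(grid) unique(grid$chrom)

#' Validate a sample sheet
#'
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `tissue` (one of "tumour", "lnm") and `subtype` (one of "TNBC", "ERpos").
#' @param paired require exactly one tumour and one lnm sample per patient.
#' @return the validated sheet (invisibly unchanged except for type coercion).
#' @export
validate_sample_sheet <- function(samples, paired = FALSE) {
  need <- c("sample_id", "patient_id", "tissue", "subtype")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in need) samples[[col]] <- as.character(samples[[col]])
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids in sheet")
  bad <- setdiff(unique(samples$tissue), c("tumour", "lnm"))
  if (length(bad)) stop("unknown tissue value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$subtype), c("TNBC", "ERpos"))
  if (length(bad)) stop("unknown subtype value(s): ", paste(bad, collapse = ", "))
  if (paired) {
    tab <- table(samples$patient_id, samples$tissue)
    if (!all(tab == 1L)) {
      stop("pairing requires exactly one tumour and one lnm sample per patient")
    }
  }
  samples
}

#' Build a pair table from a sample sheet
#'
#' @param samples validated sample sheet (one tumour and one lnm per patient).
#' @return data.frame with one row per patient: `patient_id`, `tumour_id`,
#'   `lnm_id`, `subtype`.
#' @export
pair_table <- function(samples) {
  samples <- validate_sample_sheet(samples, paired = TRUE)
  tum <- samples[samples$tissue == "tumour", ]
  ln <- samples[samples$tissue == "lnm", ]
  ln <- ln[match(tum$patient_id, ln$patient_id), ]
  data.frame(patient_id = tum$patient_id,
             tumour_id = tum$sample_id,
             lnm_id = ln$sample_id,
             subtype = tum$subtype,
             stringsAsFactors = FALSE)
}

#' Construct a copy-number cohort
#'
#' Bundles a probe grid, a probes x samples matrix of log2 ratios and the
#' sample sheet. All profiles are aligned to the same grid.
#'
#' @param grid a `probe_grid`.
#' @param values numeric matrix, `nrow(grid)` rows, one column per sample;
#'   column names must equal `samples$sample_id`.
#' @param samples sample sheet data.frame.
#' @return a `cn_cohort` list with elements `grid`, `values`, `samples`.
#' @export
cn_cohort <- function(grid, values, samples) {
  stopifnot(inherits(grid, "probe_grid"))
  samples <- validate_sample_sheet(samples)
  values <- as.matrix(values)
  if (nrow(values) != nrow(grid)) stop("value matrix does not match grid size")
  if (is.null(colnames(values)) || !identical(colnames(values), samples$sample_id)) {
    if (ncol(values) != nrow(samples)) stop("sample sheet does not cover all columns")
    if (!is.null(colnames(values))) {
      miss <- setdiff(colnames(values), samples$sample_id)
      if (length(miss)) stop("sample(s) in matrix missing from sheet: ",
                             paste(miss, collapse = ", "))
      samples <- samples[match(colnames(values), samples$sample_id), ]
    } else {
      colnames(values) <- samples$sample_id
    }
  }
  structure(list(grid = grid, values = values, samples = samples),
            class = "cn_cohort")
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat("cn_cohort:", nrow(x$grid), "probes on",
      length(grid_chroms(x$grid)), "chromosome(s),",
      ncol(x$values), "sample(s)\n")
  invisible(x)
}

#' Read a probe-level log2-ratio matrix with its sample sheet
#'
#' The matrix file is tab-delimited with columns `probe_id`, `chrom`, `pos`
#' followed by one column per sample; the sample sheet is tab-delimited with
#' columns `sample_id`, `patient_id`, `tissue`, `subtype`. Rows are re-sorted
#' into grid order. Probes with a non-finite value in any sample are dropped
#' from the grid for all samples, with a warning giving the count.
#'
#' @param path probe matrix TSV.
#' @param sample_sheet sample sheet TSV path, or a data.frame.
#' @return a `cn_cohort`.
#' @export
read_probe_matrix <- function(path, sample_sheet) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(tab))) {
    stop("probe matrix must have columns probe_id, chrom, pos")
  }
  if (is.character(sample_sheet) && length(sample_sheet) == 1L) {
    sample_sheet <- read.delim(sample_sheet, stringsAsFactors = FALSE)
  }
  samples <- validate_sample_sheet(sample_sheet)
  sample_cols <- setdiff(names(tab), need)
  miss <- setdiff(sample_cols, samples$sample_id)
  if (length(miss)) {
    stop("sample(s) in matrix missing from sheet: ", paste(miss, collapse = ", "))
  }
  samples <- samples[match(sample_cols, samples$sample_id), ]
  vals <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  keep <- rowSums(!is.finite(vals)) == 0L
  if (any(!keep)) {
    warning(sum(!keep), " probe(s) with non-finite values dropped from all samples")
    tab <- tab[keep, , drop = FALSE]
    vals <- vals[keep, , drop = FALSE]
  }
  grid <- probe_grid(tab$probe_id, tab$chrom, tab$pos)
  vals <- vals[match(grid$probe_id, tab$probe_id), , drop = FALSE]
  tab_chr <- table(grid$chrom)
  if (any(tab_chr < 2)) {
    stop("chromosome(s) with <2 probes: ",
         paste(names(tab_chr)[tab_chr < 2], collapse = ", "))
  }
  cn_cohort(grid, vals, samples)
}

#' Write a cohort as a probe matrix TSV plus sample sheet TSV
#'
#' @param cohort a `cn_cohort`.
#' @param path output probe matrix TSV.
#' @param sheet_path output sample sheet TSV (skipped if `NULL`).
#' @param digits decimal places for log2 ratios (default 6, lossless for the
#'   stated round-trip precision).
#' @return `path`, invisibly.
#' @export
write_probe_matrix <- function(cohort, path, sheet_path = NULL, digits = 6) {
  out <- data.frame(cohort$grid, round(cohort$values, digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheet_path)) {
    write.table(cohort$samples, sheet_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Restrict a cohort to a probe subset (platform downscaling)
#'
#' Emulates downscaling a dense platform to a sparser one by keeping only
#' the probes shared with the sparser platform. Order is preserved.
#'
#' @param cohort a `cn_cohort`.
#' @param keep character vector of probe ids to keep (subset of the grid).
#' @return a `cn_cohort` on the restricted grid.
#' @export
subset_to_platform <- function(cohort, keep) {
  keep <- as.character(keep)
  unknown <- setdiff(keep, cohort$grid$probe_id)
  if (length(unknown)) {
    stop("unknown probe id(s) in keep: ", paste(head(unknown, 3), collapse = ", "))
  }
  idx <- which(cohort$grid$probe_id %in% keep)
  g <- cohort$grid[idx, , drop = FALSE]
  class(g) <- c("probe_grid", "data.frame")
  cn_cohort(g, cohort$values[idx, , drop = FALSE], cohort$samples)
}

#' Construct a segment set
#'
#' A piecewise-constant description of a profile: per-chromosome intervals
#' (0-based half-open genomic spans with half-open probe-index spans), the
#' segment mean, the number of probes and a state call.
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `mean` and optionally `start_idx`, `end_idx`, `state`.
#' @return a `segment_set` data.frame.
#' @export
segment_set <- function(df) {
  need <- c("sample_id", "chrom", "start", "end", "n_probes", "mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment set missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"state" %in% names(df)) df$state <- NA_character_
  if (!"start_idx" %in% names(df)) df$start_idx <- NA_integer_
  if (!"end_idx" %in% names(df)) df$end_idx <- NA_integer_
  if (any(df$start >= df$end)) stop("segment with start >= end")
  if (any(df$n_probes < 1)) stop("segment with fewer than one probe")
  o <- order(chrom_rank(df$chrom), df$start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("segment_set", "data.frame")
  df
}

#' Write segments to SEG or BED
#'
#' SEG columns: sample, chrom, loc.start (1-based), loc.end (inclusive),
#' num.mark, seg.mean. BED columns: chrom, start (0-based), end (half-open),
#' name (state), score (mean x 1000, clamped to \[-1000, 1000\]).
#'
#' @param segs a `segment_set`.
#' @param path output path.
#' @param format "seg" or "bed".
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path, format = c("seg", "bed")) {
  format <- match.arg(format)
  if (format == "seg") {
    out <- data.frame(sample = segs$sample_id, chrom = segs$chrom,
                      loc.start = segs$start + 1, loc.end = segs$end,
                      num.mark = segs$n_probes,
                      seg.mean = round(segs$mean, 6),
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(chrom = segs$chrom, start = segs$start, end = segs$end,
                      name = ifelse(is.na(segs$state), "segment", segs$state),
                      score = pmax(-1000, pmin(1000, round(segs$mean * 1000))),
                      stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tname\tscore", con)
    if (nrow(out)) {
      write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a SEG file back into a segment set
#'
#' Inverse of [write_segments()] with `format = "seg"`: converts 1-based
#' inclusive coordinates back to the internal 0-based half-open convention.
#'
#' @param path SEG file path.
#' @return a `segment_set` (probe indices and states are not stored in SEG
#'   and come back as `NA`).
#' @export
read_segments <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  segment_set(data.frame(sample_id = as.character(tab$sample),
                         chrom = as.character(tab$chrom),
                         start = tab$loc.start - 1, end = tab$loc.end,
                         n_probes = tab$num.mark, mean = tab$seg.mean,
                         stringsAsFactors = FALSE))
}
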