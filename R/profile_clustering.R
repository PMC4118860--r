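# Correlation-distance, average-linkage clustering of smoothed profiles and
# matched-pair concordance scoring.

as_sample_matrix <- function(x) {
  if (inherits(x, "smoothed_set")) x$values else as.matrix(x)
}

#' Correlation distance between samples
#'
#' `d_ij = 1 - r_ij` with `r` the Pearson correlation between the two samples'
#' (smoothed) genome-wide vectors; range \[0, 2\], zero diagonal.
#'
#' @param x samples x features matrix (rownames = sample ids) or a
#'   `smoothed_set`.
#' @return symmetric distance matrix of class `matrix`.
#' @export
correlation_distance <- function(x) {
  m <- as_sample_matrix(x)
  if (ncol(m) < 2) stop("need at least 2 features")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance sample(s): ",
         paste(rownames(m)[v == 0], collapse = ", "))
  }
  d <- 1 - cor(t(m))
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Inter-cluster distance is the arithmetic mean of all cross-pair distances.
#' The merge sequence is deterministic; exact ties are resolved by the
#' clustering engine's lowest-index rule.
#'
#' @param d symmetric distance matrix (e.g. from [correlation_distance()]).
#' @return an object of class `hclust` (`$merge`, `$height`, `$order`).
#' @export
average_linkage <- function(d) {
  if (nrow(as.matrix(d)) < 2) stop("need at least 2 samples")
  hclust(as.dist(d), method = "average")
}

#' Matched-pair concordance of a clustering
#'
#' A pair is concordant iff the matched tumour is the metastasis's nearest
#' neighbour — strictly smallest distance among all other samples. Exact ties
#' count as discordant, with a warning. "Nearest" is evaluated on the distance
#' matrix by default; `method = "dendrogram"` uses cophenetic distances of the
#' average-linkage tree instead (dendrogram-sibling view).
#'
#' @param d distance matrix over all samples.
#' @param pairs a [pair_table()].
#' @param method "distance" (default) or "dendrogram".
#' @return list with `per_pair` (patient_id, nearest sample, concordant flag)
#'   and `rate` (fraction of concordant pairs).
#' @export
pair_concordance <- function(d, pairs, method = c("distance", "dendrogram")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  ids <- rownames(d)
  miss <- setdiff(c(pairs$tumour_id, pairs$lnm_id), ids)
  if (length(miss)) stop("missing sample(s): ", paste(miss, collapse = ", "))
  if (method == "dendrogram") {
    d <- as.matrix(cophenetic(average_linkage(d)))[ids, ids]
  }
  per <- lapply(seq_len(nrow(pairs)), function(i) {
    lnm <- pairs$lnm_id[i]
    tum <- pairs$tumour_id[i]
    dd <- d[lnm, setdiff(ids, lnm)]
    nn <- names(dd)[which.min(dd)]
    tied <- sum(dd == min(dd)) > 1
    conc <- identical(nn, tum) && !tied
    if (tied && identical(nn, tum)) {
      warning("pair ", pairs$patient_id[i],
              ": nearest-neighbour tie; counted discordant")
    }
    data.frame(patient_id = pairs$patient_id[i], lnm_id = lnm,
               tumour_id = tum, nearest = nn, concordant = conc,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_pair = per, rate = mean(per$concordant))
}

#' Export clustering results
#'
#' Writes the leaf-ordered correlation matrix as TSV and the dendrogram in
#' Newick format (ultrametric; each branch carries half the merge height, so
#' two leaves merged at height h sit at depth h/2). Optionally renders a
#' raster heatmap with a tumour/metastasis annotation track.
#'
#' @param d distance matrix.
#' @param dendro an [average_linkage()] tree (computed from `d` if `NULL`).
#' @param path_prefix output path prefix; writes `<prefix>_correlation.tsv`
#'   and `<prefix>_dendrogram.nwk` (and `<prefix>_heatmap.png` if `png`).
#' @param samples optional sample sheet for the annotation track.
#' @param png also write a raster heatmap.
#' @return character vector of written paths, invisibly.
#' @export
export_heatmap <- function(d, dendro = NULL, path_prefix = "clustering",
                           samples = NULL, png = FALSE) {
  d <- as.matrix(d)
  if (is.null(dendro)) dendro <- average_linkage(d)
  leaves <- dendro$labels[dendro$order]
  co <- (1 - d)[leaves, leaves]
  tsv <- paste0(path_prefix, "_correlation.tsv")
  write.table(data.frame(sample_id = rownames(co), co, check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  nwk <- paste0(path_prefix, "_dendrogram.nwk")
  ape::write.tree(ape::as.phylo(dendro), file = nwk)
  paths <- c(tsv, nwk)
  if (png) {
    fig <- paste0(path_prefix, "_heatmap.png")
    grDevices::png(fig, width = 800, height = 800)
    graphics::image(seq_len(nrow(co)), seq_len(ncol(co)), co,
                    col = grDevices::hcl.colors(64, "Blue-Yellow"),
                    xlab = "", ylab = "", axes = FALSE,
                    main = "Smoothed-profile correlation (leaf order)")
    graphics::axis(1, seq_len(nrow(co)), rownames(co), las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(ncol(co)), colnames(co), las = 2, cex.axis = 0.6)
    grDevices::dev.off()
    paths <- c(paths, fig)
  }
  invisible(paths)
}
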