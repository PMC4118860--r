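# Gaussian kernel-convolution smoothing of probe-level log2 ratios onto a
# regular per-chromosome evaluation grid.
#
# The smoother is the normalized (Nadaraya-Watson) form: at grid point g the
# value is sum(w_i x_i)/sum(w_i) with w_i = exp(-(pos_i - g)^2 / (2 sigma^2)),
# computed per chromosome so no signal leaks across chromosome boundaries.
# Normalizing the weights makes the smoother mean-preserving, so profiles
# measured at different probe densities remain directly comparable and flat
# signals are preserved at chromosome edges without padding.

#' Smoothing parameters
#'
#' @param sigma_bp Gaussian kernel scale in bp (default 1 Mb).
#' @param grid_spacing_bp evaluation mesh spacing; default `sigma_bp / 4`, a
#'   standard over-sampling of a Gaussian.
#' @param truncation_sigmas kernel support cutoff in units of sigma (>= 3).
#' @return a `smooth_params` list.
#' @export
smooth_params <- function(sigma_bp = 1e6, grid_spacing_bp = sigma_bp / 4,
                          truncation_sigmas = 5) {
  stopifnot(sigma_bp > 0, grid_spacing_bp > 0, truncation_sigmas >= 3)
  structure(list(sigma_bp = sigma_bp, grid_spacing_bp = grid_spacing_bp,
                 truncation_sigmas = truncation_sigmas),
            class = "smooth_params")
}

# evaluation grid for one chromosome: regular mesh spanning the probes
eval_positions <- function(pos, sp) {
  seq(sp$grid_spacing_bp / 2,
      max(pos) + sp$grid_spacing_bp / 2, by = sp$grid_spacing_bp)
}

# m x n row-normalized truncated Gaussian weight matrix
kernel_weight_matrix <- function(probe_pos, grid_pos, sp) {
  d <- outer(grid_pos, probe_pos, "-")
  w <- exp(-d^2 / (2 * sp$sigma_bp^2))
  w[abs(d) > sp$truncation_sigmas * sp$sigma_bp] <- 0
  rs <- rowSums(w)
  if (any(rs == 0)) stop("grid point with no probe inside the kernel support")
  w / rs
}

smoothed_grid <- function(grid, sp) {
  chroms <- grid_chroms(grid)
  parts <- lapply(chroms, function(ch) {
    pos <- grid$pos[grid$chrom == ch]
    if (length(pos) < 2) stop("chromosome ", ch, " has fewer than 2 probes")
    data.frame(chrom = ch, pos = eval_positions(pos, sp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

check_undersmoothing <- function(grid, sp) {
  spacing <- median(unlist(lapply(grid_chroms(grid), function(ch) {
    diff(grid$pos[grid$chrom == ch])
  })))
  if (sp$sigma_bp < spacing / 2) {
    warning("sigma_bp (", sp$sigma_bp, ") below half the median probe spacing (",
            spacing, "): under-smoothing")
  }
}

#' Smooth one probe-level profile
#'
#' @param values numeric log2 ratios aligned to `grid`.
#' @param grid a [probe_grid()].
#' @param sp a [smooth_params()].
#' @param sample_id provenance label.
#' @return a `smoothed_profile`: list with `grid` (chrom, pos data.frame of
#'   evaluation points), `value`, `sample_id` and `params`. Evaluation grids
#'   are identical for all samples smoothed with the same parameters on the
#'   same probe grid.
#' @export
smooth_profile <- function(values, grid, sp = smooth_params(),
                           sample_id = "sample") {
  stopifnot(length(values) == nrow(grid), all(is.finite(values)))
  check_undersmoothing(grid, sp)
  eg <- smoothed_grid(grid, sp)
  out <- numeric(nrow(eg))
  for (ch in grid_chroms(grid)) {
    pi <- grid$chrom == ch
    gi <- eg$chrom == ch
    w <- kernel_weight_matrix(grid$pos[pi], eg$pos[gi], sp)
    out[gi] <- as.numeric(w %*% values[pi])
  }
  structure(list(grid = eg, value = out, sample_id = sample_id, params = sp),
            class = "smoothed_profile")
}

#' Stack smoothed profiles into a samples x grid-points matrix
#'
#' Concatenates each profile's per-chromosome smoothed values genome-wide in
#' fixed (natural) chromosome order.
#'
#' @param profiles list of [smooth_profile()] results on identical grids.
#' @return a `smoothed_set`: list with `grid` (chrom, pos), `values`
#'   (samples x grid points matrix, rownames = sample ids) and `params`.
#' @export
stack_smoothed <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  g0 <- profiles[[1]]$grid
  for (p in profiles) {
    if (!isTRUE(all.equal(p$grid, g0))) stop("smoothed grids do not match")
  }
  vals <- do.call(rbind, lapply(profiles, `[[`, "value"))
  rownames(vals) <- vapply(profiles, `[[`, character(1), "sample_id")
  structure(list(grid = g0, values = vals, params = profiles[[1]]$params),
            class = "smoothed_set")
}

#' Smooth every sample of a cohort
#'
#' Equivalent to [smooth_profile()] per sample followed by [stack_smoothed()],
#' but computes one kernel weight matrix per chromosome and applies it to all
#' samples at once.
#'
#' @param cohort a [cn_cohort()].
#' @param sp a [smooth_params()].
#' @return a `smoothed_set` (see [stack_smoothed()]).
#' @export
smooth_cohort <- function(cohort, sp = smooth_params()) {
  grid <- cohort$grid
  check_undersmoothing(grid, sp)
  eg <- smoothed_grid(grid, sp)
  out <- matrix(0, ncol(cohort$values), nrow(eg),
                dimnames = list(colnames(cohort$values), NULL))
  for (ch in grid_chroms(grid)) {
    pi <- grid$chrom == ch
    gi <- eg$chrom == ch
    w <- kernel_weight_matrix(grid$pos[pi], eg$pos[gi], sp)
    out[, gi] <- t(w %*% cohort$values[pi, , drop = FALSE])
  }
  structure(list(grid = eg, values = out, params = sp), class = "smoothed_set")
}
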