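# Independent brute-force oracles and small fixture builders shared by the
# test files. These deliberately re-derive results by the most direct route
# possible (double loops, exhaustive enumeration) and never call the package
# code paths they are used to check.

# direct O(n*m) Nadaraya-Watson smoother, one chromosome, no truncation
brute_smooth <- function(x, pos, grid_pos, sigma) {
  vapply(grid_pos, function(g) {
    w <- exp(-(pos - g)^2 / (2 * sigma^2))
    sum(w * x) / sum(w)
  }, numeric(1))
}

# textbook UPGMA on a distance matrix: returns sorted merge heights
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# exhaustive two-sided rank-sum p-value over all C(n1+n2, n1) assignments
brute_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  stats_null <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  center <- n1 * length(y) / 2
  mean(abs(stats_null - center) >= abs(obs - center))
}

# exhaustive CBS arc search: max pooled-variance two-sample t over all arcs
brute_max_arc <- function(x, min_width = 2L) {
  n <- length(x)
  best <- list(stat = -Inf, i = NA, j = NA)
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      if (i == 0 && j == n) next
      arc <- x[(i + 1):j]
      rest <- x[-((i + 1):j)]
      k <- length(arc)
      ssw <- sum((arc - mean(arc))^2) + sum((rest - mean(rest))^2)
      denom <- (ssw / (n - 2)) * (1 / k + 1 / (n - k))
      stat <- if (denom <= 0) {
        if (mean(arc) == mean(rest)) 0 else Inf
      } else {
        abs(mean(arc) - mean(rest)) / sqrt(denom)
      }
      if (stat > best$stat) best <- list(stat = stat, i = i, j = j)
    }
  }
  best
}

# tiny handmade grid: one chromosome, evenly spaced probes
toy_grid <- function(n = 5, spacing = 1e4, chrom = "chr1") {
  probe_grid(sprintf("p%03d", seq_len(n)), rep(chrom, n),
             spacing / 2 + (seq_len(n) - 1) * spacing)
}

# coarse desk-scale simulation parameters used across tests (100 kb probes
# keep CBS runtimes small without changing any analysis behaviour)
coarse_params <- function(...) {
  sim_params(probe_spacing_bp = 1e5, ...)
}

# wrap a plain matrix as a smoothed_set on a synthetic evaluation grid
fake_smoothed <- function(values, chrom = "chr1", spacing = 1e5) {
  structure(list(grid = data.frame(chrom = rep(chrom, ncol(values)),
                                   pos = spacing / 2 +
                                     (seq_len(ncol(values)) - 1) * spacing,
                                   stringsAsFactors = FALSE),
                 values = values,
                 params = smooth_params(sigma_bp = spacing, grid_spacing_bp = spacing)),
            class = "smoothed_set")
}
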