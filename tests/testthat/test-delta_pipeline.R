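test_that("quantile normalization matches the mean-of-sorted-values oracle", {
  qn <- quantile_normalize_pair(c(1, 2, 3), c(4, 6, 8))
  expect_equal(qn$tumour, c(2.5, 4, 5.5))
  expect_equal(qn$lnm, c(2.5, 4, 5.5))

  # values return in each sample's own probe order
  qn2 <- quantile_normalize_pair(c(3, 1, 2), c(4, 6, 8))
  expect_equal(qn2$tumour, c(5.5, 2.5, 4))

  x <- c(0.2, -0.1, 0.4)
  same <- quantile_normalize_pair(x, x)
  expect_equal(same$tumour, x)
  expect_equal(same$lnm, x)

  set.seed(20)
  r <- quantile_normalize_pair(rnorm(500), rnorm(500, 1, 2))
  expect_identical(sort(r$tumour), sort(r$lnm))
})

test_that("delta values behave as metastasis minus tumour", {
  expect_equal(make_delta(c(1, 2), c(1, 2)), c(0, 0))
  tum <- rep(0, 50)
  lnm <- tum; lnm[10:20] <- 0.8
  expect_equal(make_delta(tum, lnm)[10:20], rep(0.8, 11))
  expect_error(make_delta(1:3, 1:4), "mismatch")

  # post-normalization deltas are centred near zero
  sim <- simulate_cohort(2, 2, coarse_params(seed = 23L))
  for (i in seq_len(nrow(sim$pairs))) {
    dpf <- delta_profile(sim$cohort$values[, sim$pairs$tumour_id[i]],
                         sim$cohort$values[, sim$pairs$lnm_id[i]],
                         sim$cohort$grid)
    expect_lt(abs(mean(dpf$delta)), 0.01)
  }
})

test_that("delta segmentation annotates events with states and flags", {
  p <- coarse_params(n_chrom = 1L, noise_sd = 0.1, seed = 25L,
                     n_cna_mean_per_subtype = c(TNBC = 0, ERpos = 0))
  grid <- make_toy_genome(p)
  n <- nrow(grid)

  # null: identical pair -> one neutral segment for the chromosome
  set.seed(1)
  tum <- rnorm(n, 0, 0.1)
  d0 <- segment_delta(delta_profile(tum, tum, grid))
  expect_equal(nrow(d0$segments), 1)
  expect_equal(d0$segments$state, "neutral")

  # +0.8 metastasis-private event over 30 probes
  lnm <- tum + rnorm(n, 0, 0.1)
  lnm[200:229] <- lnm[200:229] + 0.8
  d1 <- segment_delta(delta_profile(tum, lnm, grid, "P1"))
  hit <- d1$segments[d1$segments$passes_threshold, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$passes_min_probes)
  expect_equal(hit$state, "gain")
  expect_equal(hit$lnm_state, "gain")
  expect_equal(hit$tumour_state, "neutral")
  # on a flat background the event occupies the far tail of the value
  # distribution, so two-sample quantile normalization attenuates it
  # (rank-k averaging); the segment stays a clear gain nonetheless
  expect_gt(hit$mean, 0.4)

  # a 0.15 event never yields a qualifying (|mean| > 0.2) segment
  lnm2 <- tum + rnorm(n, 0, 0.1)
  lnm2[300:329] <- lnm2[300:329] + 0.15
  d2 <- segment_delta(delta_profile(tum, lnm2, grid, "P2"))
  expect_false(any(d2$segments$passes_threshold))
})

test_that("segment counting applies the 0.2 and 10-probe filters", {
  p <- coarse_params(n_chrom = 1L, noise_sd = 0.05, seed = 26L,
                     n_cna_mean_per_subtype = c(TNBC = 0, ERpos = 0))
  grid <- make_toy_genome(p)
  n <- nrow(grid)
  set.seed(2)
  tum <- rnorm(n, 0, 0.05)
  lnm <- tum + rnorm(n, 0, 0.05)
  lnm[100:129] <- lnm[100:129] + 0.5   # 30 probes
  lnm[400:404] <- lnm[400:404] - 0.6   # 5 probes
  d <- segment_delta(delta_profile(tum, lnm, grid))
  expect_equal(unname(count_delta_segments(d)),
               c(2L, 1L))
  # and a null profile counts (0, 0)
  d0 <- segment_delta(delta_profile(tum, tum, grid))
  expect_equal(unname(count_delta_segments(d0)), c(0L, 0L))
})

test_that("subtype comparison equals exact enumeration", {
  r <- compare_subtype_counts(c(5, 6, 7, 1, 2, 3),
                              rep(c("TNBC", "ERpos"), each = 3))
  expect_equal(r$p_value, 0.1)  # 2 * 1/20 under the exact null

  expect_equal(compare_subtype_counts(c(2, 2, 2, 2),
                                      rep(c("TNBC", "ERpos"), each = 2))$p_value,
               1)

  set.seed(27)
  for (rep in 1:5) {
    x <- sample(1:50, sample(3:6, 1))
    y <- sample(51:100, sample(3:6, 1)) - 50L
    while (any(y %in% x)) y <- y + 0.5  # keep enumeration tie-free
    r <- compare_subtype_counts(c(x, y), rep(c("TNBC", "ERpos"),
                                             c(length(x), length(y))))
    expect_equal(r$p_value, brute_wilcoxon_p(x, y))
  }
  expect_error(compare_subtype_counts(1:3, c("TNBC", "ERpos", "ERpos")),
               ">= 2 patients")
})

test_that("overlap search groups cross-patient segments by direction", {
  mk_prof <- function(pid, chrom, start, end, mean) {
    structure(list(patient_id = pid,
                   segments = segment_set(data.frame(
                     sample_id = pid, chrom = chrom, start = start, end = end,
                     n_probes = 20L, mean = mean))),
              class = "delta_profile")
  }
  # disjoint chromosomes: no groups
  expect_length(find_overlaps(list(mk_prof("A", "chr1", 0, 1e6, 0.5),
                                   mk_prof("B", "chr2", 0, 1e6, 0.5))), 0)

  # overlapping but opposite signs: one inconsistent group
  g <- find_overlaps(list(mk_prof("A", "chr1", 0, 1e6, 0.5),
                          mk_prof("B", "chr1", 5e5, 2e6, -0.5)))
  expect_length(g, 1)
  expect_false(g[[1]]$consistent_direction)
  expect_equal(g[[1]]$start, 5e5)
  expect_equal(g[[1]]$end, 1e6)

  # three patients, same region, same sign: consistent
  g3 <- find_overlaps(list(mk_prof("A", "chr1", 0, 1e6, 0.4),
                           mk_prof("B", "chr1", 2e5, 9e5, 0.3),
                           mk_prof("C", "chr1", 5e5, 2e6, 0.6)))
  expect_length(g3, 1)
  expect_true(g3[[1]]$consistent_direction)
  expect_equal(g3[[1]]$n_patients, 3)

  # sub-threshold segments never enter the search
  expect_length(find_overlaps(list(mk_prof("A", "chr1", 0, 1e6, 0.05),
                                   mk_prof("B", "chr1", 0, 1e6, 0.5))), 0)
})

test_that("end-to-end null and label-swap equivariance hold", {
  p <- coarse_params(n_chrom = 1L, noise_sd = 0, p_private_lnm_event = 0,
                     p_private_tumour_event = 0, seed = 28L)
  sim <- simulate_cohort(2, 2, p)
  res <- delta_pipeline(sim$cohort)
  expect_true(all(res$counts$n_segments == 0))
  expect_length(res$overlaps, 0)
  expect_equal(res$wilcoxon$filtered$p_value, 1)

  # noisy cohort, swapped tumour/lnm labels: counts invariant, deltas negate
  p2 <- coarse_params(n_chrom = 1L, noise_sd = 0.1, seed = 29L)
  sim2 <- simulate_cohort(2, 2, p2)
  fwd <- delta_pipeline(sim2$cohort)
  swapped <- sim2$cohort
  swapped$samples$tissue <- ifelse(swapped$samples$tissue == "tumour",
                                   "lnm", "tumour")
  rev <- delta_pipeline(swapped)
  expect_equal(rev$counts$n_segments, fwd$counts$n_segments)
  expect_equal(rev$counts$n_segments_min_probes,
               fwd$counts$n_segments_min_probes)
  for (i in seq_along(fwd$profiles)) {
    expect_equal(rev$profiles[[i]]$delta, -fwd$profiles[[i]]$delta)
    expect_equal(rev$profiles[[i]]$segments$mean,
                 -fwd$profiles[[i]]$segments$mean)
  }
})

test_that("high-noise pairs are flagged and excluded from group statistics", {
  p <- coarse_params(n_chrom = 1L, seed = 30L)
  sim <- simulate_cohort(3, 3, p, n_noisy = 1)
  expect_message(res <- delta_pipeline(sim$cohort), "excluding high-noise")
  expect_true(res$counts$excluded[res$counts$patient_id == "P01"])
  expect_equal(sum(res$counts$excluded), 1)
  expect_true(all(is.na(res$counts$n_segments[res$counts$excluded])))
  expect_length(res$profiles, 5)
})
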