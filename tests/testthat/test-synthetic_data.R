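test_that("toy genome has the expected probe layout and is deterministic", {
  p <- sim_params(n_chrom = 2L, chrom_length_bp = 1e6, probe_spacing_bp = 1e4)
  g <- make_toy_genome(p)
  expect_equal(nrow(g), 200)
  expect_identical(g, make_toy_genome(p))

  p2 <- sim_params(n_chrom = 3L, chrom_length_bp = 30e6, probe_spacing_bp = 4e4)
  g2 <- make_toy_genome(p2)
  expect_equal(nrow(g2), 2250)
  for (ch in unique(g2$chrom)) {
    expect_true(all(diff(g2$pos[g2$chrom == ch]) > 0))
  }
  expect_error(make_toy_genome(sim_params(chrom_length_bp = 1e5,
                                          probe_spacing_bp = 5e4)),
               "fewer than 10 probes")
})

test_that("clonal backbones reflect subtype burden and amplitude signs", {
  p <- coarse_params(seed = 5L)
  grid <- make_toy_genome(p)

  p0 <- coarse_params(n_cna_mean_per_subtype = c(TNBC = 0, ERpos = 0))
  set.seed(1)
  flat <- simulate_clone(grid, "TNBC", p0)
  expect_equal(flat$mu, numeric(nrow(grid)))
  expect_equal(nrow(flat$segments), 0)

  set.seed(42)
  n_tnbc <- replicate(200, nrow(simulate_clone(grid, "TNBC", p)$segments))
  n_er <- replicate(200, nrow(simulate_clone(grid, "ERpos", p)$segments))
  tt <- t.test(n_tnbc, n_er, alternative = "greater")
  expect_lt(tt$p.value, 0.01)

  p_gain_only <- coarse_params(p_gain = 1)
  set.seed(7)
  cl <- simulate_clone(grid, "TNBC", p_gain_only)
  expect_true(all(cl$segments$amplitude > 0))
})

test_that("pairs share the clone exactly and diverge only by private events", {
  p <- coarse_params(noise_sd = 0, p_private_lnm_event = 0,
                     p_private_tumour_event = 0)
  grid <- make_toy_genome(p)
  set.seed(2)
  clone <- simulate_clone(grid, "TNBC", p)
  pr <- simulate_pair(clone, grid, p)
  expect_identical(pr$tumour, pr$lnm)
  expect_identical(pr$tumour, clone$mu)

  # forced LNM-private event, zero noise: delta is exactly the event
  p1 <- coarse_params(noise_sd = 0, p_private_lnm_event = 1,
                      p_private_tumour_event = 0,
                      private_amplitude_range = c(0.8, 0.8))
  set.seed(9)
  pr1 <- simulate_pair(clone, grid, p1)
  ev <- pr1$truth$private_lnm
  delta <- pr1$lnm - pr1$tumour
  in_ev <- grid$chrom == ev$chrom & grid$pos >= ev$start & grid$pos < ev$end
  expect_equal(unique(delta[in_ev]), ev$amplitude)
  expect_equal(unique(delta[!in_ev]), 0)
  expect_equal(abs(ev$amplitude), 0.8)
  expect_equal(sum(in_ev), ev$n_probes)
})

test_that("matched pairs correlate above all non-matched pairs", {
  sim <- simulate_cohort(15, 15, coarse_params(seed = 21L))
  r <- cor(sim$cohort$values)
  hits <- vapply(seq_len(nrow(sim$pairs)), function(i) {
    lnm <- sim$pairs$lnm_id[i]
    others <- setdiff(colnames(r), lnm)
    names(which.max(r[lnm, others])) == sim$pairs$tumour_id[i]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohorts are reproducible and extensible without perturbing patients", {
  p <- coarse_params(seed = 13L)
  a <- simulate_cohort(3, 3, p)
  b <- simulate_cohort(3, 3, p)
  expect_identical(a$cohort$values, b$cohort$values)

  bigger <- simulate_cohort(3, 5, p)
  expect_identical(bigger$cohort$values[, 1:6], a$cohort$values[, 1:6])
})

test_that("biphasic mixtures behave at the degenerate and disjoint extremes", {
  p <- coarse_params(noise_sd = 0, mixture_fraction = 1, biphasic = TRUE)
  grid <- make_toy_genome(p)
  set.seed(31)
  case <- simulate_biphasic_case(grid, p)
  expect_equal(case$tumour, case$component_a)
  expect_equal(case$tumour, case$lnm)

  # 50/50 mixture of disjoint clones: both events present, attenuated
  p5 <- coarse_params(noise_sd = 0, mixture_fraction = 0.5, biphasic = TRUE,
                      n_cna_mean_per_subtype = c(TNBC = 2, ERpos = 2))
  set.seed(5)
  case5 <- simulate_biphasic_case(grid, p5)
  segs <- rbind(case5$truth$clone_a, case5$truth$clone_b)
  for (k in seq_len(nrow(segs))) {
    idx <- grid$chrom == segs$chrom[k] & grid$pos >= segs$start[k] &
      grid$pos < segs$end[k]
    expected_alone <- abs(segs$amplitude[k])
    got <- mean(abs(case5$tumour[idx]))
    expect_gt(got, 0)           # present
    expect_lt(got, expected_alone)  # attenuated by mixing
  }
})

test_that("injected recurrent events land in every metastasis", {
  inj <- list(chrom = "chr2", start = 10e6, end = 15e6, amplitude = 0.5)
  sim <- simulate_cohort(3, 3, coarse_params(noise_sd = 0,
                                             p_private_lnm_event = 0,
                                             p_private_tumour_event = 0,
                                             seed = 2L),
                         inject = inj)
  grid <- sim$cohort$grid
  in_ev <- grid$chrom == "chr2" & grid$pos >= 10e6 & grid$pos < 15e6
  for (i in seq_len(nrow(sim$pairs))) {
    delta <- sim$cohort$values[, sim$pairs$lnm_id[i]] -
      sim$cohort$values[, sim$pairs$tumour_id[i]]
    expect_equal(unique(delta[in_ev]), 0.5)
  }
})

test_that("cohort writer emits matrix, sheet and truth JSON", {
  sim <- simulate_cohort(2, 2, coarse_params(n_chrom = 1L, seed = 8L))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_probe_matrix(file.path(dir, "probe_matrix.tsv"),
                            file.path(dir, "sample_sheet.tsv"))
  expect_equal(back$values, sim$cohort$values, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_named(truth$patients, sim$pairs$patient_id)
})
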