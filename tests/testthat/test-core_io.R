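test_that("probe matrix round-trips and row order does not matter", {
  grid <- toy_grid(3)
  samples <- data.frame(sample_id = c("S1", "S2"),
                        patient_id = c("P1", "P1"),
                        tissue = c("tumour", "lnm"),
                        subtype = c("TNBC", "TNBC"))
  vals <- matrix(c(0.1, -0.2, 0.3, 0.4, 0, -0.5), 3, 2,
                 dimnames = list(NULL, samples$sample_id))
  co <- cn_cohort(grid, vals, samples)

  mpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_probe_matrix(co, mpath, spath)
  back <- read_probe_matrix(mpath, spath)
  expect_equal(back$grid$probe_id, grid$probe_id)
  expect_equal(back$values, vals, tolerance = 1e-6)
  expect_equal(back$samples$tissue, samples$tissue)

  # shuffle the file rows: result identical
  lines <- readLines(mpath)
  writeLines(c(lines[1], lines[c(3, 4, 2)]), mpath)
  shuffled <- read_probe_matrix(mpath, spath)
  expect_equal(shuffled$values, back$values)
  expect_equal(shuffled$grid, back$grid)
})

test_that("non-finite probes are dropped globally with a warning", {
  grid <- toy_grid(4)
  samples <- data.frame(sample_id = c("S1", "S2"), patient_id = c("P1", "P1"),
                        tissue = c("tumour", "lnm"), subtype = c("TNBC", "TNBC"))
  tab <- data.frame(grid, S1 = c(0.1, NA, 0.3, 0.4), S2 = c(1, 2, 3, 4),
                    check.names = FALSE)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(co <- read_probe_matrix(mpath, samples), "1 probe")
  expect_equal(nrow(co$grid), 3)
  expect_equal(co$values[, "S2"], c(1, 3, 4), ignore_attr = TRUE)
})

test_that("reader validates probes, samples and chromosome sizes", {
  expect_error(probe_grid(c("a", "a"), c("chr1", "chr1"), c(1, 2)), "duplicate")
  expect_error(probe_grid(c("a", "b"), c("chr1", "chr1"), c(5, 5)),
               "strictly increasing")
  grid <- toy_grid(3)
  tab <- data.frame(grid, S1 = 1:3, SX = 4:6, check.names = FALSE)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = "S1", patient_id = "P1",
                      tissue = "tumour", subtype = "TNBC")
  expect_error(read_probe_matrix(mpath, sheet), "missing from sheet")
})

test_that("platform downscaling preserves values and commutes with subtraction", {
  grid <- toy_grid(100)
  samples <- data.frame(sample_id = c("S1", "S2"), patient_id = c("P1", "P1"),
                        tissue = c("tumour", "lnm"), subtype = c("ERpos", "ERpos"))
  set.seed(11)
  vals <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, samples$sample_id))
  co <- cn_cohort(grid, vals, samples)

  expect_equal(subset_to_platform(co, grid$probe_id)$values, co$values)

  keep <- grid$probe_id[seq(5, 100, by = 5)]
  sub <- subset_to_platform(co, keep)
  expect_equal(nrow(sub$grid), 20)
  expect_equal(sub$values[, 1], vals[seq(5, 100, by = 5), 1], ignore_attr = TRUE)

  # subset(a - b) == subset(a) - subset(b)
  diff_full <- cn_cohort(grid,
                         co$values[, 1, drop = FALSE] - co$values[, 2],
                         samples[1, ])
  expect_equal(subset_to_platform(diff_full, keep)$values[, 1],
               sub$values[, 1] - sub$values[, 2], ignore_attr = TRUE)

  expect_error(subset_to_platform(co, "nope"), "unknown probe")
})

test_that("downscaled platform gives near-identical smoothed profiles", {
  # dense noiseless profile vs its 1-in-5 subset, both smoothed at 1 Mb
  p <- sim_params(n_chrom = 1L, chrom_length_bp = 20e6, probe_spacing_bp = 5e3,
                  noise_sd = 0, p_private_lnm_event = 0,
                  p_private_tumour_event = 0, seed = 3L)
  grid <- make_toy_genome(p)
  set.seed(3)
  clone <- simulate_clone(grid, "TNBC", p)
  keep <- grid$probe_id[seq(5, nrow(grid), by = 5)]
  s_full <- smooth_profile(clone$mu, grid)
  idx <- match(keep, grid$probe_id)
  g_sub <- grid[idx, ]
  class(g_sub) <- c("probe_grid", "data.frame")
  s_sub <- smooth_profile(clone$mu[idx], g_sub)
  expect_equal(length(s_full$value), length(s_sub$value))
  expect_gt(cor(s_full$value, s_sub$value), 0.99)
})

test_that("segment writers follow SEG/BED conventions and round-trip", {
  segs <- segment_set(data.frame(
    sample_id = "S1", chrom = "chr1", start = 0, end = 1000,
    n_probes = 10L, mean = 0.5, state = "gain"))
  bed <- withr::local_tempfile(fileext = ".bed")
  seg <- withr::local_tempfile(fileext = ".seg")
  write_segments(segs, bed, "bed")
  write_segments(segs, seg, "seg")
  expect_equal(strsplit(readLines(bed)[2], "\t")[[1]][1:3],
               c("chr1", "0", "1000"))
  expect_equal(strsplit(readLines(seg)[2], "\t")[[1]][2:4],
               c("chr1", "1", "1000"))

  # empty set -> header-only files
  empty <- segs[0, ]
  class(empty) <- c("segment_set", "data.frame")
  write_segments(empty, bed, "bed")
  write_segments(empty, seg, "seg")
  expect_length(readLines(bed), 1)
  expect_length(readLines(seg), 1)

  # 7-segment round trip through SEG
  set.seed(4)
  seven <- segment_set(data.frame(
    sample_id = "S1", chrom = rep(c("chr1", "chr2"), c(4, 3)),
    start = c(0, 100, 250, 400, 0, 50, 90),
    end = c(100, 250, 400, 600, 50, 90, 200),
    n_probes = c(3L, 5L, 4L, 6L, 2L, 2L, 4L),
    mean = round(rnorm(7), 6)))
  write_segments(seven, seg, "seg")
  back <- read_segments(seg)
  cols <- c("sample_id", "chrom", "start", "end", "n_probes", "mean")
  expect_equal(as.data.frame(back)[cols], as.data.frame(seven)[cols])
})

test_that("pair table construction and pairing validation", {
  samples <- data.frame(
    sample_id = c("A_T", "A_L", "B_T", "B_L"),
    patient_id = c("A", "A", "B", "B"),
    tissue = c("tumour", "lnm", "tumour", "lnm"),
    subtype = c("TNBC", "TNBC", "ERpos", "ERpos"))
  pt <- pair_table(samples)
  expect_equal(pt$tumour_id, c("A_T", "B_T"))
  expect_equal(pt$lnm_id, c("A_L", "B_L"))
  expect_error(pair_table(samples[-2, ]), "pairing requires")
  expect_error(validate_sample_sheet(transform(samples, tissue = "organ")),
               "unknown tissue")
})
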