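# Synthetic paired tumour / lymph-node-metastasis cohort generator.
#
# The generator emulates the structure the downstream analysis assumes:
# paired profiles sharing a clonal CNA backbone, subtype-dependent aberration
# burden (TNBC > ER+), i.i.d. Gaussian probe noise, occasional high-noise
# hybridizations, pair-private focal events, and rare biphasic tumours made
# of two molecularly distinct components. Every draw is recorded as ground
# truth so recovery can be scored exactly.

#' Simulation parameters
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length (bp).
#' @param probe_spacing_bp regular probe spacing (bp); first probe at
#'   `spacing/2`.
#' @param n_cna_mean_per_subtype named vector: Poisson mean of clonal CNAs per
#'   subtype. TNBC carries the larger burden (genomic instability).
#' @param cna_length_meanlog,cna_length_sdlog log-normal parameters of clonal
#'   CNA length in bp.
#' @param amp_gain_mean,amp_loss_mean,amp_sd Gaussian parameters of the signed
#'   log2 amplitude of clonal events (gains positive, losses negative).
#' @param p_gain probability a clonal event is a gain.
#' @param noise_sd per-probe Gaussian noise SD (log2 scale).
#' @param noisy_hyb_sd_multiplier noise multiplier applied to one sample of a
#'   flagged poor-quality hybridization.
#' @param p_private_lnm_event per-pair probability of one LNM-private focal
#'   event (divergence of the metastasis from the clone).
#' @param p_private_tumour_event per-pair probability of one tumour-private
#'   focal event.
#' @param private_event_length_bp length-2 range (bp) of private event spans.
#' @param private_amplitude_range length-2 range of private event |log2|
#'   amplitudes; sign is drawn with equal probability.
#' @param biphasic if `TRUE`, [simulate_cohort()] makes its first patient a
#'   two-component tumour.
#' @param mixture_fraction fraction of component A in a biphasic tumour.
#' @param seed root seed; per-patient child streams are derived from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_chrom = 3L,
                       chrom_length_bp = 60e6,
                       probe_spacing_bp = 25e3,
                       n_cna_mean_per_subtype = c(TNBC = 12, ERpos = 5),
                       cna_length_meanlog = log(3e6),
                       cna_length_sdlog = 0.8,
                       amp_gain_mean = 0.6,
                       amp_loss_mean = -0.6,
                       amp_sd = 0.15,
                       p_gain = 0.5,
                       noise_sd = 0.15,
                       noisy_hyb_sd_multiplier = 6,
                       p_private_lnm_event = 0.8,
                       p_private_tumour_event = 0.3,
                       private_event_length_bp = c(5e5, 2e6),
                       private_amplitude_range = c(0.3, 0.8),
                       biphasic = FALSE,
                       mixture_fraction = 0.5,
                       seed = 1L) {
  p <- list(n_chrom = as.integer(n_chrom),
            chrom_length_bp = chrom_length_bp,
            probe_spacing_bp = probe_spacing_bp,
            n_cna_mean_per_subtype = n_cna_mean_per_subtype,
            cna_length_meanlog = cna_length_meanlog,
            cna_length_sdlog = cna_length_sdlog,
            amp_gain_mean = amp_gain_mean,
            amp_loss_mean = amp_loss_mean,
            amp_sd = amp_sd,
            p_gain = p_gain,
            noise_sd = noise_sd,
            noisy_hyb_sd_multiplier = noisy_hyb_sd_multiplier,
            p_private_lnm_event = p_private_lnm_event,
            p_private_tumour_event = p_private_tumour_event,
            private_event_length_bp = private_event_length_bp,
            private_amplitude_range = private_amplitude_range,
            biphasic = isTRUE(biphasic),
            mixture_fraction = mixture_fraction,
            seed = as.integer(seed))
  stopifnot(p$probe_spacing_bp > 0, p$noise_sd >= 0,
            p$noisy_hyb_sd_multiplier >= 1,
            p$p_private_lnm_event >= 0, p$p_private_lnm_event <= 1,
            p$p_private_tumour_event >= 0, p$p_private_tumour_event <= 1,
            p$p_gain >= 0, p$p_gain <= 1,
            p$amp_gain_mean > 0, p$amp_loss_mean < 0,
            p$mixture_fraction >= 0, p$mixture_fraction <= 1,
            all(c("TNBC", "ERpos") %in% names(p$n_cna_mean_per_subtype)))
  class(p) <- "sim_params"
  p
}

# deterministic child seed below 2^31, so per-patient streams are independent
# of cohort size and earlier patients
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629) + 1L
}

#' Build a regular toy probe grid
#'
#' @param p a [sim_params()] object.
#' @return a [probe_grid()] with probes every `probe_spacing_bp`, first probe
#'   at half the spacing. Deterministic given `p`.
#' @export
make_toy_genome <- function(p) {
  per_chrom <- floor((p$chrom_length_bp - p$probe_spacing_bp / 2) /
                       p$probe_spacing_bp) + 1
  if (per_chrom < 10) stop("fewer than 10 probes per chromosome")
  chroms <- paste0("chr", seq_len(p$n_chrom))
  pos <- p$probe_spacing_bp / 2 + (seq_len(per_chrom) - 1) * p$probe_spacing_bp
  probe_grid(probe_id = sprintf("p_%s_%06d", rep(chroms, each = per_chrom),
                                rep(seq_len(per_chrom), p$n_chrom)),
             chrom = rep(chroms, each = per_chrom),
             pos = rep(pos, p$n_chrom))
}

probes_in_event <- function(grid, chrom, start, end) {
  which(grid$chrom == chrom & grid$pos >= start & grid$pos < end)
}

draw_event_span <- function(p, len) {
  chroms <- paste0("chr", seq_len(p$n_chrom))
  chrom <- sample(chroms, 1L)
  len <- min(len, p$chrom_length_bp)
  start <- floor(runif(1, 0, p$chrom_length_bp - len))
  c(chrom = chrom, start = start, end = start + len)
}

#' Simulate a clonal CNA backbone
#'
#' Draws `K ~ Poisson(mean[subtype])` non-overlapping CNA intervals with
#' log-normal lengths and signed Gaussian amplitudes on a flat (log2 = 0)
#' background. Overlapping draws are rejection-resampled; if placement fails
#' after bounded retries, K is reduced with a warning.
#'
#' @param grid a [probe_grid()].
#' @param subtype "TNBC" or "ERpos".
#' @param p a [sim_params()].
#' @return a `clone_map` list: `segments` (chrom, start, end, amplitude) and
#'   `mu` (true per-probe log2 mean).
#' @export
simulate_clone <- function(grid, subtype, p) {
  k <- rpois(1, p$n_cna_mean_per_subtype[[subtype]])
  segs <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     amplitude = numeric(), stringsAsFactors = FALSE)
  placed <- 0L
  tries <- 0L
  max_tries <- 100L * max(k, 1L)
  while (placed < k && tries < max_tries) {
    tries <- tries + 1L
    len <- rlnorm(1, p$cna_length_meanlog, p$cna_length_sdlog)
    sp <- draw_event_span(p, len)
    start <- as.numeric(sp["start"]); end <- as.numeric(sp["end"])
    same <- segs$chrom == sp["chrom"]
    if (any(same & segs$start < end & start < segs$end)) next
    gain <- runif(1) < p$p_gain
    amp <- if (gain) max(0.2, rnorm(1, p$amp_gain_mean, p$amp_sd))
           else min(-0.2, rnorm(1, p$amp_loss_mean, p$amp_sd))
    segs <- rbind(segs, data.frame(chrom = sp["chrom"], start = start,
                                   end = end, amplitude = amp,
                                   stringsAsFactors = FALSE))
    placed <- placed + 1L
  }
  if (placed < k) {
    warning("placed ", placed, " of ", k, " clonal events (overlap rejection)")
  }
  mu <- numeric(nrow(grid))
  for (i in seq_len(nrow(segs))) {
    idx <- probes_in_event(grid, segs$chrom[i], segs$start[i], segs$end[i])
    mu[idx] <- mu[idx] + segs$amplitude[i]
  }
  rownames(segs) <- NULL
  list(segments = segs, mu = mu)
}

draw_private_event <- function(grid, p) {
  len <- runif(1, p$private_event_length_bp[1], p$private_event_length_bp[2])
  sp <- draw_event_span(p, len)
  amp <- runif(1, p$private_amplitude_range[1], p$private_amplitude_range[2]) *
    sample(c(-1, 1), 1)
  data.frame(chrom = sp["chrom"], start = as.numeric(sp["start"]),
             end = as.numeric(sp["end"]), amplitude = amp,
             n_probes = length(probes_in_event(grid, sp["chrom"],
                                               as.numeric(sp["start"]),
                                               as.numeric(sp["end"]))),
             stringsAsFactors = FALSE)
}

add_event <- function(mu, grid, ev) {
  idx <- probes_in_event(grid, ev$chrom, ev$start, ev$end)
  mu[idx] <- mu[idx] + ev$amplitude
  mu
}

#' Simulate one tumour/LNM pair from a clonal backbone
#'
#' Both samples inherit the clone's true means exactly; divergence enters
#' only through explicit private focal events (one per sample at most), so
#' ground truth is unambiguous. Independent Gaussian noise is added per probe;
#' a flagged poor hybridization multiplies one randomly chosen sample's noise
#' SD by `noisy_hyb_sd_multiplier`.
#'
#' @param clone output of [simulate_clone()].
#' @param grid the [probe_grid()] the clone was drawn on.
#' @param p a [sim_params()].
#' @param noisy_hyb flag this pair as a poor-quality hybridization.
#' @return list with `tumour` and `lnm` numeric log2 vectors and a `truth`
#'   record (private events per sample, noise SDs used, flags).
#' @export
simulate_pair <- function(clone, grid, p, noisy_hyb = FALSE) {
  mu_t <- clone$mu
  mu_l <- clone$mu
  priv_l <- priv_t <- NULL
  if (runif(1) < p$p_private_lnm_event) {
    priv_l <- draw_private_event(grid, p)
    mu_l <- add_event(mu_l, grid, priv_l)
  }
  if (runif(1) < p$p_private_tumour_event) {
    priv_t <- draw_private_event(grid, p)
    mu_t <- add_event(mu_t, grid, priv_t)
  }
  sd_t <- sd_l <- p$noise_sd
  if (noisy_hyb) {
    if (runif(1) < 0.5) sd_t <- sd_t * p$noisy_hyb_sd_multiplier
    else sd_l <- sd_l * p$noisy_hyb_sd_multiplier
  }
  n <- nrow(grid)
  list(tumour = mu_t + rnorm(n, 0, sd_t),
       lnm = mu_l + rnorm(n, 0, sd_l),
       truth = list(private_lnm = priv_l, private_tumour = priv_t,
                    noise_sd_tumour = sd_t, noise_sd_lnm = sd_l,
                    noisy_hyb = noisy_hyb))
}

#' Simulate a biphasic (two-component) tumour case
#'
#' The tumour is a mixture of two independent clones A and B, mixed in linear
#' copy space (`log2(f 2^a + (1-f) 2^b)`, since DNA mixes linearly in copy
#' number); the metastasis derives from component A only. Component profiles
#' are emitted separately, emulating the separate re-hybridization of the two
#' histological components.
#'
#' @param grid a [probe_grid()].
#' @param p a [sim_params()] with `mixture_fraction` set.
#' @param subtype clone burden subtype for both components.
#' @return list with `tumour`, `lnm`, `component_a`, `component_b` log2
#'   vectors and a `truth` record (both clones' segments, mixture fraction).
#' @export
simulate_biphasic_case <- function(grid, p, subtype = "TNBC") {
  clone_a <- simulate_clone(grid, subtype, p)
  clone_b <- simulate_clone(grid, subtype, p)
  f <- p$mixture_fraction
  mu_mix <- log2(f * 2^clone_a$mu + (1 - f) * 2^clone_b$mu)
  n <- nrow(grid)
  list(tumour = mu_mix + rnorm(n, 0, p$noise_sd),
       lnm = clone_a$mu + rnorm(n, 0, p$noise_sd),
       component_a = clone_a$mu + rnorm(n, 0, p$noise_sd),
       component_b = clone_b$mu + rnorm(n, 0, p$noise_sd),
       truth = list(clone_a = clone_a$segments, clone_b = clone_b$segments,
                    mixture_fraction = f))
}

#' Simulate a full paired cohort with ground truth
#'
#' Patients are simulated on independent child RNG streams derived from the
#' root seed, so the cohort is extensible without perturbing earlier patients.
#' Optionally a recurrent differential CNA (same region, same sign) is
#' injected into every LNM, for power testing of the group comparison.
#'
#' @param n_tnbc,n_erpos numbers of TNBC and ER+ pairs (defaults 10 + 10).
#' @param p a [sim_params()].
#' @param inject optional recurrent LNM event:
#'   `list(chrom =, start =, end =, amplitude =)`.
#' @param n_noisy number of pairs flagged as poor hybridizations (the first
#'   `n_noisy` patients).
#' @return list of class `cn_cohort_sim`: `cohort` (a [cn_cohort()]), `pairs`
#'   (a [pair_table()]) and `truth` (per-patient records, injection, params).
#' @export
simulate_cohort <- function(n_tnbc = 10L, n_erpos = 10L, p = sim_params(),
                            inject = NULL, n_noisy = 0L) {
  grid <- make_toy_genome(p)
  n_pat <- n_tnbc + n_erpos
  stopifnot(n_pat >= 1L, n_noisy <= n_pat)
  subtypes <- c(rep("TNBC", n_tnbc), rep("ERpos", n_erpos))
  pat_ids <- sprintf("P%02d", seq_len(n_pat))
  vals <- matrix(0, nrow(grid), 2L * n_pat)
  truth <- vector("list", n_pat)
  names(truth) <- pat_ids
  sample_ids <- character(2L * n_pat)
  for (i in seq_len(n_pat)) {
    set.seed(child_seed(p$seed, i))
    if (p$biphasic && i == 1L) {
      case <- simulate_biphasic_case(grid, p, subtypes[i])
      pair <- list(tumour = case$tumour, lnm = case$lnm,
                   truth = c(case$truth, list(biphasic = TRUE,
                                              private_lnm = NULL,
                                              private_tumour = NULL,
                                              noisy_hyb = FALSE)))
      pair$truth$components <- list(a = case$component_a, b = case$component_b)
      clone_segments <- case$truth$clone_a
    } else {
      clone <- simulate_clone(grid, subtypes[i], p)
      pair <- simulate_pair(clone, grid, p, noisy_hyb = i <= n_noisy)
      pair$truth$biphasic <- FALSE
      clone_segments <- clone$segments
    }
    if (!is.null(inject)) {
      pair$lnm <- add_event(pair$lnm, grid, as.data.frame(inject))
      pair$truth$injected <- as.data.frame(inject)
    }
    pair$truth$clone_segments <- clone_segments
    pair$truth$subtype <- subtypes[i]
    truth[[i]] <- pair$truth
    tcol <- 2L * i - 1L
    vals[, tcol] <- pair$tumour
    vals[, tcol + 1L] <- pair$lnm
    sample_ids[tcol] <- paste0(pat_ids[i], "_T")
    sample_ids[tcol + 1L] <- paste0(pat_ids[i], "_L")
  }
  colnames(vals) <- sample_ids
  samples <- data.frame(sample_id = sample_ids,
                        patient_id = rep(pat_ids, each = 2L),
                        tissue = rep(c("tumour", "lnm"), n_pat),
                        subtype = rep(subtypes, each = 2L),
                        stringsAsFactors = FALSE)
  cohort <- cn_cohort(grid, vals, samples)
  structure(list(cohort = cohort, pairs = pair_table(samples),
                 truth = list(patients = truth, inject = inject, params = p)),
            class = "cn_cohort_sim")
}

#' Write a simulated cohort to disk
#'
#' Writes the standard probe-matrix TSV, the sample sheet TSV and the ground
#' truth as JSON.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_probe_matrix(sim$cohort, file.path(dir, "probe_matrix.tsv"),
                     file.path(dir, "sample_sheet.tsv"))
  truth <- sim$truth
  truth$params <- unclass(truth$params)
  truth$patients <- lapply(truth$patients, function(tr) {
    tr$components <- NULL  # probe-level vectors stay out of the JSON
    tr
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
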