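# End-to-end driver: simulate (or load) -> smooth -> cluster -> compare
# (overall and per subtype) -> delta pipeline, with a resolved config and a
# structured report written beside the stage outputs.

#' Build a run configuration
#'
#' A plain nested list that round-trips losslessly through YAML. Parameter
#' blocks override the corresponding constructor defaults; all stage seeds
#' are derived deterministically from the single root seed, so enabling or
#' disabling one stage never changes another's randomness.
#'
#' @param n_tnbc,n_erpos cohort sizes (pairs per subtype).
#' @param seed root seed.
#' @param n_noisy number of poor-hybridization pairs to simulate.
#' @param inject optional recurrent LNM event
#'   (`list(chrom =, start =, end =, amplitude =)`).
#' @param sim,smooth,compare,cbs,delta named lists of overrides for
#'   [sim_params()], [smooth_params()], [compare_params()], [cbs_params()],
#'   [delta_params()].
#' @param input optional directory with `probe_matrix.tsv` and
#'   `sample_sheet.tsv` to load instead of simulating.
#' @return a `run_config` list.
#' @export
run_config <- function(n_tnbc = 10L, n_erpos = 10L, seed = 1L, n_noisy = 0L,
                       inject = NULL, sim = list(), smooth = list(),
                       compare = list(), cbs = list(), delta = list(),
                       input = NULL) {
  structure(list(n_tnbc = as.integer(n_tnbc), n_erpos = as.integer(n_erpos),
                 seed = as.integer(seed), n_noisy = as.integer(n_noisy),
                 inject = inject, sim = sim, smooth = smooth,
                 compare = compare, cbs = cbs, delta = delta, input = input),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write) or the reconstructed `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}

resolve_params <- function(config) {
  sim <- do.call(sim_params,
                 c(config$sim[setdiff(names(config$sim), "seed")],
                   list(seed = child_seed(config$seed, 101L))))
  smooth <- do.call(smooth_params, config$smooth)
  compare <- do.call(compare_params,
                     c(config$compare[setdiff(names(config$compare), "seed")],
                       list(seed = child_seed(config$seed, 102L),
                            sigma_bp = smooth$sigma_bp)))
  cbs <- do.call(cbs_params,
                 c(config$cbs[setdiff(names(config$cbs), "seed")],
                   list(seed = child_seed(config$seed, 103L))))
  delta <- do.call(delta_params, c(config$delta, list(cbs = cbs)))
  list(sim = sim, smooth = smooth, compare = compare, delta = delta)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the complete analysis
#'
#' Executes simulate (or load) -> smooth -> cluster -> compare (overall and
#' per subtype) -> delta pipeline, writes every stage's outputs plus the
#' resolved configuration to `out_dir`, and returns a single structured
#' report (concordance, significant comparative regions, per-patient delta
#' counts, Wilcoxon p, overlap groups). Fully reproducible from the resolved
#' config and root seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; `NULL` skips file output).
#' @return the report, a nested list (also written as `report.json`).
#' @export
run_all <- function(config, out_dir = NULL) {
  pars <- resolve_params(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(config, file.path(out_dir, "config_resolved.yaml"))
  }
  sim <- stage("simulate/load", {
    if (!is.null(config$input)) {
      cohort <- read_probe_matrix(file.path(config$input, "probe_matrix.tsv"),
                                  file.path(config$input, "sample_sheet.tsv"))
      list(cohort = cohort, pairs = pair_table(cohort$samples), truth = NULL)
    } else {
      simulate_cohort(config$n_tnbc, config$n_erpos, pars$sim,
                      inject = config$inject, n_noisy = config$n_noisy)
    }
  })
  cohort <- sim$cohort
  pairs <- sim$pairs
  if (!is.null(out_dir) && is.null(config$input)) {
    write_probe_matrix(cohort, file.path(out_dir, "probe_matrix.tsv"),
                       file.path(out_dir, "sample_sheet.tsv"))
  }
  smoothed <- stage("smooth", smooth_cohort(cohort, pars$smooth))
  clust <- stage("cluster", {
    d <- correlation_distance(smoothed)
    conc <- pair_concordance(d, pairs)
    if (!is.null(out_dir)) {
      export_heatmap(d, path_prefix = file.path(out_dir, "clustering"))
      write.table(conc$per_pair, file.path(out_dir, "concordance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    conc
  })
  comp <- stage("compare", {
    groups <- list(all = pairs,
                   TNBC = pairs[pairs$subtype == "TNBC", ],
                   ERpos = pairs[pairs$subtype == "ERpos", ])
    lapply(groups, function(pg) {
      if (nrow(pg) < 2) return(NULL)
      ids <- c(pg$tumour_id, pg$lnm_id)
      sm <- list(grid = smoothed$grid,
                 values = smoothed$values[ids, , drop = FALSE],
                 params = smoothed$params)
      class(sm) <- "smoothed_set"
      labs <- cohort$samples$tissue[match(ids, cohort$samples$sample_id)]
      permutation_test(sm, labs, pg, pars$compare)
    })
  })
  if (!is.null(out_dir)) {
    for (nm in names(comp)) {
      if (is.null(comp[[nm]])) next
      write.table(data.frame(chrom = comp[[nm]]$grid$chrom,
                             pos = comp[[nm]]$grid$pos, D = comp[[nm]]$D),
                  file.path(out_dir, paste0("difference_curve_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(comp[[nm]]$regions,
                  file.path(out_dir, paste0("significant_regions_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  dres <- stage("delta", delta_pipeline(cohort, pars$delta))
  if (!is.null(out_dir)) {
    for (dprof in dres$profiles) {
      write_segments(dprof$segments,
                     file.path(out_dir, paste0("delta_segments_",
                                               dprof$patient_id, ".seg")))
    }
    write.table(dres$counts, file.path(out_dir, "delta_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ov <- do.call(rbind, lapply(seq_along(dres$overlaps), function(k) {
      g <- dres$overlaps[[k]]
      data.frame(group = k, chrom = g$chrom, start = g$start, end = g$end,
                 n_patients = g$n_patients,
                 consistent_direction = g$consistent_direction,
                 patients = paste(g$members$patient_id, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ov)) {
      ov <- data.frame(group = integer(), chrom = character(),
                       start = numeric(), end = numeric(),
                       n_patients = integer(),
                       consistent_direction = logical(),
                       patients = character())
    }
    write.table(ov, file.path(out_dir, "overlap_groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  report <- list(
    n_pairs = nrow(pairs),
    n_tnbc = sum(pairs$subtype == "TNBC"),
    n_erpos = sum(pairs$subtype == "ERpos"),
    concordance_rate = clust$rate,
    discordant_patients = clust$per_pair$patient_id[!clust$per_pair$concordant],
    comparative = lapply(comp, function(r) {
      if (is.null(r)) return(NULL)
      list(n_significant_regions = nrow(r$regions),
           threshold = r$threshold, p_global = r$p_global,
           n_perm = r$n_perm_used)
    }),
    delta = list(
      n_excluded_pairs = sum(dres$counts$excluded),
      excluded_patients = dres$counts$patient_id[dres$counts$excluded],
      median_count_tnbc = median(dres$counts$n_segments_min_probes[
        dres$counts$subtype == "TNBC" & !dres$counts$excluded]),
      median_count_erpos = median(dres$counts$n_segments_min_probes[
        dres$counts$subtype == "ERpos" & !dres$counts$excluded]),
      wilcoxon_p = dres$wilcoxon$filtered$p_value,
      wilcoxon_W = dres$wilcoxon$filtered$W,
      n_overlap_groups = length(dres$overlaps),
      n_consistent_direction = sum(vapply(dres$overlaps,
                                          `[[`, logical(1),
                                          "consistent_direction"))))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(structure(list(report = report, cohort = cohort, pairs = pairs,
                           smoothed = smoothed, clustering = clust,
                           comparative = comp, delta = dres,
                           truth = sim$truth),
                      class = "run_result"))
}
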