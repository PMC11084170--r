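# End-to-end pipelines: per-metric WSH clock runs, per-scheme region clock
# runs, and the two reciprocal-filtering combinations. Every filter stage
# logs input -> output counts, and reports carry the counts needed to
# recompute them from the emitted intermediates.

#' Analysis configuration
#'
#' @param cor_low,cor_high,padj_max Locus-selection thresholds
#'   (defaults 0.25, 0.5, 0.05).
#' @param schemes Window schemes (default [default_window_schemes()], 14).
#' @param min_cov Minimum per-CpG coverage for window methylation (5).
#' @param split_fraction Train fraction (0.8).
#' @param seed Master seed.
#' @param rfe_tol RFE relative MAE tolerance (0.05).
#' @param metric_params [metric_params()] used for scoring.
#' @param rf_params,lasso_params Model parameter lists; seeds default to
#'   the master seed.
#' @export
analysis_config <- function(cor_low = 0.25, cor_high = 0.5, padj_max = 0.05,
                            schemes = default_window_schemes(), min_cov = 5L,
                            split_fraction = 0.8, seed = 1L, rfe_tol = 0.05,
                            metric_params = wshclock::metric_params(),
                            rf_params = NULL, lasso_params = NULL) {
  stopifnot(cor_low > 0, cor_low < 1, cor_high > 0, cor_high < 1,
            padj_max > 0, padj_max < 1)
  if (is.null(rf_params)) {
    rf_params <- rf_clock_params(split_fraction = split_fraction, seed = seed)
  }
  if (is.null(lasso_params)) {
    lasso_params <- lasso_clock_params(split_fraction = split_fraction, seed = seed)
  }
  structure(as.list(environment()), class = "analysis_config")
}

#' Load an exported cohort from disk
#'
#' Reads the metadata table plus one read-level TSV (and, if present, one
#' coverage file) per sample, as written by [export_cohort()].
#'
#' @param dir Directory holding `metadata.tsv`, `<id>.reads.tsv` and
#'   optionally `<id>.cov.tsv`.
#' @return A cohort list (`samples`, `metadata`) compatible with the
#'   pipeline functions.
#' @export
load_cohort <- function(dir) {
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  samples <- vector("list", nrow(meta))
  names(samples) <- meta$sample_id
  for (i in seq_len(nrow(meta))) {
    id <- meta$sample_id[i]
    rp <- file.path(dir, sprintf("%s.reads.tsv", id))
    if (!file.exists(rp)) stop("missing read-level file for sample ", id)
    samples[[i]] <- list(sample_id = id, age = meta$age[i],
                         calls = read_readlevel_records(rp))
  }
  list(samples = samples, metadata = meta)
}

cohort_coverage <- function(cohort) {
  lapply(cohort$samples, function(s) reads_to_coverage(s$calls))
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Score a whole cohort under one metric
#'
#' @param cohort Cohort list (see [simulate_cohort()] / [load_cohort()]).
#' @param metric Metric name.
#' @param params [metric_params()].
#' @return Locus-by-sample score matrix.
#' @export
score_cohort <- function(cohort, metric, params = metric_params()) {
  sl <- lapply(cohort$samples, function(s) score_sample(s$calls, metric, params))
  assemble_score_matrix(sl, metric)
}

#' Run the WSH clock pipeline for all five metrics
#'
#' Per metric: score every sample, assemble the score matrix, Spearman
#' correlation with age, subset selection, and a random-forest clock on the
#' `high` subset. Metrics whose `high` subset has fewer than 2 loci are
#' skipped with a warning.
#'
#' @param cohort Cohort list.
#' @param config [analysis_config()].
#' @param metrics Metrics to run (default all five).
#' @param verbose Log filter-stage counts (default FALSE).
#' @return A run report: per-metric locus counts at each stage, model
#'   summaries and evaluations, plus provenance (config seed).
#' @export
run_wsh_pipeline <- function(cohort, config = analysis_config(),
                             metrics = wsh_metric_names(), verbose = FALSE) {
  ages <- cohort$metadata$age
  sections <- list()
  matrices <- list()
  for (metric in metrics) {
    mat <- score_cohort(cohort, metric, config$metric_params)
    rec <- correlate_with_age(mat, ages, method = "spearman")
    sel <- select_loci(rec, config$cor_low, config$cor_high, config$padj_max)
    pipeline_log(verbose, "[%s] %d loci -> %d tested -> %d high", metric,
                 nrow(mat), nrow(rec), length(sel$high))
    section <- list(metric = metric,
                    n_loci = nrow(mat), n_tested = nrow(rec),
                    n_negative = length(sel$negative),
                    n_positive = length(sel$positive),
                    n_high = length(sel$high),
                    subsets = sel[c("negative", "positive", "high")])
    if (length(sel$high) >= 2L) {
      fit <- fit_wsh_rf_clock(mat, ages, sel$high, config$rf_params)
      section$model <- list(best = fit$best,
                            cv = fit$cv[c("mae", "mae_sd", "r2", "r2_sd")],
                            test = fit$test[c("mae", "r2", "r2_cor", "n")])
      section$fit <- fit
    } else {
      warning(sprintf("metric %s: high subset has %d loci; clock skipped",
                      metric, length(sel$high)))
    }
    sections[[metric]] <- section
    matrices[[metric]] <- mat
  }
  list(kind = "wsh", metrics = sections, matrices = matrices,
       provenance = list(seed = config$seed,
                         thresholds = c(config$cor_low, config$cor_high,
                                        config$padj_max)))
}

#' Run the region clock pipeline for every window scheme
#'
#' Per scheme: segment the genome, compute the window methylation matrix,
#' deduplicate identical rows, Pearson-filter windows against age, and fit
#' a LASSO clock. Schemes with fewer than 2 surviving windows are skipped
#' with a warning.
#'
#' @param cohort Cohort list (coverage is aggregated from reads when no
#'   coverage tables are attached).
#' @param chrom_sizes Chromosome-sizes table for segmentation.
#' @param config [analysis_config()].
#' @param verbose Log filter-stage counts.
#' @return Run report with one section per scheme and a Table-4-shaped
#'   `summary` (scheme, CV and test R^2/MAE, non-zero coefficient count).
#' @export
run_region_pipeline <- function(cohort, chrom_sizes, config = analysis_config(),
                                verbose = FALSE) {
  ages <- cohort$metadata$age
  cov_list <- cohort_coverage(cohort)
  sections <- list()
  rows <- list()
  for (label in names(config$schemes)) {
    scheme <- config$schemes[[label]]
    windows <- segment_genome(chrom_sizes, scheme)
    mat <- window_average_methylation(cov_list, windows, config$min_cov)
    n_before_dedup <- nrow(mat)
    mat <- deduplicate_windows(mat)
    rec <- correlate_with_age(mat, ages, method = "pearson")
    sig <- rec$locus[!is.na(rec$p_adj) & rec$p_adj < config$padj_max &
                       abs(rec$coefficient) >= config$cor_high]
    pipeline_log(verbose, "[%s] %d windows -> %d determined -> %d dedup -> %d correlated",
                 label, nrow(windows), n_before_dedup, nrow(mat), length(sig))
    section <- list(scheme = label, n_windows = nrow(windows),
                    n_determined = n_before_dedup, n_dedup = nrow(mat),
                    n_correlated = length(sig), selected_windows = sig)
    if (length(sig) >= 2L) {
      fit <- fit_region_lasso_clock(mat, ages, sig, config$lasso_params)
      section$model <- list(lambda = fit$lambda, n_nonzero = fit$n_nonzero,
                            cv = fit$cv[c("mae", "r2")],
                            train = fit$train[c("mae", "r2")],
                            test = fit$test[c("mae", "r2", "n")])
      section$fit <- fit
      section$matrix <- mat
      rows[[label]] <- data.table::data.table(
        scheme = label, cv_r2 = fit$cv$r2, cv_mae = fit$cv$mae,
        test_r2 = fit$test$r2, test_mae = fit$test$mae,
        n_nonzero = fit$n_nonzero)
    } else {
      warning(sprintf("scheme %s: only %d correlated windows; clock skipped",
                      label, length(sig)))
      rows[[label]] <- data.table::data.table(
        scheme = label, cv_r2 = NA_real_, cv_mae = NA_real_,
        test_r2 = NA_real_, test_mae = NA_real_, n_nonzero = NA_integer_)
    }
    sections[[label]] <- section
  }
  list(kind = "region", schemes = sections,
       summary = data.table::rbindlist(rows),
       provenance = list(seed = config$seed, min_cov = config$min_cov))
}

#' Parse locus keys into genomic intervals
#'
#' Keys are `chrom:pos` (single-CpG anchors) or `chrom:p1.p2.p3.p4`
#' (epipolymorphism quartets). The interval spans the anchor positions.
#'
#' @param keys Character vector of locus keys.
#' @return `data.table` with `locus`, `chrom`, `start_pos`, `end_pos`
#'   (1-based, inclusive).
#' @export
parse_locus_keys <- function(keys) {
  sp <- strsplit(keys, ":", fixed = TRUE)
  chrom <- vapply(sp, `[[`, character(1L), 1L)
  pos_part <- vapply(sp, `[[`, character(1L), 2L)
  pl <- lapply(strsplit(pos_part, ".", fixed = TRUE), as.integer)
  data.table::data.table(locus = keys, chrom = chrom,
                         start_pos = vapply(pl, min, integer(1L)),
                         end_pos = vapply(pl, max, integer(1L)))
}

loci_in_windows <- function(locus_keys, windows) {
  if (length(locus_keys) == 0L || nrow(windows) == 0L) return(character())
  li <- parse_locus_keys(locus_keys)
  win <- data.table::as.data.table(windows)
  hit <- logical(nrow(li))
  for (i in seq_len(nrow(li))) {
    # any-overlap between 0-based locus interval [start-1, end) and window [s, e)
    w <- win[win$chrom == li$chrom[i]]
    hit[i] <- any(li$start_pos[i] - 1L < w$end & li$end_pos[i] > w$start)
  }
  li$locus[hit]
}

#' WSH clock restricted to age-correlated windows
#'
#' Reciprocal filtering, direction 1: the metric's highly correlated loci
#' are restricted to those overlapping the age-correlated windows of a
#' region run, and a random-forest clock is fitted on the intersection.
#'
#' @param mat The metric's score matrix.
#' @param ages Ages aligned with columns.
#' @param high_loci The metric's `high` locus keys.
#' @param selected_windows Window table (`chrom`, `start`, `end`) of the
#'   age-correlated windows from the region run.
#' @param config [analysis_config()].
#' @return Report list; if the intersection is empty or has fewer than 2
#'   loci, `empty_intersection` is TRUE and no model is fitted.
#' @export
run_combined_wsh_on_windows <- function(mat, ages, high_loci, selected_windows,
                                        config = analysis_config()) {
  keep <- loci_in_windows(high_loci, selected_windows)
  out <- list(kind = "combined_wsh_on_windows",
              n_high = length(high_loci), n_in_windows = length(keep),
              loci = keep, empty_intersection = length(keep) < 2L)
  if (!out$empty_intersection) {
    fit <- fit_wsh_rf_clock(mat, ages, keep, config$rf_params)
    out$model <- list(best = fit$best, cv = fit$cv[c("mae", "r2")],
                      test = fit$test[c("mae", "r2", "n")])
    out$fit <- fit
  }
  out
}

#' Region clock restricted to windows overlapping heterogeneity loci
#'
#' Reciprocal filtering, direction 2: a scheme's age-correlated windows are
#' restricted to those overlapping a metric's highly correlated loci, and a
#' LASSO clock is fitted on the remaining windows.
#'
#' @param mat Window methylation matrix (rownames `chrom:start-end`).
#' @param ages Ages aligned with columns.
#' @param selected_windows Character keys of the scheme's age-correlated
#'   windows.
#' @param high_loci The metric's `high` locus keys.
#' @param config [analysis_config()].
#' @export
run_combined_region_on_loci <- function(mat, ages, selected_windows, high_loci,
                                        config = analysis_config()) {
  win <- parse_window_keys(selected_windows)
  li <- parse_locus_keys(high_loci)
  keep <- logical(nrow(win))
  for (i in seq_len(nrow(win))) {
    l <- li[li$chrom == win$chrom[i]]
    keep[i] <- any(l$start_pos - 1L < win$end[i] & l$end_pos > win$start[i])
  }
  feats <- selected_windows[keep]
  out <- list(kind = "combined_region_on_loci",
              n_selected = length(selected_windows),
              n_overlapping = length(feats), windows = feats,
              empty_intersection = length(feats) < 2L)
  if (!out$empty_intersection) {
    fit <- fit_region_lasso_clock(mat, ages, feats, config$lasso_params)
    out$model <- list(lambda = fit$lambda, n_nonzero = fit$n_nonzero,
                      cv = fit$cv[c("mae", "r2")], test = fit$test[c("mae", "r2", "n")])
    out$fit <- fit
  }
  out
}

#' Parse window keys (`chrom:start-end`) into a window table
#' @param keys Character vector of window keys.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open).
#' @export
parse_window_keys <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+)$", keys))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed window key: ", keys[bad][1L])
  data.table::data.table(window = keys,
                         chrom = vapply(m, `[[`, character(1L), 2L),
                         start = as.integer(vapply(m, `[[`, character(1L), 3L)),
                         end = as.integer(vapply(m, `[[`, character(1L), 4L)))
}

# Strip model objects so a report can be serialized deterministically.
report_for_json <- function(report) {
  scrub <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      x$fit <- NULL; x$matrix <- NULL
      lapply(x, scrub)
    } else x
  }
  scrub(report)
}

#' Serialize a run report to canonical JSON
#'
#' Model objects and matrices are dropped; counts, subsets and evaluations
#' are kept. Identical runs produce identical JSON strings.
#'
#' @param report A pipeline report.
#' @param path Optional output path.
#' @return The JSON string, invisibly if `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  report <- report_for_json(report)
  report$matrices <- NULL
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
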