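# Synthetic RRBS cohort generator. Produces an age-annotated cohort of
# read-level methylomes with planted loci of four classes:
#   het_pos / het_neg - heterogeneity loci: reads are coherent haplotypes
#       (all-M with probability p_locus, else all-U) whose calls are then
#       flipped independently with an age-dependent probability
#       eps(age) = clamp(eps0 + b1*a + b2*a^2, 0, 0.5), a = normalised age;
#       het_neg uses the reversed age axis. Growing eps raises PDR, PM,
#       FDRP and qFDRP and lowers MHL, so one dial drives all five metrics.
#   mean_drift - per-CpG per-read Bernoulli calls with a logit-linear
#       age-dependent methylation probability (average methylation moves
#       with age, as a window-based clock requires).
#   null - haplotype loci with age-constant parameters.
# Loci live on a toy two-chromosome genome, spaced >= 2 kb so that window
# segmentation assigns loci to windows unambiguously.

#' Configuration of a synthetic RRBS cohort
#'
#' Defaults state the world the simulator emulates: a human-blood-like
#' cohort of 180 donors aged 19-56 years, loci of 6 CpGs with
#' negative-binomial read depth around 30x, reads spanning 4-6 CpGs.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_samples Number of donors (default 180).
#' @param age_low,age_high Age range in years (defaults 19 and 56).
#' @param n_loci_het_pos,n_loci_het_neg Numbers of planted heterogeneity
#'   loci with increasing/decreasing disorder (defaults 50 each).
#' @param n_loci_mean Mean-methylation drift loci (default 50).
#' @param n_loci_null Null loci with age-constant parameters (default 500).
#' @param cpgs_per_locus CpGs per locus (default 6).
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size
#'   for reads per locus per sample (defaults 30 and 8).
#' @param read_span_cpgs Range of CpGs covered by one read (default 4:6).
#' @param disorder_link Numeric `c(eps0, b1, b2)` of the flip-probability
#'   link (default `c(0.05, 0.25, -0.10)`: disorder rises fast in youth and
#'   saturates, mirroring a quadratic global trend).
#' @param mean_link Numeric `c(mu0, gamma)` of the logit-linear methylation
#'   probability for drift loci (default `c(-1, 2)`).
#' @param cpg_spacing_bp Distance between CpGs within a locus (default 15).
#' @param locus_spacing_bp Distance between locus starts (default 2000).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_samples = 180L,
                              age_low = 19, age_high = 56,
                              n_loci_het_pos = 50L, n_loci_het_neg = 50L,
                              n_loci_mean = 50L, n_loci_null = 500L,
                              cpgs_per_locus = 6L,
                              coverage_mean = 30, coverage_dispersion = 8,
                              read_span_cpgs = 4:6,
                              disorder_link = c(0.05, 0.25, -0.10),
                              mean_link = c(-1, 2),
                              cpg_spacing_bp = 15L, locus_spacing_bp = 2000L) {
  if (n_samples < 1L) stop("degenerate config: n_samples must be >= 1")
  n_loci <- n_loci_het_pos + n_loci_het_neg + n_loci_mean + n_loci_null
  if (n_loci < 1L) stop("degenerate config: at least one locus required")
  if (age_low >= age_high) stop("age_low must be < age_high")
  stopifnot(cpgs_per_locus >= 1L, coverage_mean > 0, coverage_dispersion > 0,
            all(read_span_cpgs >= 1L), length(disorder_link) == 3L,
            length(mean_link) == 2L)
  structure(as.list(environment())[setdiff(ls(), c("n_loci"))],
            class = "simulation_config")
}

disorder_eps <- function(a, link) {
  pmin(pmax(link[1L] + link[2L] * a + link[3L] * a^2, 0), 0.5)
}

# Locus map on the toy genome: loci alternate between chrSim1 and chrSim2.
build_locus_map <- function(config) {
  n <- config$n_loci_het_pos + config$n_loci_het_neg + config$n_loci_mean +
    config$n_loci_null
  cls <- rep(c("het_pos", "het_neg", "mean_drift", "null"),
             times = c(config$n_loci_het_pos, config$n_loci_het_neg,
                       config$n_loci_mean, config$n_loci_null))
  chrom <- rep(c("chrSim1", "chrSim2"), length.out = n)
  idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- 10000L + (idx_on_chrom - 1L) * config$locus_spacing_bp
  data.table::data.table(
    locus_id = sprintf("L%04d", seq_len(n)),
    class = cls, chrom = chrom, start = start,
    cpg_pos = lapply(start, function(s) s + (seq_len(config$cpgs_per_locus) - 1L) *
                       config$cpg_spacing_bp))
}

#' Chromosome sizes of the simulated toy genome
#'
#' @param config A [simulation_config()].
#' @return `data.table` with `chrom` and `size` (bp), covering every locus.
#' @export
simulated_chrom_sizes <- function(config) {
  map <- build_locus_map(config)
  chrom <- NULL
  sz <- map[, list(size = max(start) + config$cpgs_per_locus *
                     config$cpg_spacing_bp + 10000L), by = "chrom"]
  data.table::setnames(sz, c("chrom", "size"))
  sz
}

simulate_locus_reads <- function(n_reads, cpg_pos, class, p_locus, eps, p_meth,
                                 span_range) {
  k <- length(cpg_pos)
  spans <- if (length(span_range) == 1L) rep.int(span_range, n_reads)
           else sample(span_range, n_reads, replace = TRUE)
  spans <- pmin(spans, k)
  starts <- floor(stats::runif(n_reads) * (k - spans + 1L)) + 1L
  idx <- sequence(spans, from = starts)   # per-read contiguous CpG indices
  total <- length(idx)
  if (class == "mean_drift") {
    st <- stats::rbinom(total, 1L, p_meth)
  } else {
    hap <- rep.int(stats::rbinom(n_reads, 1L, p_locus), spans)
    flip <- stats::rbinom(total, 1L, eps)
    st <- as.integer(hap != flip)
  }
  list(pos = cpg_pos[idx], state = st, n_calls = spans)
}

#' Simulate an age-annotated RRBS cohort
#'
#' Ages are drawn uniformly on `[age_low, age_high]`. Each sample receives
#' negative-binomially many reads per locus, generated by the per-class
#' models described in [simulation_config()]. Fully reproducible from the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   * `samples`: named list per sample of `list(sample_id, age, calls)`
#'     where `calls` is a calls table;
#'   * `metadata`: `data.table(sample_id, age)`;
#'   * `truth`: per-locus `data.table` of class labels and planted
#'     parameters;
#'   * `loci`: locus map (chromosome, start, CpG positions);
#'   * `config`: the input configuration.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  map <- build_locus_map(config)
  n_loci <- nrow(map)
  # locus-level planted parameters, fixed across samples
  map$p_locus <- stats::runif(n_loci, 0.3, 0.7)
  gamma_sign <- rep_len(c(1, -1), n_loci)
  map$gamma <- ifelse(map$class == "mean_drift", gamma_sign * config$mean_link[2L], 0)
  ages <- stats::runif(config$n_samples, config$age_low, config$age_high)
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  eps0 <- disorder_eps(0, config$disorder_link)  # null / baseline disorder
  samples <- vector("list", config$n_samples)
  names(samples) <- sample_ids
  for (s in seq_len(config$n_samples)) {
    a <- (ages[s] - config$age_low) / (config$age_high - config$age_low)
    n_reads <- stats::rnbinom(n_loci, mu = config$coverage_mean,
                              size = config$coverage_dispersion)
    pos_l <- vector("list", n_loci); st_l <- vector("list", n_loci)
    ncall_l <- vector("list", n_loci)
    read_counter <- 0L
    first_id <- integer(n_loci)
    for (i in seq_len(n_loci)) {
      first_id[i] <- read_counter + 1L
      if (n_reads[i] == 0L) next
      cls <- map$class[i]
      eps <- switch(cls,
                    het_pos = disorder_eps(a, config$disorder_link),
                    het_neg = disorder_eps(1 - a, config$disorder_link),
                    null = eps0,
                    0)
      p_meth <- if (cls == "mean_drift") {
        stats::plogis(config$mean_link[1L] + map$gamma[i] * a)
      } else NA_real_
      rr <- simulate_locus_reads(n_reads[i], map$cpg_pos[[i]], cls,
                                 map$p_locus[i], eps, p_meth,
                                 config$read_span_cpgs)
      read_counter <- read_counter + n_reads[i]
      pos_l[[i]] <- rr$pos; st_l[[i]] <- rr$state; ncall_l[[i]] <- rr$n_calls
    }
    ncalls <- unlist(ncall_l)
    calls <- data.table::data.table(
      read_id = rep.int(sprintf("%s_r%06d", sample_ids[s], seq_len(read_counter)),
                        ncalls),
      chrom = rep.int(map$chrom, vapply(pos_l, length, integer(1L))),
      pos = unlist(pos_l),
      state = unlist(st_l))
    samples[[s]] <- list(sample_id = sample_ids[s], age = ages[s], calls = calls)
  }
  truth <- map[, c("locus_id", "class", "chrom", "start", "p_locus", "gamma")]
  truth$eps_young <- ifelse(truth$class == "het_pos", disorder_eps(0, config$disorder_link),
                     ifelse(truth$class == "het_neg", disorder_eps(1, config$disorder_link),
                            eps0))
  truth$eps_old <- ifelse(truth$class == "het_pos", disorder_eps(1, config$disorder_link),
                   ifelse(truth$class == "het_neg", disorder_eps(0, config$disorder_link),
                          eps0))
  list(samples = samples,
       metadata = data.table::data.table(sample_id = sample_ids, age = ages),
       truth = truth,
       loci = map,
       config = config)
}

#' Export a simulated cohort to methylome_io formats
#'
#' Writes one read-level TSV and one Bismark coverage file per sample plus a
#' metadata TSV, all readable by the package's own readers. Coverage files
#' are exact per-CpG aggregations of the read-level files.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of written paths.
#' @export
export_cohort <- function(cohort, outdir) {
  if (length(cohort$samples) == 0L) stop("empty sample list")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("unwritable path: ", outdir)
  paths <- list(reads = character(), coverage = character())
  for (s in cohort$samples) {
    rp <- file.path(outdir, sprintf("%s.reads.tsv", s$sample_id))
    cp <- file.path(outdir, sprintf("%s.cov.tsv", s$sample_id))
    write_readlevel_records(s$calls, rp)
    write_bismark_coverage(reads_to_coverage(s$calls), cp)
    paths$reads <- c(paths$reads, rp)
    paths$coverage <- c(paths$coverage, cp)
  }
  mp <- file.path(outdir, "metadata.tsv")
  write_sample_metadata(cohort$metadata, mp)
  paths$metadata <- mp
  tp <- file.path(outdir, "truth.tsv")
  truth_flat <- cohort$truth
  data.table::fwrite(truth_flat, tp, sep = "\t", quote = FALSE)
  paths$truth <- tp
  invisible(paths)
}
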