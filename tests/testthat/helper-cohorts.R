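# Shared simulated cohorts, built once per test run and memoised.

.cohort_cache <- new.env(parent = emptyenv())

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# Small cohort for unit-level pipeline tests (seconds to score).
small_cohort <- function() {
  cached("small", simulate_cohort(simulation_config(
    seed = 11L, n_samples = 24L, n_loci_het_pos = 6L, n_loci_het_neg = 6L,
    n_loci_mean = 6L, n_loci_null = 30L)))
}

# The default stated-world cohort used by the acceptance criteria.
acceptance_cohort <- function() {
  cached("acceptance", simulate_cohort(simulation_config(seed = 42L)))
}

acceptance_pdr_matrix <- function() {
  cached("acceptance_pdr", score_cohort(acceptance_cohort(), "PDR"))
}

# Map anchor-locus keys back to simulated locus classes via the truth table.
locus_class_of <- function(keys, cohort) {
  li <- parse_locus_keys(keys)
  tr <- cohort$truth
  spacing <- cohort$config$locus_spacing_bp
  vapply(seq_len(nrow(li)), function(i) {
    j <- which(tr$chrom == li$chrom[i] & tr$start <= li$start_pos[i] &
                 tr$start + spacing > li$start_pos[i])
    if (length(j)) tr$class[j[1L]] else NA_character_
  }, character(1L))
}

locus_id_of <- function(keys, cohort) {
  li <- parse_locus_keys(keys)
  tr <- cohort$truth
  spacing <- cohort$config$locus_spacing_bp
  vapply(seq_len(nrow(li)), function(i) {
    j <- which(tr$chrom == li$chrom[i] & tr$start <= li$start_pos[i] &
                 tr$start + spacing > li$start_pos[i])
    if (length(j)) tr$locus_id[j[1L]] else NA_character_
  }, character(1L))
}

cohort_coverage_test <- function(co) {
  lapply(co$samples, function(s) reads_to_coverage(s$calls))
}
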