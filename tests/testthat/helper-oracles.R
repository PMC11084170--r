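# Independent brute-force oracles for the five WSH kernels. These are
# written as literal enumerations (explicit loops over reads, pairs and
# substrings) and share no code with the package implementations.

oracle_pdr <- function(reads, min_cpgs = 4L, min_depth = 10L) {
  elig <- Filter(function(r) length(r$state) >= min_cpgs, reads)
  if (length(elig) < min_depth) return(NA_real_)
  disc <- 0L
  for (r in elig) {
    has_m <- FALSE; has_u <- FALSE
    for (s in r$state) {
      if (s == 1L) has_m <- TRUE else has_u <- TRUE
    }
    if (has_m && has_u) disc <- disc + 1L
  }
  disc / length(elig)
}

oracle_pm <- function(reads, quartet, min_depth = 10L) {
  pats <- character()
  for (r in reads) {
    st <- character(4L)
    ok <- TRUE
    for (k in 1:4) {
      w <- which(r$pos == quartet[k])
      if (length(w) == 0L) { ok <- FALSE; break }
      st[k] <- as.character(r$state[w])
    }
    if (ok) pats <- c(pats, paste(st, collapse = ""))
  }
  if (length(pats) < min_depth) return(NA_real_)
  freqs <- table(pats) / length(pats)
  1 - sum(freqs^2)
}

oracle_mhl <- function(reads, min_depth = 10L) {
  if (length(reads) < min_depth) return(NA_real_)
  L <- max(vapply(reads, function(r) length(r$state), integer(1L)))
  num <- 0; den <- 0
  for (l in seq_len(L)) {
    n_sub <- 0L; n_meth <- 0L
    for (r in reads) {
      k <- length(r$state)
      if (k < l) next
      for (start in 1:(k - l + 1L)) {
        n_sub <- n_sub + 1L
        if (all(r$state[start:(start + l - 1L)] == 1L)) n_meth <- n_meth + 1L
      }
    }
    if (n_sub > 0L) {
      num <- num + l * (n_meth / n_sub)
      den <- den + l
    }
  }
  num / den
}

oracle_pair_discordance <- function(r1, r2, anchor, window) {
  shared <- 0L; differing <- 0L
  for (k in seq_along(r1$pos)) {
    p <- r1$pos[k]
    if (abs(p - anchor) > window) next
    w <- which(r2$pos == p)
    if (length(w) == 0L || abs(r2$pos[w] - anchor) > window) next
    shared <- shared + 1L
    if (r1$state[k] != r2$state[w]) differing <- differing + 1L
  }
  c(shared = shared, differing = differing)
}

oracle_fdrp <- function(reads, anchor, window = 50L, min_depth = 10L) {
  n <- length(reads)
  if (n < min_depth) return(NA_real_)
  n_pairs <- 0L; n_disc <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- oracle_pair_discordance(reads[[i]], reads[[j]], anchor, window)
      if (d["shared"] >= 1L) {
        n_pairs <- n_pairs + 1L
        if (d["differing"] > 0L) n_disc <- n_disc + 1L
      }
    }
  }
  if (n_pairs == 0L) return(NA_real_)
  n_disc / n_pairs
}

oracle_qfdrp <- function(reads, anchor, window = 50L, min_depth = 10L) {
  n <- length(reads)
  if (n < min_depth) return(NA_real_)
  vals <- numeric()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- oracle_pair_discordance(reads[[i]], reads[[j]], anchor, window)
      if (d["shared"] >= 1L) vals <- c(vals, d["differing"] / d["shared"])
    }
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

# Random small read set for oracle-equivalence checks. All reads carry a
# call at the anchor CpG; positions come from a pool of <= 8 CpGs spread
# over ~110 bp so the FDRP window restriction is exercised.
random_read_set <- function(seed, max_reads = 12L, max_cpgs = 8L) {
  set.seed(seed)
  n_cpgs <- sample(2:max_cpgs, 1L)
  pool <- sort(sample(seq(101L, 211L, by = 10L), n_cpgs))
  anchor <- sample(pool, 1L)
  n_reads <- sample(2:max_reads, 1L)
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    others <- setdiff(pool, anchor)
    extra <- if (length(others)) {
      k <- sample.int(length(others) + 1L, 1L) - 1L
      if (k > 0) others[sample.int(length(others), k)] else integer()
    } else integer()
    pos <- sort(c(anchor, extra))
    reads[[i]] <- list(pos = pos,
                       state = sample(c(0L, 1L), length(pos), replace = TRUE))
  }
  list(reads = reads, anchor = anchor, pool = pool)
}

# Build a calls table from a list of reads on one chromosome.
reads_to_calls <- function(reads, chrom = "chr1") {
  data.table::rbindlist(lapply(seq_along(reads), function(i) {
    data.table::data.table(read_id = sprintf("r%03d", i), chrom = chrom,
                           pos = reads[[i]]$pos, state = reads[[i]]$state)
  }))
}

# n identical reads over the given positions with the given states.
uniform_reads <- function(n, pos, states) {
  replicate(n, list(pos = pos, state = states), simplify = FALSE)
}
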