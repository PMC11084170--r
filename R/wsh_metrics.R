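# Within-sample heterogeneity (WSH) scores computed from read-level
# methylation calls. Five metrics are implemented:
#   PDR   - proportion of discordant reads (methylation erosion)
#   PM    - epipolymorphism over 4-CpG windows (cell-type heterogeneity)
#   MHL   - methylation haplotype load (co-methylation conservation)
#   FDRP  - fraction of discordant read pairs at a CpG
#   qFDRP - mean normalised Hamming distance over read pairs at a CpG
# All scores live in [0,1]. The anchor unit is a single CpG site except for
# PM, whose unit is a window of four consecutive covered CpGs.

#' Parameters for WSH score computation
#'
#' @param min_depth Minimum number of (eligible/covering) reads required to
#'   emit a score; loci below this depth yield `NA`. Default 10.
#' @param pdr_min_cpgs_per_read Minimum number of CpG calls a read must carry
#'   to enter the PDR computation. Default 4.
#' @param fdrp_max_reads Cap on the number of reads whose pairs are
#'   enumerated for FDRP/qFDRP; deeper loci are deterministically
#'   subsampled. Default 40. `Inf` disables subsampling.
#' @param fdrp_window_bp Only CpGs within this many base pairs of the anchor
#'   CpG enter a pair comparison. Default 50.
#' @param rng_seed Seed controlling pair subsampling (combined with the
#'   anchor position so every locus has its own reproducible draw).
#' @return A list of class `metric_params`.
#' @export
metric_params <- function(min_depth = 10L, pdr_min_cpgs_per_read = 4L,
                          fdrp_max_reads = 40L, fdrp_window_bp = 50L,
                          rng_seed = 1L) {
  stopifnot(min_depth >= 2L, pdr_min_cpgs_per_read >= 1L,
            fdrp_max_reads >= 2L, fdrp_window_bp >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 pdr_min_cpgs_per_read = as.integer(pdr_min_cpgs_per_read),
                 fdrp_max_reads = fdrp_max_reads,
                 fdrp_window_bp = as.numeric(fdrp_window_bp),
                 rng_seed = as.integer(rng_seed)),
            class = "metric_params")
}

wsh_metric_names <- function() c("PDR", "PM", "MHL", "FDRP", "qFDRP")

# Convert a calls table (read_id/chrom/pos/state) into a list of reads, each
# a list(pos = integer, state = integer 0/1), in file order.
#' Split a calls table into per-read records
#' @param calls A calls table (see [read_readlevel_records()]).
#' @return A named list of `list(pos, state)` per read, in first-appearance order.
#' @export
calls_to_reads <- function(calls) {
  calls <- data.table::as.data.table(calls)
  ids <- unique(calls$read_id)
  sp <- split(calls, factor(calls$read_id, levels = ids))
  lapply(sp, function(d) list(pos = d$pos, state = d$state))
}

# -- kernels -----------------------------------------------------------------
# Each kernel takes a list of reads assumed to satisfy its precondition
# (e.g. all reads span the anchor CpG) and returns a score in [0,1] or NA.

#' Proportion of discordant reads at a CpG
#'
#' A read is discordant if it carries both a methylated and an unmethylated
#' call. Only reads with at least `pdr_min_cpgs_per_read` calls are
#' eligible; the score is the discordant fraction among eligible reads, or
#' `NA` when fewer than `min_depth` reads are eligible.
#'
#' @param reads List of reads (`list(pos, state)`), all spanning the anchor.
#' @param params A [metric_params()] object.
#' @return Score in \[0,1\] or `NA`.
#' @export
compute_pdr <- function(reads, params = metric_params()) {
  len <- lengths(lapply(reads, `[[`, "pos"))
  elig <- len >= params$pdr_min_cpgs_per_read
  if (sum(elig) < params$min_depth) return(NA_real_)
  mixed <- vapply(reads[elig], function(r) any(r$state == 1L) && any(r$state == 0L),
                  logical(1L))
  mean(mixed)
}

#' Epipolymorphism of a 4-CpG window
#'
#' One minus the sum of squared empirical frequencies of the 16 possible
#' 4-CpG methylation patterns (epialleles) among reads covering all four
#' anchor CpGs.
#'
#' @param reads List of reads, each covering all four quartet positions.
#' @param quartet Integer vector of the 4 strictly increasing CpG positions.
#' @inheritParams compute_pdr
#' @export
compute_pm <- function(reads, quartet, params = metric_params()) {
  stopifnot(length(quartet) == 4L, !is.unsorted(quartet, strictly = TRUE))
  pat <- vapply(reads, function(r) {
    s <- r$state[match(quartet, r$pos)]
    if (anyNA(s)) return(NA_integer_)
    sum(s * c(8L, 4L, 2L, 1L))
  }, integer(1L))
  pat <- pat[!is.na(pat)]
  if (length(pat) < params$min_depth) return(NA_real_)
  p <- tabulate(pat + 1L, nbins = 16L) / length(pat)
  1 - sum(p^2)
}

#' Methylation haplotype load at a CpG
#'
#' Over the reads spanning the anchor CpG, for each substring length l the
#' fraction M_l of contiguous all-methylated call substrings of length l is
#' computed across reads; the score is the weighted mean sum(l * M_l) /
#' sum(l), summed over lengths with at least one observed substring.
#' Substrings never bridge the gap between two reads.
#'
#' @inheritParams compute_pdr
#' @export
compute_mhl <- function(reads, params = metric_params()) {
  if (length(reads) < params$min_depth) return(NA_real_)
  L <- max(lengths(lapply(reads, `[[`, "pos")))
  m_l <- numeric(L); tot_l <- numeric(L)
  for (r in reads) {
    k <- length(r$state)
    runs <- rle(r$state)
    mruns <- runs$lengths[runs$values == 1L]
    for (l in seq_len(k)) {
      tot_l[l] <- tot_l[l] + (k - l + 1L)
      if (length(mruns)) m_l[l] <- m_l[l] + sum(pmax(mruns - l + 1L, 0L))
    }
  }
  obs <- tot_l > 0
  w <- seq_len(L)[obs]
  sum(w * (m_l[obs] / tot_l[obs])) / sum(w)
}

# Deterministic subsample of k out of n indices, seeded by (rng_seed, anchor)
# without disturbing the caller's RNG stream.
subsample_indices <- function(n, k, rng_seed, anchor) {
  if (n <= k) return(seq_len(n))
  seed <- (as.double(rng_seed) * 48271 + as.double(anchor)) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sort(sample.int(n, k))
}

fdrp_pair_stats <- function(reads, anchor, params) {
  n <- length(reads)
  keep <- subsample_indices(n, params$fdrp_max_reads, params$rng_seed, anchor)
  reads <- reads[keep]
  n <- length(reads)
  w <- params$fdrp_window_bp
  reads <- lapply(reads, function(r) {
    sel <- abs(r$pos - anchor) <= w
    list(pos = r$pos[sel], state = r$state[sel])
  })
  upos <- sort(unique(unlist(lapply(reads, `[[`, "pos"))))
  X <- matrix(NA_integer_, n, length(upos))
  for (i in seq_len(n)) X[i, match(reads[[i]]$pos, upos)] <- reads[[i]]$state
  S <- !is.na(X)
  M <- X; M[!S] <- 0L
  U <- S - M                       # 1 where observed and unmethylated
  shared <- tcrossprod(S * 1L)
  ndiff <- tcrossprod(M, U) + tcrossprod(U, M)
  iu <- upper.tri(shared)
  sh <- shared[iu]; nd <- ndiff[iu]
  ok <- sh >= 1L
  list(n_pairs = sum(ok),
       fdrp = if (any(ok)) mean(nd[ok] > 0L) else NA_real_,
       qfdrp = if (any(ok)) mean(nd[ok] / sh[ok]) else NA_real_)
}

#' Fraction of discordant read pairs at a CpG
#'
#' All unordered pairs among the covering reads (deterministically
#' subsampled to at most `fdrp_max_reads`) are compared at their shared
#' CpGs within `fdrp_window_bp` of the anchor; a pair is discordant if it
#' differs at one or more shared CpGs. The score is the discordant fraction
#' over pairs sharing at least one CpG.
#'
#' @inheritParams compute_pdr
#' @param anchor The anchor CpG position (1-based).
#' @export
compute_fdrp <- function(reads, anchor, params = metric_params()) {
  if (length(reads) < params$min_depth) return(NA_real_)
  fdrp_pair_stats(reads, anchor, params)$fdrp
}

#' Quantitative fraction of discordant read pairs at a CpG
#'
#' Like [compute_fdrp()], but each pair contributes its normalised Hamming
#' distance (fraction of shared CpGs at which the two reads differ) instead
#' of a 0/1 discordance indicator; a concordant pair contributes 0.
#'
#' @inheritParams compute_fdrp
#' @export
compute_qfdrp <- function(reads, anchor, params = metric_params()) {
  if (length(reads) < params$min_depth) return(NA_real_)
  fdrp_pair_stats(reads, anchor, params)$qfdrp
}

# -- per-sample scoring ------------------------------------------------------

check_calls_sorted <- function(calls) {
  pos <- read_id <- chrom <- NULL
  bad <- calls[, list(bad = is.unsorted(pos, strictly = TRUE) ||
                        length(unique(chrom)) != 1L), by = "read_id"]
  if (any(bad$bad)) {
    stop("unsorted input: each read must have strictly increasing positions on one chromosome")
  }
}

#' Score every heterogeneity locus of one sample
#'
#' Enumerates anchor loci (every covered CpG; for PM, every run of four
#' consecutive covered CpGs) and applies the metric kernel. Vectorised fast
#' paths are used for PDR/PM/MHL; FDRP/qFDRP iterate anchors with matrix
#' pair enumeration. All paths agree with the exported kernels.
#'
#' @param calls Calls table of one sample.
#' @param metric One of `"PDR"`, `"PM"`, `"MHL"`, `"FDRP"`, `"qFDRP"`.
#' @param params A [metric_params()] object.
#' @return A `data.table` with columns `locus` (key string
#'   `chrom:pos` or `chrom:p1.p2.p3.p4` for PM), `chrom`, `score`; attribute
#'   `metric` records the metric. Loci below `min_depth` are omitted only if
#'   entirely uncovered; insufficient depth yields `NA` scores is not
#'   reported as a locus at all.
#' @export
score_sample <- function(calls, metric = wsh_metric_names(), params = metric_params()) {
  metric <- match.arg(metric)
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) {
    out <- data.table::data.table(locus = character(), chrom = character(), score = numeric())
    data.table::setattr(out, "metric", metric)
    return(out)
  }
  check_calls_sorted(calls)
  out <- switch(metric,
                PDR = score_pdr_sample(calls, params),
                PM = score_pm_sample(calls, params),
                MHL = score_mhl_sample(calls, params),
                FDRP = score_pairwise_sample(calls, params, "fdrp"),
                qFDRP = score_pairwise_sample(calls, params, "qfdrp"))
  data.table::setattr(out, "metric", metric)
  out[]
}

score_pdr_sample <- function(calls, params) {
  read_id <- chrom <- pos <- state <- n_calls <- mixed <- NULL
  rd <- calls[, list(n_calls = .N,
                     mixed = any(state == 1L) && any(state == 0L)), by = "read_id"]
  dt <- calls[rd, on = "read_id"][n_calls >= params$pdr_min_cpgs_per_read]
  res <- dt[, list(n = .N, disc = sum(mixed)), by = c("chrom", "pos")]
  res <- res[res$n >= params$min_depth]
  data.table::setorder(res, chrom, pos)
  data.table::data.table(locus = sprintf("%s:%d", res$chrom, res$pos),
                         chrom = res$chrom, score = res$disc / res$n)
}

score_mhl_sample <- function(calls, params) {
  read_id <- chrom <- pos <- state <- NULL
  # per unique methylation string: substring totals and all-M substring counts
  rd <- calls[, list(chrom = chrom[1L],
                     str = paste(state, collapse = "")), by = "read_id"]
  ustr <- unique(rd$str)
  per_str <- lapply(ustr, function(s) {
    st <- as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
    k <- length(st)
    runs <- rle(st)
    mruns <- runs$lengths[runs$values == 1L]
    l <- seq_len(k)
    m <- vapply(l, function(li) if (length(mruns)) sum(pmax(mruns - li + 1L, 0L)) else 0L,
                numeric(1L))
    data.table::data.table(l = l, m = m, tot = k - l + 1)
  })
  names(per_str) <- ustr
  str_tab <- data.table::rbindlist(per_str, idcol = "str")
  rd_l <- str_tab[rd, on = "str", allow.cartesian = TRUE]
  depth <- calls[, list(n_reads = .N), by = c("chrom", "pos")]
  dt <- calls[, list(read_id, chrom, pos)][rd_l[, list(read_id, l, m, tot)],
                                           on = "read_id", allow.cartesian = TRUE]
  agg <- dt[, list(m = sum(m), tot = sum(tot)), by = c("chrom", "pos", "l")]
  sc <- agg[, list(score = sum(l * (m / tot)) / sum(l)), by = c("chrom", "pos")]
  sc <- sc[depth, on = c("chrom", "pos")][n_reads >= params$min_depth]
  data.table::setorder(sc, chrom, pos)
  data.table::data.table(locus = sprintf("%s:%d", sc$chrom, sc$pos),
                         chrom = sc$chrom, score = sc$score)
}

score_pm_sample <- function(calls, params) {
  read_id <- chrom <- pos <- state <- idx <- NULL
  out <- vector("list", 0L)
  for (ch in unique(calls$chrom)) {
    dc <- calls[chrom == ch]
    covered <- sort(unique(dc$pos))
    if (length(covered) < 4L) next
    dc <- dc[order(read_id, pos)]
    dc[, "idx" := match(dc$pos, covered)]
    g <- dc[, {
      k <- .N
      if (k >= 4L) {
        j <- seq_len(k - 3L)
        ok <- idx[j + 3L] == idx[j] + 3L
        j <- j[ok]
        list(start_idx = idx[j],
             pattern = state[j] * 8L + state[j + 1L] * 4L + state[j + 2L] * 2L + state[j + 3L])
      } else list(start_idx = integer(), pattern = integer())
    }, by = "read_id"]
    if (nrow(g) == 0L) next
    qs <- g[, {
      n <- .N
      p <- tabulate(pattern + 1L, nbins = 16L) / n
      list(n = n, score = 1 - sum(p^2))
    }, by = "start_idx"]
    qs <- qs[qs$n >= params$min_depth]
    if (nrow(qs) == 0L) next
    p1 <- covered[qs$start_idx]; p2 <- covered[qs$start_idx + 1L]
    p3 <- covered[qs$start_idx + 2L]; p4 <- covered[qs$start_idx + 3L]
    out[[length(out) + 1L]] <- data.table::data.table(
      locus = sprintf("%s:%d.%d.%d.%d", ch, p1, p2, p3, p4),
      chrom = ch, score = qs$score)
  }
  if (length(out) == 0L) {
    return(data.table::data.table(locus = character(), chrom = character(), score = numeric()))
  }
  data.table::rbindlist(out)
}

score_pairwise_sample <- function(calls, params, which_stat) {
  read_id <- chrom <- pos <- NULL
  out <- vector("list", 0L)
  for (ch in unique(calls$chrom)) {
    dc <- calls[chrom == ch]
    data.table::setorder(dc, pos, read_id)
    posv <- dc$pos; readv <- dc$read_id; statev <- dc$state
    depth <- table(posv)
    anchors <- as.integer(names(depth)[depth >= params$min_depth])
    if (length(anchors) == 0L) next
    scores <- numeric(length(anchors))
    for (a in seq_along(anchors)) {
      p <- anchors[a]
      lo <- findInterval(p - params$fdrp_window_bp - 1e-9, posv) + 1L
      hi <- findInterval(p + params$fdrp_window_bp + 1e-9, posv)
      win_reads <- readv[lo:hi]; win_pos <- posv[lo:hi]; win_state <- statev[lo:hi]
      cov_reads <- win_reads[win_pos == p]
      keep <- subsample_indices(length(cov_reads), params$fdrp_max_reads,
                                params$rng_seed, p)
      cov_reads <- cov_reads[keep]
      ri <- match(win_reads, cov_reads)
      sel <- !is.na(ri)
      upos <- sort(unique(win_pos[sel]))
      n <- length(cov_reads)
      X <- matrix(NA_integer_, n, length(upos))
      X[cbind(ri[sel], match(win_pos[sel], upos))] <- win_state[sel]
      S <- !is.na(X)
      M <- X; M[!S] <- 0L
      U <- S - M
      shared <- tcrossprod(S * 1L)
      ndiff <- tcrossprod(M, U) + tcrossprod(U, M)
      iu <- upper.tri(shared)
      sh <- shared[iu]; nd <- ndiff[iu]
      ok <- sh >= 1L
      scores[a] <- if (!any(ok)) NA_real_
                   else if (which_stat == "fdrp") mean(nd[ok] > 0L)
                   else mean(nd[ok] / sh[ok])
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      locus = sprintf("%s:%d", ch, anchors), chrom = ch, score = scores)
  }
  if (length(out) == 0L) {
    return(data.table::data.table(locus = character(), chrom = character(), score = numeric()))
  }
  data.table::rbindlist(out)
}

#' Assemble per-sample scores into a locus-by-sample matrix
#'
#' Takes the union of loci across samples; cells are `NA` where a sample did
#' not emit the locus (insufficient depth or no coverage).
#'
#' @param score_list Named list (by sample id) of [score_sample()] outputs,
#'   all computed under the same metric.
#' @param metric Metric name; must match the attribute on every element.
#' @return Numeric matrix loci x samples with a `metric` attribute.
#' @export
assemble_score_matrix <- function(score_list, metric = NULL) {
  stopifnot(length(score_list) >= 1L, !is.null(names(score_list)))
  metrics <- vapply(score_list, function(s) attr(s, "metric") %||% NA_character_,
                    character(1L))
  if (is.null(metric)) metric <- metrics[[1L]]
  if (any(!is.na(metrics) & metrics != metric)) {
    stop("samples scored under different metrics cannot be assembled")
  }
  loci <- unique(unlist(lapply(score_list, `[[`, "locus")))
  mat <- matrix(NA_real_, nrow = length(loci), ncol = length(score_list),
                dimnames = list(loci, names(score_list)))
  for (j in seq_along(score_list)) {
    s <- score_list[[j]]
    mat[s$locus, j] <- s$score
  }
  attr(mat, "metric") <- metric
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
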