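# Genome segmentation into window sets and per-window average-methylation
# feature matrices computed from Bismark coverage files. Window coordinates
# are 0-based half-open (BED); CpG positions are 1-based (Bismark), so a CpG
# at position p lies in window [s, e) iff p - 1 is in [s, e).

#' Define a window scheme
#'
#' @param type `"fixed"` (consecutive non-overlapping bins) or `"sliding"`.
#' @param size Window width in bp.
#' @param step Step in bp (sliding only; default 20).
#' @return A list of class `window_scheme` with a `label` such as `"250bp"`
#'   or `"100_20"`.
#' @export
window_scheme <- function(type = c("fixed", "sliding"), size, step = 20L) {
  type <- match.arg(type)
  stopifnot(size >= 1L)
  label <- if (type == "fixed") sprintf("%dbp", as.integer(size))
           else sprintf("%d_%d", as.integer(size), as.integer(step))
  structure(list(type = type, size = as.integer(size),
                 step = if (type == "sliding") as.integer(step) else NA_integer_,
                 label = label),
            class = "window_scheme")
}

#' The 14 default window schemes
#'
#' Thirteen fixed bin sizes from 9 kb down to 100 bp plus a 100 bp sliding
#' window with 20 bp step.
#'
#' @return Named list of [window_scheme()] objects.
#' @export
default_window_schemes <- function() {
  sizes <- c(9000L, 8000L, 7000L, 6000L, 5000L, 4000L, 3000L, 2000L,
             1000L, 500L, 250L, 150L, 100L)
  schemes <- c(lapply(sizes, function(s) window_scheme("fixed", s)),
               list(window_scheme("sliding", 100L, 20L)))
  names(schemes) <- vapply(schemes, `[[`, character(1L), "label")
  schemes
}

is_sex_or_mito <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("X", "Y", "M", "MT")
}

#' Segment a genome into windows
#'
#' Fixed schemes tile each autosome with consecutive non-overlapping windows
#' (the trailing partial window is kept); sliding schemes start at 0, step,
#' 2*step, ... while the start is inside the chromosome, truncating trailing
#' windows at the chromosome end. Sex chromosomes and the mitochondrion are
#' excluded.
#'
#' @param chrom_sizes Table with columns `chrom` and `size` (bp).
#' @param scheme A [window_scheme()].
#' @return `data.table` with `chrom`, `start`, `end`, `set_label`, in
#'   genomic order.
#' @export
segment_genome <- function(chrom_sizes, scheme) {
  if (!inherits(scheme, "window_scheme")) stop("unknown scheme")
  chrom_sizes <- data.table::as.data.table(chrom_sizes)
  chrom_sizes <- chrom_sizes[!is_sex_or_mito(chrom_sizes$chrom)]
  out <- vector("list", nrow(chrom_sizes))
  for (i in seq_len(nrow(chrom_sizes))) {
    len <- as.integer(chrom_sizes$size[i])
    if (scheme$type == "fixed") {
      starts <- seq.int(0L, len - 1L, by = scheme$size)
    } else {
      starts <- seq.int(0L, len - 1L, by = scheme$step)
    }
    ends <- pmin(starts + scheme$size, len)
    out[[i]] <- data.table::data.table(chrom = chrom_sizes$chrom[i],
                                       start = starts, end = ends)
  }
  res <- data.table::rbindlist(out)
  res$set_label <- scheme$label
  res
}

#' Per-window average methylation across samples
#'
#' For each sample, CpGs with total coverage below `min_cov` are dropped;
#' a window's value is the call-weighted proportion of methylated calls,
#' sum(count_meth) / sum(count_meth + count_unmeth), over its surviving
#' CpGs. Windows with no surviving CpG in at least one sample (including
#' CpG-free windows) are removed, so the returned matrix has no NA cells.
#'
#' @param cov_list Named list (sample id) of coverage tables
#'   (see [read_bismark_coverage()]).
#' @param windows Window set from [segment_genome()].
#' @param min_cov Minimum per-CpG coverage (default 5).
#' @param per_cpg_mean If `TRUE`, average the per-CpG methylation fractions
#'   instead of call-weighting.
#' @return Numeric matrix windows x samples, rownames `chrom:start-end`,
#'   with attributes `windows` (the retained window table) and `set_label`.
#' @export
window_average_methylation <- function(cov_list, windows, min_cov = 5L,
                                       per_cpg_mean = FALSE) {
  windows <- data.table::as.data.table(windows)
  if (nrow(windows) == 0L) stop("empty window set")
  stopifnot(length(cov_list) >= 1L, !is.null(names(cov_list)))
  wkey <- sprintf("%s:%d-%d", windows$chrom, windows$start, windows$end)
  win <- data.table::data.table(chrom = windows$chrom,
                                wstart = windows$start, wend = windows$end,
                                wid = seq_len(nrow(windows)))
  data.table::setkey(win, chrom, wstart, wend)
  mat <- matrix(NA_real_, nrow(windows), length(cov_list),
                dimnames = list(wkey, names(cov_list)))
  for (j in seq_along(cov_list)) {
    cov <- data.table::as.data.table(cov_list[[j]])
    cov <- cov[(cov$count_meth + cov$count_unmeth) >= min_cov]
    if (nrow(cov) == 0L) next
    # 1-based CpG p maps to 0-based point [p-1, p)
    q <- data.table::data.table(chrom = cov$chrom,
                                wstart = cov$pos - 1L, wend = cov$pos,
                                cm = cov$count_meth, cu = cov$count_unmeth)
    ov <- data.table::foverlaps(q, win, type = "within", nomatch = NULL)
    if (nrow(ov) == 0L) next
    cm <- cu <- wid <- NULL
    agg <- if (per_cpg_mean) {
      ov[, list(v = mean(cm / (cm + cu))), by = "wid"]
    } else {
      ov[, list(v = sum(cm) / sum(cm + cu)), by = "wid"]
    }
    mat[agg$wid, j] <- agg$v
  }
  keep <- rowSums(is.na(mat)) == 0L
  mat <- mat[keep, , drop = FALSE]
  attr(mat, "windows") <- windows[keep]
  attr(mat, "set_label") <- windows$set_label[1L]
  mat
}

#' Remove duplicate window rows
#'
#' Among windows with identical value vectors across all samples, keeps the
#' first in genomic order. Overlapping sliding windows covering the same
#' CpGs produce such duplicates.
#'
#' @param mat Matrix from [window_average_methylation()].
#' @return The deduplicated matrix; attribute `dedup_map` is a `data.table`
#'   mapping each removed row key to the kept row key.
#' @export
deduplicate_windows <- function(mat) {
  if (nrow(mat) <= 1L) {
    attr(mat, "dedup_map") <- data.table::data.table(removed = character(),
                                                     kept = character())
    return(mat)
  }
  key <- apply(mat, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  kept_names <- rownames(mat)[first]
  kept_of <- kept_names[match(key[!first], key[first])]
  map <- data.table::data.table(removed = rownames(mat)[!first], kept = kept_of)
  out <- mat[first, , drop = FALSE]
  w <- attr(mat, "windows")
  if (!is.null(w)) attr(out, "windows") <- w[first]
  attr(out, "set_label") <- attr(mat, "set_label")
  attr(out, "dedup_map") <- map
  out
}
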