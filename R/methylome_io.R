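# Readers/writers for the plain-text formats the package exchanges:
# Bismark coverage TSV, a read-level methylation-call TSV, BED window sets,
# locus-by-sample score matrices and sample metadata.

#' Read a Bismark coverage file
#'
#' Parses the 6-column tab-separated coverage format produced by
#' `bismark2bedGraph`/`coverage2cytosine`: chromosome, start, end,
#' methylation percentage, methylated count, unmethylated count. Both the
#' point dialect (`start == end`) and the 1-based inclusive interval dialect
#' are accepted; the position reported is `start`.
#'
#' @param path Path to a (plain-text, uncompressed) coverage file.
#' @return A `data.table` with columns `chrom`, `pos`, `meth_percent`,
#'   `count_meth`, `count_unmeth`, one row per input line, in file order.
#' @export
read_bismark_coverage <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  meth_percent = numeric(),
                                  count_meth = integer(),
                                  count_unmeth = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    stop(sprintf("coverage format error at line %d: expected 6 tab-separated columns, got %d",
                 which(nf != 6L)[1L], nf[which(nf != 6L)[1L]]))
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos   <- suppressWarnings(as.integer(m[, 2L]))
  end   <- suppressWarnings(as.integer(m[, 3L]))
  pct   <- suppressWarnings(as.numeric(m[, 4L]))
  cm    <- suppressWarnings(as.integer(m[, 5L]))
  cu    <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(pos) | is.na(end) | is.na(pct) | is.na(cm) | is.na(cu))
  if (length(bad)) {
    stop(sprintf("coverage format error at line %d: non-numeric field", bad[1L]))
  }
  bad <- which(pct < 0 | pct > 100)
  if (length(bad)) {
    stop(sprintf("coverage format error at line %d: methylation %% outside [0,100]", bad[1L]))
  }
  bad <- which(cm < 0 | cu < 0 | (cm + cu) < 1L)
  if (length(bad)) {
    stop(sprintf("coverage format error at line %d: invalid counts", bad[1L]))
  }
  data.table::data.table(chrom = m[, 1L], pos = pos, meth_percent = pct,
                         count_meth = cm, count_unmeth = cu)
}

#' Write a Bismark-style coverage file
#'
#' Emits the point dialect (`start == end`, 1-based).
#'
#' @param cov A coverage table as returned by [read_bismark_coverage()].
#' @param path Output path.
#' @export
write_bismark_coverage <- function(cov, path) {
  cov <- data.table::as.data.table(cov)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   cov$chrom, cov$pos, cov$pos,
                   format(cov$meth_percent, trim = TRUE, scientific = FALSE),
                   cov$count_meth, cov$count_unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Read read-level methylation call records
#'
#' The read-level TSV dialect carries, per line: read id, chromosome, a
#' comma-separated list of 1-based CpG positions and a methylation string
#' over `{M, U}` of matching length. This is the per-molecule information
#' content of a Bismark XM-tagged alignment, without the alignment.
#'
#' @param path Path to a read-level TSV.
#' @return A calls `data.table` with one row per CpG call: columns
#'   `read_id`, `chrom`, `pos` (integer) and `state` (integer, 1 =
#'   methylated, 0 = unmethylated), positions ascending within each read.
#' @export
read_readlevel_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_calls())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    stop(sprintf("read-level format error at line %d: expected 4 columns", which(nf != 4L)[1L]))
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  pos_list <- strsplit(m[, 3L], ",", fixed = TRUE)
  state_list <- strsplit(m[, 4L], "", fixed = TRUE)
  npos <- lengths(pos_list); nst <- lengths(state_list)
  if (any(npos != nst)) {
    i <- which(npos != nst)[1L]
    stop(sprintf("read-level format error at line %d: %d positions but %d states", i, npos[i], nst[i]))
  }
  pos <- suppressWarnings(as.integer(unlist(pos_list)))
  if (anyNA(pos)) {
    i <- findInterval(which(is.na(pos))[1L], cumsum(npos) - npos + 1L)
    stop(sprintf("read-level format error at line %d: non-integer position", i))
  }
  st_chr <- unlist(state_list)
  if (!all(st_chr %in% c("M", "U"))) {
    bad_row <- rep.int(seq_along(npos), npos)[which(!st_chr %in% c("M", "U"))[1L]]
    stop(sprintf("read-level format error at line %d: state characters must be M or U", bad_row))
  }
  row_of <- rep.int(seq_along(npos), npos)
  unsorted <- vapply(split(pos, row_of), function(p) is.unsorted(p, strictly = TRUE), logical(1L))
  if (any(unsorted)) {
    stop(sprintf("read-level format error at line %d: positions not strictly increasing",
                 as.integer(names(unsorted)[unsorted][1L])))
  }
  data.table::data.table(read_id = rep.int(m[, 1L], npos),
                         chrom = rep.int(m[, 2L], npos),
                         pos = pos,
                         state = as.integer(st_chr == "M"))
}

#' Write read-level methylation call records
#'
#' @param calls A calls table (see [read_readlevel_records()]).
#' @param path Output path.
#' @export
write_readlevel_records <- function(calls, path) {
  calls <- data.table::as.data.table(calls)
  pos <- state <- read_id <- chrom <- NULL
  per_read <- calls[, list(chrom = chrom[1L],
                           pos_str = paste(pos, collapse = ","),
                           st_str = paste(ifelse(state == 1L, "M", "U"), collapse = "")),
                    by = "read_id"]
  writeLines(sprintf("%s\t%s\t%s\t%s", per_read$read_id, per_read$chrom,
                     per_read$pos_str, per_read$st_str), path)
  invisible(path)
}

empty_calls <- function() {
  data.table::data.table(read_id = character(), chrom = character(),
                         pos = integer(), state = integer())
}

#' Aggregate read-level calls to per-CpG coverage
#'
#' Per CpG: counts of methylated and unmethylated calls over all reads, and
#' the methylation percentage. Exactly reproduces a Bismark coverage file
#' derived from the same calls.
#'
#' @param calls A calls table.
#' @return A coverage `data.table` (see [read_bismark_coverage()]),
#'   sorted by chromosome then position.
#' @export
reads_to_coverage <- function(calls) {
  calls <- data.table::as.data.table(calls)
  chrom <- pos <- state <- NULL
  cov <- calls[, list(count_meth = sum(state == 1L),
                      count_unmeth = sum(state == 0L)), by = c("chrom", "pos")]
  data.table::setorder(cov, chrom, pos)
  cov[, "meth_percent" := 100 * cov$count_meth / (cov$count_meth + cov$count_unmeth)]
  data.table::setcolorder(cov, c("chrom", "pos", "meth_percent", "count_meth", "count_unmeth"))
  cov[]
}

#' Write a window set as BED
#'
#' Standard 3+1-column BED: chromosome, 0-based start, end (half-open) and
#' the window-set label.
#'
#' @param windows A table with columns `chrom`, `start`, `end` and
#'   optionally `set_label`.
#' @param path Output path.
#' @export
write_bed_windows <- function(windows, path) {
  windows <- data.table::as.data.table(windows)
  if (any(windows$start >= windows$end)) {
    stop("invalid window: start must be < end (0-based half-open)")
  }
  lab <- if ("set_label" %in% names(windows)) windows$set_label else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", windows$chrom,
                     as.integer(windows$start), as.integer(windows$end), lab), path)
  invisible(path)
}

#' Read a BED window set written by [write_bed_windows()]
#'
#' @param path Path to a 4-column BED file.
#' @return A `data.table` with `chrom`, `start`, `end`, `set_label`.
#' @export
read_bed_windows <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "set_label"),
                          colClasses = list(character = c(1L, 4L), integer = 2:3))
  if (any(dt$start >= dt$end)) stop("invalid window in BED: start >= end")
  dt
}

#' Write / read a locus-by-sample score matrix
#'
#' Loci are rows (first column `locus`), samples are columns (header row of
#' sample ids); missing scores are written as `NA`. Round-trips exactly.
#'
#' @param mat Numeric matrix with locus-key rownames and sample-id colnames.
#' @param path Output path.
#' @export
write_score_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicate locus keys in score matrix")
  meta <- attr(mat, "metric")
  # %.17g preserves doubles exactly, so write -> read is bit-identical
  vals <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  vals[is.na(mat)] <- "NA"
  body <- paste(rownames(mat), apply(vals, 1L, paste, collapse = "\t"),
                sep = "\t")
  if (nrow(mat) == 0L) body <- character()
  lines <- c(if (!is.null(meta)) sprintf("# metric=%s", meta),
             paste(c("locus", colnames(mat)), collapse = "\t"),
             body)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_score_matrix
#' @param path Path to a score-matrix TSV.
#' @return For the reader: the numeric matrix, with a `metric` attribute if
#'   the file records one.
#' @export
read_score_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  metric <- NULL
  skip <- 0L
  if (startsWith(first, "# metric=")) {
    metric <- sub("^# metric=", "", first)
    skip <- 1L
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = skip, na.strings = "NA")
  if (anyDuplicated(dt$locus)) stop("duplicate locus keys in score matrix file")
  mat <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(mat) <- dt$locus
  if (!is.null(metric)) attr(mat, "metric") <- metric
  mat
}

#' Read / write the sample metadata table
#'
#' Two tab-separated columns: `sample_id` and `age` (years).
#'
#' @param path Path to the metadata TSV.
#' @return A `data.table` with `sample_id` (character) and `age` (numeric).
#' @export
read_sample_metadata <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "sample_id"))
  if (!all(c("sample_id", "age") %in% names(dt))) {
    stop("metadata must have columns sample_id and age")
  }
  if (any(dt$age < 0)) stop("ages must be non-negative")
  dt
}

#' @rdname read_sample_metadata
#' @param meta Metadata table with `sample_id` and `age`.
#' @export
write_sample_metadata <- function(meta, path) {
  data.table::fwrite(data.table::as.data.table(meta)[, c("sample_id", "age")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
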