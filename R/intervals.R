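#' Genomic interval tables
#'
#' All region-valued objects in this package (enhancers, peaks, CpG islands,
#' conserved noncoding elements, TADs, promoters, blacklist regions, loop
#' anchors) are tibbles with at least the columns `chrom`, `start`, `end`,
#' using 0-based half-open coordinates (the BED convention).  Optional
#' columns `name`, `score` and `strand` follow BED6.  `interval_tbl()`
#' validates and normalises such a table; every interval operation in the
#' package calls it on its inputs.
#'
#' @param chrom Character vector of chromosome names, or a data frame that
#'   already carries `chrom`/`start`/`end` columns.
#' @param start,end Integer coordinates, 0-based half-open; `end > start`.
#' @param ... Further columns (e.g. `name`, `score`, `strand`) recycled to
#'   the common length.
#' @return A tibble with validated interval columns.
#' @examples
#' interval_tbl("chr1", 100, 200)
#' @export
interval_tbl <- function(chrom, start = NULL, end = NULL, ...) {
  if (is.data.frame(chrom)) {
    x <- as_tibble(chrom)
  } else {
    x <- tibble(chrom = as.character(chrom),
                start = as.numeric(start),
                end = as.numeric(end), ...)
  }
  validate_intervals(x)
}

validate_intervals <- function(x, what = "interval table") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("%s has empty chromosome names", what))
  }
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    abort(sprintf("%s has missing coordinates", what))
  }
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad)) {
    abort(sprintf(
      "%s has invalid coordinates (start < 0 or end <= start) at row(s) %s",
      what, paste(head(bad, 5), collapse = ", ")))
  }
  x
}

# GRanges bridge: BED 0-based half-open -> 1-based closed
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}


# GenomicRanges emits a warning when two objects share no sequence levels;
# for pairwise overlap queries on arbitrary tables that situation is an
# ordinary "no overlap" answer, so it is silenced here.
ov_count <- function(q, s) suppressWarnings(GenomicRanges::countOverlaps(q, s))
ov_hits <- function(q, s) suppressWarnings(GenomicRanges::findOverlaps(q, s))

# point intervals at the floor midpoint of each record
midpoints_gr <- function(x) {
  m <- floor((x$start + x$end) / 2)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = m + 1, width = 1))
}

#' Read a BED file
#'
#' Reads BED3/BED6 records into an interval tibble.  `track`, `browser` and
#' `#`-comment lines are skipped; columns beyond the sixth are ignored.
#' Gzip-compressed files are read transparently.
#'
#' @param path Path to a BED (optionally `.gz`) file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present
#'   in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("line %d: fewer than 3 tab-separated columns",
                  lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    abort(sprintf("line %d: non-integer coordinate", lineno[bad[1]]))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    abort(sprintf("line %d: invalid interval (end <= start or start < 0)",
                  lineno[bad[1]]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  }
  if (all(nf >= 6)) out$strand <- vapply(fields, `[[`, "", 6)
  out
}

#' Write intervals as BED
#'
#' @param x Interval tibble; `name`, `score`, `strand` columns are written
#'   when present (BED6), otherwise BED3.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x[["name"]]) || !is.null(x[["score"]]) || !is.null(x[["strand"]])) {
    cols <- c(cols, list(
      if (is.null(x[["name"]])) rep(".", nrow(x)) else as.character(x$name),
      if (is.null(x[["score"]])) rep("0", nrow(x)) else as.character(x$score),
      if (is.null(x[["strand"]])) rep(".", nrow(x)) else as.character(x$strand)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Flag referent intervals overlapped by a query set
#'
#' A referent is flagged `TRUE` iff at least one query overlaps it, each
#' referent counted at most once regardless of how many queries hit it.
#' With `midpoint = TRUE` a query overlaps a referent iff the query's
#' midpoint, `floor((start + end) / 2)`, lies inside the referent — the rule
#' used for CpG-island and conserved-element overlap proportions.
#'
#' @param referents,queries Interval tibbles.
#' @param midpoint Use the midpoint-of-query rule instead of base-pair
#'   intersection.
#' @return Logical vector, one flag per referent row.
#' @export
overlap_flags <- function(referents, queries, midpoint = FALSE) {
  referents <- validate_intervals(referents, "referents")
  queries <- validate_intervals(queries, "queries")
  if (nrow(referents) == 0) return(logical(0))
  if (nrow(queries) == 0) return(rep(FALSE, nrow(referents)))
  qgr <- if (midpoint) midpoints_gr(queries) else as_gr(queries)
  ov_count(as_gr(referents), qgr) > 0
}

#' Remove records of one set that overlap another
#'
#' Whole-record removal (`bedtools intersect -v` semantics): a record of `a`
#' is dropped if it shares at least one base with any record of `b`; records
#' are never trimmed.  Used for excluding promoter- and blacklist-overlapping
#' peaks.
#'
#' @param a,b Interval tibbles.
#' @return The rows of `a` with zero base-pair intersection with `b`, in the
#'   original order.
#' @export
subtract_overlapping <- function(a, b) {
  a <- validate_intervals(a, "a")
  b <- validate_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  a[ov_count(as_gr(a), as_gr(b)) == 0, , drop = FALSE]
}

#' Jaccard index of two interval sets
#'
#' Each set is first collapsed to its base-pair union; the index is the
#' number of shared bases over the number of bases covered by either set.
#' Returns 0 when both sets are empty.
#'
#' @param a,b Interval tibbles.
#' @return A number in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  a <- validate_intervals(a, "a")
  b <- validate_intervals(b, "b")
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  ga <- GenomicRanges::reduce(as_gr(a))
  gb <- GenomicRanges::reduce(as_gr(b))
  inter <- sum(IRanges::width(suppressWarnings(
    GenomicRanges::intersect(ga, gb))))
  uni <- sum(IRanges::width(suppressWarnings(
    GenomicRanges::union(ga, gb))))
  if (uni == 0) return(0)
  inter / uni
}

#' Promoter windows around transcription start sites
#'
#' One interval `[TSS - flank, TSS + flank)` per gene, where the TSS is
#' `start` for `+`-strand genes and `end - 1` for `-`-strand genes; windows
#' are clipped at coordinate 0.  The default `flank = 2000` gives the
#' TSS±2 kb promoter definition used to separate promoters from enhancers.
#'
#' @param genes Gene-model tibble with columns `chrom`, `start`, `end`,
#'   `strand` (`+` or `-`) and optionally `gene_id` (carried through).
#' @param flank Half-width of the promoter window in bases.
#' @return Interval tibble of promoter windows.
#' @export
promoter_regions <- function(genes, flank = 2000) {
  genes <- validate_intervals(genes, "gene table")
  if (is.null(genes[["strand"]]) || any(is.na(genes$strand)) ||
      !all(genes$strand %in% c("+", "-"))) {
    abort("gene table needs a strand column with values '+' or '-'")
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  out <- tibble(chrom = genes$chrom,
                start = pmax(0, tss - flank),
                end = tss + flank)
  if (!is.null(genes[["gene_id"]])) out$gene_id <- genes$gene_id
  out$strand <- genes$strand
  out
}

#' Sort an interval table
#'
#' Lexicographic on chromosome, then numeric on start and end, giving the
#' deterministic order used for written output.
#'
#' @param x Interval tibble.
#' @return The sorted tibble.
#' @export
sort_intervals <- function(x) {
  x <- validate_intervals(x)
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Nearest-rank percentile threshold
#'
#' The smallest observed value whose cumulative fraction reaches
#' `pct / 100`: the `ceiling(pct/100 * n)`-th order statistic.  With
#' `distinct = TRUE` ties are collapsed before ranking, so the threshold
#' marks a boundary between activity *levels* rather than between ranks —
#' the rule used for hub calling, where loop counts are small integers with
#' heavy ties.
#'
#' @param x Numeric values.
#' @param pct Percentile in (0, 100).
#' @param distinct Collapse tied values before taking the rank.
#' @return The threshold value.
#' @export
percentile_threshold <- function(x, pct = 90, distinct = FALSE) {
  if (!length(x)) abort("percentile of an empty set is undefined")
  if (pct <= 0 || pct >= 100) abort("pct must be in (0, 100)")
  v <- sort(if (distinct) unique(x) else x)
  v[ceiling(pct / 100 * length(v))]
}
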