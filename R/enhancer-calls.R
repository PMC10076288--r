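#' Read a CAGE tag matrix
#'
#' Tab-separated file with columns `id`, `chrom`, `start`, `end` followed by
#' one column per replicate of non-negative tag values.
#'
#' @param path Path to the TSV (header line required).
#' @return Tibble with the annotation coordinates and replicate columns.
#' @export
read_cage_matrix <- function(path) {
  x <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE))
  need <- c("id", "chrom", "start", "end")
  if (!all(need %in% names(x)) || ncol(x) < 5) {
    abort("CAGE matrix needs columns id, chrom, start, end, rep1..repN")
  }
  validate_intervals(x, "CAGE matrix")
}

#' Combine CAGE replicates into one tag value per annotation
#'
#' Replicates are combined by the arithmetic mean over all replicate
#' columns; annotations whose replicates are all zero keep a combined value
#' of 0 (the mean is only meaningful where at least one replicate is
#' nonzero, and is identically zero otherwise).  Zeros count in the
#' divisor: `(3, 0, 0)` combines to 1.
#'
#' @param cage CAGE matrix tibble as returned by [read_cage_matrix()]: `id`,
#'   `chrom`, `start`, `end`, then replicate columns.
#' @return Tibble `id`, `chrom`, `start`, `end`, `combined`.
#' @export
combine_replicates <- function(cage) {
  cage <- validate_intervals(cage, "CAGE matrix")
  repcols <- setdiff(names(cage), c("id", "chrom", "start", "end"))
  if (!length(repcols)) abort("CAGE matrix has no replicate columns")
  reps <- as.matrix(cage[repcols])
  if (!is.numeric(reps) || anyNA(reps)) abort("replicate values must be numeric")
  if (any(reps < 0)) abort("negative CAGE tag value")
  tibble(id = cage$id, chrom = cage$chrom, start = cage$start,
         end = cage$end, combined = rowMeans(reps))
}

#' Call enhancers from H3K27ac peaks
#'
#' Enhancers are H3K27ac peaks with zero base-pair intersection with gene
#' promoter windows (TSS±2 kb) and with blacklist regions; removal is
#' whole-record and input order is preserved.
#'
#' @param h3k27ac_peaks,promoters,blacklist Interval tibbles.
#' @return The retained peaks.
#' @export
call_enhancers <- function(h3k27ac_peaks, promoters, blacklist) {
  out <- subtract_overlapping(h3k27ac_peaks, promoters)
  subtract_overlapping(out, blacklist)
}

#' Classify enhancers as CAGE-tag highly active (CHA) or regular
#'
#' The classification threshold is the nearest-rank `pct`-th percentile of
#' combined CAGE tag values over annotations with a nonzero combined tag.
#' An enhancer is CHA iff it intersects at least one CAGE annotation whose
#' combined tag is at or above the threshold (inclusive); all other
#' enhancers — including those with no CAGE overlap at all — are regular.
#'
#' @param enhancers Interval tibble of called enhancers.
#' @param cage Combined CAGE tibble from [combine_replicates()] (`id`,
#'   `chrom`, `start`, `end`, `combined`).
#' @param pct Percentile in (0, 100); default 90.
#' @return The enhancer tibble with columns `enhancer_id`, `combined_cage`
#'   (largest combined tag among overlapping annotations, 0 if none) and
#'   `label` (`"CHA"`/`"regular"`); the threshold is stored in attribute
#'   `cage_threshold`.
#' @export
classify_cha <- function(enhancers, cage, pct = 90) {
  enhancers <- validate_intervals(enhancers, "enhancers")
  if (!"combined" %in% names(cage)) {
    abort("cage must carry a 'combined' column (see combine_replicates())")
  }
  cage <- validate_intervals(cage, "cage")
  nz <- cage$combined[cage$combined > 0]
  if (!length(nz)) abort("no CAGE annotation with nonzero combined tag; threshold undefined")
  thr <- percentile_threshold(nz, pct)
  hits <- ov_hits(as_gr(enhancers), as_gr(cage))
  best <- rep(0, nrow(enhancers))
  if (length(hits)) {
    agg <- tapply(cage$combined[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), max)
    best[as.integer(names(agg))] <- as.numeric(agg)
  }
  high <- cage[cage$combined >= thr, , drop = FALSE]
  is_cha <- ov_count(as_gr(enhancers), as_gr(high)) > 0
  out <- enhancers
  if (is.null(out[["enhancer_id"]])) {
    out$enhancer_id <- if (!is.null(out[["name"]])) as.character(out$name) else
      sprintf("enh_%05d", seq_len(nrow(out)))
  }
  out$combined_cage <- best
  out$label <- ifelse(is_cha, "CHA", "regular")
  structure(out, cage_threshold = thr, class = c("cha_enhancer_table",
                                                 class(out)))
}

#' @rdname classify_cha
#' @param x A classified enhancer table.
#' @param ... Unused.
#' @export
glance.cha_enhancer_table <- function(x, ...) {
  tibble(n_enhancers = nrow(x),
         n_cha = sum(x$label == "CHA"),
         n_regular = sum(x$label == "regular"),
         cha_fraction = mean(x$label == "CHA"),
         cage_threshold = attr(x, "cage_threshold"))
}

#' Annotation-overlap proportions of CHA versus regular enhancers
#'
#' Computes, per enhancer label, the proportion of enhancers overlapped by
#' an annotation set (CpG islands, conserved noncoding elements, ...) using
#' the midpoint-of-query rule, and tests the 2x2 label-by-overlap table
#' with the two-sided Fisher's exact test.
#'
#' @param table Classified enhancer table from [classify_cha()].
#' @param annotation Interval tibble of query annotations.
#' @return One-row tibble: counts, proportions per label and `fisher_p`.
#' @export
annotation_overlap_test <- function(table, annotation) {
  if (!"label" %in% names(table)) abort("table must carry a 'label' column")
  if (!nrow(table)) abort("empty enhancer table")
  hit <- overlap_flags(table, annotation, midpoint = TRUE)
  label_overlap_table(table$label, hit)
}

# shared 2x2 summary for label-vs-flag tests
label_overlap_table <- function(label, hit) {
  cha <- label == "CHA"
  a <- sum(cha & hit); b <- sum(cha & !hit)
  c <- sum(!cha & hit); d <- sum(!cha & !hit)
  tibble(
    n_cha = a + b, n_cha_hit = a,
    prop_cha = if (a + b > 0) a / (a + b) else NA_real_,
    n_regular = c + d, n_regular_hit = c,
    prop_regular = if (c + d > 0) c / (c + d) else NA_real_,
    fisher_p = fisher_exact(a, b, c, d))
}

#' Write a classified enhancer table as BED6
#'
#' The label is stored in the BED name field (prefixed by the enhancer id)
#' and the combined CAGE tag in the score field.
#'
#' @param table Classified enhancer table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enhancer_bed <- function(table, path) {
  x <- tibble(chrom = table$chrom, start = table$start, end = table$end,
              name = paste(table$enhancer_id, table$label, sep = "|"),
              score = table$combined_cage,
              strand = rep(".", nrow(table)))
  write_bed(x, path)
}
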