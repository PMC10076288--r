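#' Read and write HiChIP loop tables (BEDPE)
#'
#' Loops are intra-chromosomal pairs of anchors with a significance
#' q-value, as produced by loop callers on HiChIP contact data.  Files are
#' tab-separated with columns `chrom1, start1, end1, chrom2, start2, end2,
#' name, count, qvalue` (no header).  Inter-chromosomal records are
#' rejected at parse time; anchors are stored so `start1 <= start2`.
#'
#' @param path Path to the BEDPE file (optionally gzipped).
#' @return Loop tibble with the columns above.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- read.table(gzfile(path), header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 9) abort("BEDPE needs 9 columns (anchors, name, count, qvalue)")
  names(x)[1:9] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                     "name", "count", "qvalue")
  validate_loops(as_tibble(x[1:9]))
}

validate_loops <- function(loops) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(need %in% names(loops))) {
    abort("loop table needs anchor columns chrom1/start1/end1/chrom2/start2/end2")
  }
  loops <- as_tibble(loops)
  if (any(loops$chrom1 != loops$chrom2)) {
    abort(sprintf("inter-chromosomal loop at row %s",
                  which(loops$chrom1 != loops$chrom2)[1]))
  }
  swap <- loops$start1 > loops$start2
  if (any(swap)) {
    tmp <- loops[swap, c("start1", "end1")]
    loops[swap, c("start1", "end1")] <- loops[swap, c("start2", "end2")]
    loops[swap, c("start2", "end2")] <- tmp
  }
  for (side in 1:2) {
    validate_intervals(
      tibble(chrom = loops[[paste0("chrom", side)]],
             start = loops[[paste0("start", side)]],
             end = loops[[paste0("end", side)]]),
      sprintf("anchor %d", side))
  }
  loops
}

#' @rdname read_bedpe
#' @param loops Loop tibble.
#' @return For `write_bedpe()`: `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  loops <- validate_loops(loops)
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  writeLines(paste(loops$chrom1, fmt(loops$start1), fmt(loops$end1),
                   loops$chrom2, fmt(loops$start2), fmt(loops$end2),
                   if (is.null(loops[["name"]])) "." else loops$name,
                   if (is.null(loops[["count"]])) 0 else loops$count,
                   if (is.null(loops[["qvalue"]])) NA else
                     format(loops$qvalue, digits = 10, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

anchor_gr <- function(loops, side) {
  GenomicRanges::GRanges(
    seqnames = loops[[paste0("chrom", side)]],
    ranges = IRanges::IRanges(start = loops[[paste0("start", side)]] + 1,
                              end = loops[[paste0("end", side)]]))
}

#' Keep high-confidence loops
#'
#' Retains loops with `qvalue < q_max` (strict inequality: a loop at
#' exactly the cutoff is removed).
#'
#' @param loops Loop tibble.
#' @param q_max Significance cutoff; default `1e-6`.
#' @return The filtered loop tibble.
#' @export
filter_loops <- function(loops, q_max = 1e-6) {
  loops <- validate_loops(loops)
  if (is.null(loops[["qvalue"]]) || anyNA(loops$qvalue)) {
    abort(sprintf("missing q-value at row %s",
                  if (is.null(loops[["qvalue"]])) "all" else
                    which(is.na(loops$qvalue))[1]))
  }
  loops[loops$qvalue < q_max, , drop = FALSE]
}

# per-element distinct loop indices touching either anchor
element_loop_hits <- function(loops, elements) {
  egr <- as_gr(elements)
  h1 <- ov_hits(egr, anchor_gr(loops, 1))
  h2 <- ov_hits(egr, anchor_gr(loops, 2))
  distinct(tibble(
    element = c(S4Vectors::queryHits(h1), S4Vectors::queryHits(h2)),
    loop = c(S4Vectors::subjectHits(h1), S4Vectors::subjectHits(h2))))
}

#' Loops per regulatory element
#'
#' Counts, for each element, the distinct loops having at least one anchor
#' with base-pair intersection with the element; a loop whose two anchors
#' both touch the element counts once.
#'
#' @param loops Filtered loop tibble.
#' @param elements Interval tibble (e.g. a classified enhancer table); an
#'   `enhancer_id` or `name` column is carried through as the element id.
#' @return Tibble `element_id`, `loop_count` (zero-count elements included),
#'   plus `label` when present in `elements`.
#' @export
loops_per_element <- function(loops, elements) {
  elements <- validate_intervals(elements, "elements")
  loops <- validate_loops(loops)
  id <- if (!is.null(elements[["enhancer_id"]])) elements$enhancer_id
        else if (!is.null(elements[["name"]])) as.character(elements$name)
        else sprintf("el_%05d", seq_len(nrow(elements)))
  hits <- element_loop_hits(loops, elements)
  cnt <- integer(nrow(elements))
  if (nrow(hits)) {
    tb <- table(hits$element)
    cnt[as.integer(names(tb))] <- as.integer(tb)
  }
  out <- tibble(element_id = id, loop_count = cnt)
  if (!is.null(elements[["label"]])) out$label <- elements$label
  out
}

#' Loop-anchor involvement of CHA versus regular enhancers
#'
#' Per label, the proportion of enhancers with at least one loop anchor
#' overlap, with a two-sided Fisher's exact test on the 2x2 table.
#'
#' @param loops Filtered loop tibble.
#' @param table Classified enhancer table.
#' @return One-row tibble of counts, proportions and `fisher_p`.
#' @export
anchor_overlap_test <- function(loops, table) {
  lp <- loops_per_element(loops, table)
  label_overlap_table(table$label, lp$loop_count >= 1)
}

#' Short versus long loop ratio per chromosome
#'
#' Loop distance is measured midpoint-to-midpoint between anchors; the
#' ratio is the count of loops shorter than `threshold` over the count at
#' or beyond it (a loop at exactly the threshold is long).  Chromosomes
#' with no long loop get `NA`.
#'
#' @param loops Loop tibble.
#' @param threshold Distance cutoff in bases; default 200 kb.
#' @return Tibble `chrom`, `n_short`, `n_long`, `ratio`.
#' @export
short_long_ratio <- function(loops, threshold = 200000) {
  loops <- validate_loops(loops)
  dist <- floor((loops$start2 + loops$end2) / 2) -
    floor((loops$start1 + loops$end1) / 2)
  tibble(chrom = loops$chrom1, short = dist < threshold) %>%
    group_by(.data$chrom) %>%
    summarise(n_short = sum(.data$short),
              n_long = sum(!.data$short), .groups = "drop") %>%
    mutate(ratio = ifelse(.data$n_long > 0,
                          .data$n_short / .data$n_long, NA_real_))
}

#' TAD-border overlap of CHA versus regular enhancers
#'
#' Border regions are `[boundary - buffer, boundary + buffer)` around every
#' TAD start and end; an enhancer overlaps a border iff it shares at least
#' one base with a border region.  Tested per label with Fisher's exact
#' test.
#'
#' @param elements Classified enhancer table.
#' @param tads Interval tibble of TADs (non-overlapping per chromosome).
#' @param buffer Half-width of the border region in bases; default 10 kb.
#' @return One-row tibble of counts, proportions and `fisher_p`.
#' @export
tad_border_overlap <- function(elements, tads, buffer = 10000) {
  tads <- validate_intervals(tads, "tads")
  borders <- tibble(
    chrom = rep(tads$chrom, 2),
    start = pmax(0, c(tads$start, tads$end) - buffer),
    end = c(tads$start, tads$end) + buffer)
  hit <- overlap_flags(elements, borders, midpoint = FALSE)
  label_overlap_table(elements$label, hit)
}

#' Call hub CHA regulatory units
#'
#' A regulatory unit is a gene promoter together with the CHA enhancers it
#' loops to.  For each promoter the number of distinct significant loops
#' with one anchor on the promoter and the other on a CHA enhancer is
#' counted; promoters with at least one such loop form the reference
#' population.  The hub threshold is the nearest-rank `pct`-th percentile
#' of the distinct observed loop counts (ties collapsed, see
#' [percentile_threshold()]), and a unit is a hub iff its count is at or
#' above the threshold.
#'
#' @param loops Filtered loop tibble.
#' @param table Classified enhancer table (CHA labels assigned).
#' @param promoters Promoter tibble with a `gene_id` column.
#' @param pct Percentile in (0, 100); default 90.
#' @return A `cha_regulatory_units` tibble: `gene_id`, promoter coordinates,
#'   `loop_count`, `hub`, and `enhancers` (list-column of connected CHA
#'   enhancer ids); attribute `hub_threshold`.
#' @export
call_hubs <- function(loops, table, promoters, pct = 90) {
  promoters <- validate_intervals(promoters, "promoters")
  if (is.null(promoters[["gene_id"]])) abort("promoters need a gene_id column")
  loops <- validate_loops(loops)
  cha <- table[table$label == "CHA", , drop = FALSE]
  if (!nrow(cha)) abort("no CHA enhancer in the table")
  pid <- if (!is.null(cha[["enhancer_id"]])) cha$enhancer_id else
    sprintf("enh_%05d", which(table$label == "CHA"))
  pgr <- as_gr(promoters); egr <- as_gr(cha)
  links <- NULL
  for (sides in list(c(1, 2), c(2, 1))) {
    hp <- ov_hits(anchor_gr(loops, sides[1]), pgr)
    he <- ov_hits(anchor_gr(loops, sides[2]), egr)
    m <- left_join(
      tibble(loop = S4Vectors::queryHits(hp),
             promoter = S4Vectors::subjectHits(hp)),
      tibble(loop = S4Vectors::queryHits(he),
             enhancer = S4Vectors::subjectHits(he)),
      by = "loop", relationship = "many-to-many")
    links <- bind_rows(links, m[!is.na(m$enhancer), ])
  }
  if (is.null(links) || !nrow(links)) {
    abort("no promoter is connected to a CHA enhancer by a significant loop")
  }
  per <- links %>%
    group_by(.data$promoter) %>%
    summarise(loop_count = length(unique(.data$loop)),
              enhancers = list(sort(unique(pid[.data$enhancer]))),
              .groups = "drop")
  thr <- percentile_threshold(per$loop_count, pct, distinct = TRUE)
  out <- tibble(
    gene_id = promoters$gene_id[per$promoter],
    chrom = promoters$chrom[per$promoter],
    start = promoters$start[per$promoter],
    end = promoters$end[per$promoter],
    loop_count = per$loop_count,
    hub = per$loop_count >= thr,
    enhancers = per$enhancers) %>%
    arrange(.data$chrom, .data$start, .data$gene_id)
  structure(out, hub_threshold = thr,
            class = c("cha_regulatory_units", class(out)))
}

#' @rdname call_hubs
#' @param x A `cha_regulatory_units` table.
#' @param ... Unused.
#' @export
tidy.cha_regulatory_units <- function(x, ...) {
  out <- as_tibble(x)
  out$n_enhancers <- lengths(out$enhancers)
  out$enhancers <- vapply(out$enhancers, paste, "", collapse = ",")
  out
}

#' @rdname call_hubs
#' @export
glance.cha_regulatory_units <- function(x, ...) {
  tibble(n_units = nrow(x), n_hubs = sum(x$hub),
         hub_threshold = attr(x, "hub_threshold"),
         n_hub_genes = length(unique(x$gene_id[x$hub])))
}

#' Partition unit genes into hub and non-hub sets
#'
#' Unique gene ids from a regulatory-unit table, split by hub status; a
#' gene with several promoters is a hub gene if any of its promoters is a
#' hub.
#'
#' @param units `cha_regulatory_units` table from [call_hubs()].
#' @return List with character vectors `hub_genes` and `nonhub_genes`.
#' @export
unit_gene_sets <- function(units) {
  hub <- unique(units$gene_id[units$hub])
  list(hub_genes = hub,
       nonhub_genes = setdiff(unique(units$gene_id), hub))
}
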