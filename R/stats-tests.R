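#' Two-sided Fisher's exact test, safe in the extreme tail
#'
#' Computes the two-sided p-value as the sum of hypergeometric point
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed point probability (up to a relative tolerance of
#' 1e-7, the dominant implementation convention).  All sums are taken in
#' log space, so p-values down to the smallest representable double are
#' accurate to at least six significant digits — the regime needed to
#' compare tens of thousands of enhancers against loop-anchor overlap.
#'
#' @param a Either a 2x2 matrix/table (rows = group, columns = outcome) or
#'   the top-left cell count.
#' @param b,c,d Remaining cell counts when `a` is scalar, reading the table
#'   row-wise.
#' @return The two-sided p-value (1 for an all-zero table).
#' @examples
#' fisher_exact(matrix(c(1012, 185, 10025, 15187), 2, byrow = TRUE))
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) || is.table(a)) {
    if (!all(dim(a) == c(2, 2))) abort("need a 2x2 table")
    tb <- as.numeric(t(a))
    a <- tb[1]; b <- tb[2]; c <- tb[3]; d <- tb[4]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) return(1)
  p <- fisher_support_p(a + b, c + d, a + c)
  lo <- max(0, (a + c) - (c + d))
  p[a - lo + 1]
}

# Two-sided p for every admissible top-left cell at fixed margins
# (row1 total m, row2 total n, column1 total k).  Shared by fisher_exact and
# the exhaustive-sweep tests so the scalar and vector paths cannot diverge.
fisher_support_p <- function(m, n, k) {
  x <- max(0, k - n):min(k, m)
  lp <- dhyper(x, m, n, k, log = TRUE)
  tol <- log1p(1e-7)
  vapply(lp, function(lobs) {
    keep <- lp <= lobs + tol
    mx <- max(lp[keep])
    min(1, exp(mx + log(sum(exp(lp[keep] - mx)))))
  }, numeric(1))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a gene set of
#' interest and an annotated set, against a background universe (typically
#' all protein-coding genes).  `expected` is the overlap under random
#' drawing and `fold_enrichment = overlap / expected`.
#'
#' @param hits Character vector of genes of interest (must lie in
#'   `background`).
#' @param annotation Character vector of annotated genes; only its
#'   intersection with the background is used.
#' @param background Character vector: the gene universe.
#' @return One-row tibble with `overlap`, `expected`, `fold_enrichment`
#'   and `p` (`P(X >= overlap)`).
#' @export
hypergeom_enrichment <- function(hits, annotation, background) {
  background <- unique(as.character(background))
  if (!length(background)) abort("background gene set is empty")
  hits <- unique(as.character(hits))
  if (!all(hits %in% background)) {
    abort("hits must be a subset of the background")
  }
  ann <- intersect(unique(as.character(annotation)), background)
  k <- length(intersect(hits, ann))
  N <- length(background); K <- length(ann); n <- length(hits)
  expected <- n * K / N
  tibble(
    overlap = k,
    expected = expected,
    fold_enrichment = if (expected > 0) k / expected else NA_real_,
    p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Binomial projection test for interval enrichment
#'
#' Projects each query onto its midpoint and asks whether more midpoints
#' fall inside the (union-collapsed) referent set than expected from the
#' referents' genomic coverage fraction: an upper-tail binomial test with
#' success probability `coverage / genome_size`.
#'
#' @param queries Interval tibble (e.g. variants as 1-bp intervals).
#' @param referents Interval tibble (e.g. CHA enhancers).
#' @param genome_size Total genome size in bases; must be at least the
#'   collapsed referent coverage.
#' @return One-row tibble with `overlap` (midpoints inside referents),
#'   `expected`, `fold_enrichment` and `p`.
#' @export
projection_test <- function(queries, referents, genome_size) {
  queries <- validate_intervals(queries, "queries")
  referents <- validate_intervals(referents, "referents")
  cov <- sum(IRanges::width(GenomicRanges::reduce(as_gr(referents))))
  if (genome_size < cov) abort("genome_size smaller than referent coverage")
  n <- nrow(queries)
  k <- sum(ov_count(midpoints_gr(queries),
                                        as_gr(referents)) > 0)
  ps <- cov / genome_size
  if (ps == 0 && k > 0) abort("queries overlap referents with zero coverage")
  tibble(
    overlap = k,
    expected = n * ps,
    fold_enrichment = if (n * ps > 0) k / (n * ps) else NA_real_,
    p = if (k == 0) 1 else pbinom(k - 1, n, ps, lower.tail = FALSE))
}

#' Relative-distance Kolmogorov-Smirnov test
#'
#' For each query midpoint lying between two consecutive referent midpoints
#' at positions `L < q <= R`, the relative distance is
#' `d = min(q - L, R - q) / (R - L)`, a value in `[0, 0.5]` that is
#' Uniform(0, 0.5) when queries are placed independently of referents.
#' Distances are pooled across chromosomes and compared to that uniform law
#' with a one-sample two-sided KS test; small distances indicate spatial
#' proximity of queries to referents.
#'
#' @param queries,referents Interval tibbles; midpoints are used for both.
#'   Queries outside the referent hull of their chromosome are dropped, as
#'   are chromosomes with fewer than two referents.
#' @return A list of class `cha_reldist` with elements `D`, `p`,
#'   `mean_relative_distance`, `n_queries` and the vector `d`.
#' @export
relative_distance_ks <- function(queries, referents) {
  queries <- validate_intervals(queries, "queries")
  referents <- validate_intervals(referents, "referents")
  qm <- floor((queries$start + queries$end) / 2)
  rm_ <- floor((referents$start + referents$end) / 2)
  d <- unlist(lapply(unique(referents$chrom), function(ch) {
    mids <- sort(unique(rm_[referents$chrom == ch]))
    if (length(mids) < 2) return(numeric(0))
    q <- qm[queries$chrom == ch]
    q <- q[q >= mids[1] & q <= mids[length(mids)]]
    if (!length(q)) return(numeric(0))
    idx <- findInterval(q, mids, rightmost.closed = TRUE)
    idx[idx == length(mids)] <- length(mids) - 1
    L <- mids[idx]; R <- mids[idx + 1]
    pmin(q - L, R - q) / (R - L)
  }), use.names = FALSE)
  if (!length(d)) abort("no query lies within the referent hull")
  ks <- suppressWarnings(ks.test(d, "punif", min = 0, max = 0.5))
  structure(
    list(D = unname(ks$statistic), p = ks$p.value,
         mean_relative_distance = mean(d), n_queries = length(d), d = d),
    class = "cha_reldist")
}

#' @export
print.cha_reldist <- function(x, ...) {
  cat(sprintf(
    "Relative-distance KS test: D = %.4f, p = %.3g (n = %d, mean d = %.4f)\n",
    x$D, x$p, x$n_queries, x$mean_relative_distance))
  invisible(x)
}

#' @rdname relative_distance_ks
#' @param x A `cha_reldist` object.
#' @param ... Unused.
#' @export
tidy.cha_reldist <- function(x, ...) {
  tibble(statistic = x$D, p.value = x$p,
         mean_relative_distance = x$mean_relative_distance,
         n_queries = x$n_queries)
}

#' Wilcoxon rank-sum comparison of two groups of signal summaries
#'
#' Two-sided Mann-Whitney test with the normal approximation and tie
#' correction (no continuity correction), as used throughout for comparing
#' tag densities or pause indices between enhancer classes.
#'
#' @param a,b Numeric vectors of per-element summaries.
#' @return One-row tibble with `statistic` (rank-sum W) and `p.value`.
#' @export
compare_signal <- function(a, b) {
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    # fully tied data: no evidence of a shift in either direction
    return(tibble(statistic = length(a) * length(b) / 2, p.value = 1))
  }
  w <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = FALSE))
  tibble(statistic = unname(w$statistic), p.value = w$p.value)
}
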