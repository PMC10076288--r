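#' RNA-polymerase pause index per gene
#'
#' The pause index is the ratio of tag density (tags per base) in the
#' promoter-proximal window, by default TSS-50 to TSS+300 in transcribed
#' orientation, to the length-normalised density over the remaining gene
#' body (from the end of the promoter window to the TES).  Genes with zero
#' promoter density are filtered out; genes with positive promoter density
#' but an empty body signal get `pause_index = Inf`.  A gene is `paused`
#' when its pause index strictly exceeds `cutoff` (default 2).
#'
#' @param track Run-on sequencing coverage as a track tibble.
#' @param genes Gene-model tibble (`chrom`, `start`, `end`, `strand`,
#'   `gene_id`); gene bodies must be longer than the promoter window.
#' @param promoter_window Length-2 window around the TSS in transcribed
#'   orientation; default `c(-50, 300)`.
#' @param cutoff Pause-index cutoff for calling a gene paused.
#' @return Tibble `gene_id`, `tss_density`, `body_density`, `pause_index`,
#'   `paused`, one row per retained gene; attribute `n_filtered` counts
#'   genes dropped for zero promoter density.
#' @export
pause_index_table <- function(track, genes, promoter_window = c(-50, 300),
                              cutoff = 2) {
  track <- validate_intervals(track, "track")
  genes <- validate_intervals(genes, "gene table")
  if (is.null(genes[["strand"]]) || !all(genes$strand %in% c("+", "-"))) {
    abort("gene table needs strand '+'/'-'")
  }
  if (is.null(genes[["gene_id"]])) {
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  }
  w1 <- promoter_window[1]; w2 <- promoter_window[2]
  lens <- chrom_extents(track, genes)
  covs <- lapply(setNames(unique(genes$chrom), unique(genes$chrom)),
                 function(ch) chrom_coverage(track, ch, lens[[ch]]))
  rows <- lapply(seq_len(nrow(genes)), function(j) {
    plus <- genes$strand[j] == "+"
    tss <- if (plus) genes$start[j] else genes$end[j] - 1
    if (plus) {
      prom <- c(tss + w1, tss + w2)        # [tss-50, tss+300)
      body <- c(tss + w2, genes$end[j])    # [tss+300, TES)
    } else {
      prom <- c(tss - w2 + 1, tss - w1 + 1)  # [tss-299, tss+51)
      body <- c(genes$start[j], tss - w2 + 1)
    }
    if (body[2] <= body[1]) {
      warn(sprintf("gene %s: empty gene body; skipped", genes$gene_id[j]))
      return(NULL)
    }
    cv <- covs[[genes$chrom[j]]]
    seg <- function(r) {
      s <- max(0, r[1]); e <- min(length(cv), r[2])
      if (e <= s) 0 else mean(cv[(s + 1):e])
    }
    tibble(gene_id = genes$gene_id[j],
           tss_density = seg(prom), body_density = seg(body))
  })
  out <- bind_rows(rows)
  n_filtered <- sum(out$tss_density == 0)
  out <- out[out$tss_density > 0, , drop = FALSE]
  out$pause_index <- ifelse(out$body_density > 0,
                            out$tss_density / out$body_density, Inf)
  out$paused <- out$pause_index > cutoff
  structure(out, n_filtered = n_filtered)
}

#' Compare pausing between hub and non-hub gene sets
#'
#' Medians of the pause index per group with percentile-bootstrap 95%
#' confidence intervals, a two-sided Wilcoxon rank-sum test, and the
#' proportion of paused genes per group (pause index strictly greater than
#' the cutoff used in [pause_index_table()]) with a two-sided Fisher's
#' exact test.
#'
#' @param records Pause-record tibble from [pause_index_table()].
#' @param hub_genes,nonhub_genes Character vectors of gene ids.
#' @param boot Number of bootstrap replicates for the median CI.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap (restored afterwards).
#' @return A list of class `cha_pausing` with the group summaries and
#'   p-values; see `tidy()`/`glance()` methods.
#' @export
compare_pausing <- function(records, hub_genes, nonhub_genes, boot = 10000,
                            conf = 0.95, seed = 1234) {
  hub <- records$pause_index[records$gene_id %in% hub_genes]
  non <- records$pause_index[records$gene_id %in% nonhub_genes]
  if (!length(hub) || !length(non)) {
    abort("both gene sets need at least one retained pause record")
  }
  ci <- function(x) {
    withr::with_seed(seed, {
      meds <- vapply(seq_len(boot),
                     function(i) median(sample(x, replace = TRUE)),
                     numeric(1))
      quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    })
  }
  ci_hub <- ci(hub); ci_non <- ci(non)
  w <- compare_signal(hub, non)
  prop <- c(mean(records$paused[records$gene_id %in% hub_genes]),
            mean(records$paused[records$gene_id %in% nonhub_genes]))
  fp <- fisher_exact(sum(records$paused[records$gene_id %in% hub_genes]),
                     sum(!records$paused[records$gene_id %in% hub_genes]),
                     sum(records$paused[records$gene_id %in% nonhub_genes]),
                     sum(!records$paused[records$gene_id %in% nonhub_genes]))
  structure(list(
    n_hub = length(hub), n_nonhub = length(non),
    median_hub = median(hub), median_hub_ci = ci_hub,
    median_nonhub = median(non), median_nonhub_ci = ci_non,
    wilcoxon_p = w$p.value,
    prop_paused_hub = prop[1], prop_paused_nonhub = prop[2],
    fisher_p = fp), class = "cha_pausing")
}

#' @export
print.cha_pausing <- function(x, ...) {
  cat(sprintf(
    paste0("Pause index, hub vs non-hub genes\n",
           "  median hub    : %.2f [%.2f-%.2f] (n = %d)\n",
           "  median non-hub: %.2f [%.2f-%.2f] (n = %d)\n",
           "  Wilcoxon p = %.3g\n",
           "  paused: %.0f%% vs %.0f%%, Fisher p = %.3g\n"),
    x$median_hub, x$median_hub_ci[1], x$median_hub_ci[2], x$n_hub,
    x$median_nonhub, x$median_nonhub_ci[1], x$median_nonhub_ci[2],
    x$n_nonhub, x$wilcoxon_p,
    100 * x$prop_paused_hub, 100 * x$prop_paused_nonhub, x$fisher_p))
  invisible(x)
}

#' @rdname compare_pausing
#' @param x A `cha_pausing` object.
#' @param ... Unused.
#' @export
tidy.cha_pausing <- function(x, ...) {
  tibble(group = c("hub", "nonhub"),
         n = c(x$n_hub, x$n_nonhub),
         median = c(x$median_hub, x$median_nonhub),
         ci_low = c(x$median_hub_ci[1], x$median_nonhub_ci[1]),
         ci_high = c(x$median_hub_ci[2], x$median_nonhub_ci[2]),
         prop_paused = c(x$prop_paused_hub, x$prop_paused_nonhub))
}

#' @rdname compare_pausing
#' @export
glance.cha_pausing <- function(x, ...) {
  tibble(wilcoxon_p = x$wilcoxon_p, fisher_p = x$fisher_p,
         median_hub = x$median_hub, median_nonhub = x$median_nonhub,
         prop_paused_hub = x$prop_paused_hub,
         prop_paused_nonhub = x$prop_paused_nonhub)
}
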