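#' Read variant and summary-statistic tables
#'
#' Variants: TSV with header, columns `id`, `chrom`, `position` plus any of
#' `pics_prob`, `trait`, `risk_allele`.  Summary statistics: TSV with
#' header, columns `id`, `beta`, `se`, `p` plus any of `chrom`, `position`,
#' `gene`, `trait`, `effect_allele`, `other_allele`.  LD: long-format TSV
#' `id1`, `id2`, `r2`.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_variants <- function(path) {
  x <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
  if (!all(c("id", "chrom", "position") %in% names(x))) {
    abort("variant table needs id, chrom, position")
  }
  x
}

#' @rdname read_variants
#' @export
read_summary_stats <- function(path) {
  x <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
  if (!all(c("id", "beta", "se", "p") %in% names(x))) {
    abort("summary statistics need id, beta, se, p")
  }
  if (any(x$se <= 0)) abort("standard errors must be positive")
  x
}

#' @rdname read_variants
#' @export
read_ld_table <- function(path) {
  x <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
  if (!all(c("id1", "id2", "r2") %in% names(x))) {
    abort("LD table needs id1, id2, r2")
  }
  if (any(x$r2 < 0 | x$r2 > 1)) abort("r2 must lie in [0, 1]")
  x
}

#' Filter variants by fine-mapping posterior probability
#'
#' Keeps variants whose fine-mapping (PICS) probability is at or above
#' `min_prob` (inclusive), preserving input order.
#'
#' @param variants Variant tibble with a `pics_prob` column.
#' @param min_prob Inclusive threshold; default 0.025.
#' @return The filtered tibble.
#' @export
filter_pics <- function(variants, min_prob = 0.025) {
  if (is.null(variants[["pics_prob"]])) abort("variants need a pics_prob column")
  bad <- which(is.na(variants$pics_prob) | variants$pics_prob < 0 |
                 variants$pics_prob > 1)
  if (length(bad)) {
    abort(sprintf("pics_prob outside [0, 1] at row %s", bad[1]))
  }
  variants[variants$pics_prob >= min_prob, , drop = FALSE]
}

#' Map variants to genes through CHA enhancer-promoter loops
#'
#' A (variant, gene) pair is emitted iff the variant position falls inside
#' a CHA enhancer and a significant loop links that enhancer to the gene's
#' promoter; one variant may map to several genes through one enhancer
#' with multiple promoter contacts.
#'
#' @param variants Variant tibble (`id`, `chrom`, `position`).
#' @param table Classified enhancer table.
#' @param loops Filtered loop tibble.
#' @param promoters Promoter tibble with `gene_id`.
#' @return Tibble `variant_id`, `enhancer_id`, `gene_id`, distinct pairs.
#' @export
map_variants_to_genes <- function(variants, table, loops, promoters) {
  promoters <- validate_intervals(promoters, "promoters")
  if (is.null(promoters[["gene_id"]])) abort("promoters need a gene_id column")
  cha <- table[table$label == "CHA", , drop = FALSE]
  eid <- if (!is.null(cha[["enhancer_id"]])) cha$enhancer_id else
    sprintf("enh_%05d", seq_len(nrow(cha)))
  if (!nrow(cha) || !nrow(variants)) {
    return(tibble(variant_id = character(), enhancer_id = character(),
                  gene_id = character()))
  }
  vgr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$position + 1, width = 1))
  hv <- ov_hits(vgr, as_gr(cha))
  if (!length(hv)) {
    return(tibble(variant_id = character(), enhancer_id = character(),
                  gene_id = character()))
  }
  loops <- validate_loops(loops)
  pgr <- as_gr(promoters); egr <- as_gr(cha)
  eg_links <- NULL
  for (sides in list(c(1, 2), c(2, 1))) {
    he <- ov_hits(anchor_gr(loops, sides[1]), egr)
    hp <- ov_hits(anchor_gr(loops, sides[2]), pgr)
    m <- left_join(
      tibble(loop = S4Vectors::queryHits(he),
             enhancer = S4Vectors::subjectHits(he)),
      tibble(loop = S4Vectors::queryHits(hp),
             promoter = S4Vectors::subjectHits(hp)),
      by = "loop", relationship = "many-to-many")
    eg_links <- bind_rows(eg_links, m[!is.na(m$promoter), ])
  }
  if (is.null(eg_links) || !nrow(eg_links)) {
    return(tibble(variant_id = character(), enhancer_id = character(),
                  gene_id = character()))
  }
  ve <- tibble(variant = S4Vectors::queryHits(hv),
               enhancer = S4Vectors::subjectHits(hv))
  left_join(ve, eg_links, by = "enhancer",
            relationship = "many-to-many") %>%
    filter(!is.na(.data$promoter)) %>%
    mutate(variant_id = variants$id[.data$variant],
           enhancer_id = eid[.data$enhancer],
           gene_id = promoters$gene_id[.data$promoter]) %>%
    distinct(.data$variant_id, .data$enhancer_id, .data$gene_id)
}

# r2 lookup, symmetric, missing pairs treated as independence
ld_r2 <- function(ld, ids1, ids2) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab <- setNames(ld$r2, key(ld$id1, ld$id2))
  r2 <- tab[key(ids1, ids2)]
  miss <- is.na(r2)
  r2[miss] <- 0
  list(r2 = unname(r2), n_missing = sum(miss))
}

#' Greedy LD clumping of summary statistics
#'
#' Variants are visited in order of ascending p-value (ties broken by
#' ascending position, then id) and accepted iff their LD `r2` with every
#' previously accepted variant within `window` bases is below `r2_max`.
#' Pairs absent from the LD table count as independent (`r2 = 0`) with a
#' warning.
#'
#' @param stats Summary-statistic tibble with `id`, `position`, `p` (and
#'   optionally `chrom`: variants on different chromosomes are always
#'   independent).
#' @param ld Long-format LD tibble (`id1`, `id2`, `r2`).
#' @param r2_max Exclusive LD ceiling for acceptance.
#' @param window Distance in bases within which LD is checked.
#' @return The accepted rows of `stats`, in acceptance order.
#' @export
clump <- function(stats, ld, r2_max = 0.1, window = 250000) {
  if (!all(c("id", "position", "p") %in% names(stats))) {
    abort("stats need id, position, p for clumping")
  }
  ord <- order(stats$p, stats$position, stats$id)
  s <- stats[ord, , drop = FALSE]
  kept <- integer(0)
  n_missing <- 0L
  for (i in seq_len(nrow(s))) {
    near <- kept[abs(s$position[kept] - s$position[i]) <= window]
    if (!is.null(s[["chrom"]])) near <- near[s$chrom[near] == s$chrom[i]]
    if (length(near)) {
      lk <- ld_r2(ld, rep(s$id[i], length(near)), s$id[near])
      n_missing <- n_missing + lk$n_missing
      if (any(lk$r2 >= r2_max)) next
    }
    kept <- c(kept, i)
  }
  if (n_missing > 0) {
    warn(sprintf("%d variant pair(s) missing from the LD table; treated as r2 = 0",
                 n_missing))
  }
  s[kept, , drop = FALSE]
}

#' Fixed-effects inverse-variance-weighted Mendelian randomization
#'
#' Per-instrument Wald ratios `beta_out / beta_exp` with first-order
#' standard errors `se_out / |beta_exp|` are combined by fixed-effects
#' inverse-variance weighting; the p-value is two-sided normal on
#' `beta_ivw / se_ivw`.  When both tables carry `effect_allele`/
#' `other_allele` columns, instruments whose alleles are swapped between
#' exposure and outcome have the outcome effect sign flipped, and
#' instruments with incompatible alleles are dropped.
#'
#' @param exposure,outcome Summary-statistic tibbles (`id`, `beta`, `se`).
#' @param instruments Optional character vector of instrument ids; default
#'   all ids shared by both tables.
#' @param gene,trait Optional labels carried into the result.
#' @return A `cha_mr` object: `gene`, `trait`, `n_instruments`, `beta`,
#'   `se`, `p` and the per-instrument `ratios` tibble.  Errors when fewer
#'   than 3 usable instruments remain.
#' @export
ivw_mr <- function(exposure, outcome, instruments = NULL, gene = NA_character_,
                   trait = NA_character_) {
  if (is.null(instruments)) instruments <- intersect(exposure$id, outcome$id)
  ex <- exposure[match(instruments, exposure$id), , drop = FALSE]
  ou <- outcome[match(instruments, outcome$id), , drop = FALSE]
  ok <- !is.na(ex$id) & !is.na(ou$id)
  ex <- ex[ok, , drop = FALSE]; ou <- ou[ok, , drop = FALSE]
  if (!is.null(ex[["effect_allele"]]) && !is.null(ou[["effect_allele"]])) {
    same <- ex$effect_allele == ou$effect_allele
    swapped <- if (!is.null(ex[["other_allele"]]) &&
                   !is.null(ou[["other_allele"]])) {
      !same & ex$effect_allele == ou$other_allele &
        ex$other_allele == ou$effect_allele
    } else {
      rep(FALSE, length(same))
    }
    ou$beta[swapped] <- -ou$beta[swapped]
    keep <- same | swapped
    ex <- ex[keep, , drop = FALSE]; ou <- ou[keep, , drop = FALSE]
  }
  zero <- ex$beta == 0
  if (any(zero)) {
    warn(sprintf("%d instrument(s) with zero exposure effect dropped",
                 sum(zero)))
    ex <- ex[!zero, , drop = FALSE]; ou <- ou[!zero, , drop = FALSE]
  }
  if (nrow(ex) < 3) {
    abort(sprintf(
      "Mendelian randomization requires at least 3 independent instrumental variables; got %d",
      nrow(ex)))
  }
  ratio <- ou$beta / ex$beta
  se <- ou$se / abs(ex$beta)
  w <- se^-2
  beta <- sum(ratio * w) / sum(w)
  se_ivw <- sum(w)^-0.5
  structure(list(
    gene = gene, trait = trait, n_instruments = nrow(ex),
    beta = beta, se = se_ivw,
    p = 2 * pnorm(-abs(beta / se_ivw)),
    ratios = tibble(id = ex$id, beta_exp = ex$beta, beta_out = ou$beta,
                    ratio = ratio, se = se)), class = "cha_mr")
}

#' @export
print.cha_mr <- function(x, ...) {
  cat(sprintf(
    "IVW Mendelian randomization%s: beta = %.3f, SE = %.3f, p = %.3g (%d instruments)\n",
    if (!is.na(x$gene)) sprintf(" [%s ~ %s]", x$gene, x$trait) else "",
    x$beta, x$se, x$p, x$n_instruments))
  invisible(x)
}

#' @rdname ivw_mr
#' @param x A `cha_mr` object.
#' @param ... Unused.
#' @export
tidy.cha_mr <- function(x, ...) x$ratios

#' @rdname ivw_mr
#' @export
glance.cha_mr <- function(x, ...) {
  tibble(gene = x$gene, trait = x$trait, n_instruments = x$n_instruments,
         beta = x$beta, se = x$se, p = x$p)
}

#' Screen gene-trait pairs with IVW Mendelian randomization
#'
#' For each (gene, trait) pair: cis eQTL variants with `p < p_eqtl_max`
#' within `window` bases of the gene's TSS are clumped at `r2 < r2_max`;
#' when at least 3 instruments survive, fixed-effects IVW MR of trait on
#' gene expression is run and the pair is flagged causal iff
#' `p < alpha`.  Pairs with fewer instruments are reported as not
#' testable.
#'
#' @param pairs Tibble with columns `gene_id`, `trait`.
#' @param eqtl Exposure summary statistics with columns `gene`, `id`,
#'   `chrom`, `position`, `beta`, `se`, `p`.
#' @param gwas Outcome summary statistics with columns `trait`, `id`,
#'   `beta`, `se`, `p`.
#' @param ld Long-format LD tibble.
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`) used for the TSS window.
#' @param p_eqtl_max Genome-wide significance cutoff for instruments.
#' @param window Half-width of the cis window around the TSS, in bases.
#' @param r2_max LD independence ceiling for clumping.
#' @param alpha Nominal significance level for the causal flag.
#' @return Tibble with one row per pair: `gene_id`, `trait`, `testable`,
#'   `n_instruments`, `beta`, `se`, `p`, `causal`.
#' @export
mr_screen <- function(pairs, eqtl, gwas, ld, genes, p_eqtl_max = 5e-8,
                      window = 500000, r2_max = 0.1, alpha = 0.05) {
  genes <- validate_intervals(genes, "gene table")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  names(tss) <- genes$gene_id
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene_id[i]; tr <- pairs$trait[i]
    base <- tibble(gene_id = g, trait = tr, testable = FALSE,
                   n_instruments = 0L, beta = NA_real_, se = NA_real_,
                   p = NA_real_, causal = FALSE)
    if (!g %in% names(tss)) return(base)
    ex <- eqtl[eqtl$gene == g & eqtl$p < p_eqtl_max &
                 abs(eqtl$position - tss[[g]]) <= window, , drop = FALSE]
    if (nrow(ex) < 3) return(base)
    ex <- clump(ex, ld, r2_max = r2_max, window = 2 * window)
    ou <- gwas[gwas$trait == tr, , drop = FALSE]
    inst <- intersect(ex$id, ou$id)
    if (length(inst) < 3) return(base)
    fit <- ivw_mr(ex, ou, instruments = inst, gene = g, trait = tr)
    tibble(gene_id = g, trait = tr, testable = TRUE,
           n_instruments = fit$n_instruments, beta = fit$beta,
           se = fit$se, p = fit$p, causal = fit$p < alpha)
  })
  bind_rows(rows)
}
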