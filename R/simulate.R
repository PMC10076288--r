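#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators with defaults
#' that echo the magnitudes of the study system: a 2 x 5 Mb genome with 300
#' genes and 2000 enhancers, a planted CHA fraction of 4.5%, hub promoters
#' whose loop degree sits far above a 1-9 background, pause-index medians
#' of 2.96 (hub) and 5.15 (non-hub), and a causal effect of 0.41 for
#' planted gene-trait pairs.  Every generator is a deterministic function
#' of the configuration, including its `seed`.
#'
#' @param seed Integer seed; each generator derives its own stream from it.
#' @param ... Named overrides of any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1234, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = tibble(chrom = c("chr1", "chr2"), length = c(5e6, 5e6)),
    # gene model
    n_genes = 300,
    gene_length = c(8000, 25000),
    gene_margin = 2500,
    # enhancer landscape
    n_enhancers = 2000,
    enhancer_width = c(500, 1800),
    n_promoter_peaks = 60,
    n_blacklist_peaks = 20,
    n_blacklist = 20,
    blacklist_width = 10000,
    # CAGE model
    cha_fraction = 0.045,
    cage_nb_mu = 4,
    cage_nb_size = 2,
    cha_multiplier = 100,
    n_zero_cage = 100,
    # annotation enrichment (CGI / conserved elements)
    cgi_rate_cha = 0.14, cgi_rate_regular = 0.06,
    hcne_rate_cha = 0.31, hcne_rate_regular = 0.10,
    n_background_cgi = 150, n_background_hcne = 150,
    annotation_width = c(400, 1200),
    # TADs
    tad_size = 7e5,
    # signal model
    track_background = 0.1,
    peak_height_regular = 2,
    peak_height_cha = 6,
    # connectome model
    n_connected_promoters = 200,
    n_hubs = 8,
    hub_degrees = c(30, 31),
    background_degree_support = 1:9,
    background_degree_lambda = 4,
    regular_loop_rate = 0.4,
    regular_loop_mean = 4.5,
    n_decoy_loops = 300,
    # run-on / pausing model
    pi_median_hub = 2.96,
    pi_median_nonhub = 5.15,
    pi_sdlog = 0.5,
    body_density = c(0.5, 2),
    # variant / MR model
    n_mr_genes = 40,
    n_causal = 13,
    theta = 0.41,
    n_instruments = 20,
    beta_exposure = c(0.2, 0.5),
    se_exposure = 0.002,
    se_outcome = 0.05,
    n_redundant = 3,
    redundant_r2 = 0.95,
    background_r2_max = 0.05,
    traits = c("rheumatoid_arthritis", "systemic_lupus_erythematosus",
               "inflammatory_bowel_disease", "type_1_diabetes"),
    n_pics_cha = 60, n_pics_regular = 30, n_pics_background = 60)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown sim_config parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  if (cfg$cha_fraction <= 0 || cfg$cha_fraction >= 1) {
    abort("cha_fraction must lie in (0, 1)")
  }
  structure(cfg, class = "sim_config")
}

sim_seed <- function(cfg, offset) cfg$seed + offset

#' Simulate the genomic backbone
#'
#' Places non-overlapping, strand-annotated gene bodies on the configured
#' chromosomes (one gene per uniform slot with jitter and margins so the
#' promoter and metagene windows stay on-contig), together with promoter
#' windows, blacklist regions, contiguous TADs, and CpG-island /
#' conserved-element annotations.  When a classified enhancer table is
#' supplied, annotations are planted with label-dependent rates (midpoint
#' inside the enhancer), so overlap-proportion tests recover a known
#' contrast; otherwise annotation placement is uniform.
#'
#' @param cfg A [sim_config()].
#' @param enhancers Optional classified enhancer table used to enrich
#'   CGI/HCNE placement at CHA enhancers.
#' @return List with tibbles `genes`, `promoters`, `blacklist`, `tads`,
#'   `cgi`, `hcne`.
#' @export
simulate_genome <- function(cfg, enhancers = NULL) {
  withr::with_seed(sim_seed(cfg, 1), {
    per_chrom <- split_count(cfg$n_genes, nrow(cfg$genome))
    genes <- bind_rows(lapply(seq_len(nrow(cfg$genome)), function(i) {
      n <- per_chrom[i]
      if (cfg$genome$length[i] < n * (diff(cfg$gene_length) +
                                      2 * cfg$gene_margin)) {
        abort("genome too small for the requested gene count")
      }
      slot <- floor(cfg$genome$length[i] / n)
      len <- round(runif(n, cfg$gene_length[1],
                         min(cfg$gene_length[2], slot - 2 * cfg$gene_margin)))
      slack <- slot - len - 2 * cfg$gene_margin
      start <- (seq_len(n) - 1) * slot + cfg$gene_margin +
        floor(runif(n) * pmax(1, slack))
      tibble(chrom = cfg$genome$chrom[i], start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE))
    }))
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    genes <- genes[c("chrom", "start", "end", "gene_id", "strand")]
    promoters <- promoter_regions(genes)
    promoters$gene_id <- genes$gene_id
    blacklist <- bind_rows(lapply(seq_len(nrow(cfg$genome)), function(i) {
      n <- split_count(cfg$n_blacklist, nrow(cfg$genome))[i]
      s <- floor(runif(n, 0, cfg$genome$length[i] - cfg$blacklist_width))
      tibble(chrom = cfg$genome$chrom[i], start = s,
             end = s + cfg$blacklist_width)
    }))
    tads <- bind_rows(lapply(seq_len(nrow(cfg$genome)), function(i) {
      bnd <- seq(0, cfg$genome$length[i], by = cfg$tad_size)
      if (bnd[length(bnd)] < cfg$genome$length[i]) {
        bnd <- c(bnd, cfg$genome$length[i])
      }
      tibble(chrom = cfg$genome$chrom[i], start = bnd[-length(bnd)],
             end = bnd[-1])
    }))
    cgi <- place_annotations(cfg, enhancers, cfg$cgi_rate_cha,
                             cfg$cgi_rate_regular, cfg$n_background_cgi)
    hcne <- place_annotations(cfg, enhancers, cfg$hcne_rate_cha,
                              cfg$hcne_rate_regular, cfg$n_background_hcne)
    list(genes = genes, promoters = promoters, blacklist = blacklist,
         tads = tads, cgi = cgi, hcne = hcne)
  })
}

split_count <- function(n, k) {
  base <- rep(floor(n / k), k)
  extra <- n - sum(base)
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
  base
}

place_annotations <- function(cfg, enhancers, rate_cha, rate_regular,
                              n_background) {
  w <- function(n) round(runif(n, cfg$annotation_width[1],
                               cfg$annotation_width[2]))
  background <- bind_rows(lapply(seq_len(nrow(cfg$genome)), function(i) {
    n <- split_count(n_background, nrow(cfg$genome))[i]
    wd <- w(n)
    m <- floor(runif(n, max(wd), cfg$genome$length[i] - max(wd)))
    tibble(chrom = cfg$genome$chrom[i], start = m - floor(wd / 2),
           end = m - floor(wd / 2) + wd)
  }))
  if (is.null(enhancers)) return(sort_intervals(background))
  rate <- ifelse(enhancers$label == "CHA", rate_cha, rate_regular)
  hit <- runif(nrow(enhancers)) < rate
  idx <- which(hit)
  wd <- w(length(idx))
  # midpoint of the annotation lands inside the enhancer
  m <- floor(enhancers$start[idx] +
               runif(length(idx)) * (enhancers$end[idx] -
                                     enhancers$start[idx]))
  planted <- tibble(chrom = enhancers$chrom[idx],
                    start = pmax(0, m - floor(wd / 2)),
                    end = pmax(0, m - floor(wd / 2)) + wd)
  sort_intervals(bind_rows(background, planted))
}

#' Simulate the enhancer landscape with planted CHA enhancers
#'
#' Generates H3K27ac peaks (true enhancers in free intergenic cells, plus
#' planted promoter- and blacklist-overlapping peaks that the enhancer
#' caller must remove), a three-replicate CAGE tag matrix, and background
#' signal tracks with taller peaks at planted CHA enhancers.  Background
#' CAGE tags are drawn from a shifted negative binomial (zero inflation is
#' realised by the enhancers that carry no CAGE annotation); planted CHA
#' annotations are multiplied by `cha_multiplier` so they exceed the 90th
#' tag percentile.  The number of tag-carrying annotations is derived from
#' the planted count k as 10k - 1, which makes the inclusive top decile of
#' nonzero tags exactly the planted set, and makes the by-chance CHA
#' fraction under a unit multiplier equal to `cha_fraction`.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return List: `peaks` (all H3K27ac peaks, shuffled), `cage` (replicate
#'   matrix), tracks `atac`, `h3k27ac`, `input`, and `truth` (planted CHA
#'   enhancer ids, per-peak roles, planted tag values).
#' @export
simulate_enhancer_landscape <- function(cfg, genome) {
  withr::with_seed(sim_seed(cfg, 2), {
    cell <- 2200
    blocked <- bind_rows(genome$promoters[c("chrom", "start", "end")],
                         genome$blacklist[c("chrom", "start", "end")])
    per_chrom <- split_count(cfg$n_enhancers, nrow(cfg$genome))
    enh <- bind_rows(lapply(seq_len(nrow(cfg$genome)), function(i) {
      ch <- cfg$genome$chrom[i]
      cells <- tibble(chrom = ch,
                      start = seq(0, cfg$genome$length[i] - cell, by = cell))
      cells$end <- cells$start + cell
      free <- subtract_overlapping(cells, blocked)
      if (nrow(free) < per_chrom[i]) {
        abort("genome too small for the requested enhancer count")
      }
      pick <- free[sample(nrow(free), per_chrom[i]), , drop = FALSE]
      wd <- round(runif(per_chrom[i], cfg$enhancer_width[1],
                        cfg$enhancer_width[2]))
      off <- floor(runif(per_chrom[i]) * (cell - wd))
      tibble(chrom = ch, start = pick$start + off,
             end = pick$start + off + wd)
    }))
    enh <- sort_intervals(enh)
    enh$name <- sprintf("enh_%05d", seq_len(nrow(enh)))

    # planted CHA enhancers, balanced across chromosomes
    k <- round(cfg$cha_fraction * cfg$n_enhancers)
    k_per <- split_count(k, nrow(cfg$genome))
    n_nonzero <- 10 * k - 1
    nz_per <- split_count(n_nonzero, nrow(cfg$genome))
    planted <- character(0); carriers <- character(0)
    for (i in seq_len(nrow(cfg$genome))) {
      ids <- enh$name[enh$chrom == cfg$genome$chrom[i]]
      car <- sample(ids, nz_per[i])
      planted <- c(planted, car[seq_len(k_per[i])])
      carriers <- c(carriers, car)
    }

    # CAGE matrix: one 200-bp annotation centred in each carrier enhancer,
    # plus all-zero annotations on non-carriers
    carrier_rows <- enh[match(carriers, enh$name), ]
    mid <- floor((carrier_rows$start + carrier_rows$end) / 2)
    base_tag <- 1 + rnbinom(length(carriers), size = cfg$cage_nb_size,
                            mu = cfg$cage_nb_mu)
    tag <- ifelse(carriers %in% planted, base_tag * cfg$cha_multiplier,
                  base_tag)
    zero_ids <- sample(setdiff(enh$name, carriers),
                       min(cfg$n_zero_cage, cfg$n_enhancers - n_nonzero))
    zero_rows <- enh[match(zero_ids, enh$name), ]
    cage <- bind_rows(
      tibble(id = sprintf("cage_%05d", seq_along(carriers)),
             chrom = carrier_rows$chrom, start = mid - 100, end = mid + 100,
             rep1 = tag, rep2 = tag, rep3 = tag),
      tibble(id = sprintf("cage_z%04d", seq_along(zero_ids)),
             chrom = zero_rows$chrom,
             start = floor((zero_rows$start + zero_rows$end) / 2) - 100,
             end = floor((zero_rows$start + zero_rows$end) / 2) + 100,
             rep1 = 0, rep2 = 0, rep3 = 0))

    # planted promoter- and blacklist-overlapping peaks
    pr <- genome$promoters[sample(nrow(genome$promoters),
                                  cfg$n_promoter_peaks), ]
    prom_peaks <- tibble(chrom = pr$chrom,
                         start = pr$start + 500, end = pr$start + 1500,
                         name = sprintf("promopeak_%03d",
                                        seq_len(cfg$n_promoter_peaks)))
    bl <- genome$blacklist[sample(nrow(genome$blacklist),
                                  cfg$n_blacklist_peaks, replace = TRUE), ]
    bl_peaks <- tibble(chrom = bl$chrom,
                       start = bl$start + 100, end = bl$start + 900,
                       name = sprintf("blpeak_%03d",
                                      seq_len(cfg$n_blacklist_peaks)))
    peaks <- bind_rows(enh, prom_peaks, bl_peaks)
    peaks <- peaks[sample(nrow(peaks)), , drop = FALSE]

    bg <- tibble(chrom = cfg$genome$chrom, start = 0,
                 end = cfg$genome$length, value = cfg$track_background)
    bump <- function(scale) {
      h <- ifelse(enh$name %in% planted, cfg$peak_height_cha,
                  cfg$peak_height_regular) * scale
      bind_rows(bg, tibble(chrom = enh$chrom, start = enh$start,
                           end = enh$end, value = h))
    }
    list(peaks = peaks, cage = cage,
         atac = bump(1), h3k27ac = bump(1.5), input = bg,
         truth = list(planted_cha = sort(planted),
                      carriers = sort(carriers),
                      true_enhancers = enh$name,
                      removed_peaks = c(prom_peaks$name, bl_peaks$name),
                      tags = tibble(id = carriers, tag = tag)))
  })
}

#' Simulate an enhancer-promoter connectome with planted hubs
#'
#' Draws chromatin loops between CHA enhancers and gene promoters on the
#' same chromosome.  A fixed number of planted hub promoters receive loop
#' degrees far above the background support (defaults 30-31 versus 1-9,
#' Poisson-weighted), so hub calling at the 90th percentile of distinct
#' loop counts recovers exactly the planted set.  Regular enhancers loop
#' to promoters at a lower rate, giving the CHA versus regular loop-density
#' contrast, and decoy loops carry q-values at or above the significance
#' cutoff so loop filtering is exercised.  True loops have q < 1e-6.
#'
#' @param cfg A [sim_config()].
#' @param table Classified enhancer table.
#' @param promoters Promoter tibble with `gene_id`.
#' @return List: `loops` (unfiltered loop tibble) and `truth` (hub gene
#'   ids, connected gene ids, planted per-promoter CHA degrees).
#' @export
simulate_connectome <- function(cfg, table, promoters) {
  withr::with_seed(sim_seed(cfg, 3), {
    cha <- table[table$label == "CHA", , drop = FALSE]
    if (!nrow(cha)) abort("no CHA enhancer to wire into the connectome")
    idx_conn <- sample(nrow(promoters), cfg$n_connected_promoters)
    hubs <- idx_conn[seq_len(cfg$n_hubs)]
    degrees <- integer(cfg$n_connected_promoters)
    degrees[seq_len(cfg$n_hubs)] <-
      rep(cfg$hub_degrees, length.out = cfg$n_hubs)
    supp <- cfg$background_degree_support
    pr_supp <- stats::dpois(supp, cfg$background_degree_lambda)
    degrees[-seq_len(cfg$n_hubs)] <-
      sample(supp, cfg$n_connected_promoters - cfg$n_hubs, replace = TRUE,
             prob = pr_supp / sum(pr_supp))
    cha_rows <- lapply(seq_along(idx_conn), function(j) {
      p <- promoters[idx_conn[j], ]
      pool <- which(cha$chrom == p$chrom)
      if (length(pool) < degrees[j]) {
        abort("not enough same-chromosome CHA enhancers for the requested degree")
      }
      e <- cha[sample(pool, degrees[j]), ]
      tibble(chrom1 = p$chrom, start1 = p$start, end1 = p$end,
             chrom2 = e$chrom, start2 = e$start, end2 = e$end)
    })
    # regular-enhancer loops (lower density)
    reg <- table[table$label == "regular", , drop = FALSE]
    looped <- runif(nrow(reg)) < cfg$regular_loop_rate
    reg_rows <- lapply(which(looped), function(j) {
      n <- 1 + rpois(1, cfg$regular_loop_mean - 1)
      pool <- which(promoters$chrom == reg$chrom[j])
      pr <- promoters[sample(pool, min(n, length(pool))), ]
      tibble(chrom1 = reg$chrom[j], start1 = reg$start[j], end1 = reg$end[j],
             chrom2 = pr$chrom, start2 = pr$start, end2 = pr$end)
    })
    loops <- bind_rows(c(cha_rows, reg_rows))
    loops$qvalue <- runif(nrow(loops)) * 1e-7
    # decoys at or above the cutoff
    if (cfg$n_decoy_loops > 0) {
      ei <- sample(nrow(table), cfg$n_decoy_loops, replace = TRUE)
      dec <- lapply(ei, function(i) {
        pool <- which(promoters$chrom == table$chrom[i])
        p <- promoters[sample(pool, 1), ]
        tibble(chrom1 = table$chrom[i], start1 = table$start[i],
               end1 = table$end[i], chrom2 = p$chrom, start2 = p$start,
               end2 = p$end, qvalue = runif(1, 1e-6, 1))
      })
      loops <- bind_rows(loops, bind_rows(dec))
    }
    loops <- validate_loops(loops)
    loops$name <- sprintf("loop_%06d", seq_len(nrow(loops)))
    loops$count <- 1 + rpois(nrow(loops), 20)
    loops <- loops[c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                     "name", "count", "qvalue")]
    list(loops = loops,
         truth = list(
           hub_genes = sort(promoters$gene_id[hubs]),
           connected_genes = sort(promoters$gene_id[idx_conn]),
           degrees = tibble(gene_id = promoters$gene_id[idx_conn],
                            cha_degree = degrees)))
  })
}

#' Simulate run-on sequencing coverage with known pause indices
#'
#' Each gene receives a true pause index drawn log-normally with a
#' group-specific median (hub genes versus all others) and a uniform body
#' density; coverage is written as exact step functions over the
#' promoter-proximal window and the gene body, so recomputed pause indices
#' equal the planted ones.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene-model tibble.
#' @param hub_genes Character vector of hub gene ids (lower pause index).
#' @return List: `track` (coverage tibble) and `truth` (per-gene true
#'   pause index and body density).
#' @export
simulate_groseq <- function(cfg, genes, hub_genes = character(0)) {
  withr::with_seed(sim_seed(cfg, 4), {
    is_hub <- genes$gene_id %in% hub_genes
    med <- ifelse(is_hub, cfg$pi_median_hub, cfg$pi_median_nonhub)
    pi_true <- rlnorm(nrow(genes), meanlog = log(med), sdlog = cfg$pi_sdlog)
    body <- runif(nrow(genes), cfg$body_density[1], cfg$body_density[2])
    rows <- lapply(seq_len(nrow(genes)), function(j) {
      plus <- genes$strand[j] == "+"
      tss <- if (plus) genes$start[j] else genes$end[j] - 1
      if (plus) {
        prom <- c(tss - 50, tss + 300); bd <- c(tss + 300, genes$end[j])
      } else {
        prom <- c(tss - 299, tss + 51); bd <- c(genes$start[j], tss - 299)
      }
      tibble(chrom = genes$chrom[j],
             start = c(prom[1], bd[1]), end = c(prom[2], bd[2]),
             value = c(pi_true[j] * body[j], body[j]))
    })
    track <- bind_rows(rows)
    # pad contig ends so coverage vectors span the genome
    pad <- tibble(chrom = cfg$genome$chrom,
                  start = cfg$genome$length - 1, end = cfg$genome$length,
                  value = 0)
    list(track = sort_intervals(bind_rows(track, pad)),
         truth = tibble(gene_id = genes$gene_id, true_pi = pi_true,
                        body_density = body, hub = is_hub))
  })
}

#' Simulate fine-mapped variants, eQTL/GWAS summary statistics and LD
#'
#' For a set of study genes, draws strong cis instruments (exposure effects
#' well past genome-wide significance), outcome effects equal to
#' `theta * beta_exposure` plus noise for causal genes and pure noise
#' otherwise, a block-diagonal LD table with near-independent instruments
#' plus planted redundant variants in high LD, and fine-mapped (PICS-like)
#' point variants placed inside CHA enhancers, regular enhancers and the
#' open genome.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene-model tibble.
#' @param table Optional classified enhancer table (for variant placement).
#' @param loops Optional filtered loop tibble (for variant-gene truth).
#' @param promoters Optional promoter tibble with `gene_id`.
#' @param study_genes Optional gene ids to screen; defaults to a random
#'   sample of `n_mr_genes`.
#' @return List: `variants`, `eqtl`, `gwas`, `ld`, `pairs` (gene-trait
#'   pairs to screen) and `truth` (causal gene-trait pairs, planted
#'   variant-gene links).
#' @export
simulate_gwas_eqtl <- function(cfg, genes, table = NULL, loops = NULL,
                               promoters = NULL, study_genes = NULL) {
  withr::with_seed(sim_seed(cfg, 5), {
    if (is.null(study_genes)) {
      study_genes <- sort(sample(genes$gene_id, cfg$n_mr_genes))
    }
    gsub <- genes[match(study_genes, genes$gene_id), ]
    tss <- ifelse(gsub$strand == "+", gsub$start, gsub$end - 1)
    trait <- sample(cfg$traits, length(study_genes), replace = TRUE)
    causal <- seq_along(study_genes) %in%
      sample(length(study_genes), min(cfg$n_causal, length(study_genes)))
    eqtl <- NULL; gwas <- NULL; ld <- NULL
    for (i in seq_along(study_genes)) {
      n <- cfg$n_instruments
      pos <- tss[i] + round(runif(n, -0.8, 0.8) * 5e5)
      pos <- pmax(0, pos)
      id <- sprintf("rs%s_%03d", gsub("gene_", "", study_genes[i]),
                    seq_len(n + cfg$n_redundant))
      b_exp <- sample(c(-1, 1), n, TRUE) *
        runif(n, cfg$beta_exposure[1], cfg$beta_exposure[2])
      # redundant shadows of the first instruments, slightly weaker
      rid <- seq_len(cfg$n_redundant)
      pos <- c(pos, pos[rid] + 1000)
      b_exp <- c(b_exp, 0.9 * b_exp[rid])
      ntot <- n + cfg$n_redundant
      se_e <- rep(cfg$se_exposure, ntot)
      b_out <- (if (causal[i]) cfg$theta * b_exp else 0) +
        rnorm(ntot, 0, cfg$se_outcome)
      eqtl <- bind_rows(eqtl, tibble(
        gene = study_genes[i], id = id, chrom = gsub$chrom[i],
        position = pos, beta = b_exp, se = se_e,
        p = 2 * pnorm(-abs(b_exp / se_e))))
      gwas <- bind_rows(gwas, tibble(
        trait = trait[i], id = id, beta = b_out,
        se = cfg$se_outcome,
        p = 2 * pnorm(-abs(b_out / cfg$se_outcome))))
      pair_r2 <- function(i1, i2, r2) tibble(id1 = id[i1], id2 = id[i2],
                                             r2 = r2)
      cmb <- utils::combn(ntot, 2)
      r2 <- runif(ncol(cmb), 0, cfg$background_r2_max)
      shadow <- (cmb[1, ] %in% rid & cmb[2, ] == cmb[1, ] + n)
      r2[shadow] <- cfg$redundant_r2
      ld <- bind_rows(ld, pair_r2(cmb[1, ], cmb[2, ], r2))
    }
    pairs <- tibble(gene_id = study_genes, trait = trait)
    # fine-mapped point variants in and around enhancers
    variants <- NULL; links <- NULL
    if (!is.null(table)) {
      place_in <- function(rows, n, prefix) {
        if (!nrow(rows) || n == 0) return(NULL)
        pick_i <- sample(nrow(rows), n, replace = TRUE)
        pick <- rows[pick_i, ]
        tibble(id = sprintf("%s_%04d", prefix, seq_len(n)),
               chrom = pick$chrom,
               position = floor(pick$start +
                                runif(n) * (pick$end - pick$start)),
               pics_prob = runif(n),
               trait = sample(cfg$traits, n, replace = TRUE),
               .row = pick_i)
      }
      cha <- table[table$label == "CHA", , drop = FALSE]
      reg <- table[table$label == "regular", , drop = FALSE]
      in_cha <- place_in(cha, cfg$n_pics_cha, "rsCHA")
      in_reg <- place_in(reg, cfg$n_pics_regular, "rsREG")
      # background variants rejected out of CHA footprints so the planted
      # variant-gene truth is exhaustive (arithmetic membership test,
      # independent of the interval engine)
      nb <- cfg$n_pics_background
      cha_by_chrom <- split(cha, cha$chrom)
      in_any_cha <- function(chrom, pos) {
        vapply(seq_along(pos), function(i) {
          cc <- cha_by_chrom[[chrom[i]]]
          if (is.null(cc)) return(FALSE)
          any(cc$start <= pos[i] & pos[i] < cc$end)
        }, logical(1))
      }
      bg_chrom <- sample(cfg$genome$chrom, nb, replace = TRUE)
      bg_pos <- floor(runif(nb) *
        cfg$genome$length[match(bg_chrom, cfg$genome$chrom)])
      while (any(hit <- in_any_cha(bg_chrom, bg_pos))) {
        bg_pos[hit] <- floor(runif(sum(hit)) *
          cfg$genome$length[match(bg_chrom[hit], cfg$genome$chrom)])
      }
      variants <- bind_rows(
        in_cha[setdiff(names(in_cha), ".row")],
        in_reg[setdiff(names(in_reg), ".row")],
        tibble(id = sprintf("rsBG_%04d", seq_len(nb)),
               chrom = bg_chrom, position = bg_pos,
               pics_prob = runif(nb),
               trait = sample(cfg$traits, nb, replace = TRUE)))
      # truth for variant->gene mapping, derived by exact coordinate joins
      # on the constructed loop anchors (never by interval overlap)
      if (!is.null(loops) && !is.null(promoters) && !is.null(in_cha)) {
        ekey <- paste(cha$chrom, cha$start, cha$end)
        pkey <- paste(promoters$chrom, promoters$start, promoters$end)
        k1 <- paste(loops$chrom1, loops$start1, loops$end1)
        k2 <- paste(loops$chrom2, loops$start2, loops$end2)
        eg <- bind_rows(
          tibble(e = match(k1, ekey), g = match(k2, pkey)),
          tibble(e = match(k2, ekey), g = match(k1, pkey)))
        eg <- eg[!is.na(eg$e) & !is.na(eg$g), ]
        ve <- tibble(variant_id = in_cha$id, e = in_cha$.row)
        links <- left_join(ve, eg, by = "e",
                           relationship = "many-to-many") %>%
          filter(!is.na(.data$g)) %>%
          mutate(enhancer_id = cha$enhancer_id[.data$e],
                 gene_id = promoters$gene_id[.data$g]) %>%
          distinct(.data$variant_id, .data$enhancer_id, .data$gene_id)
      }
    }
    list(variants = variants, eqtl = eqtl, gwas = gwas, ld = ld,
         pairs = pairs,
         truth = list(causal_pairs = pairs[causal, , drop = FALSE],
                      variant_gene_links = links))
  })
}

#' Run the whole synthetic study end to end
#'
#' Generates the genome, the enhancer landscape, the connectome, run-on
#' coverage and MR inputs under one configuration, and runs the pipeline
#' (enhancer calling, CHA classification, loop filtering, hub calling,
#' pause indices) on the generated data.
#'
#' @param cfg A [sim_config()].
#' @return A list with the generated inputs, the pipeline results and all
#'   planted truths.
#' @export
simulate_study <- function(cfg = sim_config()) {
  genome <- simulate_genome(cfg)
  land <- simulate_enhancer_landscape(cfg, genome)
  enhancers <- call_enhancers(land$peaks, genome$promoters,
                              genome$blacklist)
  cage <- combine_replicates(land$cage)
  table <- classify_cha(enhancers, cage)
  genome[c("cgi", "hcne")] <-
    simulate_genome(cfg, enhancers = table)[c("cgi", "hcne")]
  conn <- simulate_connectome(cfg, table, genome$promoters)
  loops <- filter_loops(conn$loops)
  units <- call_hubs(loops, table, genome$promoters)
  sets <- unit_gene_sets(units)
  gro <- simulate_groseq(cfg, genome$genes, hub_genes = conn$truth$hub_genes)
  pause <- pause_index_table(gro$track, genome$genes)
  mr_in <- simulate_gwas_eqtl(cfg, genome$genes, table = table,
                              loops = loops, promoters = genome$promoters,
                              study_genes = NULL)
  list(cfg = cfg, genome = genome, landscape = land, enhancers = enhancers,
       cage = cage, table = table, connectome = conn, loops = loops,
       units = units, gene_sets = sets, groseq = gro, pause = pause,
       mr = mr_in)
}

#' Write all simulated inputs to a directory
#'
#' Emits the exact plain-text formats the package readers consume (BED,
#' BEDPE, bedGraph, TSV) plus truth sidecars, so generated data round-trip
#' losslessly through the I/O layer.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tsv <- function(x, f) write.table(x, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  write_bed(sim$landscape$peaks, p("h3k27ac_peaks.bed"))
  write_bed(sim$genome$blacklist, p("blacklist.bed"))
  write_bed(sim$genome$cgi, p("cgi.bed"))
  write_bed(sim$genome$hcne, p("hcne.bed"))
  write_bed(sim$genome$tads, p("tads.bed"))
  tsv(sim$genome$genes, "genes.tsv")
  tsv(sim$landscape$cage, "cage_matrix.tsv")
  write_bedgraph(sim$landscape$atac, p("atac.bedgraph"))
  write_bedgraph(sim$landscape$input, p("input.bedgraph"))
  write_bedgraph(sim$groseq$track, p("groseq.bedgraph"))
  write_bedpe(sim$connectome$loops, p("loops.bedpe"))
  write_enhancer_bed(sim$table, p("enhancers_classified.bed"))
  tsv(sim$mr$variants, "pics_variants.tsv")
  tsv(sim$mr$eqtl, "eqtl.tsv")
  tsv(sim$mr$gwas, "gwas.tsv")
  tsv(sim$mr$ld, "ld.tsv")
  tsv(tibble(id = sim$landscape$truth$planted_cha), "truth_cha.tsv")
  tsv(sim$connectome$truth$degrees, "truth_degrees.tsv")
  tsv(sim$groseq$truth, "truth_pause.tsv")
  tsv(sim$mr$truth$causal_pairs, "truth_causal_pairs.tsv")
  invisible(dir)
}
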