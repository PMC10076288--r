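small_cfg <- function(seed = 1234, ...) {
  sim_config(seed = seed,
             genome = tibble::tibble(chrom = c("chr1", "chr2"),
                                     length = c(2e6, 2e6)),
             n_genes = 80, n_enhancers = 400,
             n_connected_promoters = 60, n_hubs = 4,
             hub_degrees = 8, background_degree_support = 1:5,
             n_mr_genes = 10, n_causal = 4,
             n_pics_cha = 20, n_pics_regular = 10, n_pics_background = 20,
             ...)
}

test_that("generators are deterministic functions of the configuration", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  l1 <- simulate_enhancer_landscape(cfg, g1)
  l2 <- simulate_enhancer_landscape(cfg, g2)
  expect_identical(l1, l2)
  expect_false(identical(
    l1$cage, simulate_enhancer_landscape(small_cfg(seed = 2), g1)$cage))
})

test_that("the genome generator honours counts and promoter geometry", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 80)
  expect_equal(nrow(g$promoters), 80)
  expect_true(all(g$promoters$end - g$promoters$start == 4000))
  # gene bodies are disjoint per chromosome
  for (ch in unique(g$genes$chrom)) {
    gg <- dplyr::arrange(g$genes[g$genes$chrom == ch, ], start)
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # TADs tile each chromosome without gaps
  for (ch in cfg$genome$chrom) {
    tt <- g$tads[g$tads$chrom == ch, ]
    expect_equal(tt$start[-1], tt$end[-nrow(tt)])
  }
})

test_that("the landscape plants exactly the configured CHA structure", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  land <- simulate_enhancer_landscape(cfg, g)
  k <- round(cfg$cha_fraction * cfg$n_enhancers)
  expect_equal(length(land$truth$planted_cha), k)
  expect_equal(length(land$truth$carriers), 10 * k - 1)
  enh <- call_enhancers(land$peaks, g$promoters, g$blacklist)
  expect_setequal(enh$name, land$truth$true_enhancers)
  expect_equal(nrow(land$peaks) - nrow(enh),
               length(land$truth$removed_peaks))
  tb <- classify_cha(enh, combine_replicates(land$cage))
  expect_setequal(tb$enhancer_id[tb$label == "CHA"], land$truth$planted_cha)
})

test_that("a unit CAGE multiplier yields chance-level classification", {
  cfg <- small_cfg(cha_multiplier = 1)
  g <- simulate_genome(cfg)
  land <- simulate_enhancer_landscape(cfg, g)
  enh <- call_enhancers(land$peaks, g$promoters, g$blacklist)
  tb <- classify_cha(enh, combine_replicates(land$cage))
  recall <- mean(land$truth$planted_cha %in%
                   tb$enhancer_id[tb$label == "CHA"])
  expect_lt(recall, 0.5)  # far from the exact recovery of a strong multiplier
  frac <- mean(tb$label == "CHA")
  expect_gte(frac, cfg$cha_fraction)
  expect_lt(frac, 3 * cfg$cha_fraction)
})

test_that("planted annotation enrichment is recovered by the overlap test", {
  cfg <- small_cfg(n_enhancers = 600, cgi_rate_cha = 0.5,
                   cgi_rate_regular = 0.1, n_background_cgi = 40)
  g <- simulate_genome(cfg)
  land <- simulate_enhancer_landscape(cfg, g)
  enh <- call_enhancers(land$peaks, g$promoters, g$blacklist)
  tb <- classify_cha(enh, combine_replicates(land$cage))
  ann <- simulate_genome(cfg, enhancers = tb)
  ov <- annotation_overlap_test(tb, ann$cgi)
  expect_gt(ov$prop_cha, 0.3)
  expect_lt(ov$prop_regular, 0.25)
})

test_that("the connectome generator wires the planted degrees exactly", {
  cfg <- small_cfg(n_enhancers = 1200, hub_degrees = 12,
                   background_degree_support = 1:5)
  g <- simulate_genome(cfg)
  land <- simulate_enhancer_landscape(cfg, g)
  enh <- call_enhancers(land$peaks, g$promoters, g$blacklist)
  tb <- classify_cha(enh, combine_replicates(land$cage))
  conn <- simulate_connectome(cfg, tb, g$promoters)
  loops <- filter_loops(conn$loops)
  expect_lt(nrow(loops), nrow(conn$loops))  # decoys removed
  units <- call_hubs(loops, tb, g$promoters)
  got <- units[match(conn$truth$degrees$gene_id, units$gene_id), ]
  expect_equal(got$loop_count, conn$truth$degrees$cha_degree)
  expect_setequal(units$gene_id[units$hub], conn$truth$hub_genes)
})

test_that("run-on coverage inverts to the planted pause indices", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  gro <- simulate_groseq(cfg, g$genes, hub_genes = g$genes$gene_id[1:5])
  rec <- pause_index_table(gro$track, g$genes)
  expect_equal(nrow(rec), nrow(g$genes))  # every gene has promoter signal
  m <- dplyr::left_join(rec, gro$truth, by = "gene_id")
  expect_equal(m$pause_index, m$true_pi, tolerance = 1e-9)
})

test_that("simulated files round-trip through the package readers", {
  cfg <- small_cfg()
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  peaks <- read_bed(file.path(dir, "h3k27ac_peaks.bed"))
  expect_equal(peaks[c("chrom", "start", "end")],
               sim$landscape$peaks[c("chrom", "start", "end")],
               tolerance = 1e-9)
  lo <- read_bedpe(file.path(dir, "loops.bedpe"))
  expect_equal(lo[1:8], sim$connectome$loops[1:8], tolerance = 1e-9)
  expect_equal(lo$qvalue, sim$connectome$loops$qvalue, tolerance = 1e-8)
  tr <- read_bedgraph(file.path(dir, "groseq.bedgraph"))
  expect_equal(tr[c("chrom", "start", "end")],
               sim$groseq$track[c("chrom", "start", "end")],
               tolerance = 1e-9)
  expect_equal(tr$value, sim$groseq$track$value, tolerance = 1e-6)
  cg <- read_cage_matrix(file.path(dir, "cage_matrix.tsv"))
  expect_equal(cg, sim$landscape$cage, tolerance = 1e-9)
  ss <- read_summary_stats(file.path(dir, "eqtl.tsv"))
  expect_equal(ss$beta, sim$mr$eqtl$beta, tolerance = 1e-12)
  ld <- read_ld_table(file.path(dir, "ld.tsv"))
  expect_equal(nrow(ld), nrow(sim$mr$ld))
})
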