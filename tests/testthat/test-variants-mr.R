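test_that("PICS filtering is inclusive at the probability cutoff", {
  v <- tibble::tibble(id = c("a", "b", "c"), chrom = "chr1",
                      position = 1:3, pics_prob = c(0.025, 0.0249, 0.9))
  expect_equal(filter_pics(v)$id, c("a", "c"))
  v$pics_prob[2] <- 1.2
  expect_error(filter_pics(v), "pics_prob")
  withr::with_seed(41, {
    u <- tibble::tibble(id = sprintf("v%04d", 1:1000), chrom = "chr1",
                        position = 1:1000, pics_prob = runif(1000))
    kept <- nrow(filter_pics(u))
    expect_gt(kept, 950); expect_lte(kept, 1000)
  })
})

test_that("variants map to genes only through CHA enhancer loops", {
  enh <- interval_tbl(c("chr1", "chr1"), c(10000, 30000), c(11000, 31000),
                      name = c("eC", "eR"))
  enh$enhancer_id <- enh$name
  enh$label <- c("CHA", "regular")
  prom <- interval_tbl(rep("chr1", 2), c(100000, 200000),
                       c(104000, 204000))
  prom$gene_id <- c("IFNGR2_like", "IFNAR2_like")
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = c(10000, 10000, 30000),
    end1 = c(11000, 11000, 31000),
    chrom2 = "chr1", start2 = c(100000, 200000, 100000),
    end2 = c(104000, 204000, 104000),
    name = c("l1", "l2", "l3"), count = 5, qvalue = 1e-8)
  v <- tibble::tibble(id = c("rs_in_cha", "rs_in_reg"), chrom = "chr1",
                      position = c(10500, 30500))
  mp <- map_variants_to_genes(v, enh, loops, prom)
  expect_equal(nrow(mp), 2)  # one variant, two promoter contacts
  expect_setequal(mp$gene_id, c("IFNGR2_like", "IFNAR2_like"))
  expect_true(all(mp$variant_id == "rs_in_cha"))
  # adding loops can only add pairs
  mp1 <- map_variants_to_genes(v, enh, loops[1, ], prom)
  expect_true(all(do.call(paste, mp1) %in% do.call(paste, mp)))
})

test_that("clumping keeps the best variant per LD block within the window", {
  s <- tibble::tibble(id = c("v1", "v2"), chrom = "chr1",
                      position = c(1000, 5000), p = c(1e-10, 1e-8))
  ld <- tibble::tibble(id1 = "v1", id2 = "v2", r2 = 0.9)
  expect_equal(clump(s, ld, r2_max = 0.5, window = 250000)$id, "v1")
  s2 <- s; s2$position[2] <- 1e6 + 1000
  expect_equal(nrow(clump(s2, ld, r2_max = 0.5, window = 250000)), 2)
  expect_warning(
    kept <- clump(s, tibble::tibble(id1 = character(), id2 = character(),
                                    r2 = numeric()),
                  r2_max = 0.5, window = 250000),
    "treated as r2 = 0")
  expect_equal(nrow(kept), 2)
})

test_that("clumping equals an independent greedy re-run on block-diagonal LD", {
  withr::with_seed(47, {
    n <- 50
    block <- rep(1:10, each = 5)
    s <- tibble::tibble(id = sprintf("v%02d", 1:n), chrom = "chr1",
                        position = block * 40000 + rep(seq(0, 4000, 1000), 10),
                        p = runif(n))
    pairs <- t(utils::combn(n, 2))
    same <- block[pairs[, 1]] == block[pairs[, 2]]
    ld <- tibble::tibble(id1 = s$id[pairs[same, 1]],
                         id2 = s$id[pairs[same, 2]],
                         r2 = runif(sum(same), 0.2, 1))
    got <- clump(s, ld, r2_max = 0.4, window = 20000)
    expect_equal(got$id, bf_clump(s, ld, r2_max = 0.4, window = 20000))
    # record order never matters
    got2 <- clump(s[sample(n), ], ld, r2_max = 0.4, window = 20000)
    expect_equal(got2$id, got$id)
  })
})

test_that("IVW reduces to closed forms on degenerate instrument sets", {
  ex <- tibble::tibble(id = c("a", "b", "c", "d"), beta = c(2, 2, 2, 2),
                       se = 0.01)
  ou <- tibble::tibble(id = c("a", "b", "c", "d"), beta = c(1, 1, 1, 1),
                       se = 0.1)
  fit <- ivw_mr(ex, ou)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se, (0.1 / 2) / sqrt(4))

  ex3 <- tibble::tibble(id = c("a", "b", "c"), beta = 1, se = 0.01)
  ou3 <- tibble::tibble(id = c("a", "b", "c"), beta = c(0.4, 0.5, 0.3),
                        se = 0.05)
  expect_equal(ivw_mr(ex3, ou3)$beta, 0.4)
})

test_that("IVW refuses sparse instrument sets and drops zero exposures", {
  ex <- tibble::tibble(id = c("a", "b"), beta = 1, se = 0.01)
  ou <- tibble::tibble(id = c("a", "b"), beta = 1, se = 0.05)
  expect_error(ivw_mr(ex, ou), "at least 3 independent instrumental variables")
  ex4 <- tibble::tibble(id = letters[1:4], beta = c(1, 1, 1, 0), se = 0.01)
  ou4 <- tibble::tibble(id = letters[1:4], beta = 1, se = 0.05)
  expect_warning(fit <- ivw_mr(ex4, ou4), "zero exposure")
  expect_equal(fit$n_instruments, 3)
})

test_that("IVW is invariant to instrument order and joint sign flips; se shrinks", {
  withr::with_seed(53, {
    n <- 10
    ex <- tibble::tibble(id = sprintf("i%02d", 1:n),
                         beta = runif(n, 0.2, 0.5) * sample(c(-1, 1), n, TRUE),
                         se = 0.002)
    ou <- tibble::tibble(id = ex$id, beta = 0.41 * ex$beta + rnorm(n, 0, 0.05),
                         se = 0.05)
  })
  f1 <- ivw_mr(ex, ou)
  perm <- sample(nrow(ex))
  f2 <- ivw_mr(ex[perm, ], ou[perm, ])
  expect_equal(f2$beta, f1$beta)
  ex3 <- ex; ou3 <- ou
  ex3$beta[1:3] <- -ex3$beta[1:3]; ou3$beta[1:3] <- -ou3$beta[1:3]
  f3 <- ivw_mr(ex3, ou3)
  expect_equal(f3$beta, f1$beta)
  f_sub <- ivw_mr(ex[1:5, ], ou[1:5, ])
  expect_lt(f1$se, f_sub$se)
})

test_that("allele harmonisation flips swapped outcome effects", {
  ex <- tibble::tibble(id = letters[1:3], beta = c(0.3, 0.4, 0.5), se = 0.002,
                       effect_allele = c("A", "C", "G"),
                       other_allele = c("T", "G", "A"))
  ou <- ex
  ou$beta <- 0.5 * ex$beta
  ou$se <- 0.05
  # swap the allele labels of one instrument and flip its reported effect
  ou$effect_allele[2] <- "G"; ou$other_allele[2] <- "C"
  ou$beta[2] <- -ou$beta[2]
  fit <- ivw_mr(ex, ou)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$n_instruments, 3)
})

test_that("the MR screen gates on instrument count and flags causal pairs", {
  cfg <- sim_config(seed = 99)
  genes <- simulate_genome(cfg)$genes
  mr <- simulate_gwas_eqtl(cfg, genes)
  scr <- suppressWarnings(
    mr_screen(mr$pairs, mr$eqtl, mr$gwas, mr$ld, genes))
  expect_equal(nrow(scr), nrow(mr$pairs))
  expect_true(all(scr$testable))
  truth <- mr$truth$causal_pairs$gene_id
  expect_gte(sum(scr$causal & scr$gene_id %in% truth), length(truth) - 1)
  # starving a gene of instruments makes its pair untestable
  g1 <- mr$pairs$gene_id[1]
  eqtl_thin <- mr$eqtl[!(mr$eqtl$gene == g1 &
                           seq_len(nrow(mr$eqtl)) %in%
                           which(mr$eqtl$gene == g1)[-(1:2)]), ]
  scr2 <- suppressWarnings(
    mr_screen(mr$pairs[1, ], eqtl_thin, mr$gwas, mr$ld, genes))
  expect_false(scr2$testable)
  expect_equal(scr2$n_instruments, 0L)
})
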