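mk_loops <- function(a1s, a1e, a2s, a2e, q = 1e-8, chrom = "chr1") {
  tibble::tibble(chrom1 = chrom, start1 = a1s, end1 = a1e,
                 chrom2 = chrom, start2 = a2s, end2 = a2e,
                 name = sprintf("l%03d", seq_along(a1s)),
                 count = 10, qvalue = q)
}

test_that("loop filtering is strict at the q-value cutoff", {
  lo <- mk_loops(c(0, 0, 0), c(10, 10, 10), c(100, 100, 100),
                 c(110, 110, 110), q = c(1e-6, 9e-7, 0.5))
  kept <- filter_loops(lo)
  expect_equal(kept$name, "l002")
  lo$qvalue[1] <- NA
  expect_error(filter_loops(lo), "q-value")
  # uniform q-values survive the cutoff essentially never
  withr::with_seed(3, {
    lo2 <- mk_loops(rep(0, 1000), rep(10, 1000), rep(100, 1000),
                    rep(110, 1000), q = runif(1000))
    expect_lte(nrow(filter_loops(lo2)), 1)
  })
})

test_that("inter-chromosomal loops are rejected and anchors ordered", {
  lo <- mk_loops(500, 600, 0, 100)
  v <- filter_loops(lo)
  expect_lte(v$start1, v$start2)
  bad <- lo; bad$chrom2 <- "chr9"
  expect_error(filter_loops(bad), "inter-chromosomal")
})

test_that("loops per element count distinct loops, once per loop", {
  el <- interval_tbl("chr1", 1000, 2000, name = "E")
  lo <- mk_loops(c(900, 1500, 1900), c(1100, 1600, 2100),
                 c(5000, 6000, 7000), c(5100, 6100, 7100))
  expect_equal(loops_per_element(lo, el)$loop_count, 3L)
  # both anchors of one loop on the element: counted once
  lo2 <- mk_loops(1000, 1200, 1800, 2000)
  expect_equal(loops_per_element(lo2, el)$loop_count, 1L)
  # star graph: hub element touches k spokes
  k <- 7
  hub <- interval_tbl("chr1", 10000, 11000, name = "hub")
  spokes <- mk_loops(rep(10000, k), rep(11000, k),
                     seq(50000, by = 5000, length.out = k),
                     seq(50000, by = 5000, length.out = k) + 1000)
  expect_equal(loops_per_element(spokes, hub)$loop_count, k)
})

test_that("short/long ratio splits at the distance threshold", {
  lo <- mk_loops(c(0, 0, 0, 0), c(1000, 1000, 1000, 1000),
                 c(10000, 20000, 30000, 300000),
                 c(11000, 21000, 31000, 301000))
  r <- short_long_ratio(lo)
  expect_equal(r$ratio, 3)
  # distance exactly at the threshold counts as long
  lo2 <- mk_loops(0, 1000, 200000, 201000)  # midpoints 500 and 200500
  expect_equal(short_long_ratio(lo2, threshold = 200000)$ratio, 0)
  expect_true(is.na(short_long_ratio(lo[1:3, ])$ratio))
})

test_that("exponential loop distances give the closed-form tail ratio", {
  withr::with_seed(31, {
    d <- round(stats::rexp(1000, 1 / 150000))
    lo <- mk_loops(rep(0, 1000), rep(10, 1000), d, d + 10)
    lo <- lo[d > 10, ]
    r <- short_long_ratio(lo, threshold = 200000)
    expected <- (1 - exp(-200 / 150)) / exp(-200 / 150)
    expect_equal(r$ratio, expected, tolerance = 0.15)
  })
})

test_that("TAD border overlap uses buffered boundaries", {
  tads <- interval_tbl("chr1", c(0, 500000), c(500000, 1000000))
  el <- interval_tbl(rep("chr1", 3),
                     c(495000, 250000, 505000),
                     c(496000, 251000, 506000))
  el$label <- c("CHA", "CHA", "regular")
  ov <- tad_border_overlap(el, tads, buffer = 10000)
  expect_equal(ov$n_cha_hit, 1L)       # straddles the 500 kb boundary zone
  expect_equal(ov$n_regular_hit, 1L)   # within the buffer on the other side
  ov2 <- tad_border_overlap(el[2, ], tads, buffer = 10000)
  expect_equal(ov2$n_cha_hit, 0L)      # deep interior
})

test_that("hub calling uses the tie-collapsed percentile and inclusive threshold", {
  # 10 promoters, one with ten-fold the loop count of the rest
  prom <- interval_tbl(rep("chr1", 10), seq(0, by = 10000, length.out = 10),
                       seq(0, by = 10000, length.out = 10) + 4000)
  prom$gene_id <- sprintf("g%02d", 1:10)
  enh <- interval_tbl("chr1", seq(500000, by = 5000, length.out = 12),
                      seq(500000, by = 5000, length.out = 12) + 1000,
                      name = sprintf("e%02d", 1:12))
  enh$enhancer_id <- enh$name
  enh$label <- "CHA"
  rows <- list()
  for (i in 1:9) rows[[i]] <- mk_loops(prom$start[i], prom$end[i],
                                       enh$start[i], enh$end[i])
  rows[[10]] <- mk_loops(rep(prom$start[10], 10), rep(prom$end[10], 10),
                         enh$start[c(1:10)], enh$end[c(1:10)])
  loops <- dplyr::bind_rows(rows)
  units <- call_hubs(loops, enh, prom, pct = 90)
  expect_equal(attr(units, "hub_threshold"), 10)
  expect_equal(sum(units$hub), 1)
  expect_equal(units$gene_id[units$hub], "g10")
  expect_equal(sort(units$enhancers[units$hub][[1]]), sprintf("e%02d", 1:10))

  # all promoters with equal counts: everyone is a hub
  units_eq <- call_hubs(dplyr::bind_rows(rows[1:9]), enh, prom, pct = 90)
  expect_true(all(units_eq$hub))

  # loop/promoter record order never changes the result
  perm <- sample(nrow(loops))
  units_p <- call_hubs(loops[perm, ], enh, prom[sample(10), ], pct = 90)
  expect_equal(glance(units_p), glance(units))

  # raising pct never increases the hub count
  hubs_by_pct <- vapply(c(50, 75, 90, 99), function(p) {
    sum(call_hubs(loops, enh, prom, pct = p)$hub)
  }, numeric(1))
  expect_true(all(diff(hubs_by_pct) <= 0))

  expect_error(call_hubs(mk_loops(2e6, 2e6 + 10, 3e6, 3e6 + 10), enh, prom),
               "no promoter")
})

test_that("unit gene sets collapse duplicates and prefer hub status", {
  units <- tibble::tibble(
    gene_id = c("a", "a", "b", "c"),
    chrom = "chr1", start = 1:4, end = 2:5,
    loop_count = c(10, 1, 2, 3), hub = c(TRUE, FALSE, FALSE, TRUE),
    enhancers = list("e1", "e2", "e3", "e4"))
  gs <- unit_gene_sets(units)
  expect_equal(sort(gs$hub_genes), c("a", "c"))
  expect_equal(gs$nonhub_genes, "b")
})
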