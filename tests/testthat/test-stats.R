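test_that("two-sided Fisher matches base R on ordinary tables", {
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(0, 0, 0, 0), 1)
  withr::with_seed(101, {
    for (i in 1:200) {
      t <- matrix(rpois(4, 6), 2)
      expect_equal(fisher_exact(t),
                   stats::fisher.test(t)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("Fisher p-values survive the extreme tail", {
  p <- fisher_exact(matrix(c(1012, 185, 10025, 15187), 2, byrow = TRUE))
  expect_equal(p, 1.8753e-214, tolerance = 1e-4)
  # symmetric under simultaneous row and column swap
  expect_equal(fisher_exact(15187, 10025, 185, 1012), p)
})

test_that("Fisher equals exhaustive enumeration on random small tables", {
  withr::with_seed(7, {
    for (i in 1:150) {
      cells <- sample(0:12, 4, replace = TRUE)
      expect_equal(fisher_exact(cells[1], cells[2], cells[3], cells[4]),
                   bf_fisher(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-12)
    }
  })
})

test_that("hypergeometric enrichment matches a direct tail sum", {
  bg <- sprintf("g%05d", 1:20000)
  ann <- bg[1:200]
  withr::with_seed(23, {
    hits <- c(ann[1:8], sample(bg[-(1:200)], 81))  # k = 8 of 89 draws
  })
  e <- hypergeom_enrichment(hits, ann, bg)
  expect_equal(e$overlap, 8)
  expect_equal(e$expected, 89 * 200 / 20000)
  expect_equal(e$fold_enrichment, 8 / (89 * 200 / 20000))
  expect_equal(e$p, sum(stats::dhyper(8:89, 200, 19800, 89)),
               tolerance = 1e-12)
  # saturation and empty overlap
  sat <- hypergeom_enrichment(ann, ann, ann)
  expect_equal(sat$fold_enrichment, 1)
  expect_equal(sat$p, 1)
  none <- hypergeom_enrichment(bg[300:320], ann, bg)
  expect_equal(none$p, 1)
  # p is monotone non-increasing in the overlap at fixed marginals
  ps <- vapply(0:10, function(k) {
    hypergeom_enrichment(c(ann[seq_len(k)],
                           bg[10000 + seq_len(89 - k)]), ann, bg)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_enrichment("x", ann, character(0)), "background")
})

test_that("projection test uses coverage fraction and the binomial tail", {
  genome <- 1e6
  refs <- interval_tbl("chr1", seq(0, 9e5, by = 1e5),
                       seq(0, 9e5, by = 1e5) + 5000)  # 5% coverage
  withr::with_seed(29, {
    pos <- c(vapply(1:50, function(i) {  # 50 planted inside
      r <- refs[sample(nrow(refs), 1), ]
      floor(runif(1, r$start, r$end - 1))
    }, numeric(1)), floor(runif(150, 0, genome)))
  })
  q <- interval_tbl("chr1", pos, pos + 1)
  pt <- projection_test(q, refs, genome)
  k <- pt$overlap; n <- 200
  expect_gte(k, 50)
  expect_equal(pt$p, sum(stats::dbinom(k:n, n, 0.05)), tolerance = 1e-12)
  expect_equal(pt$fold_enrichment, k / (n * 0.05))
  # full-coverage referents: no enrichment possible
  full <- projection_test(q, interval_tbl("chr1", 0, genome), genome)
  expect_equal(full$fold_enrichment, 1)
  expect_equal(full$p, 1)
  # zero hits give p = 1
  far <- projection_test(interval_tbl("chr1", 990000, 990001), refs, genome)
  expect_equal(far$p, 1)
  expect_error(projection_test(q, refs, 10), "coverage")
})

test_that("relative distance is 0 at referent midpoints and 0.5 at gap centers", {
  refs <- interval_tbl("chr1", seq(0, 9000, by = 1000),
                       seq(0, 9000, by = 1000) + 100)  # midpoints at k*1000+50
  at_mid <- interval_tbl("chr1", seq(1050, 8050, by = 1000),
                         seq(1050, 8050, by = 1000) + 1)
  r0 <- relative_distance_ks(at_mid, refs)
  expect_equal(r0$mean_relative_distance, 0)
  expect_equal(r0$D, 1)
  at_center <- interval_tbl("chr1", seq(1550, 8550, by = 1000),
                            seq(1550, 8550, by = 1000) + 1)
  r5 <- relative_distance_ks(at_center, refs)
  expect_true(all(r5$d == 0.5))
  expect_error(relative_distance_ks(interval_tbl("chr1", 50000, 50001), refs),
               "hull")
})

test_that("relative distance is invariant to translation and scaling", {
  withr::with_seed(37, {
    refs <- rand_intervals(20, chroms = "chrA", size = 50000)
    q <- rand_intervals(100, chroms = "chrA", size = 50000)
  })
  r1 <- relative_distance_ks(q, refs)
  shift <- function(x, k) {
    x$start <- x$start * k[2] + k[1]; x$end <- x$end * k[2] + k[1]; x
  }
  r2 <- relative_distance_ks(shift(q, c(1e6, 1)), shift(refs, c(1e6, 1)))
  expect_equal(r2$d, r1$d)
  r3 <- relative_distance_ks(shift(q, c(0, 8)), shift(refs, c(0, 8)))
  expect_lt(max(abs(r3$d - r1$d)), 0.01)
})
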