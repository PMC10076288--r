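# Brute-force per-base oracles for interval operations, used to check the
# production code paths on toy genomes.  Deliberately naive: O(n * m) loops
# over explicit base sets, no shared code with R/.

bf_bases <- function(x) {
  # set of 0-based covered positions, tagged by chromosome
  unlist(lapply(seq_len(nrow(x)), function(i) {
    if (x$end[i] > x$start[i]) {
      paste0(x$chrom[i], ":", x$start[i]:(x$end[i] - 1))
    } else character(0)
  }))
}

bf_overlap_flags <- function(referents, queries, midpoint = FALSE) {
  vapply(seq_len(nrow(referents)), function(i) {
    rs <- referents$start[i]; re <- referents$end[i]
    rc <- referents$chrom[i]
    any(vapply(seq_len(nrow(queries)), function(j) {
      if (queries$chrom[j] != rc) return(FALSE)
      if (midpoint) {
        m <- floor((queries$start[j] + queries$end[j]) / 2)
        m >= rs && m < re
      } else {
        queries$start[j] < re && queries$end[j] > rs
      }
    }, logical(1)))
  }, logical(1))
}

bf_subtract <- function(a, b) {
  keep <- vapply(seq_len(nrow(a)), function(i) {
    !any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
  a[keep, , drop = FALSE]
}

bf_jaccard <- function(a, b) {
  ba <- unique(bf_bases(a)); bb <- unique(bf_bases(b))
  u <- union(ba, bb)
  if (!length(u)) return(0)
  length(intersect(ba, bb)) / length(u)
}

# random interval set on a toy genome
rand_intervals <- function(n, chroms = c("chrA", "chrB"), size = 10000,
                           max_width = 400) {
  w <- sample(max_width, n, replace = TRUE)
  s <- sample(size - max_width, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = s, end = s + w)
}

# exhaustive two-sided Fisher p by plain choose() arithmetic
bf_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
  obs <- pr[x == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# independent greedy clump used as a re-run oracle
bf_clump <- function(stats, ld, r2_max, window) {
  look <- function(i1, i2) {
    hit <- (ld$id1 == i1 & ld$id2 == i2) | (ld$id1 == i2 & ld$id2 == i1)
    if (any(hit)) ld$r2[which(hit)[1]] else 0
  }
  s <- stats[order(stats$p, stats$position, stats$id), , drop = FALSE]
  kept <- c()
  for (i in seq_len(nrow(s))) {
    ok <- TRUE
    for (j in kept) {
      if (abs(s$position[j] - s$position[i]) <= window &&
          look(s$id[i], s$id[j]) >= r2_max) ok <- FALSE
    }
    if (ok) kept <- c(kept, i)
  }
  s$id[kept]
}
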