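#' Read and write bedGraph signal tracks
#'
#' A signal track is a tibble `chrom`, `start`, `end`, `value` in bedGraph
#' convention (0-based half-open, constant value per record).  When records
#' overlap, their values add when the track is materialised to per-base
#' coverage.
#'
#' @param path Path to a bedGraph file (optionally gzipped); `track`,
#'   `browser` and comment lines are skipped.
#' @return Track tibble.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  value = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4)) abort("bedGraph needs 4 tab-separated columns")
  out <- tibble(chrom = vapply(f, `[[`, "", 1),
                start = as.numeric(vapply(f, `[[`, "", 2)),
                end = as.numeric(vapply(f, `[[`, "", 3)),
                value = as.numeric(vapply(f, `[[`, "", 4)))
  validate_intervals(out, "bedGraph")
}

#' @rdname read_bedgraph
#' @param track Track tibble.
#' @return For `write_bedgraph()`: `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  track <- validate_intervals(track, "track")
  writeLines(paste(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   format(track$value, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Total tag count of a track
#'
#' Sum of value times record width over the whole genome.
#'
#' @param track Track tibble.
#' @return A number.
#' @export
track_total <- function(track) {
  sum(track$value * (track$end - track$start))
}

#' Normalize a track to a fixed tag total
#'
#' Scales every value by `target_total / track_total(track)` so the genome
#' total equals `target_total` (default 10 million tags, the convention
#' used before profile computation and input subtraction).
#'
#' @param track Track tibble.
#' @param target_total Desired genome-wide tag total.
#' @return The scaled track.
#' @export
normalize_track <- function(track, target_total = 1e7) {
  tot <- track_total(track)
  if (!is.finite(tot) || tot <= 0) abort("track has non-positive tag total")
  track$value <- track$value * (target_total / tot)
  track
}

# chromosome lengths implied by a set of tracks/tables
chrom_extents <- function(...) {
  xs <- list(...)
  xs <- xs[!vapply(xs, is.null, TRUE)]
  ext <- bind_rows(lapply(xs, function(x) x[c("chrom", "end")]))
  tapply(ext$end, ext$chrom, max)
}

# materialise one chromosome to a per-base numeric vector; overlapping
# bedGraph records add
chrom_coverage <- function(track, chrom, len) {
  v <- numeric(len)
  rows <- which(track$chrom == chrom)
  for (i in rows) {
    s <- max(0, track$start[i]); e <- min(len, track$end[i])
    if (e > s) v[(s + 1):e] <- v[(s + 1):e] + track$value[i]
  }
  v
}

profile_from_windows <- function(cov_by_chrom, chrom, idx_list, bin) {
  # idx_list: list of 0-based genomic position vectors, one per center,
  # already oriented 5'->3'
  acc <- NULL; n <- 0L
  for (j in seq_along(chrom)) {
    v <- cov_by_chrom[[chrom[j]]][idx_list[[j]] + 1]
    bins <- colMeans(matrix(v, nrow = bin))
    acc <- if (is.null(acc)) bins else acc + bins
    n <- n + 1L
  }
  list(sum = acc, n = n)
}

#' Tag-density profile centered on annotations
#'
#' For each annotation midpoint, per-base coverage in `[mid - span/2,
#' mid + span/2)` is averaged within consecutive bins of `bin` bases; the
#' profile is the mean over centers.  When `input_track` is supplied its
#' identically computed profile is subtracted bin-wise (normalise both
#' tracks first; negative values are retained).  Centers whose window
#' leaves the contig are skipped with a warning.
#'
#' @param track Track tibble (typically after [normalize_track()]).
#' @param centers Interval tibble of annotations.
#' @param bin Bin width in bases.
#' @param span Window width in bases; must be divisible by `bin`.
#' @param input_track Optional control track to subtract.
#' @return A `cha_profile` tibble with columns `offset` (bp relative to the
#'   center, left edge of each bin) and `value`; attribute `n_centers`.
#' @export
density_profile <- function(track, centers, bin = 10, span = 10000,
                            input_track = NULL) {
  track <- validate_intervals(track, "track")
  centers <- validate_intervals(centers, "centers")
  if (span %% bin != 0) abort("span must be divisible by bin")
  half <- span / 2
  lens <- chrom_extents(track, input_track, centers)
  mids <- floor((centers$start + centers$end) / 2)
  ok <- mids - half >= 0 & mids + half <= lens[centers$chrom] &
    centers$chrom %in% names(lens)
  if (any(!ok)) {
    warn(sprintf("%d center(s) closer than span/2 to a contig edge; skipped",
                 sum(!ok)))
  }
  if (!any(ok)) abort("no usable center")
  chrom <- centers$chrom[ok]; mids <- mids[ok]
  idx <- lapply(mids, function(m) (m - half):(m + half - 1))
  offsets <- seq(-half, half - bin, by = bin)
  prof <- function(tr) {
    covs <- lapply(
      setNames(unique(chrom), unique(chrom)),
      function(ch) chrom_coverage(tr, ch, lens[[ch]]))
    r <- profile_from_windows(covs, chrom, idx, bin)
    r$sum / r$n
  }
  value <- prof(track)
  if (!is.null(input_track)) value <- value - prof(validate_intervals(input_track))
  structure(tibble(offset = offsets, value = value),
            n_centers = sum(ok), bin = bin,
            class = c("cha_profile", class(tibble())))
}

#' Metagene profiles around TSS and TES
#'
#' Strand-oriented mean coverage in windows around the transcription start
#' site (default -1000..+5000) and end site (default -1000..+2000), in
#' 10-bp bins; minus-strand windows run 5'->3' along the gene, so the
#' returned offsets always read in the direction of transcription.
#'
#' @param track Track tibble.
#' @param genes Gene-model tibble (`chrom`, `start`, `end`, `strand`).
#' @param tss_window,tes_window Length-2 integer windows around the TSS and
#'   TES, in transcribed orientation.
#' @param bin Bin width in bases.
#' @param input_track Optional control track to subtract.
#' @return List with two `cha_profile` tibbles, `tss` and `tes`.
#' @export
metagene_profile <- function(track, genes, tss_window = c(-1000, 5000),
                             tes_window = c(-1000, 2000), bin = 10,
                             input_track = NULL) {
  track <- validate_intervals(track, "track")
  genes <- validate_intervals(genes, "gene table")
  if (is.null(genes[["strand"]]) || !all(genes$strand %in% c("+", "-"))) {
    abort("gene table needs strand '+'/'-'")
  }
  lens <- chrom_extents(track, input_track, genes)
  one <- function(anchor_pos, window) {
    w <- window[1]:(window[2] - 1)
    idx <- lapply(seq_len(nrow(genes)), function(j) {
      if (genes$strand[j] == "+") anchor_pos[j] + w else anchor_pos[j] - w
    })
    ok <- vapply(seq_len(nrow(genes)), function(j) {
      rng <- range(idx[[j]])
      rng[1] >= 0 && rng[2] < lens[genes$chrom[j]]
    }, logical(1))
    if (any(!ok)) warn(sprintf("%d gene window(s) leave the contig; skipped",
                               sum(!ok)))
    if (!any(ok)) abort("no usable gene window")
    chrom <- genes$chrom[ok]
    prof <- function(tr) {
      covs <- lapply(setNames(unique(chrom), unique(chrom)),
                     function(ch) chrom_coverage(tr, ch, lens[[ch]]))
      r <- profile_from_windows(covs, chrom, idx[ok], bin)
      r$sum / r$n
    }
    value <- prof(track)
    if (!is.null(input_track)) value <- value - prof(input_track)
    structure(tibble(offset = seq(window[1], window[2] - bin, by = bin),
                     value = value),
              n_centers = sum(ok), bin = bin,
              class = c("cha_profile", class(tibble())))
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  list(tss = one(tss, tss_window), tes = one(tes, tes_window))
}
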