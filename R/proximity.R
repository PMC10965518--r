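#' Merge breakend neighbourhoods into disjoint intervals
#'
#' Each breakend contributes the window `[max(1, pos - d), min(L, pos + d)]`
#' on its chromosome; overlapping or adjacent windows are merged. The merged
#' set is the "near SV sites" territory used for proximity stratification.
#'
#' @param breakends An [sv_breakends] table.
#' @param d Distance threshold in bp (>= 0).
#' @param genome A [genome_def]; windows are clipped at chromosome ends.
#' @return A [GenomicRanges::GRanges] of disjoint, sorted intervals
#'   (1-based inclusive).
#' @export
merge_neighborhoods <- function(breakends, d, genome) {
  if (d < 0) stopf("'d' must be >= 0")
  check_chromosomes(breakends$chrom, genome, breakends$pos, "breakend")
  if (nrow(breakends) == 0L) {
    return(GenomicRanges::GRanges(seqlengths = genome$lengths))
  }
  L <- genome$lengths[breakends$chrom]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(breakends$chrom, levels = genome$names),
    ranges = IRanges::IRanges(
      start = pmax(1, breakends$pos - d),
      end = pmin(L, breakends$pos + d)
    ),
    seqlengths = genome$lengths
  )
  GenomicRanges::reduce(sort(gr))
}

#' Partition SNVs by proximity to SV breakends
#'
#' An SNV is "near" when it falls inside a merged breakend neighbourhood of
#' half-width `d`; all others (including every SNV on a chromosome with no
#' breakend) are "far".
#'
#' @param snvs An [snv_records] table.
#' @param breakends An [sv_breakends] table on the same chromosome
#'   namespace.
#' @param d Distance threshold in bp (default 1e6, i.e. "within 1 Mb of SV
#'   sites").
#' @param genome A [genome_def].
#' @return A list of class `proximity_partition`: `near` and `far`
#'   ([snv_records] subsets), `intervals` (the merged [GenomicRanges::GRanges]),
#'   and `d`.
#' @export
partition_snvs <- function(snvs, breakends, d = 1e6, genome) {
  check_chromosomes(snvs$chrom, genome, snvs$pos, "SNV")
  intervals <- merge_neighborhoods(breakends, d, genome)
  near_idx <- logical(nrow(snvs))
  if (nrow(snvs) > 0 && length(intervals) > 0) {
    snv_gr <- GenomicRanges::GRanges(
      seqnames = factor(snvs$chrom, levels = genome$names),
      ranges = IRanges::IRanges(snvs$pos, snvs$pos),
      seqlengths = genome$lengths
    )
    hits <- GenomicRanges::findOverlaps(snv_gr, intervals)
    near_idx[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  structure(
    list(
      near = snvs[near_idx, , drop = FALSE],
      far = snvs[!near_idx, , drop = FALSE],
      intervals = intervals,
      d = d
    ),
    class = "proximity_partition"
  )
}

#' @export
print.proximity_partition <- function(x, ...) {
  cat(sprintf(
    "proximity_partition (d = %.0f bp): %d near, %d far, %d merged intervals\n",
    x$d, nrow(x$near), nrow(x$far), length(x$intervals)
  ))
  invisible(x)
}

#' Expected SNV count near SV sites under uniform random placement
#'
#' The naive expectation is `n_snv / genome_length * n_sv * 2 * range_R`:
#' each of the `n_sv` SV sites claims `2 * range_R` bp of flanking
#' territory and SNVs are assumed uniform over the genome. The formula is
#' deliberately uncapped — it ignores neighbourhood overlap and chromosome
#' ends and can exceed `n_snv`; see [observed_vs_expected_curve()] for the
#' overlap-corrected companion value.
#'
#' @param n_snv Total SNV count (>= 0).
#' @param genome_length Genome length G in bp (> 0).
#' @param n_sv Number of SV sites counted (>= 0).
#' @param range_R Flank range in bp (vectorised).
#' @return Numeric vector of expected counts, one per `range_R`.
#' @export
#' @examples
#' expected_random_count(1000, 2e9, 100, 1e6) # 100
expected_random_count <- function(n_snv, genome_length, n_sv, range_R) {
  if (genome_length <= 0) stopf("'genome_length' must be > 0")
  if (n_snv < 0 || n_sv < 0 || any(range_R < 0)) {
    stopf("counts and ranges must be >= 0")
  }
  n_snv / genome_length * n_sv * 2 * range_R
}

# Total merged neighbourhood length by an interval sweep; same semantics
# as merge_neighborhoods() (asserted in the tests) without the S4
# container overhead, for the per-range loop of the expectation curve.
merged_neighborhood_length <- function(breakends, d, genome) {
  total <- 0
  for (chr in unique(breakends$chrom)) {
    p <- breakends$pos[breakends$chrom == chr]
    L <- genome$lengths[[chr]]
    sp <- sort(p)
    s <- pmax(1, sp - d)
    e <- pmin(L, sp + d)
    cme <- cummax(e)
    gap <- which(s[-1] > cme[-length(cme)] + 1) # next interval starts a group
    group_end <- c(gap, length(e))
    group_start <- c(1, gap + 1)
    total <- total + sum(cme[group_end] - s[group_start] + 1)
  }
  total
}

# Distance from each SNV to its nearest breakend on the same chromosome
# (Inf on breakend-free chromosomes). An SNV lies in a merged d-
# neighbourhood exactly when this distance is <= d, so one pass yields
# observed near-counts for every range at once.
nearest_breakend_distance <- function(snvs, breakends, genome) {
  check_chromosomes(snvs$chrom, genome, snvs$pos, "SNV")
  check_chromosomes(breakends$chrom, genome, breakends$pos, "breakend")
  dist <- rep(Inf, nrow(snvs))
  for (chr in unique(snvs$chrom)) {
    bp <- sort(breakends$pos[breakends$chrom == chr])
    if (length(bp) == 0L) next
    i <- which(snvs$chrom == chr)
    pos <- snvs$pos[i]
    right <- findInterval(pos, bp) # index of last breakend <= pos
    d_left <- ifelse(right >= 1, pos - bp[pmax(right, 1)], Inf)
    d_right <- ifelse(right < length(bp), bp[pmin(right + 1, length(bp))] - pos,
                      Inf)
    dist[i] <- pmin(d_left, d_right)
  }
  dist
}

#' Observed vs expected near-SV SNV counts over a range grid
#'
#' For each flank range R, counts the SNVs observed within R of any
#' breakend (equivalently, inside the merged neighbourhoods of
#' [partition_snvs()]) and reports two expectations under uniform
#' placement: the naive closed form ([expected_random_count()]) and the
#' overlap-corrected value `n_snv * merged_length / G`, which accounts
#' for neighbourhood overlap and chromosome-end clipping.
#'
#' @param snvs An [snv_records] table.
#' @param breakends An [sv_breakends] table.
#' @param genome A [genome_def].
#' @param ranges Ascending vector of ranges in bp; default log-spaced
#'   1 kb - 10 Mb (half-decade steps).
#' @param count_sv `"breakends"` (default) or `"events"`: what "SV number"
#'   counts in the naive formula.
#' @return A `data.frame` of class `expected_random_curve` with columns
#'   `range, observed, expected_naive, expected_corrected, merged_length`,
#'   plus attribute `count_sv` recording the SV counting unit used.
#' @export
observed_vs_expected_curve <- function(snvs, breakends, genome,
                                       ranges = 10^seq(3, 7, by = 0.5),
                                       count_sv = c("breakends", "events")) {
  count_sv <- match.arg(count_sv)
  if (is.unsorted(ranges, strictly = FALSE)) {
    stopf("'ranges' must be sorted ascending")
  }
  n_snv <- nrow(snvs)
  n_sv <- if (count_sv == "breakends") nrow(breakends) else
    length(unique(breakends$event_id))

  dist <- nearest_breakend_distance(snvs, breakends, genome)
  rows <- lapply(ranges, function(R) {
    merged_len <- merged_neighborhood_length(breakends, R, genome)
    data.frame(
      range = R,
      observed = sum(dist <= R),
      expected_naive = expected_random_count(n_snv, genome$total, n_sv, R),
      expected_corrected = n_snv * merged_len / genome$total,
      merged_length = merged_len
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("expected_random_curve", "data.frame")
  attr(out, "count_sv") <- count_sv
  out
}

#' Export merged neighbourhoods as BED
#'
#' Written 0-based half-open, the on-disk BED convention.
#'
#' @param intervals A [GenomicRanges::GRanges], e.g. from
#'   [merge_neighborhoods()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  lines <- sprintf("%s\t%.0f\t%.0f",
                   as.character(GenomicRanges::seqnames(intervals)),
                   GenomicRanges::start(intervals) - 1,
                   GenomicRanges::end(intervals))
  writeLines(lines, path)
  invisible(path)
}
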