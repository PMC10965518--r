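# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use different code paths (explicit loops, lookup
# tables, per-bp membership vectors) from the implementations they check.

# --- tiny text fixtures ----------------------------------------------------

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##contig=<ID=chr2,length=1000000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    lines
  ), path)
  path
}

write_test_bedpe <- function(lines, path = tempfile(fileext = ".bedpe")) {
  writeLines(lines, path)
  path
}

# A small genome with sequence, built once per test run.
test_genome_env <- new.env()

small_genome <- function() {
  if (is.null(test_genome_env$small)) {
    test_genome_env$small <- simulate_genome(
      n_chrom = 2, lengths = 5e6, seed = 424243, with_sequence = TRUE
    )
  }
  test_genome_env$small
}

# --- independent oracles ---------------------------------------------------

# Per-record 96-channel tally using an explicit base-by-base complement
# table and string reversal; no shared code with classify_context().
oracle_channel <- function(ref, alt, context) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- character(length(ref))
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; ctx <- strsplit(context[i], "")[[1]]
    if (length(ctx) != 3 || any(!ctx %in% names(comp)) ||
        !r %in% names(comp) || !a %in% names(comp) ||
        ctx[2] != r || r == a) {
      out[i] <- NA_character_
      next
    }
    if (r %in% c("A", "G")) {
      r <- comp[[r]]; a <- comp[[a]]
      ctx <- rev(unname(comp[ctx]))
    }
    out[i] <- paste0(ctx[1], "[", r, ">", a, "]", ctx[3])
  }
  out
}

oracle_spectrum_tally <- function(channels) {
  counts <- stats::setNames(integer(96), sbs96_channels())
  for (ch in channels) {
    if (!is.na(ch)) counts[ch] <- counts[ch] + 1L
  }
  counts
}

# O(n * m) nearest-breakend partition: an SNV is near iff its distance to
# some breakend on the same chromosome is <= d.
oracle_partition_near <- function(snvs, breakends, d) {
  near <- logical(nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    on_chrom <- breakends$pos[breakends$chrom == snvs$chrom[i]]
    near[i] <- length(on_chrom) > 0 &&
      min(abs(on_chrom - snvs$pos[i])) <= d
  }
  near
}

# Per-bp membership union of breakend windows on a toy genome.
oracle_merged_length <- function(breakends, d, genome) {
  total <- 0
  for (chr in genome$names) {
    L <- genome$lengths[[chr]]
    member <- logical(L)
    for (p in breakends$pos[breakends$chrom == chr]) {
      member[max(1, p - d):min(L, p + d)] <- TRUE
    }
    total <- total + sum(member)
  }
  total
}

# Brute-force window assignment by looping over records.
oracle_window_counts <- function(pos, L, w) {
  n_win <- ceiling(L / w)
  counts <- integer(n_win)
  for (p in pos) {
    idx <- min((p - 1) %/% w + 1, n_win)
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

# Random snv_records on a given chromosome/length (positions clear of the
# chromosome ends so every record is classifiable).
random_snvs <- function(n, genome, seed) {
  set.seed(seed)
  chrom <- sample(genome$names, n, replace = TRUE, prob = genome$lengths)
  L <- genome$lengths[chrom]
  pos <- floor(runif(n, 2, L - 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  snv_records(chrom, pos, ref, alt)
}

# Point-mass signature matrix: one column per requested channel.
point_mass_refs <- function(channels) {
  chans <- sbs96_channels()
  mat <- vapply(channels, function(ch) as.numeric(chans == ch),
                numeric(96))
  rownames(mat) <- chans
  colnames(mat) <- paste0("pm_", seq_along(channels))
  mat
}
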