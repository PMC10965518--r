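test_that("classify_context applies pyrimidine normalisation", {
  expect_equal(classify_context("G", "T", "AGC"), "G[C>A]T")
  expect_equal(classify_context("T", "G", "ATC"), "A[T>G]C")
  expect_equal(classify_context("A", "C", "TAG"), "C[T>G]A")
  expect_true(is.na(classify_context("C", "A", "ANA")))
  expect_true(is.na(classify_context("C", "A", "AGA"))) # centre mismatch
  expect_true(is.na(classify_context("C", "C", "ACA"))) # ref == alt
})

test_that("classify_context matches the per-record oracle on random input", {
  set.seed(101)
  bases <- c("A", "C", "G", "T", "N")
  n <- 500
  ref <- sample(bases[1:4], n, replace = TRUE)
  alt <- sample(bases[1:4], n, replace = TRUE)
  ctx <- vapply(seq_len(n), function(i) {
    mid <- if (runif(1) < 0.9) ref[i] else sample(bases, 1)
    paste0(sample(bases, 1, prob = c(rep(0.24, 4), 0.04)), mid,
           sample(bases, 1, prob = c(rep(0.24, 4), 0.04)))
  }, character(1))
  expect_equal(classify_context(ref, alt, ctx), oracle_channel(ref, alt, ctx))
})

test_that("build_spectrum tallies records and conserves totals", {
  gen <- small_genome()
  empty <- build_spectrum(snv_records(character(), numeric(), character(),
                                      character()), gen$sequence)
  expect_true(all(empty == 0))
  expect_equal(attr(empty, "total_classified"), 0L)

  # 5 copies of the same SNV pile into one channel
  base_at <- substring(as.character(gen$sequence[["chr1"]]), 1000, 1000)
  alt <- setdiff(c("A", "C", "G", "T"), base_at)[1]
  five <- snv_records(rep("chr1", 5), rep(1000, 5), rep(base_at, 5),
                      rep(alt, 5))
  spec <- build_spectrum(five, gen$sequence)
  expect_equal(max(spec), 5L)
  expect_equal(attr(spec, "total_classified"), 5L)

  # position 1 lacks a 5' flank -> unclassifiable, still counted
  edge <- snv_records("chr1", 1, "A", "C")
  spec_edge <- build_spectrum(edge, gen$sequence)
  expect_equal(attr(spec_edge, "total_classified") +
                 attr(spec_edge, "unclassifiable"), 1L)
  expect_equal(attr(spec_edge, "unclassifiable"), 1L)
})

test_that("build_spectrum equals a brute-force tally on 200 random SNVs", {
  set.seed(77)
  seq10k <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  sequence <- Biostrings::DNAStringSet(c(toy = seq10k))
  pos <- sample(2:9999, 200, replace = TRUE)
  ref <- substring(seq10k, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  snvs <- snv_records(rep("toy", 200), pos, ref, alt)

  spec <- build_spectrum(snvs, sequence)
  ctx <- substring(seq10k, pos - 1, pos + 1)
  expected <- oracle_spectrum_tally(oracle_channel(ref, alt, ctx))
  expect_equal(unclass(spec)[sbs96_channels()], expected,
               ignore_attr = TRUE)
  expect_equal(attr(spec, "total_classified"), 200L)
})

test_that("spectra are strand-invariant and additive", {
  set.seed(5)
  n <- 300
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ctx <- paste0(sample(bases, n, TRUE), ref, sample(bases, n, TRUE))

  fwd <- spectrum_from_channels(classify_context(ref, alt, ctx))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_ctx <- vapply(ctx, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1))
  rev_spec <- spectrum_from_channels(
    classify_context(unname(comp[ref]), unname(comp[alt]), unname(rc_ctx))
  )
  expect_equal(unclass(fwd), unclass(rev_spec))

  # additivity: concatenation = channel-wise sum
  half <- seq_len(n / 2)
  s1 <- spectrum_from_channels(classify_context(ref[half], alt[half], ctx[half]))
  s2 <- spectrum_from_channels(classify_context(ref[-half], alt[-half], ctx[-half]))
  expect_equal(as.integer(fwd), as.integer(s1) + as.integer(s2))
})

test_that("split_by_basepair separates T-centred from C-centred counts", {
  zero <- spectrum_from_channels(stats::setNames(numeric(96), sbs96_channels()))
  expect_equal(split_by_basepair(zero), c(AT = 0, GC = 0))

  counts <- stats::setNames(numeric(96), sbs96_channels())
  counts["A[T>G]C"] <- 12
  only_t <- spectrum_from_channels(counts)
  expect_equal(split_by_basepair(only_t)[["GC"]], 0)
  expect_equal(split_by_basepair(only_t)[["AT"]], 12)

  # constructed 30 T-centred + 70 C-centred records
  chans <- c(rep("A[T>A]A", 30), rep("G[C>T]G", 70))
  mixed <- spectrum_from_channels(chans)
  expect_equal(split_by_basepair(mixed), c(AT = 30, GC = 70))
  expect_equal(sum(split_by_basepair(mixed)),
               attr(mixed, "total_classified"))
})

test_that("compare_extreme_channels handles identity and k = 48", {
  set.seed(8)
  counts <- stats::setNames(rpois(96, 10), sbs96_channels())
  spec <- spectrum_from_channels(counts)
  spectra <- list(a1 = spec, a2 = spec, b1 = spec, b2 = spec)
  conds <- c(a1 = "ctl", a2 = "ctl", b1 = "irr", b2 = "irr")

  cmp <- compare_extreme_channels(spectra, conds, "ctl", "irr", k = 10,
                                  class = "AT")
  expect_equal(cmp$highest$statistic, 0)
  expect_equal(cmp$highest$p_value, 1)

  all48 <- compare_extreme_channels(spectra, conds, "ctl", "irr", k = 48,
                                    class = "AT")
  expect_setequal(all48$highest$channels, all48$lowest$channels)
  expect_equal(all48$highest$statistic, all48$lowest$statistic)

  # < 2 samples per condition: p-value unavailable, not an error
  few <- compare_extreme_channels(spectra[c("a1", "b1")],
                                  conds[c("a1", "b1")], "ctl", "irr")
  expect_true(is.na(few$highest$p_value))
})

test_that("inflated channels are detected in the top-k but not bottom-k", {
  chans_at <- sbs96_channels()[substr(sbs96_channels(), 3, 3) == "T"]

  set.seed(2024)
  hits <- replicate(100, {
    # structured base profile shared by both conditions (real spectra have
    # strongly unequal channel intensities), with the 10 naturally highest
    # T-centred channels inflated 3x in the second condition
    base_lambda <- stats::setNames(rlnorm(96, log(15), 0.8),
                                   sbs96_channels())
    target <- chans_at[order(base_lambda[chans_at],
                             decreasing = TRUE)][1:10]
    make_spec <- function(lambda) {
      spectrum_from_channels(stats::setNames(rpois(96, lambda),
                                             sbs96_channels()))
    }
    lam_b <- base_lambda
    lam_b[target] <- lam_b[target] * 3
    spectra <- c(
      lapply(1:5, function(i) make_spec(base_lambda)),
      lapply(1:5, function(i) make_spec(lam_b))
    )
    names(spectra) <- c(paste0("ctl", 1:5), paste0("irr", 1:5))
    conds <- stats::setNames(rep(c("ctl", "irr"), each = 5), names(spectra))
    cmp <- compare_extreme_channels(spectra, conds, "ctl", "irr", k = 10,
                                    class = "AT")
    c(top = cmp$highest$p_value < 0.05, bottom = cmp$lowest$p_value < 0.05)
  })
  expect_gte(mean(hits["top", ]), 0.95)
  expect_lte(mean(hits["bottom", ]), 0.10)
})
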