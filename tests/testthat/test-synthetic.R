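test_that("simulate_genome is deterministic and composition-uniform", {
  a <- simulate_genome(2, c(1e4, 5e3), seed = 123)
  b <- simulate_genome(2, c(1e4, 5e3), seed = 123)
  expect_identical(as.character(a$sequence), as.character(b$sequence))
  expect_equal(a$genome$total, 1.5e4)
  c_ <- simulate_genome(2, c(1e4, 5e3), seed = 124)
  expect_false(identical(as.character(a$sequence), as.character(c_$sequence)))

  big <- simulate_genome(1, 1e6, seed = 7)
  freq <- Biostrings::letterFrequency(big$sequence[[1]],
                                      c("A", "C", "G", "T")) / 1e6
  expect_true(all(abs(freq - 0.25) < 0.01))

  none <- simulate_genome(3, 1e5, seed = 1, with_sequence = FALSE)
  expect_null(none$sequence)
  expect_equal(length(none$genome$names), 3)
})

test_that("simulate_svs respects hotspot weight extremes", {
  g <- genome_def("chr1", 1e8)
  expect_equal(nrow(simulate_svs(g, 0, seed = 1)), 0)

  # weight 1, single hotspot: every breakend inside it
  hot <- data.frame(chrom = "chr1", start = 4e7, end = 4.1e7, weight = 1)
  bk <- simulate_svs(g, 200, hot, hotspot_weight = 1, seed = 2)
  expect_equal(nrow(bk), 400)
  expect_true(all(bk$pos >= 4e7 & bk$pos <= 4.1e7))
  expect_equal(length(unique(bk$event_id)), 200)

  # weight 0: positions indistinguishable from uniform
  unif <- simulate_svs(g, 5000, hot, hotspot_weight = 0, seed = 3)
  ks <- suppressWarnings(ks.test(unif$pos, "punif", 1, 1e8))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditions simulated from one hotspot table share architecture", {
  g <- genome_def(paste0("chr", 1:6), rep(2e7, 6))
  hot <- simulate_hotspots(g, n_hotspots = 5, seed = 40)
  a <- simulate_svs(g, 150, hot, hotspot_weight = 0.8, seed = 41)
  b <- simulate_svs(g, 150, hot, hotspot_weight = 0.8, seed = 42)
  expect_false(identical(a$pos, b$pos)) # different seed stream
  st <- chromosome_sv_stats(a, b, g)
  expect_gt(st$pearson_r, 0.5) # same hotspot weights drive both
})

test_that("simulate_snvs builds both components as specified", {
  g <- genome_def(c("chr1", "chr2"), c(2e6, 2e6))
  refs <- synthetic_signatures(k = 2, seed = 50, at_column = NA)
  svs <- sv_breakends(c("chr1", "chr2"), c(1e6, 5e5))

  # b = 0: every SNV within the cluster width of some breakend
  prox <- simulate_snvs(g, svs, refs, mixture_background = c(1, 0),
                        b = 0, k = 50, cluster_width = 2e4, seed = 51)
  expect_true(all(prox$stratum == "sv_proximal"))
  near <- oracle_partition_near(prox, svs, 2e4)
  expect_true(all(near))
  expect_false(any(prox$pos %in% svs$pos)) # never on the breakend itself

  # k = 0: uniform background; near-fraction tracks merged length / G
  bg <- simulate_snvs(g, svs, refs, mixture_background = c(1, 0),
                      b = 500, k = 0, cluster_width = 2e4, seed = 52)
  expect_true(all(bg$stratum == "background"))
  part <- partition_snvs(bg, svs, d = 1e5, genome = g)
  p_hat <- nrow(part$near) / nrow(bg)
  p_true <- sum(GenomicRanges::width(part$intervals)) / g$total
  se <- sqrt(p_true * (1 - p_true) / nrow(bg))
  expect_lt(abs(p_hat - p_true), 4 * se)
})

test_that("a point-mass mixture lands every classified SNV in its channel", {
  gen <- small_genome()
  refs <- point_mass_refs(c("A[T>G]C", "G[C>A]T"))
  svs <- sv_breakends(character(), numeric())
  snvs <- simulate_snvs(gen$genome, svs, refs,
                        mixture_background = c(1, 0), b = 30, k = 0,
                        sequence = gen$sequence, seed = 53)
  expect_equal(attr(snvs, "n_fallback"), 0L)
  spec <- build_spectrum(snvs, gen$sequence)
  expect_equal(unname(spec["A[T>G]C"]), nrow(snvs))
  expect_equal(sum(spec), nrow(snvs))
})

test_that("drawn channels are realised faithfully against the sequence", {
  gen <- small_genome()
  refs <- synthetic_signatures(k = 3, seed = 54)
  svs <- simulate_svs(gen$genome, 5, seed = 55)
  snvs <- simulate_snvs(gen$genome, svs, refs,
                        mixture_background = c(0.5, 0.3, 0.2),
                        b = 20, k = 10, cluster_width = 5e4,
                        sequence = gen$sequence, seed = 56)
  expect_equal(attr(snvs, "n_fallback"), 0L)
  expect_equal(snvs$channel_drawn, snvs$channel_realized)
  expect_equal(classify_snv(snvs, gen$sequence), snvs$channel_realized)
})

test_that("truth files round-trip and validate their schema", {
  bundle <- simulate_dataset(seed = 3, n_chrom = 2, chrom_length = 1e6,
                             with_sequence = FALSE, n_sv = 10, b = 5,
                             k = 5, cluster_width = 1e4)
  path <- tempfile(fileext = ".json")
  write_truth(bundle$truth, path)
  back <- read_truth(path)
  expect_equal(back$seed, bundle$truth$seed)
  expect_equal(back$b, bundle$truth$b)
  expect_equal(back$mixtures$near, bundle$truth$mixtures$near)
  expect_equal(back$genome$lengths, bundle$truth$genome$lengths)

  broken <- jsonlite::read_json(path)
  broken$cluster_width <- NULL
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(broken, path2, auto_unbox = TRUE)
  expect_error(read_truth(path2), "cluster_width")
})

test_that("the recorded seed regenerates identical call sets", {
  b1 <- simulate_dataset(seed = 11, n_chrom = 2, chrom_length = 1e6,
                         with_sequence = FALSE, n_sv = 10, b = 5, k = 5,
                         cluster_width = 1e4)
  b2 <- simulate_dataset(seed = b1$truth$seed, n_chrom = 2,
                         chrom_length = 1e6, with_sequence = FALSE,
                         n_sv = 10, b = 5, k = 5, cluster_width = 1e4)
  for (cond in names(b1$snvs)) {
    expect_identical(b1$snvs[[cond]], b2$snvs[[cond]])
    expect_identical(b1$svs[[cond]], b2$svs[[cond]])
  }
})

test_that("write_bundle emits a complete readable file set", {
  bundle <- simulate_dataset(seed = 21, n_chrom = 2, chrom_length = 5e5,
                             n_sv = 5, b = 20, k = 5, cluster_width = 1e4)
  dir <- tempfile()
  paths <- write_bundle(bundle, dir)
  expect_true(all(file.exists(unlist(paths))))

  g <- read_chrom_sizes(paths$chrom_sizes)
  expect_equal(g$total, bundle$genome$total)
  cond <- bundle$truth$conditions[1]
  snvs <- read_snv_vcf(paths[[paste0("snv_", cond)]], genome = g)
  expect_equal(nrow(snvs), nrow(bundle$snvs[[cond]]))
  svs <- read_sv_breakends(paths[[paste0("sv_", cond)]], dialect = "bedpe",
                           genome = g)
  expect_equal(sort(svs$pos), sort(bundle$svs[[cond]]$pos))
  refs <- read_signature_matrix(paths$signatures)
  expect_equal(refs, bundle$refs, tolerance = 1e-9)
})
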