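test_that("count_in_windows tiles chromosomes and assigns every record", {
  g <- genome_def("chr1", 100)
  snvs <- snv_records(c("chr1", "chr1"), c(10, 60), c("C", "T"), c("A", "G"))
  none <- sv_breakends(character(), numeric())
  tab <- count_in_windows(snvs, none, g, w = 50)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$snv_count, c(1, 1))
  expect_equal(tab$start, c(1, 51))
  expect_equal(tab$end, c(50, 100))
  expect_false(any(tab$partial))

  # empty input: all-zero counts, one window per ceil(L / w)
  g2 <- genome_def(c("c1", "c2"), c(95, 40))
  empty <- count_in_windows(
    snv_records(character(), numeric(), character(), character()),
    none, g2, w = 30
  )
  expect_equal(nrow(empty), ceiling(95 / 30) + ceiling(40 / 30))
  expect_true(all(empty$snv_count == 0))
  expect_equal(sum(empty$partial), 2) # 95 %% 30 and 40 %% 30 remainders
})

test_that("window counts match brute-force assignment and conserve totals", {
  set.seed(21)
  g <- genome_def(c("chr1", "chr2"), c(1e5, 7e4))
  for (rep in 1:10) {
    snvs <- random_snvs(200, g, seed = 300 + rep)
    bk <- sv_breakends(
      chrom = sample(g$names, 40, replace = TRUE),
      pos = sample.int(7e4, 40, replace = TRUE)
    )
    w <- sample(c(1e4, 2.5e4, 3.3e4), 1)
    tab <- count_in_windows(snvs, bk, g, w)
    expect_equal(sum(tab$snv_count), nrow(snvs))
    expect_equal(sum(tab$sv_count), nrow(bk))
    for (chr in g$names) {
      expect_equal(
        tab$snv_count[tab$chrom == chr],
        oracle_window_counts(snvs$pos[snvs$chrom == chr],
                             g$lengths[[chr]], w)
      )
    }
  }
})

test_that("fit_decomposition recovers an exact line and flags degeneracy", {
  g <- genome_def("chr1", 150)
  tab <- data.frame(
    chrom = "chr1", start = c(1, 51, 101), end = c(50, 100, 150),
    width = 50, partial = FALSE,
    sv_count = c(0, 1, 2), snv_count = c(10, 15, 20)
  )
  class(tab) <- c("window_counts", "data.frame")
  attr(tab, "w") <- 50
  fit <- fit_decomposition(tab)
  expect_equal(fit$slope, 5)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept_rate, 10 / (50 / 1e6))

  # constant SNV counts: slope 0, intercept the constant
  tab$snv_count <- c(7, 7, 7)
  flat <- fit_decomposition(tab)
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 7)

  # all SV counts identical: slope undefined
  tab$sv_count <- c(3, 3, 3)
  expect_error(fit_decomposition(tab), "degenerate")
})

test_that("noiseless linear data is recovered to machine precision", {
  set.seed(3)
  g <- genome_def(paste0("chr", 1:4), rep(9e6, 4))
  w <- 1.5e6
  b <- 2; k <- 30
  sv_per_window <- sample(0:8, 24, replace = TRUE)
  # place exactly b*(w/1e6) + k*sv SNVs and sv breakends in each window
  tabs <- count_in_windows(
    snv_records(character(), numeric(), character(), character()),
    sv_breakends(character(), numeric()), g, w
  )
  snv_n <- b * (w / 1e6) + k * sv_per_window
  chrom <- rep(tabs$chrom, snv_n)
  pos <- unlist(mapply(function(s, n) s + seq_len(n), tabs$start, snv_n))
  snvs <- snv_records(chrom, pos, "C", "A")
  bk <- sv_breakends(rep(tabs$chrom, sv_per_window),
                     unlist(mapply(function(s, n) s + 100 + seq_len(n),
                                   tabs$start, sv_per_window)))
  fit <- fit_decomposition(count_in_windows(snvs, bk, g, w))
  expect_equal(fit$slope, k, tolerance = 1e-10)
  expect_equal(fit$intercept_rate, b, tolerance = 1e-10)
})

test_that("generator parameters are recovered by the regression", {
  # moderate-size version of the recovery experiment (the acceptance suite
  # runs the full 20-seed protocol)
  g <- genome_def(paste0("chr", 1:10), rep(75e6, 10))
  ests <- vapply(1:5, function(s) {
    svs <- simulate_svs(g, n_sv = 50, hotspots = NULL, seed = 100 + s)
    snvs <- simulate_snvs(g, svs, synthetic_signatures(seed = 1),
                          mixture_background = c(1, 0, 0, 0),
                          b = 2, k = 30, cluster_width = 5e5,
                          seed = 200 + s)
    fit <- fit_decomposition(count_in_windows(snvs, svs, g, 15e6))
    c(fit$intercept_rate, fit$slope)
  }, numeric(2))
  expect_equal(mean(ests[1, ]), 2, tolerance = 0.15)
  expect_equal(mean(ests[2, ]), 30, tolerance = 0.15)
})

test_that("compare_conditions reports identity and undefined ratios", {
  tab <- data.frame(
    chrom = "chr1", start = seq(1, 451, 50), end = seq(50, 500, 50),
    width = 50, partial = FALSE,
    sv_count = c(0, 1, 2, 3, 4, 0, 1, 2, 3, 4),
    snv_count = c(11, 14, 22, 26, 30, 9, 16, 19, 27, 32)
  )
  class(tab) <- c("window_counts", "data.frame")
  attr(tab, "w") <- 50
  fit <- fit_decomposition(tab)
  cmp <- compare_conditions(fit, fit)
  expect_equal(cmp$slope_ratio$ratio, 1.0)
  expect_equal(cmp$intercept_rate_ratio$ratio, 1.0)
  expect_true(cmp$slope_ratio$lower <= 1 && cmp$slope_ratio$upper >= 1)

  # zero intercept in the numerator: ratio 0, flagged as undefined CI
  fit0 <- fit
  fit0$intercept <- 0; fit0$intercept_rate <- 0
  cmp0 <- compare_conditions(fit, fit0)
  expect_equal(cmp0$intercept_rate_ratio$ratio, 0)
  expect_false(cmp0$intercept_rate_ratio$defined)

  fit_w <- fit
  fit_w$w <- 99
  expect_error(compare_conditions(fit, fit_w), "window size")
})

test_that("chromosome_sv_stats computes correlations and normalisation", {
  g <- genome_def(paste0("chr", 1:5), rep(2e6, 5),
                  chrom_counts = c(2, 2, 2, 2, 2))
  counts <- c(10, 8, 6, 4, 2)
  # identical per-chromosome counts give r = 1
  bk_a <- sv_breakends(rep(g$names, counts), rep(1000, sum(counts)))
  st <- chromosome_sv_stats(bk_a, bk_a, g)
  expect_equal(st$pearson_r, 1)

  # doubling condition B: r = 1, normalised totals ratio 2
  bk_b <- sv_breakends(rep(g$names, 2 * counts), rep(2000, 2 * sum(counts)))
  st2 <- chromosome_sv_stats(bk_a, bk_b, g)
  expect_equal(st2$pearson_r, 1)
  expect_equal(st2$normalized_total_b / st2$normalized_total_a, 2)
  expect_equal(st2$normalized_total_a, sum(counts) / 2)

  expect_error(chromosome_sv_stats(bk_a, bk_a, genome_def("c1", 10)),
               ">= 3 chromosomes")
})

test_that("shared hotspots raise cross-condition chromosome correlation
           above a hotspot-shuffled null", {
  g <- genome_def(paste0("chr", 1:12), rep(10e6, 12))
  wins <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    hot <- simulate_hotspots(g, n_hotspots = 8, seed = 5000 + r)
    hot_null <- simulate_hotspots(g, n_hotspots = 8, seed = 9000 + r)
    a <- simulate_svs(g, 100, hot, hotspot_weight = 0.7, seed = 1 + 3 * r)
    b_shared <- simulate_svs(g, 100, hot, hotspot_weight = 0.7,
                             seed = 2 + 3 * r)
    b_null <- simulate_svs(g, 100, hot_null, hotspot_weight = 0.7,
                           seed = 3 + 3 * r)
    r_shared <- chromosome_sv_stats(a, b_shared, g)$pearson_r
    r_null <- chromosome_sv_stats(a, b_null, g)$pearson_r
    wins <- wins + (r_shared > r_null)
  }
  expect_gte(wins / n_rep, 0.95)
})
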