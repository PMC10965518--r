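#' Assemble a pipeline run configuration
#'
#' Defaults follow the analysis conventions used throughout the package:
#' proximity threshold 1 Mb, window sizes 15/30/60 Mb (optionally 10 Mb),
#' and a log-spaced 1 kb - 10 Mb range grid for the expected-random curve.
#'
#' @param snv_paths Named character vector of VCF paths, names =
#'   condition labels.
#' @param sv_paths Named character vector of BEDPE paths, same names.
#' @param chrom_sizes Path to a chrom-sizes/.fai file (or a [genome_def]).
#' @param fasta Optional FASTA path; spectrum and signature stages are
#'   skipped without it.
#' @param signatures Optional path to a reference signature matrix (or the
#'   matrix itself); signature refitting is skipped without it.
#' @param d Proximity threshold in bp (default 1e6).
#' @param window_sizes Regression window sizes in bp
#'   (default `c(15, 30, 60) * 1e6`).
#' @param ranges Range grid in bp for the expected-random curve.
#' @param seed Integer seed recorded in every output.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(snv_paths, sv_paths, chrom_sizes, fasta = NULL,
                       signatures = NULL, d = 1e6,
                       window_sizes = c(15e6, 30e6, 60e6),
                       ranges = 10^seq(3, 7, by = 0.5),
                       seed = 1, out_dir = "svsnv_out") {
  if (is.null(names(snv_paths)) || is.null(names(sv_paths)) ||
      !identical(sort(names(snv_paths)), sort(names(sv_paths)))) {
    stopf("'snv_paths' and 'sv_paths' must be named by the same conditions")
  }
  if (any(window_sizes <= 0) || any(ranges <= 0) || d < 0) {
    stopf("sizes must be positive and d >= 0")
  }
  structure(
    list(snv_paths = snv_paths, sv_paths = sv_paths,
         chrom_sizes = chrom_sizes, fasta = fasta, signatures = signatures,
         d = d, window_sizes = window_sizes, ranges = ranges,
         seed = seed, out_dir = out_dir),
    class = "run_config"
  )
}

# Stable fingerprint of the analysis settings (the output location is not
# part of the analysis), so every report can state exactly which settings
# produced it and identical runs give identical summaries.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  fields <- unclass(config)
  fields$out_dir <- NULL
  writeLines(deparse(lapply(fields, unname)), tmp)
  unname(tools::md5sum(tmp))
}

exposure_summary <- function(fit) {
  if (inherits(fit, "exposure_vector")) {
    list(status = "ok", exposures = as.list(fit$exposures),
         cosine = fit$cosine, total = fit$total)
  } else {
    list(status = "not_analyzed", n_snv = fit$n_snv)
  }
}

#' Run the full SV/SNV co-analysis
#'
#' Orchestrates every stage on the inputs named in the configuration:
#' reads and validates call sets, builds per-condition 96-channel spectra
#' (when sequence is available), computes observed-vs-expected proximity
#' curves, fits the windowed SNV-on-SV decomposition at every configured
#' window size, compares conditions (slope and intercept-rate ratios,
#' per-chromosome SV statistics), refits stratified signature exposures
#' (when a reference matrix is available), and writes per-stage tables
#' plus a machine-readable JSON summary stamped with the configuration
#' hash and seed.
#'
#' @param config A [run_config].
#' @param quiet Suppress per-stage log messages (default `FALSE`).
#' @return The summary list, invisibly; all outputs are written under
#'   `config$out_dir`.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  genome <- stage("genome", {
    if (inherits(config$chrom_sizes, "genome_def")) config$chrom_sizes
    else read_chrom_sizes(config$chrom_sizes)
  })
  conditions <- names(config$snv_paths)

  sequence <- NULL
  if (!is.null(config$fasta)) {
    sequence <- stage("sequence", Biostrings::readDNAStringSet(config$fasta))
    names(sequence) <- sub("\\s.*$", "", names(sequence))
  }
  refs <- NULL
  if (!is.null(config$signatures)) {
    refs <- stage("signatures", {
      if (is.matrix(config$signatures)) {
        validate_signature_matrix(config$signatures)
        config$signatures[sbs96_channels(), , drop = FALSE]
      } else {
        read_signature_matrix(config$signatures)
      }
    })
  }

  snvs <- list(); svs <- list()
  for (cond in conditions) {
    snvs[[cond]] <- stage("read_snv", read_snv_vcf(
      config$snv_paths[[cond]], sample = cond, condition = cond,
      genome = genome
    ))
    svs[[cond]] <- stage("read_sv", read_sv_breakends(
      config$sv_paths[[cond]], dialect = "bedpe", sample = cond,
      condition = cond, genome = genome
    ))
    log_msg("[%s] %d SNVs, %d breakends", cond,
            nrow(snvs[[cond]]), nrow(svs[[cond]]))
  }

  summary <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    d = config$d,
    sv_count_unit = "breakends",
    conditions = conditions,
    input_counts = lapply(conditions, function(cond) {
      list(condition = cond, n_snv = nrow(snvs[[cond]]),
           n_breakend = nrow(svs[[cond]]),
           skip_report = as.list(attr(snvs[[cond]], "skip_report")))
    })
  )

  # spectra -------------------------------------------------------------
  if (!is.null(sequence)) {
    spectra <- stage("spectrum", lapply(snvs, build_spectrum, sequence))
    write_catalog(spectra, file.path(config$out_dir, "catalog.tsv"))
    summary$spectrum <- lapply(conditions, function(cond) {
      bp <- split_by_basepair(spectra[[cond]])
      list(condition = cond,
           total_classified = attr(spectra[[cond]], "total_classified"),
           unclassifiable = attr(spectra[[cond]], "unclassifiable"),
           at_count = unname(bp["AT"]), gc_count = unname(bp["GC"]))
    })
    log_msg("spectra written (catalog.tsv)")
  }

  # proximity curves ----------------------------------------------------
  curves <- stage("proximity", lapply(conditions, function(cond) {
    cv <- observed_vs_expected_curve(snvs[[cond]], svs[[cond]], genome,
                                     ranges = config$ranges)
    utils::write.table(as.data.frame(cv),
                       file.path(config$out_dir,
                                 paste0("expected_random_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cv
  }))
  names(curves) <- conditions
  summary$proximity <- lapply(conditions, function(cond) {
    cv <- curves[[cond]]
    at_d <- which.min(abs(cv$range - config$d))
    list(condition = cond, range = cv$range[at_d],
         observed = cv$observed[at_d],
         expected_naive = cv$expected_naive[at_d],
         expected_corrected = cv$expected_corrected[at_d])
  })
  log_msg("expected-random curves written")

  # decomposition -------------------------------------------------------
  decomp <- list()
  for (w in config$window_sizes) {
    fits <- lapply(conditions, function(cond) {
      tab <- count_in_windows(snvs[[cond]], svs[[cond]], genome, w)
      write_window_counts(tab, file.path(
        config$out_dir, sprintf("windows_%s_%gMb.tsv", cond, w / 1e6)
      ))
      fit_decomposition(tab)
    })
    names(fits) <- conditions
    cmp <- compare_conditions(fits[[1]], fits[[2]])
    decomp[[sprintf("%gMb", w / 1e6)]] <- list(
      w = w,
      fits = lapply(fits, function(f) {
        list(slope = f$slope, slope_se = f$slope_se,
             intercept = f$intercept, intercept_se = f$intercept_se,
             intercept_rate = f$intercept_rate, r_squared = f$r_squared,
             n_windows = f$n_windows)
      }),
      slope_ratio = cmp$slope_ratio[c("ratio", "lower", "upper")],
      intercept_rate_ratio =
        cmp$intercept_rate_ratio[c("ratio", "lower", "upper")]
    )
    log_msg("decomposition at %.0f Mb done", w / 1e6)
  }
  summary$decomposition <- decomp

  # per-chromosome SV statistics ----------------------------------------
  if (length(genome$names) >= 3) {
    cs <- stage("chromosome_stats", chromosome_sv_stats(
      svs[[conditions[1]]], svs[[conditions[2]]], genome
    ))
    summary$chromosome_sv <- list(
      pearson_r = cs$pearson_r, pearson_p = cs$pearson_p,
      normalized_total_a = cs$normalized_total_a,
      normalized_total_b = cs$normalized_total_b
    )
  }

  # stratified signature attribution ------------------------------------
  if (!is.null(sequence) && !is.null(refs)) {
    summary$stratified_exposures <- lapply(conditions, function(cond) {
      sa <- stage("stratified_attribution", stratified_attribution(
        snvs[[cond]], svs[[cond]], genome, sequence, refs, d = config$d
      ))
      for (stratum in c("near", "far", "whole")) {
        if (inherits(sa[[stratum]], "exposure_vector")) {
          write_exposures(sa[[stratum]], file.path(
            config$out_dir, sprintf("exposures_%s_%s.tsv", cond, stratum)
          ))
        }
      }
      list(condition = cond, n_near = sa$n_near, n_far = sa$n_far,
           near = exposure_summary(sa$near),
           far = exposure_summary(sa$far),
           whole = exposure_summary(sa$whole))
    })
    log_msg("stratified exposures written")
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("summary.json written")
  invisible(summary)
}
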