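#' Count SNVs and SV breakends in tiling genomic windows
#'
#' Windows start at position 1 of every chromosome and tile in steps of
#' `w`; the final partial window of each chromosome is kept and flagged
#' with its true length. Every record is assigned to exactly one window.
#'
#' @param snvs An [snv_records] table.
#' @param breakends An [sv_breakends] table.
#' @param genome A [genome_def].
#' @param w Window size in bp (> 0).
#' @param count_sv `"breakends"` (default) or `"events"`; with events, an
#'   event is assigned to the window of its first breakend.
#' @return A `data.frame` of class `window_counts` with columns
#'   `chrom, start, end, width, partial, sv_count, snv_count` and
#'   attribute `w`.
#' @export
count_in_windows <- function(snvs, breakends, genome, w,
                             count_sv = c("breakends", "events")) {
  count_sv <- match.arg(count_sv)
  if (w <= 0) stopf("'w' must be > 0")
  check_chromosomes(snvs$chrom, genome, snvs$pos, "SNV")
  check_chromosomes(breakends$chrom, genome, breakends$pos, "breakend")

  if (count_sv == "events" && nrow(breakends) > 0) {
    first <- !duplicated(breakends$event_id)
    breakends <- breakends[first, , drop = FALSE]
  }

  per_chrom <- lapply(genome$names, function(chr) {
    L <- genome$lengths[[chr]]
    n_win <- ceiling(L / w)
    start <- (seq_len(n_win) - 1) * w + 1
    end <- pmin(seq_len(n_win) * w, L)
    win_of <- function(pos) pmin(floor((pos - 1) / w) + 1, n_win)
    snv_pos <- snvs$pos[snvs$chrom == chr]
    sv_pos <- breakends$pos[breakends$chrom == chr]
    data.frame(
      chrom = chr, start = start, end = end,
      width = end - start + 1,
      partial = (end - start + 1) < w,
      sv_count = tabulate(win_of(sv_pos), nbins = n_win),
      snv_count = tabulate(win_of(snv_pos), nbins = n_win),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  class(out) <- c("window_counts", "data.frame")
  attr(out, "w") <- w
  attr(out, "count_sv") <- count_sv
  out
}

#' Decompose windowed SNV load into SV-dependent and SV-independent parts
#'
#' Ordinary least squares of per-window SNV count on per-window SV count.
#' The slope estimates SV-dependent SNVs per SV; the intercept estimates
#' SV-independent SNVs per window and is also reported per Mb
#' (`intercept / (w / 1e6)`), the unit in which background mutation rates
#' are usually quoted.
#'
#' @param table A `window_counts` table from [count_in_windows()].
#' @param drop_partial Exclude chromosome-end partial windows (default
#'   `TRUE`); their shorter territory would otherwise bias the intercept
#'   downward.
#' @param family `"ols"` (default) or `"poisson"` for a log-link GLM
#'   alternative (slope/intercept then live on the log scale and the
#'   derived rate fields are `NA`).
#' @return An object of class `decomposition_result`: `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `intercept_rate` (SNVs/Mb),
#'   `intercept_rate_se`, `r_squared`, `n_windows`, `w`, `residuals`.
#' @export
fit_decomposition <- function(table, drop_partial = TRUE,
                              family = c("ols", "poisson")) {
  family <- match.arg(family)
  w <- attr(table, "w")
  if (is.null(w)) stopf("'table' must come from count_in_windows()")
  if (drop_partial) table <- table[!table$partial, , drop = FALSE]
  if (nrow(table) < 3L) stopf("need >= 3 usable windows, have %d", nrow(table))
  if (stats::var(table$sv_count) == 0) {
    stopf("degenerate design: all SV counts identical, slope undefined")
  }

  if (family == "ols") {
    fit <- stats::lm(snv_count ~ sv_count, data = table)
    # summary.lm warns on exactly collinear (noise-free) input; that case
    # is legitimate here, e.g. for constructed or degenerate-noise windows
    sm <- suppressWarnings(summary(fit))
    co <- sm$coefficients
    intercept <- co["(Intercept)", "Estimate"]
    intercept_se <- co["(Intercept)", "Std. Error"]
    slope <- co["sv_count", "Estimate"]
    slope_se <- co["sv_count", "Std. Error"]
    r2 <- sm$r.squared
    mb <- w / 1e6
    res <- structure(
      list(slope = slope, slope_se = slope_se,
           intercept = intercept, intercept_se = intercept_se,
           intercept_rate = intercept / mb,
           intercept_rate_se = intercept_se / mb,
           r_squared = r2, n_windows = nrow(table), w = w,
           family = family, residuals = unname(stats::residuals(fit))),
      class = "decomposition_result"
    )
  } else {
    fit <- stats::glm(snv_count ~ sv_count, data = table, family = stats::poisson())
    co <- summary(fit)$coefficients
    res <- structure(
      list(slope = co["sv_count", "Estimate"],
           slope_se = co["sv_count", "Std. Error"],
           intercept = co["(Intercept)", "Estimate"],
           intercept_se = co["(Intercept)", "Std. Error"],
           intercept_rate = NA_real_, intercept_rate_se = NA_real_,
           r_squared = NA_real_, n_windows = nrow(table), w = w,
           family = family, residuals = unname(stats::residuals(fit))),
      class = "decomposition_result"
    )
  }
  res
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(
    paste0("decomposition_result (w = %.0f bp, n = %d windows)\n",
           "  slope      %.3f +/- %.3f SNVs per SV\n",
           "  intercept  %.3f +/- %.3f SNVs per window",
           " (%.3f SNVs/Mb)\n  R^2        %.4f\n"),
    x$w, x$n_windows, x$slope, x$slope_se,
    x$intercept, x$intercept_se, x$intercept_rate, x$r_squared
  ))
  invisible(x)
}

# Delta-method ratio with a normal-approximation CI, treating the two
# estimates as independent.
ratio_ci <- function(num, num_se, den, den_se, level = 0.95) {
  if (!is.finite(den) || den <= 0 || !is.finite(num)) {
    return(list(ratio = if (isTRUE(num == 0)) 0 else NA_real_,
                lower = NA_real_, upper = NA_real_, defined = FALSE))
  }
  r <- num / den
  if (num <= 0) {
    return(list(ratio = max(r, 0), lower = NA_real_, upper = NA_real_,
                defined = FALSE))
  }
  se <- abs(r) * sqrt((num_se / num)^2 + (den_se / den)^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ratio = r, lower = r - z * se, upper = r + z * se, defined = TRUE)
}

#' Compare decomposition results between two conditions
#'
#' Reports the ratio (B / A) of slopes (SV-dependent component) and of
#' intercept rates (SV-independent component), each with a delta-method
#' confidence interval, plus Student's and Welch's two-sample t-tests on
#' the window-level regression residuals of the two fits.
#'
#' @param res_a,res_b `decomposition_result`s for conditions A and B, fit
#'   at the same window size.
#' @param level Confidence level (default 0.95).
#' @return An object of class `condition_comparison` with elements
#'   `slope_ratio` and `intercept_rate_ratio` (each
#'   `list(ratio, lower, upper, defined)`), and `residual_tests`.
#' @export
compare_conditions <- function(res_a, res_b, level = 0.95) {
  if (!identical(res_a$w, res_b$w)) {
    stopf("results use different window sizes (%.0f vs %.0f)",
          res_a$w, res_b$w)
  }
  resid_tests <- list(student = NULL, welch = NULL)
  if (length(res_a$residuals) >= 2 && length(res_b$residuals) >= 2 &&
      stats::var(c(res_a$residuals, res_b$residuals)) > 0) {
    resid_tests$student <- stats::t.test(res_b$residuals, res_a$residuals,
                                         var.equal = TRUE)
    resid_tests$welch <- stats::t.test(res_b$residuals, res_a$residuals,
                                       var.equal = FALSE)
  }
  structure(
    list(
      slope_ratio = ratio_ci(res_b$slope, res_b$slope_se,
                             res_a$slope, res_a$slope_se, level),
      intercept_rate_ratio = ratio_ci(res_b$intercept_rate,
                                      res_b$intercept_rate_se,
                                      res_a$intercept_rate,
                                      res_a$intercept_rate_se, level),
      w = res_a$w,
      residual_tests = resid_tests
    ),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  fmt <- function(r) {
    if (!r$defined && is.na(r$ratio)) return("undefined")
    if (!r$defined) return(sprintf("%.3f (CI unavailable)", r$ratio))
    sprintf("%.3f [%.3f, %.3f]", r$ratio, r$lower, r$upper)
  }
  cat(sprintf(paste0("condition_comparison (w = %.0f bp)\n",
                     "  slope ratio (B/A)          %s\n",
                     "  intercept-rate ratio (B/A) %s\n"),
              x$w, fmt(x$slope_ratio), fmt(x$intercept_rate_ratio)))
  invisible(x)
}

#' Per-chromosome SV accumulation statistics for two conditions
#'
#' Computes per-chromosome SV counts per Mb in each condition, the Pearson
#' correlation of those rates across chromosomes (shared SV hotspots give
#' high correlation), and condition totals normalised by per-chromosome
#' copy counts when the genome definition provides them.
#'
#' @param breakends_a,breakends_b [sv_breakends] tables for the two
#'   conditions.
#' @param genome A [genome_def] with >= 3 chromosomes; its `chrom_counts`,
#'   if set, normalise the totals.
#' @return A list of class `chromosome_sv_stats`: `per_chrom` (data frame
#'   of counts and rates per Mb), `pearson_r`, `pearson_p`,
#'   `normalized_total_a`, `normalized_total_b`.
#' @export
chromosome_sv_stats <- function(breakends_a, breakends_b, genome) {
  if (length(genome$names) < 3L) stopf("need >= 3 chromosomes")
  count_by_chrom <- function(b) {
    tab <- table(factor(b$chrom, levels = genome$names))
    as.numeric(tab)
  }
  ca <- count_by_chrom(breakends_a)
  cb <- count_by_chrom(breakends_b)
  mb <- genome$lengths / 1e6
  per_chrom <- data.frame(
    chrom = genome$names,
    count_a = ca, count_b = cb,
    rate_a = ca / mb, rate_b = cb / mb,
    stringsAsFactors = FALSE
  )
  ct <- if (stats::var(ca) > 0 && stats::var(cb) > 0) {
    stats::cor.test(per_chrom$rate_a, per_chrom$rate_b)
  } else {
    NULL
  }
  copies <- genome$chrom_counts %||%
    stats::setNames(rep(1L, length(genome$names)), genome$names)
  structure(
    list(
      per_chrom = per_chrom,
      pearson_r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
      pearson_p = if (is.null(ct)) NA_real_ else ct$p.value,
      normalized_total_a = sum(ca / copies[genome$names]),
      normalized_total_b = sum(cb / copies[genome$names])
    ),
    class = "chromosome_sv_stats"
  )
}

#' Write a window-count table as tab-delimited text
#' @param table A `window_counts` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_counts <- function(table, path) {
  utils::write.table(as.data.frame(table)[, c("chrom", "start", "end",
                                              "sv_count", "snv_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
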