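#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length, neither all-zero.
#' @return `sum(u * v) / (||u|| * ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stopf("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# Lawson-Hanson active-set non-negative least squares:
# minimise ||A x - b||_2 subject to x >= 0. Converged when every
# zero-constrained coordinate has gradient <= tol * scale (KKT).
# Rank-deficient passive sets (e.g. duplicated signature columns) are
# handled through lm.fit, whose aliased coefficients are treated as zero.
nnls_solve <- function(A, b, tol = 1e-8) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(abs(crossprod(A, b)), 1)
  w <- as.numeric(crossprod(A, b))
  max_outer <- 3L * n + 30L
  eps <- 1e-12

  for (outer in seq_len(max_outer)) {
    cand <- which(!passive & w > tol * scale)
    if (length(cand) == 0L) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE

    repeat {
      s <- numeric(n)
      fit <- stats::lm.fit(A[, passive, drop = FALSE], b)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      s[passive] <- coefs
      if (all(s[passive] > eps)) {
        x <- s
        break
      }
      viol <- passive & s <= eps
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive[passive & x <= eps] <- FALSE
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

#' Attribute a mutation spectrum to reference signatures by NNLS refitting
#'
#' Solves `min || spec - refs %*% e ||_2` subject to `e >= 0` with an
#' active-set solver, yielding the number of SNVs attributed to each
#' reference signature. Spectra with 10 or fewer classified SNVs are
#' refused: attribution over 96 channels is meaningless at that depth.
#' If the unconstrained-optimal attribution exceeds the input total, the
#' exposures are rescaled to the total so that attributed counts never
#' exceed the mutations present.
#'
#' @param spec A `mutation_spectrum` (or named 96-count vector).
#' @param refs A 96 x K reference signature matrix
#'   ([read_signature_matrix()] layout); columns sum to 1.
#' @param min_snv Refusal threshold on total classified SNVs
#'   (default 10; strata at or below it are not analysed).
#' @return An object of class `exposure_vector`: `exposures` (named, SNV
#'   counts), `proportions`, `cosine` (reconstruction vs input),
#'   `residual` (L2 norm), `total`.
#' @export
#' @examples
#' refs <- cbind(sigA = rep(1 / 96, 96), sigB = rep(c(1 / 48, 0), 48))
#' rownames(refs) <- sbs96_channels()
#' spec <- spectrum_from_channels(
#'   stats::setNames(round(600 * refs[, 1] + 400 * refs[, 2]), rownames(refs))
#' )
#' refit_exposures(spec, refs)
refit_exposures <- function(spec, refs, min_snv = 10) {
  if (!inherits(spec, "mutation_spectrum")) spec <- spectrum_from_channels(spec)
  validate_signature_matrix(refs)
  refs <- refs[sbs96_channels(), , drop = FALSE]
  total <- attr(spec, "total_classified")
  if (total <= min_snv) {
    stopf("spectrum has %d classified SNVs; refitting requires more than %d",
          total, min_snv)
  }
  b <- as.numeric(spec)
  e <- nnls_solve(refs, b)
  if (sum(e) > total) e <- e * (total / sum(e))
  names(e) <- colnames(refs)
  recon <- as.numeric(refs %*% e)
  structure(
    list(
      exposures = e,
      proportions = if (sum(e) > 0) e / sum(e) else e,
      cosine = if (sum(recon^2) > 0) cosine_similarity(recon, b) else NA_real_,
      residual = sqrt(sum((b - recon)^2)),
      total = total
    ),
    class = "exposure_vector"
  )
}

#' @export
print.exposure_vector <- function(x, ...) {
  cat(sprintf("exposure_vector: %d SNVs, cosine = %.4f\n",
              x$total, x$cosine))
  nz <- sort(x$exposures[x$exposures > 0.5], decreasing = TRUE)
  for (s in names(nz)) {
    cat(sprintf("  %-10s %8.1f (%.1f%%)\n", s, nz[[s]],
                100 * x$proportions[[s]]))
  }
  invisible(x)
}

#' Signature attribution stratified by SV proximity
#'
#' Partitions SNVs into those within `d` of an SV breakend and the rest,
#' builds the 96-channel spectrum of each stratum and of the whole call
#' set, and refits each against the reference signatures. Strata failing
#' the `> min_snv` filter are reported as not analysed rather than
#' refitted.
#'
#' @param snvs An [snv_records] table.
#' @param breakends An [sv_breakends] table.
#' @param genome A [genome_def].
#' @param sequence A named [Biostrings::DNAStringSet] reference sequence.
#' @param refs A 96 x K reference signature matrix.
#' @param d Proximity threshold in bp (default 1e6).
#' @param min_snv Refusal threshold passed to [refit_exposures()].
#' @return A list of class `stratified_attribution` with elements `near`,
#'   `far`, `whole` — each either an `exposure_vector` or a list
#'   `list(status = "not_analyzed", n_snv = ...)` — plus `n_near`,
#'   `n_far`, and `d`.
#' @export
stratified_attribution <- function(snvs, breakends, genome, sequence, refs,
                                   d = 1e6, min_snv = 10) {
  part <- partition_snvs(snvs, breakends, d = d, genome = genome)
  fit_or_flag <- function(records) {
    spec <- build_spectrum(records, sequence)
    if (attr(spec, "total_classified") <= min_snv) {
      list(status = "not_analyzed",
           n_snv = attr(spec, "total_classified"))
    } else {
      refit_exposures(spec, refs, min_snv = min_snv)
    }
  }
  structure(
    list(
      near = fit_or_flag(part$near),
      far = fit_or_flag(part$far),
      whole = fit_or_flag(snvs),
      n_near = nrow(part$near),
      n_far = nrow(part$far),
      d = d
    ),
    class = "stratified_attribution"
  )
}

#' Write an exposure report
#'
#' Tab-delimited `(signature, exposure, proportion)` plus a JSON sidecar
#' with the fit diagnostics.
#'
#' @param fit An `exposure_vector`.
#' @param path Output path for the table; diagnostics go to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(fit, path) {
  utils::write.table(
    data.frame(signature = names(fit$exposures),
               exposure = fit$exposures,
               proportion = fit$proportions),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(total = fit$total, cosine = fit$cosine, residual = fit$residual),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
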