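#' Classify SNVs into 96-channel labels using genomic sequence
#'
#' Extracts the trinucleotide context of each record from the reference
#' sequence and applies pyrimidine normalisation ([classify_context()]).
#' Records at position 1 or the last base of a chromosome (no flank) and
#' records whose context contains an ambiguous base are unclassifiable.
#'
#' @param snvs An [snv_records] table.
#' @param sequence A named [Biostrings::DNAStringSet], one entry per
#'   chromosome.
#' @return Character vector of channel labels, `NA` where unclassifiable.
#' @export
classify_snv <- function(snvs, sequence) {
  n <- nrow(snvs)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  if (is.null(names(sequence))) stopf("'sequence' must be named by chromosome")
  names(sequence) <- sub("\\s.*$", "", names(sequence))
  missing <- setdiff(unique(snvs$chrom), names(sequence))
  if (length(missing) > 0) {
    stopf("no sequence for chromosome(s): %s", paste(missing, collapse = ", "))
  }
  for (chr in unique(snvs$chrom)) {
    i <- which(snvs$chrom == chr)
    L <- Biostrings::width(sequence[chr])
    pos <- snvs$pos[i]
    in_bounds <- pos >= 2 & pos <= L - 1
    if (!any(in_bounds)) next
    j <- i[in_bounds]
    ctx <- as.character(Biostrings::extractAt(
      sequence[[chr]], IRanges::IRanges(snvs$pos[j] - 1, snvs$pos[j] + 1)
    ))
    out[j] <- classify_context(snvs$ref[j], snvs$alt[j], ctx)
  }
  out
}

#' Build a pyrimidine-normalised 96-channel mutation spectrum
#'
#' @param snvs An [snv_records] table.
#' @param sequence A named [Biostrings::DNAStringSet] with the reference
#'   sequence of every chromosome present in `snvs`.
#' @return An object of class `mutation_spectrum`: a named integer vector
#'   of 96 channel counts (canonical order) with attributes
#'   `total_classified` and `unclassifiable`.
#' @export
#' @seealso [spectrum_from_channels()] to build a spectrum from
#'   pre-computed channel labels or counts.
build_spectrum <- function(snvs, sequence) {
  spectrum_from_channels(classify_snv(snvs, sequence))
}

#' Build a spectrum from channel labels or a 96-count vector
#'
#' @param x Either a character vector of channel labels (`NA` =
#'   unclassifiable) or a numeric vector of 96 counts named by channel.
#' @return A `mutation_spectrum`.
#' @export
spectrum_from_channels <- function(x) {
  chans <- sbs96_channels()
  if (is.character(x)) {
    bad <- !is.na(x) & !x %in% chans
    if (any(bad)) stopf("unknown channel label: %s", x[which(bad)[1]])
    counts <- table(factor(x, levels = chans))
    counts <- as.integer(counts)
    unclass_n <- sum(is.na(x))
  } else {
    if (length(x) != 96L) stopf("count vector must have length 96")
    if (is.null(names(x))) names(x) <- chans
    if (!setequal(names(x), chans)) stopf("count vector names must be the 96 channels")
    x <- x[chans]
    if (any(x < 0)) stopf("counts must be non-negative")
    counts <- as.integer(round(x))
    unclass_n <- 0L
  }
  names(counts) <- chans
  structure(counts,
            total_classified = sum(counts),
            unclassifiable = as.integer(unclass_n),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("mutation_spectrum: %d classified SNVs (%d unclassifiable)\n",
              attr(x, "total_classified"), attr(x, "unclassifiable")))
  nz <- x[x > 0]
  if (length(nz) > 0) {
    top <- sort(nz, decreasing = TRUE)
    show <- utils::head(top, 5)
    cat("  top channels:",
        paste(sprintf("%s=%d", names(show), show), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sum spectra channel-wise
#' @param ... `mutation_spectrum` objects.
#' @return Their channel-wise sum as a `mutation_spectrum`.
#' @export
add_spectra <- function(...) {
  specs <- list(...)
  counts <- Reduce(`+`, lapply(specs, as.integer))
  out <- spectrum_from_channels(stats::setNames(counts, sbs96_channels()))
  attr(out, "unclassifiable") <-
    sum(vapply(specs, function(s) attr(s, "unclassifiable") %||% 0L, 0L))
  out
}

#' Split a spectrum into A-T and G-C base-pair totals
#'
#' T-centred channels (T>A, T>C, T>G) count mutations at A-T base pairs;
#' C-centred channels (C>A, C>G, C>T) count mutations at G-C base pairs.
#'
#' @param spec A `mutation_spectrum`.
#' @return Named numeric vector `c(AT = ..., GC = ...)`.
#' @export
split_by_basepair <- function(spec) {
  chans <- sbs96_channels()
  center <- substr(chans, 3, 3)
  c(AT = sum(spec[center == "T"]), GC = sum(spec[center == "C"]))
}

# Channels belonging to a base-pair class ("AT" = T-centred, "GC" = C-centred).
basepair_channels <- function(class = c("AT", "GC")) {
  class <- match.arg(class)
  chans <- sbs96_channels()
  chans[substr(chans, 3, 3) == if (class == "AT") "T" else "C"]
}

#' Compare the extreme channels of a base-pair class between conditions
#'
#' Within one base-pair class (48 T-centred or 48 C-centred channels),
#' channels are ranked by their mean per-sample count in `condition_b`
#' (the condition whose induced channels are of interest; configurable via
#' `rank_condition`). The top-k ("highest") and bottom-k ("lowest")
#' channel subsets are then compared between conditions by a two-tailed
#' Welch's t-test on the per-sample summed counts of each subset.
#'
#' @param spectra Named list of `mutation_spectrum`, one per sample.
#' @param conditions Named character vector mapping sample name to
#'   condition label.
#' @param condition_a,condition_b The two condition labels to compare
#'   (`condition_b` is the ranking basis by default).
#' @param k Subset size (default 10, must be <= 48).
#' @param class `"AT"` or `"GC"`.
#' @param rank_condition Condition whose mean counts define the ranking;
#'   defaults to `condition_b`.
#' @return List with elements `highest` and `lowest`, each a
#'   `channel_comparison` list: `channels`, per-sample `sums_a`/`sums_b`,
#'   `statistic`, `p_value` (`NA` when either condition has < 2 samples).
#' @export
compare_extreme_channels <- function(spectra, conditions, condition_a,
                                     condition_b, k = 10,
                                     class = c("AT", "GC"),
                                     rank_condition = condition_b) {
  class <- match.arg(class)
  if (k < 1 || k > 48) stopf("'k' must be between 1 and 48")
  if (is.null(names(spectra)) || is.null(names(conditions))) {
    stopf("'spectra' and 'conditions' must be named by sample")
  }
  samples <- names(spectra)
  cond <- conditions[samples]
  if (any(is.na(cond))) stopf("every spectrum needs a condition label")

  chans <- basepair_channels(class)
  mat <- vapply(spectra, function(s) as.numeric(s[chans]),
                numeric(length(chans)))
  rownames(mat) <- chans

  rank_samples <- samples[cond == rank_condition]
  if (length(rank_samples) == 0L) {
    stopf("no samples in ranking condition '%s'", rank_condition)
  }
  mean_b <- rowMeans(mat[, rank_samples, drop = FALSE])
  ord <- order(mean_b, decreasing = TRUE)

  subset_test <- function(subset_chans, id) {
    sums_a <- colSums(mat[subset_chans, samples[cond == condition_a],
                          drop = FALSE])
    sums_b <- colSums(mat[subset_chans, samples[cond == condition_b],
                          drop = FALSE])
    stat <- NA_real_; p <- NA_real_
    if (length(sums_a) >= 2 && length(sums_b) >= 2) {
      if (stats::var(c(sums_a, sums_b)) == 0) {
        stat <- 0; p <- 1           # identical data: no evidence of difference
      } else {
        tt <- stats::t.test(sums_b, sums_a, var.equal = FALSE)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
    }
    structure(list(subset = id, channels = subset_chans,
                   sums_a = sums_a, sums_b = sums_b,
                   statistic = stat, p_value = p),
              class = "channel_comparison")
  }

  list(
    highest = subset_test(chans[ord[seq_len(k)]],
                          sprintf("%s highest %d", class, k)),
    lowest = subset_test(chans[rev(ord)[seq_len(k)]],
                         sprintf("%s lowest %d", class, k))
  )
}
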