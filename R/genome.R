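#' Construct a genome definition
#'
#' A genome definition holds the ordered chromosome names, their lengths in
#' bp, and optionally a per-chromosome copy count (used to normalise SV
#' totals in aneuploid samples). It is the coordinate frame every other
#' operation validates against.
#'
#' @param names Character vector of unique chromosome names.
#' @param lengths Integer/numeric vector of chromosome lengths (bp, > 0).
#' @param chrom_counts Optional integer vector of per-chromosome copy
#'   counts (>= 1), recycled names from `names`.
#' @return An object of class `genome_def` with elements `names`,
#'   `lengths` (named), `total` (the genome length G), and `chrom_counts`.
#' @export
#' @examples
#' genome_def(c("chr1", "chr2"), c(3e7, 2e7))
genome_def <- function(names, lengths, chrom_counts = NULL) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths)) {
    stopf("'names' and 'lengths' must have equal length")
  }
  if (anyDuplicated(names)) stopf("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stopf("chromosome lengths must be positive and finite")
  }
  if (!is.null(chrom_counts)) {
    chrom_counts <- as.integer(chrom_counts)
    if (length(chrom_counts) != length(names) || any(chrom_counts < 1L)) {
      stopf("'chrom_counts' must give one integer >= 1 per chromosome")
    }
    names(chrom_counts) <- names
  }
  names(lengths) <- names
  structure(
    list(
      names = names,
      lengths = lengths,
      total = sum(lengths),
      chrom_counts = chrom_counts
    ),
    class = "genome_def"
  )
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf(
    "genome_def: %d chromosomes, G = %.0f bp\n", length(x$names), x$total
  ))
  invisible(x)
}

#' Read a genome definition from a chromosome-sizes table
#'
#' Accepts the two-column `<chrom>\t<length>` format (as produced by
#' `samtools faidx` indices or UCSC chrom.sizes files; extra columns of a
#' `.fai` file are ignored).
#'
#' @param path Path to a tab-delimited chrom-sizes or `.fai` file.
#' @return A [genome_def].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stopf("chrom-sizes file needs >= 2 columns: %s", path)
  genome_def(tab[[1]], tab[[2]])
}

#' Build a genome definition from sequence
#'
#' @param x A [Biostrings::DNAStringSet] or a path to a FASTA file.
#' @return A [genome_def] whose chromosomes are the sequence names.
#' @export
genome_from_sequence <- function(x) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  nm <- sub("\\s.*$", "", names(x)) # FASTA headers may carry descriptions
  genome_def(nm, Biostrings::width(x))
}

# Assert that all chromosomes in `chrom` exist in the genome; positions are
# checked against chromosome length when given. Used at every module
# boundary so that records on unknown chromosomes are rejected rather than
# silently dropped (silent drops would corrupt the genome-length
# denominator of the expected-random model).
check_chromosomes <- function(chrom, genome, pos = NULL, what = "record") {
  bad <- setdiff(unique(chrom), genome$names)
  if (length(bad) > 0) {
    stopf("%s(s) on chromosome(s) absent from genome: %s",
          what, paste(bad, collapse = ", "))
  }
  if (!is.null(pos) && length(pos)) {
    L <- genome$lengths[chrom]
    out <- which(pos < 1 | pos > L)
    if (length(out) > 0) {
      stopf("%s at %s:%d outside chromosome bounds",
            what, chrom[out[1]], as.integer(pos[out[1]]))
    }
  }
  invisible(TRUE)
}
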