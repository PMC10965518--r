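#' The 96 canonical single-base-substitution channels
#'
#' Channel labels follow the COSMIC convention `5'[REF>ALT]3'`, with the
#' reference base always the pyrimidine of its base pair. Channels are
#' ordered substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then by 5'
#' flank and 3' flank alphabetically, giving the layout used throughout for
#' spectra and signature matrices.
#'
#' @return Character vector of 96 channel labels, e.g. `"A[C>A]A"`.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(p5) paste0(p5, "[", s, "]", bases)))
  }))
}

#' The six pyrimidine-normalised substitution types
#' @return Character vector `c("C>A", ..., "T>G")`.
#' @export
sbs_substitutions <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# Complement of a vector of single bases; non-ACGT maps to NA.
complement_base <- function(x) {
  out <- chartr("ACGT", "TGCA", x)
  out[!x %in% c("A", "C", "G", "T")] <- NA_character_
  out
}

# Reverse complement of trinucleotide strings (vectorised).
revcomp_trinuc <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  paste0(substr(comp, 3, 3), substr(comp, 2, 2), substr(comp, 1, 1))
}

#' Classify substitutions by trinucleotide context
#'
#' Maps each (ref, alt, context) triple to its pyrimidine-normalised
#' 96-channel label. Substitutions whose reference base is a purine are
#' reported on the opposite strand: ref and alt are complemented and the
#' context reverse-complemented. Contexts containing any base outside
#' A/C/G/T (e.g. N), contexts whose centre disagrees with `ref`, and
#' ref == alt all yield `NA` (unclassifiable).
#'
#' @param ref,alt Character vectors of single reference/alternate bases.
#' @param context Character vector of 3-base contexts centred on `ref`.
#' @return Character vector of channel labels or `NA`.
#' @export
#' @examples
#' classify_context("G", "T", "AGC") # "G[C>A]T"
#' classify_context("T", "G", "ATC") # "A[T>G]C"
classify_context <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  context <- toupper(rep_len(context, n))

  ok <- ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T") &
    ref != alt &
    nchar(context) == 3L &
    !grepl("[^ACGT]", context) &
    substr(context, 2, 2) == ref

  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)

  r <- ref[ok]
  a <- alt[ok]
  ctx <- context[ok]

  purine <- r %in% c("A", "G")
  r[purine] <- complement_base(r[purine])
  a[purine] <- complement_base(a[purine])
  ctx[purine] <- revcomp_trinuc(ctx[purine])

  out[ok] <- paste0(
    substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3)
  )
  out
}

# Split channel labels into their components. Returns a data.frame with
# columns p5, ref, alt, p3; input is assumed well-formed.
parse_channel <- function(channel) {
  data.frame(
    p5 = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    p3 = substr(channel, 7, 7),
    stringsAsFactors = FALSE
  )
}

# Pyrimidine-strand trinucleotide of each channel (e.g. "A[C>A]G" -> "ACG").
channel_trinuc <- function(channel) {
  paste0(substr(channel, 1, 1), substr(channel, 3, 3), substr(channel, 7, 7))
}
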