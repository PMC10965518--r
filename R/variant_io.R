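#' Construct a table of SNV records
#'
#' The internal SNV container is a plain data frame with one row per
#' somatic single-base substitution, in 1-based VCF coordinates.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions (bp).
#' @param ref,alt Single reference/alternate bases (A/C/G/T, ref != alt).
#' @param sample,condition Sample and condition labels (recycled).
#' @param genome Optional [genome_def] to validate coordinates against.
#' @return A `data.frame` of class `snv_records` with columns
#'   `chrom, pos, ref, alt, sample, condition`.
#' @export
snv_records <- function(chrom, pos, ref, alt, sample = "sample1",
                        condition = "A", genome = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  if (length(pos) == 0L) n <- 0L
  recycle <- function(x, what) {
    if (length(x) == n || n == 0L) return(x)
    if (length(x) == 1L) return(rep_len(x, n))
    stopf("'%s' must have length 1 or %d", what, n)
  }
  chrom <- recycle(as.character(chrom), "chrom")
  pos <- as.numeric(pos)
  ref <- recycle(toupper(as.character(ref)), "ref")
  alt <- recycle(toupper(as.character(alt)), "alt")
  if (length(pos) != n) stopf("'pos' must have length %d", n)
  if (n > 0) {
    if (any(!ref %in% c("A", "C", "G", "T")) ||
        any(!alt %in% c("A", "C", "G", "T"))) {
      stopf("ref and alt must be single bases A/C/G/T")
    }
    if (any(ref == alt)) stopf("ref must differ from alt")
    if (any(pos < 1)) stopf("positions must be >= 1")
  }
  if (!is.null(genome)) check_chromosomes(chrom, genome, pos, "SNV")
  out <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    sample = rep_len(as.character(sample), n),
    condition = rep_len(as.character(condition), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("snv_records", "data.frame")
  out
}

#' Construct a table of SV breakends
#'
#' One row per breakpoint position ("SV site"). The two breakends of a
#' single event share an `event_id`; both count as SV sites for proximity
#' analysis since both are lesion positions.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based breakpoint positions (bp).
#' @param type Event types, one of `DEL, DUP, INV, TRA, OTHER`.
#' @param event_id Event identifiers; each id may map to 1 or 2 breakends.
#' @param sample,condition Labels (recycled).
#' @param genome Optional [genome_def] for coordinate validation.
#' @return A `data.frame` of class `sv_breakends`.
#' @export
sv_breakends <- function(chrom, pos, type = "OTHER", event_id = NULL,
                         sample = "sample1", condition = "A",
                         genome = NULL) {
  n <- length(pos)
  chrom <- as.character(chrom)
  if (length(chrom) == 1L && n > 1L) chrom <- rep_len(chrom, n)
  if (length(chrom) != n) stopf("'chrom' must have length 1 or %d", n)
  pos <- as.numeric(pos)
  type <- rep_len(toupper(as.character(type)), n)
  if (n > 0 && any(!type %in% c("DEL", "DUP", "INV", "TRA", "OTHER"))) {
    stopf("type must be one of DEL, DUP, INV, TRA, OTHER")
  }
  if (n > 0 && any(pos < 1)) stopf("positions must be >= 1")
  if (is.null(event_id)) event_id <- paste0("sv", seq_len(n))
  event_id <- rep_len(as.character(event_id), n)
  if (n > 0) {
    per_event <- table(event_id)
    if (any(per_event > 2)) {
      stopf("event id(s) with more than 2 breakends: %s",
            paste(names(per_event)[per_event > 2], collapse = ", "))
    }
  }
  if (!is.null(genome)) check_chromosomes(chrom, genome, pos, "breakend")
  out <- data.frame(
    chrom = chrom, pos = pos, type = type, event_id = event_id,
    sample = rep_len(as.character(sample), n),
    condition = rep_len(as.character(condition), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sv_breakends", "data.frame")
  out
}

#' Read somatic SNVs from a VCF file
#'
#' Keeps biallelic single-base substitutions; multi-allelic records are
#' split into one record per alternate allele; indels and symbolic/other
#' alleles are skipped and tallied in a skip report attached to the result.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param sample,condition Labels applied to all records.
#' @param genome Optional [genome_def]; records on chromosomes absent from
#'   it raise an error (never a silent drop).
#' @param pass_only If `TRUE`, keep only records whose FILTER is PASS or
#'   `.`. Default keeps everything, as no filter policy is assumed.
#' @return An [snv_records] table with attribute `skip_report`, a named
#'   integer vector of skipped record counts by reason
#'   (`indel`, `symbolic`, `filtered`).
#' @export
read_snv_vcf <- function(path, sample = "sample1", condition = "A",
                         genome = NULL, pass_only = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  skip <- c(indel = 0L, symbolic = 0L, filtered = 0L)

  if (!is.null(fix) && is.null(dim(fix))) { # single record: named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0L) {
    out <- snv_records(character(), numeric(), character(), character(),
                       sample, condition)
    attr(out, "skip_report") <- skip
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  if (pass_only) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
    skip["filtered"] <- sum(!keep)
    fix <- fix[keep, , drop = FALSE]
  }

  # split multi-allelic ALT fields into one row per allele
  alts <- strsplit(fix$ALT %||% character(), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  chrom <- fix$CHROM[idx]
  pos <- as.numeric(fix$POS[idx])
  ref <- toupper(fix$REF[idx])
  alt <- toupper(unlist(alts))

  is_symbolic <- grepl("[^ACGT]", alt) | grepl("[^ACGT]", ref)
  is_snv <- !is_symbolic & nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  skip["symbolic"] <- sum(is_symbolic)
  skip["indel"] <- sum(!is_symbolic & !is_snv)

  out <- snv_records(chrom[is_snv], pos[is_snv], ref[is_snv], alt[is_snv],
                     sample, condition, genome = genome)
  attr(out, "skip_report") <- skip
  out
}

#' Write SNV records as a minimal VCF 4.2 file
#'
#' @param snvs An [snv_records] table.
#' @param path Output path.
#' @param genome Optional [genome_def]; adds contig header lines.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path, genome = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%.0f>", genome$names, genome$lengths)
    },
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(snvs) > 0) {
    sprintf("%s\t%.0f\t.\t%s\t%s\t.\tPASS\t.",
            snvs$chrom, snvs$pos, snvs$ref, snvs$alt)
  } else {
    character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read SV breakends from BEDPE or BED
#'
#' BEDPE rows (two coordinate blocks) yield two breakends sharing an event
#' id; BED rows yield one. On-disk 0-based half-open starts are converted
#' to 1-based breakpoint positions (the start coordinate of each block).
#'
#' @param path Path to a tab-delimited BEDPE (>= 6 coordinate columns) or
#'   BED (>= 3 columns) file.
#' @param dialect `"bedpe"` or `"bed"`.
#' @param sample,condition Labels applied to all records.
#' @param genome Optional [genome_def] for validation.
#' @return An [sv_breakends] table.
#' @export
read_sv_breakends <- function(path, dialect = c("bedpe", "bed"),
                              sample = "sample1", condition = "A",
                              genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL
      else stopf("cannot parse %s: %s", path, conditionMessage(e))
    }
  )
  if (is.null(tab) || nrow(tab) == 0L) {
    return(sv_breakends(character(), numeric(), sample = sample,
                        condition = condition))
  }

  if (dialect == "bedpe") {
    if (ncol(tab) < 6L) stopf("BEDPE needs >= 6 columns: %s", path)
    s1 <- as.numeric(tab[[2]]); e1 <- as.numeric(tab[[3]])
    s2 <- as.numeric(tab[[5]]); e2 <- as.numeric(tab[[6]])
    if (any(s1 < 0 | s2 < 0)) stopf("negative coordinate in %s", path)
    if (any(s1 >= e1 | s2 >= e2)) stopf("start >= end in %s", path)
    type <- if (ncol(tab) >= 11L) toupper(tab[[11]]) else "OTHER"
    type[!type %in% c("DEL", "DUP", "INV", "TRA", "OTHER")] <- "OTHER"
    id <- if (ncol(tab) >= 7L) as.character(tab[[7]]) else
      paste0("sv", seq_len(nrow(tab)))
    n <- nrow(tab)
    sv_breakends(
      chrom = c(rbind(tab[[1]], tab[[4]])),
      pos = c(rbind(s1 + 1, s2 + 1)),      # 0-based start -> 1-based
      type = rep(rep_len(type, n), each = 2),
      event_id = rep(id, each = 2),
      sample = sample, condition = condition, genome = genome
    )
  } else {
    if (ncol(tab) < 3L) stopf("BED needs >= 3 columns: %s", path)
    s <- as.numeric(tab[[2]]); e <- as.numeric(tab[[3]])
    if (any(s < 0)) stopf("negative coordinate in %s", path)
    if (any(s >= e)) stopf("start >= end in %s", path)
    id <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else
      paste0("sv", seq_len(nrow(tab)))
    sv_breakends(
      chrom = tab[[1]], pos = s + 1, type = "OTHER", event_id = id,
      sample = sample, condition = condition, genome = genome
    )
  }
}

#' Write SV breakend pairs as BEDPE
#'
#' Events with two breakends become one BEDPE row; single-breakend events
#' are written with both blocks at the same position.
#'
#' @param breakends An [sv_breakends] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_bedpe <- function(breakends, path) {
  rows <- lapply(split(seq_len(nrow(breakends)), breakends$event_id),
                 function(i) {
    b <- breakends[i, , drop = FALSE]
    b <- b[order(b$chrom, b$pos), , drop = FALSE]
    j <- if (nrow(b) == 2L) 2L else 1L
    sprintf("%s\t%.0f\t%.0f\t%s\t%.0f\t%.0f\t%s\t.\t.\t.\t%s",
            b$chrom[1], b$pos[1] - 1, b$pos[1],
            b$chrom[j], b$pos[j] - 1, b$pos[j],
            b$event_id[1], b$type[1])
  })
  writeLines(unlist(rows) %||% character(), path)
  invisible(path)
}

#' Read a reference SBS signature matrix
#'
#' Expects the COSMIC text layout: tab-delimited, first column the 96
#' channel labels in `A[C>A]A` style, remaining columns one signature
#' each. Rows are reordered to the canonical order of [sbs96_channels()]
#' and columns validated as probability vectors.
#'
#' @param path Path to the tab-delimited matrix.
#' @return A 96 x K numeric matrix, rownames the canonical channels,
#'   colnames the signature names.
#' @export
read_signature_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- labels
  validate_signature_matrix(mat)
  mat[sbs96_channels(), , drop = FALSE]
}

#' Write a signature matrix in COSMIC text layout
#' @param refs 96 x K matrix as from [read_signature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(refs, path) {
  df <- data.frame(Type = rownames(refs), refs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Validate a 96 x K signature matrix: canonical channel set, non-negative
# entries, columns summing to 1 within 1e-3.
validate_signature_matrix <- function(mat) {
  chans <- sbs96_channels()
  if (nrow(mat) != 96L) {
    stopf("signature matrix must have 96 channel rows, found %d", nrow(mat))
  }
  if (is.null(rownames(mat)) || !setequal(rownames(mat), chans)) {
    missing <- setdiff(chans, rownames(mat))
    stopf("signature matrix channel labels are not the canonical 96%s",
          if (length(missing)) paste0("; missing e.g. ", missing[1]) else "")
  }
  if (any(mat < 0)) stopf("signature matrix has negative entries")
  sums <- colSums(mat)
  off <- which(abs(sums - 1) > 1e-3)
  if (length(off) > 0) {
    stopf("signature column(s) do not sum to 1: %s",
          paste(colnames(mat)[off] %||% off, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write 96-channel catalogs (one column per sample)
#'
#' @param spectra A named list of [build_spectrum()] results, or a single
#'   spectrum.
#' @param path Output path (tab-delimited; channels as rows).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(spectra, path) {
  if (inherits(spectra, "mutation_spectrum")) {
    spectra <- list(sample1 = spectra)
  }
  mat <- do.call(cbind, lapply(spectra, as.integer))
  rownames(mat) <- sbs96_channels()
  colnames(mat) <- names(spectra)
  df <- data.frame(MutationType = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 96-channel catalog written by [write_catalog()]
#' @param path Path to the tab-delimited catalog.
#' @return A 96 x S integer matrix in canonical channel order.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  if (!setequal(rownames(mat), sbs96_channels())) {
    stopf("catalog does not contain the canonical 96 channels")
  }
  storage.mode(mat) <- "integer"
  mat[sbs96_channels(), , drop = FALSE]
}
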