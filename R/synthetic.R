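#' Simulate a genome and (optionally) its sequence
#'
#' Chromosome sequences are i.i.d. uniform A/C/G/T, reproducible for a
#' given seed. Uniform composition means every trinucleotide is equally
#' available, so simulated signature mixtures are realisable essentially
#' everywhere; real genomes are not composition-uniform (see the methods
#' vignette for what this does and does not let tests show).
#'
#' @param n_chrom Number of chromosomes (default 5).
#' @param lengths Chromosome lengths in bp (recycled to `n_chrom`;
#'   default 30 Mb each).
#' @param seed Integer seed; the same seed gives byte-identical sequence.
#' @param with_sequence Generate sequence (default `TRUE`); with `FALSE`
#'   only the coordinate frame is built, which is all the window and
#'   proximity stages need.
#' @return A list: `genome` (a [genome_def]) and `sequence` (a named
#'   [Biostrings::DNAStringSet], or `NULL`).
#' @export
simulate_genome <- function(n_chrom = 5, lengths = 30e6, seed = 1,
                            with_sequence = TRUE) {
  lengths <- rep_len(as.numeric(lengths), n_chrom)
  nm <- paste0("chr", seq_len(n_chrom))
  genome <- genome_def(nm, lengths)
  sequence <- NULL
  if (with_sequence) {
    codes <- utf8ToInt("ACGT")
    seqs <- with_seed(seed, vapply(seq_len(n_chrom), function(i) {
      intToUtf8(codes[sample.int(4L, lengths[i], replace = TRUE)])
    }, character(1)))
    sequence <- Biostrings::DNAStringSet(seqs)
    names(sequence) <- nm
  }
  list(genome = genome, sequence = sequence)
}

#' Place SV hotspot intervals on a genome
#'
#' Hotspots model the recurrent SV-induction regions shared between
#' conditions: fixed intervals with relative intensity weights from which
#' a configurable fraction of SV events is drawn.
#'
#' @param genome A [genome_def].
#' @param n_hotspots Number of hotspot intervals (default 10).
#' @param width Hotspot width in bp (default 1e6).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `chrom, start, end, weight`.
#' @export
simulate_hotspots <- function(genome, n_hotspots = 10, width = 1e6,
                              seed = 1) {
  with_seed(seed, {
    chrom <- sample(genome$names, n_hotspots, replace = TRUE,
                    prob = genome$lengths)
    L <- genome$lengths[chrom]
    start <- floor(runif(n_hotspots, 1, pmax(2, L - width))) + 1
    data.frame(
      chrom = chrom,
      start = start,
      end = pmin(start + width - 1, L),
      weight = stats::rgamma(n_hotspots, shape = 2, rate = 2) + 0.1,
      stringsAsFactors = FALSE
    )
  })
}

# Draw n uniform positions over the genome within [2, L-1] (both flanks on
# the chromosome, so every simulated SNV is classifiable).
sample_uniform_positions <- function(genome, n) {
  chrom <- sample(genome$names, n, replace = TRUE, prob = genome$lengths)
  L <- genome$lengths[chrom]
  pos <- floor(runif(n, 1, L - 2)) + 2
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate SV events
#'
#' Event positions are drawn from a mixture of a uniform-genome component
#' and a hotspot-weighted component; each event contributes two breakends
#' on the same chromosome. Uniform-component events separate their
#' breakends by a Uniform(1 kb, 100 kb) span; hotspot-component events
#' place both breakends independently within the chosen hotspot, keeping
#' the whole lesion inside the recurrently broken region. Two conditions
#' simulated from the same hotspot table share their hotspot architecture
#' and differ only through the seed stream.
#'
#' @param genome A [genome_def].
#' @param n_sv Number of SV events (each with two breakends).
#' @param hotspots Hotspot table from [simulate_hotspots()] (or `NULL`
#'   for none).
#' @param hotspot_weight Probability that an event is drawn from the
#'   hotspot component (default 0.5; 0 disables hotspots).
#' @param seed Integer seed.
#' @param sample,condition Labels for the generated records.
#' @return An [sv_breakends] table with `2 * n_sv` rows.
#' @export
simulate_svs <- function(genome, n_sv = 100, hotspots = NULL,
                         hotspot_weight = 0.5, seed = 1,
                         sample = "sim", condition = "A") {
  if (is.null(hotspots) || nrow(hotspots) == 0L) hotspot_weight <- 0
  with_seed(seed, {
    if (n_sv == 0) {
      return(sv_breakends(character(), numeric(), sample = sample,
                          condition = condition))
    }
    from_hot <- runif(n_sv) < hotspot_weight
    chrom <- character(n_sv)
    pos1 <- numeric(n_sv)
    pos2 <- numeric(n_sv)
    n_hot <- sum(from_hot)
    if (n_hot > 0) {
      row <- sample.int(nrow(hotspots), n_hot, replace = TRUE,
                        prob = hotspots$weight)
      chrom[from_hot] <- hotspots$chrom[row]
      pos1[from_hot] <- floor(runif(n_hot, hotspots$start[row],
                                    hotspots$end[row])) + 1
      pos2[from_hot] <- floor(runif(n_hot, hotspots$start[row],
                                    hotspots$end[row])) + 1
    }
    if (n_hot < n_sv) {
      u <- sample_uniform_positions(genome, n_sv - n_hot)
      chrom[!from_hot] <- u$chrom
      pos1[!from_hot] <- u$pos
      span <- floor(runif(n_sv - n_hot, 1e3, 1e5))
      L <- genome$lengths[u$chrom]
      pos2[!from_hot] <- ifelse(u$pos + span <= L, u$pos + span,
                                pmax(1, u$pos - span))
    }
    type <- sample(c("DEL", "DUP", "INV"), n_sv, replace = TRUE)
    sv_breakends(
      chrom = rep(chrom, each = 2),
      pos = c(rbind(pos1, pos2)),
      type = rep(type, each = 2),
      event_id = rep(sprintf("%s_sv%04d", condition, seq_len(n_sv)), each = 2),
      sample = sample, condition = condition, genome = genome
    )
  })
}

#' Generate a synthetic reference signature matrix
#'
#' Columns are sparse Dirichlet draws over the 96 channels (small
#' concentration, so signatures are well separated); one designated column
#' places all of its mass on T-centred channels, emulating a process that
#' mutates A-T base pairs. Intended for simulation and recovery tests —
#' these are synthetic profiles, not COSMIC signatures.
#'
#' @param k Number of signatures (default 4).
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration per channel (default 0.2).
#' @param at_column Index of the T-centred column, or `NA` for none
#'   (default 2).
#' @return A 96 x k probability matrix, columns `sig1..sigk`.
#' @export
synthetic_signatures <- function(k = 4, seed = 1, concentration = 0.2,
                                 at_column = 2) {
  chans <- sbs96_channels()
  t_centered <- substr(chans, 3, 3) == "T"
  with_seed(seed, {
    mat <- vapply(seq_len(k), function(j) {
      g <- stats::rgamma(96, shape = concentration)
      if (!is.na(at_column) && j == at_column) g[!t_centered] <- 0
      if (sum(g) == 0) g[1] <- 1
      g / sum(g)
    }, numeric(96))
    rownames(mat) <- chans
    colnames(mat) <- paste0("sig", seq_len(k))
    mat
  })
}

# Vectorised rejection sampler: find positions whose trinucleotide context
# realises each record's drawn channel (forward or reverse-complement
# strand). `draw` proposes fresh positions for a set of record indices.
# Records still unplaced after max_retry rounds fall back to a
# context-agnostic position whose centre base matches the channel's
# reference on either strand, and their realised channel is relabelled
# from the actual context.
place_by_channel <- function(channel, draw, seqchar, chrom_len,
                             max_retry = 1000) {
  n <- length(channel)
  trinuc <- channel_trinuc(channel)
  trinuc_rc <- revcomp_trinuc(trinuc)
  chrom <- character(n)
  pos <- numeric(n)
  placed <- logical(n)

  context_at <- function(chr, p) {
    substring(seqchar[chr], p - 1, p + 1)
  }

  pending <- seq_len(n)
  for (round in seq_len(max_retry)) {
    if (length(pending) == 0L) break
    prop <- draw(pending)
    ctx <- context_at(prop$chrom, prop$pos)
    ok <- ctx == trinuc[pending] | ctx == trinuc_rc[pending]
    hit <- pending[ok]
    chrom[hit] <- prop$chrom[ok]
    pos[hit] <- prop$pos[ok]
    placed[hit] <- TRUE
    pending <- pending[!ok]
  }

  fallback <- integer(0)
  if (length(pending) > 0L) {
    fallback <- pending
    ref_pyr <- substr(channel[pending], 3, 3)
    ref_any <- cbind(ref_pyr, complement_base(ref_pyr))
    for (round in seq_len(max_retry)) {
      if (length(pending) == 0L) break
      prop <- draw(pending)
      center <- substring(seqchar[prop$chrom], prop$pos, prop$pos)
      idx <- match(pending, fallback)
      ok <- center == ref_any[idx, 1] | center == ref_any[idx, 2]
      hit <- pending[ok]
      chrom[hit] <- prop$chrom[ok]
      pos[hit] <- prop$pos[ok]
      placed[hit] <- TRUE
      pending <- pending[!ok]
    }
    # an unplaceable record would need a centre base absent near its
    # stratum; place it wherever the last proposal landed
    if (length(pending) > 0L) {
      prop <- draw(pending)
      chrom[pending] <- prop$chrom
      pos[pending] <- prop$pos
      placed[pending] <- TRUE
    }
  }
  list(chrom = chrom, pos = pos, n_fallback = length(fallback))
}

#' Simulate somatic SNVs around SV breakends plus a uniform background
#'
#' Two components: a uniform SV-independent background of
#' `Poisson(b * G / 1e6)` SNVs, and an SV-proximal component of
#' `Poisson(k)` SNVs per breakend placed at `breakend +/- Uniform(1,
#' cluster_width)` (never on the breakend itself). Each SNV draws a
#' signature from its stratum's mixture and a 96-channel from that
#' signature. When sequence is supplied, positions are rejection-sampled
#' until the local trinucleotide realises the drawn channel (capped; see
#' `max_retry`), and ref/alt are written strand-consistently with the
#' sequence; without sequence, positions are kept as drawn and ref/alt
#' are taken from the channel's pyrimidine strand.
#'
#' @param genome A [genome_def].
#' @param breakends An [sv_breakends] table (the SV-proximal component is
#'   skipped when empty).
#' @param refs 96 x K signature matrix.
#' @param mixture_background,mixture_near Mixing proportions over the
#'   columns of `refs` for the background and SV-proximal strata (each
#'   sums to 1).
#' @param b Background rate in SNVs per Mb (default 2).
#' @param k Mean clustered SNVs per breakend (default 30).
#' @param cluster_width Half-width c of the proximal placement window in
#'   bp (default 5e5).
#' @param sequence Optional named [Biostrings::DNAStringSet] (or character
#'   vector) for context-consistent placement.
#' @param seed Integer seed.
#' @param sample,condition Labels.
#' @param max_retry Rejection-sampling cap per record (default 1000).
#' @return An [snv_records] table with extra columns `stratum`
#'   (`"background"`/`"sv_proximal"`), `signature`, `channel_drawn`, and
#'   `channel_realized`, plus attribute `n_fallback` (records placed
#'   context-agnostically).
#' @export
simulate_snvs <- function(genome, breakends, refs,
                          mixture_background, mixture_near = mixture_background,
                          b = 2, k = 30, cluster_width = 5e5,
                          sequence = NULL, seed = 1,
                          sample = "sim", condition = "A",
                          max_retry = 1000) {
  validate_signature_matrix(refs)
  K <- ncol(refs)
  check_mix <- function(m, what) {
    if (length(m) != K || any(m < 0) || abs(sum(m) - 1) > 1e-6) {
      stopf("'%s' must be %d non-negative proportions summing to 1", what, K)
    }
  }
  check_mix(mixture_background, "mixture_background")
  check_mix(mixture_near, "mixture_near")
  if (b < 0 || k < 0 || cluster_width <= 0) {
    stopf("need b >= 0, k >= 0, cluster_width > 0")
  }
  seqchar <- NULL
  if (!is.null(sequence)) {
    seqchar <- stats::setNames(as.character(sequence),
                               sub("\\s.*$", "", names(sequence)))
  }

  with_seed(seed, {
    # --- how many SNVs in each component -------------------------------
    n_bg <- stats::rpois(1, b * genome$total / 1e6)
    n_per_bk <- if (nrow(breakends) > 0) {
      stats::rpois(nrow(breakends), k)
    } else {
      integer(0)
    }
    n_prox <- sum(n_per_bk)
    bk_of <- rep(seq_along(n_per_bk), n_per_bk)

    stratum <- c(rep("background", n_bg), rep("sv_proximal", n_prox))
    n <- n_bg + n_prox

    # --- channels ------------------------------------------------------
    sig_idx <- integer(n)
    if (n_bg > 0) {
      sig_idx[seq_len(n_bg)] <- sample.int(K, n_bg, replace = TRUE,
                                           prob = mixture_background)
    }
    if (n_prox > 0) {
      sig_idx[n_bg + seq_len(n_prox)] <- sample.int(K, n_prox, replace = TRUE,
                                                    prob = mixture_near)
    }
    channel <- character(n)
    chans <- sbs96_channels()
    for (j in unique(sig_idx)) {
      pick <- sig_idx == j
      channel[pick] <- sample(chans, sum(pick), replace = TRUE,
                              prob = refs[, j])
    }

    # --- position proposal rules per stratum ---------------------------
    draw_positions <- function(idx) {
      out_chrom <- character(length(idx))
      out_pos <- numeric(length(idx))
      is_bg <- stratum[idx] == "background"
      if (any(is_bg)) {
        u <- sample_uniform_positions(genome, sum(is_bg))
        out_chrom[is_bg] <- u$chrom
        out_pos[is_bg] <- u$pos
      }
      if (any(!is_bg)) {
        j <- idx[!is_bg]
        bk <- bk_of[j - n_bg]
        ctr <- breakends$pos[bk]
        chr <- breakends$chrom[bk]
        L <- genome$lengths[chr]
        off <- sample(c(-1, 1), length(j), replace = TRUE) *
          floor(runif(length(j), 1, cluster_width + 1))
        p <- pmin(pmax(ctr + off, 2), L - 1)
        p[p == ctr] <- pmin(pmax(ctr + 1, 2), L - 1)[p == ctr]
        out_chrom[!is_bg] <- chr
        out_pos[!is_bg] <- p
      }
      data.frame(chrom = out_chrom, pos = out_pos, stringsAsFactors = FALSE)
    }

    # --- placement and allele realisation ------------------------------
    n_fallback <- 0L
    if (is.null(seqchar)) {
      prop <- draw_positions(seq_len(n))
      chrom <- prop$chrom
      pos <- prop$pos
      ref <- substr(channel, 3, 3)
      alt <- substr(channel, 5, 5)
      realized <- channel
    } else {
      placed <- place_by_channel(channel, draw_positions, seqchar,
                                 genome$lengths, max_retry = max_retry)
      chrom <- placed$chrom
      pos <- placed$pos
      n_fallback <- placed$n_fallback
      center <- substring(seqchar[chrom], pos, pos)
      pyr_ref <- substr(channel, 3, 3)
      pyr_alt <- substr(channel, 5, 5)
      on_pyr <- center == pyr_ref
      ref <- center
      alt <- ifelse(on_pyr, pyr_alt, complement_base(pyr_alt))
      ctx <- substring(seqchar[chrom], pos - 1, pos + 1)
      realized <- classify_context(ref, alt, ctx)
    }

    out <- snv_records(chrom, pos, ref, alt, sample = sample,
                       condition = condition, genome = genome)
    out$stratum <- if (n > 0) stratum else character(0)
    out$signature <- if (n > 0) colnames(refs)[sig_idx] else character(0)
    out$channel_drawn <- if (n > 0) channel else character(0)
    out$channel_realized <- if (n > 0) realized else character(0)
    attr(out, "n_fallback") <- n_fallback
    out
  })
}

# Default stratum mixtures over K reference columns: background of the
# first condition leans on column 1 (with some column 3); the second
# condition's background additionally activates the T-centred column 2
# ("irradiated"-like A-T enrichment); the SV-proximal mixture is shared
# and leans on the last column.
default_mixtures <- function(K) {
  stopifnot(K >= 2)
  unitize <- function(x) x / sum(x)
  bg_a <- numeric(K); bg_a[1] <- 0.7
  bg_b <- numeric(K); bg_b[1] <- 0.35; bg_b[2] <- 0.45
  near <- numeric(K); near[1] <- 0.4; near[K] <- 0.5
  if (K >= 3) {
    bg_a[3] <- 0.3; bg_b[3] <- 0.2; near[3] <- 0.1
  }
  list(
    background_a = unitize(bg_a),
    background_b = unitize(bg_b),
    near = unitize(near)
  )
}

#' Simulate a paired two-condition SV/SNV data set with ground truth
#'
#' One call produces everything the pipeline consumes: a genome (with
#' optional sequence), a shared hotspot table, per-condition SV breakends
#' drawn from the same hotspots, per-condition SNVs with an
#' SV-independent background and SV-proximal clusters, a reference
#' signature matrix, and a `simulation_truth` record of every parameter.
#' The second condition models an "irradiated"-like state: same SV count
#' and hotspot architecture, same per-SV clustered SNV rate, but a
#' background rate multiplied by `background_fold` and a background
#' signature mixture enriched in T-centred channels.
#'
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param n_chrom,chrom_length Genome shape (default 5 x 30 Mb).
#' @param with_sequence Generate sequence (default `TRUE`).
#' @param refs Reference signature matrix (default
#'   [synthetic_signatures()] with 4 columns).
#' @param n_sv SV events per condition (default 100).
#' @param b Background SNV rate of condition A in SNVs/Mb (default 2).
#' @param background_fold Background rate multiplier for condition B
#'   (default 2.8).
#' @param k Mean clustered SNVs per breakend (default 30).
#' @param cluster_width Proximal placement half-width in bp (default 5e5).
#' @param n_hotspots,hotspot_weight Hotspot architecture (default 10
#'   intervals, weight 0.5).
#' @param mixtures Optional list with elements `background_a`,
#'   `background_b`, `near` (proportions over `refs` columns).
#' @param conditions Two condition labels
#'   (default `c("unirradiated", "irradiated")`).
#' @return A list of class `simulation_bundle`: `genome`, `sequence`,
#'   `refs`, `hotspots`, `svs` (named list per condition), `snvs` (named
#'   list per condition), `truth` (a `simulation_truth`).
#' @export
simulate_dataset <- function(seed = 1, n_chrom = 5, chrom_length = 30e6,
                             with_sequence = TRUE, refs = NULL,
                             n_sv = 100, b = 2, background_fold = 2.8,
                             k = 30, cluster_width = 5e5,
                             n_hotspots = 10, hotspot_weight = 0.5,
                             mixtures = NULL,
                             conditions = c("unirradiated", "irradiated")) {
  if (length(conditions) != 2L) stopf("'conditions' must name two conditions")
  if (is.null(refs)) refs <- synthetic_signatures(seed = derive_seed(seed, 1))
  if (is.null(mixtures)) mixtures <- default_mixtures(ncol(refs))

  gen <- simulate_genome(n_chrom, chrom_length, seed = derive_seed(seed, 2),
                         with_sequence = with_sequence)
  hotspots <- simulate_hotspots(gen$genome, n_hotspots = n_hotspots,
                                seed = derive_seed(seed, 3))

  b_rates <- stats::setNames(c(b, b * background_fold), conditions)
  bg_mix <- stats::setNames(list(mixtures$background_a, mixtures$background_b),
                            conditions)

  svs <- list()
  snvs <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    svs[[cond]] <- simulate_svs(
      gen$genome, n_sv = n_sv, hotspots = hotspots,
      hotspot_weight = hotspot_weight,
      seed = derive_seed(seed, 10 + i), condition = cond
    )
    snvs[[cond]] <- simulate_snvs(
      gen$genome, svs[[cond]], refs,
      mixture_background = bg_mix[[cond]], mixture_near = mixtures$near,
      b = b_rates[[cond]], k = k, cluster_width = cluster_width,
      sequence = gen$sequence, seed = derive_seed(seed, 20 + i),
      condition = cond
    )
  }

  truth <- structure(
    list(
      seed = seed,
      genome = list(names = gen$genome$names,
                    lengths = unname(gen$genome$lengths)),
      hotspots = hotspots,
      hotspot_weight = hotspot_weight,
      n_sv = n_sv,
      b = unname(b_rates),
      background_fold = background_fold,
      k = k,
      cluster_width = cluster_width,
      mixtures = list(background_a = unname(mixtures$background_a),
                      background_b = unname(mixtures$background_b),
                      near = unname(mixtures$near)),
      signatures = colnames(refs),
      conditions = conditions
    ),
    class = "simulation_truth"
  )

  structure(
    list(genome = gen$genome, sequence = gen$sequence, refs = refs,
         hotspots = hotspots, svs = svs, snvs = snvs, truth = truth),
    class = "simulation_bundle"
  )
}

#' Write simulation ground truth as JSON
#' @param truth A `simulation_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read simulation ground truth written by [write_truth()]
#' @param path Path to the JSON file.
#' @return A `simulation_truth` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("seed", "genome", "hotspots", "hotspot_weight", "n_sv",
                "b", "background_fold", "k", "cluster_width", "mixtures",
                "conditions")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stopf("truth file %s is missing field(s): %s", path,
          paste(missing, collapse = ", "))
  }
  structure(x, class = "simulation_truth")
}

#' Write a simulation bundle to disk in standard formats
#'
#' Emits one VCF per condition, one BEDPE per condition, the genome FASTA
#' (when sequence was generated), a chrom-sizes table, the reference
#' signature matrix, and the truth JSON — everything the pipeline reads
#' back unchanged.
#'
#' @param bundle A `simulation_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (cond in names(bundle$snvs)) {
    p <- file.path(dir, paste0("snv_", cond, ".vcf"))
    write_snv_vcf(bundle$snvs[[cond]], p, genome = bundle$genome)
    paths[[paste0("snv_", cond)]] <- p
    p <- file.path(dir, paste0("sv_", cond, ".bedpe"))
    write_sv_bedpe(bundle$svs[[cond]], p)
    paths[[paste0("sv_", cond)]] <- p
  }
  sizes <- file.path(dir, "genome.chrom.sizes")
  writeLines(sprintf("%s\t%.0f", bundle$genome$names, bundle$genome$lengths),
             sizes)
  paths$chrom_sizes <- sizes
  if (!is.null(bundle$sequence)) {
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(bundle$sequence, fa)
    paths$fasta <- fa
  }
  refs_path <- file.path(dir, "signatures.tsv")
  write_signature_matrix(bundle$refs, refs_path)
  paths$signatures <- refs_path
  truth_path <- file.path(dir, "truth.json")
  write_truth(bundle$truth, truth_path)
  paths$truth <- truth_path
  invisible(paths)
}
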