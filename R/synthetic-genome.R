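#' Generate a random reference sequence set
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet] with one sequence per chromosome.
#' @export
generate_reference <- function(chrom_lengths, seed = 1L) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)),
            all(chrom_lengths >= 1))
  withr::with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs, names(chrom_lengths)))
  })
}

#' Generate a toy gene model with non-overlapping transcripts
#'
#' Places `n_genes` transcripts on the given chromosomes (allocated
#' proportionally to length) without overlap. Each transcript has 1-4 exons
#' (minimum exon 30 bp, minimum intron 20 bp), a strand, and a CDS spanning
#' part of the exonic sequence with 5'/3' UTR margins; total CDS length is
#' always a multiple of 3 and per-segment frame (phase) is annotated in
#' transcription order.
#'
#' @param n_genes number of transcripts (0 gives an empty model under which
#'   every variant classifies intergenic).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param seed integer seed.
#' @param tx_length_range allowed transcript lengths (bp).
#' @param exon_count_range allowed exon counts per transcript.
#' @return A `gene_model`: list with `transcripts` (GRanges, `tx_id` column),
#'   `exons` and `cds` (GRangesLists keyed by `tx_id`; CDS carries a `phase`
#'   column) and `chrom_lengths`.
#' @export
generate_gene_model <- function(n_genes, chrom_lengths, seed = 1L,
                                tx_length_range = c(300L, 2400L),
                                exon_count_range = c(1L, 4L)) {
  n_genes <- assert_positive_int(n_genes, "n_genes", allow_zero = TRUE)
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)),
            all(chrom_lengths >= 1))
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))

  if (n_genes == 0L) {
    return(empty_gene_model(chrom_lengths))
  }
  if (min(tx_length_range) > max(chrom_lengths)) {
    stop("invalid config: gene longer than its chromosome", call. = FALSE)
  }

  withr::with_seed(seed, {
    # Allocate genes to chromosomes proportionally to length.
    alloc <- as.vector(stats::rmultinom(1, n_genes, chrom_lengths / sum(chrom_lengths)))
    names(alloc) <- names(chrom_lengths)

    tx_rows <- list(); exon_l <- list(); cds_l <- list()
    tx_i <- 0L
    for (chrom in names(chrom_lengths)) {
      nc <- alloc[[chrom]]
      if (nc == 0L) next
      L <- chrom_lengths[[chrom]]
      slot <- L %/% nc
      max_tx <- min(max(tx_length_range), slot - 50L)
      if (max_tx < min(tx_length_range)) {
        stop("invalid config: gene longer than its chromosome slot", call. = FALSE)
      }
      for (j in seq_len(nc)) {
        tx_i <- tx_i + 1L
        tx_id <- sprintf("tx%03d", tx_i)
        tx_len <- draw1(seq(min(tx_length_range), max_tx))
        start <- (j - 1L) * slot + sample.int(slot - tx_len, 1L)
        strand <- draw1(c("+", "-"))

        st <- transcript_structure(tx_len, draw1(seq(exon_count_range[1], exon_count_range[2])))
        exon_start <- start + st$exon_offsets
        exon_end <- exon_start + st$exon_lens - 1L
        cds <- cds_from_exons(exon_start, exon_end, strand)

        tx_rows[[tx_i]] <- data.frame(chrom = chrom, start = start,
                                      end = start + tx_len - 1L,
                                      strand = strand, tx_id = tx_id,
                                      stringsAsFactors = FALSE)
        exon_l[[tx_id]] <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(exon_start, exon_end), strand = strand)
        cds_gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(cds$start, cds$end), strand = strand)
        S4Vectors::mcols(cds_gr)$phase <- cds$phase
        cds_l[[tx_id]] <- cds_gr
      }
    }
    txd <- do.call(rbind, tx_rows)
    transcripts <- GenomicRanges::GRanges(txd$chrom,
      IRanges::IRanges(txd$start, txd$end), strand = txd$strand)
    S4Vectors::mcols(transcripts)$tx_id <- txd$tx_id
    GenomeInfoDb_set_lengths(transcripts, chrom_lengths)

    structure(list(
      transcripts = transcripts,
      exons = GenomicRanges::GRangesList(exon_l),
      cds = GenomicRanges::GRangesList(cds_l),
      chrom_lengths = chrom_lengths
    ), class = "gene_model")
  })
}

empty_gene_model <- function(chrom_lengths) {
  structure(list(
    transcripts = GenomicRanges::GRanges(),
    exons = GenomicRanges::GRangesList(),
    cds = GenomicRanges::GRangesList(),
    chrom_lengths = stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  ), class = "gene_model")
}

# seqlengths assignment is cosmetic here; classification validates manually.
GenomeInfoDb_set_lengths <- function(gr, chrom_lengths) invisible(gr)

# Split a transcript of length L into k exons (>=30 bp) separated by
# introns (>=20 bp), spanning [0, L) exactly.
transcript_structure <- function(L, k) {
  while (k > 1L && L < 30L * k + 20L * (k - 1L)) k <- k - 1L
  base <- c(rep(30L, k), rep(20L, k - 1L))          # exon1..k, intron1..k-1
  extra <- L - sum(base)
  add <- if (extra > 0) as.vector(stats::rmultinom(1, extra, rep(1, 2L * k - 1L))) else rep(0L, 2L * k - 1L)
  lens <- base + add
  exon_lens <- lens[seq_len(k)]
  intron_lens <- if (k > 1L) lens[k + seq_len(k - 1L)] else integer(0)
  offsets <- cumsum(c(0L, head(exon_lens, -1L) + intron_lens))
  list(exon_lens = exon_lens, exon_offsets = offsets)
}

# Carve a CDS out of exon ranges, leaving UTR margins, with total length a
# multiple of 3; returns genomic start/end per segment + phase in
# transcription order.
cds_from_exons <- function(exon_start, exon_end, strand) {
  lens <- exon_end - exon_start + 1L
  E <- sum(lens)
  utr5 <- draw1(0:min(12L, E - 30L))
  utr3 <- draw1(0:min(12L, E - 30L - utr5))
  cds_len <- E - utr5 - utr3
  cds_len <- cds_len - (cds_len %% 3L)
  stopifnot(cds_len >= 3L)

  # Interval in exonic coordinates ordered genomically (1..E).
  if (strand == "+") { a <- utr5 + 1L; b <- utr5 + cds_len } else {
    a <- E - utr5 - cds_len + 1L; b <- E - utr5
  }
  cum <- cumsum(lens)
  seg_start <- integer(0); seg_end <- integer(0)
  for (i in seq_along(lens)) {
    lo <- cum[i] - lens[i] + 1L; hi <- cum[i]
    s <- max(a, lo); e <- min(b, hi)
    if (s <= e) {
      seg_start <- c(seg_start, exon_start[i] + (s - lo))
      seg_end <- c(seg_end, exon_start[i] + (e - lo))
    }
  }
  seg_lens <- seg_end - seg_start + 1L
  # Phase: number of bases of the next codon carried over, in transcription order.
  ord <- if (strand == "+") seq_along(seg_lens) else rev(seq_along(seg_lens))
  before <- cumsum(c(0L, seg_lens[ord][-length(seg_lens)]))
  phase_tx <- (3L - before %% 3L) %% 3L
  phase <- integer(length(seg_lens)); phase[ord] <- phase_tx
  list(start = seg_start, end = seg_end, phase = phase)
}

#' Draw random exonic (CDS) single-nucleotide variants
#'
#' Samples positions uniformly over the coding bases of a gene model, takes
#' the reference base at each position and a random alternate base.
#'
#' @param model a `gene_model` with at least one CDS.
#' @param reference a `DNAStringSet` covering the model's chromosomes.
#' @param n number of variants.
#' @param seed integer seed.
#' @return A data frame `chrom`, `pos`, `ref`, `alt`, `depth`.
#' @export
random_exonic_snvs <- function(model, reference, n, seed = 1L) {
  stopifnot(inherits(model, "gene_model"), length(model$cds) > 0)
  cds <- unlist(model$cds, use.names = FALSE)
  w <- GenomicRanges::width(cds)
  withr::with_seed(seed, {
    seg <- sample.int(length(cds), n, replace = TRUE, prob = w)
    off <- floor(runif(n) * w[seg])
    pos <- GenomicRanges::start(cds)[seg] + as.integer(off)
    chrom <- as.character(GenomicRanges::seqnames(cds))[seg]
    ref <- vapply(seq_len(n), function(i) {
      as.character(Biostrings::subseq(reference[[chrom[i]]], pos[i], pos[i]))
    }, character(1))
    alt <- vapply(ref, function(r) draw1(setdiff(c("A", "C", "G", "T"), r)),
                  character(1), USE.NAMES = FALSE)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, depth = 50L,
               stringsAsFactors = FALSE)
  })
}
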