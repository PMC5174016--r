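## Consensus host SNP calling and genomic annotation.

validate_variant_calls <- function(calls, name = "calls") {
  stopifnot(is.data.frame(calls))
  need <- c("chrom", "pos", "ref", "alt", "depth")
  if (!all(need %in% names(calls))) {
    stop(sprintf("`%s` must have columns %s", name, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(calls) == 0) return(invisible(calls))
  bases <- c("A", "C", "G", "T")
  if (!all(calls$ref %in% bases) || !all(calls$alt %in% bases)) {
    stop(sprintf("`%s` alleles must be single bases A/C/G/T (SNVs only)", name),
         call. = FALSE)
  }
  if (any(calls$ref == calls$alt)) stop(sprintf("`%s` has ref == alt", name), call. = FALSE)
  key <- paste(calls$chrom, calls$pos, calls$alt)
  if (anyDuplicated(key)) {
    stop(sprintf("`%s` has duplicate (chrom, pos, alt) records", name), call. = FALSE)
  }
  invisible(calls)
}

#' Intersect two variant callsets into consensus calls
#'
#' The final variant calls are the exact intersection of the two callers'
#' outputs on `(chrom, pos, ref, alt)`; the consensus depth is the minimum
#' of the two callers' depths at the site (a conservative summary, since
#' the source depth field is caller-specific). Sites where the two callers
#' disagree on the reference allele are excluded with a warning.
#'
#' @param calls_a,calls_b data frames with `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `depth`; single-base alleles only, `(chrom, pos, alt)` unique
#'   within each set.
#' @return A `consensus_variants` data frame (`chrom`, `pos`, `ref`, `alt`,
#'   `depth`), sorted by `(chrom, pos)`, with attribute
#'   `ref_mismatch_count`.
#' @export
intersect_call_sets <- function(calls_a, calls_b) {
  validate_variant_calls(calls_a, "calls_a")
  validate_variant_calls(calls_b, "calls_b")
  ka <- paste(calls_a$chrom, calls_a$pos, calls_a$ref, calls_a$alt)
  kb <- paste(calls_b$chrom, calls_b$pos, calls_b$ref, calls_b$alt)

  # Positions shared but with discordant reference alleles.
  pa <- paste(calls_a$chrom, calls_a$pos)
  pb <- paste(calls_b$chrom, calls_b$pos)
  shared_pos <- intersect(pa, pb)
  mism <- 0L
  if (length(shared_pos) > 0) {
    ra <- calls_a$ref[match(shared_pos, pa)]
    rb <- calls_b$ref[match(shared_pos, pb)]
    mism <- sum(ra != rb)
    if (mism > 0) {
      warning(sprintf("%d site(s) excluded: callers disagree on the reference allele", mism))
    }
  }

  ia <- match(intersect(ka, kb), ka)
  ib <- match(ka[ia], kb)
  out <- calls_a[ia, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$depth <- pmin(calls_a$depth[ia], calls_b$depth[ib])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("consensus_variants", "data.frame"),
            ref_mismatch_count = mism)
}

#' Filter consensus variants by minimal read depth
#'
#' Retains variants whose depth is at least `min_depth` (inclusive: a
#' minimal depth of 30 keeps a site at exactly 30x).
#'
#' @param calls consensus variant data frame with a `depth` column.
#' @param min_depth non-negative integer (default 30).
#' @return The filtered subset, same columns and ordering.
#' @export
filter_min_depth <- function(calls, min_depth = 30L) {
  stopifnot(is.data.frame(calls), "depth" %in% names(calls))
  min_depth <- assert_positive_int(min_depth, "min_depth", allow_zero = TRUE)
  if (nrow(calls) > 0 && any(calls$depth < 0)) {
    stop("negative depth in input", call. = FALSE)
  }
  calls[calls$depth >= min_depth, , drop = FALSE]
}

# Annotation tracks derived once from a gene model.
model_tracks <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  tx <- model$transcripts
  if (length(tx) == 0) {
    empty <- GenomicRanges::GRanges()
    return(list(tx = empty, cds = empty, utr = empty, splice = empty))
  }
  exons <- unlist(model$exons, use.names = FALSE)
  cds <- unlist(model$cds, use.names = FALSE)
  utr <- GenomicRanges::setdiff(exons, cds, ignore.strand = TRUE)
  introns <- GenomicRanges::setdiff(tx, exons, ignore.strand = TRUE)
  # Splice region: the first/last 2 bp of each intron.
  sl <- GenomicRanges::resize(introns, width = pmin(GenomicRanges::width(introns), 2L),
                              fix = "start")
  sr <- GenomicRanges::resize(introns, width = pmin(GenomicRanges::width(introns), 2L),
                              fix = "end")
  list(tx = tx, cds = cds, utr = utr, splice = c(sl, sr))
}

#' Classify variants by genomic region
#'
#' Assigns each variant exactly one region class with precedence
#' `exonic > splicing > UTR > intronic > intergenic`: exonic means inside a
#' coding (CDS) exon, splicing means within the 2 bp of an intron adjoining
#' an exon boundary, UTR is exonic-non-coding sequence, intronic is inside
#' a transcript but outside exons, and everything else is intergenic.
#'
#' @param calls variant data frame with `chrom`, `pos`.
#' @param model a `gene_model`; every variant chromosome must be in
#'   `model$chrom_lengths` and `pos` within the chromosome length.
#' @return Character vector of region classes, one per variant.
#' @export
classify_region <- function(calls, model) {
  stopifnot(is.data.frame(calls), inherits(model, "gene_model"))
  if (nrow(calls) == 0) return(character(0))
  bad_chrom <- setdiff(unique(calls$chrom), names(model$chrom_lengths))
  if (length(bad_chrom) > 0) {
    stop(sprintf("variant chromosome(s) absent from model: %s",
                 paste(bad_chrom, collapse = ", ")), call. = FALSE)
  }
  lens <- model$chrom_lengths[calls$chrom]
  if (any(calls$pos < 1 | calls$pos > lens)) {
    stop("variant position outside chromosome length", call. = FALSE)
  }
  v <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))
  tr <- model_tracks(model)
  hits <- function(track) {
    GenomicRanges::countOverlaps(v, track, ignore.strand = TRUE) > 0
  }
  cls <- rep("intergenic", nrow(calls))
  cls[hits(tr$tx)] <- "intronic"
  cls[hits(tr$utr)] <- "UTR"
  cls[hits(tr$splice)] <- "splicing"
  cls[hits(tr$cds)] <- "exonic"
  cls
}

#' Classify the coding effect of exonic variants
#'
#' Resolves each variant's codon from the CDS frame of the transcript it
#' falls in, substitutes the alternate allele (reverse-complemented for
#' minus-strand genes) and translates reference versus alternate codon with
#' the standard genetic code.
#'
#' @param calls variant data frame (`chrom`, `pos`, `ref`, `alt`); every
#'   variant must lie inside a CDS (classify with [classify_region()]
#'   first), otherwise an error is raised.
#' @param model a `gene_model`.
#' @param reference `DNAStringSet` covering the model's chromosomes.
#' @return Character vector over
#'   `{"synonymous", "nonsynonymous", "stopgain", "stoploss"}`.
#' @export
classify_coding_effect <- function(calls, model, reference) {
  stopifnot(is.data.frame(calls), inherits(model, "gene_model"))
  if (nrow(calls) == 0) return(character(0))
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  cds_tx <- lapply(names(model$cds), function(tx_id) model$cds[[tx_id]])
  names(cds_tx) <- names(model$cds)
  tx_strand <- vapply(cds_tx, function(g) as.character(GenomicRanges::strand(g))[1],
                      character(1))
  tx_chrom <- vapply(cds_tx, function(g) as.character(GenomicRanges::seqnames(g))[1],
                     character(1))

  vapply(seq_len(nrow(calls)), function(i) {
    chrom <- calls$chrom[i]; pos <- calls$pos[i]
    hit_tx <- NULL
    for (tx_id in names(cds_tx)) {
      g <- cds_tx[[tx_id]]
      if (tx_chrom[[tx_id]] == chrom &&
          any(pos >= GenomicRanges::start(g) & pos <= GenomicRanges::end(g))) {
        hit_tx <- tx_id; break
      }
    }
    if (is.null(hit_tx)) {
      stop(sprintf("variant %s:%d is not exonic (no CDS overlap)", chrom, pos),
           call. = FALSE)
    }
    g <- cds_tx[[hit_tx]]
    strand <- tx_strand[[hit_tx]]
    starts <- GenomicRanges::start(g); ends <- GenomicRanges::end(g)
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    lens <- ends - starts + 1L
    cum <- cumsum(lens)
    seg <- which(pos >= starts & pos <= ends)
    # Position within the spliced CDS, in genomic (plus-strand) order.
    cds_pos_fwd <- (if (seg > 1) cum[seg - 1L] else 0L) + (pos - starts[seg] + 1L)
    total <- sum(lens)
    cds_pos <- if (strand == "+") cds_pos_fwd else total - cds_pos_fwd + 1L

    # Spliced CDS sequence in transcription order.
    seq_fwd <- paste(vapply(seq_along(starts), function(j) {
      as.character(Biostrings::subseq(reference[[chrom]], starts[j], ends[j]))
    }, character(1)), collapse = "")
    cds_seq <- if (strand == "+") seq_fwd else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
    }

    codon_i <- (cds_pos - 1L) %/% 3L
    off <- (cds_pos - 1L) %% 3L + 1L
    ref_codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_base <- if (strand == "+") calls$alt[i] else comp[[calls$alt[i]]]
    ref_base <- if (strand == "+") calls$ref[i] else comp[[calls$ref[i]]]
    if (substr(ref_codon, off, off) != ref_base) {
      stop(sprintf("reference allele mismatch at %s:%d", chrom, pos), call. = FALSE)
    }
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt_base
    aa_ref <- code[[ref_codon]]
    aa_alt <- code[[alt_codon]]
    if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stopgain"
    else if (aa_ref == "*") "stoploss"
    else "nonsynonymous"
  }, character(1))
}

#' Distribution of variants over genomic region classes
#'
#' @param calls variant data frame.
#' @param model a `gene_model`.
#' @return Named numeric vector of fractions over the five classes
#'   (`exonic`, `splicing`, `UTR`, `intronic`, `intergenic`), summing to 1;
#'   all `NA` with attribute `undefined = TRUE` for an empty call list.
#' @export
region_distribution <- function(calls, model) {
  classes <- c("exonic", "splicing", "UTR", "intronic", "intergenic")
  if (nrow(calls) == 0) {
    out <- stats::setNames(rep(NA_real_, 5), classes)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cls <- classify_region(calls, model)
  tab <- table(factor(cls, levels = classes))
  stats::setNames(as.numeric(tab) / nrow(calls), classes)
}

#' Per-chromosome SNP density and uniformity statistic
#'
#' Density is SNPs per megabase per chromosome. Uniformity is the
#' chi-square statistic of observed per-chromosome counts against a
#' length-proportional expectation, with `k - 1` degrees of freedom.
#'
#' @param calls variant data frame with `chrom`.
#' @param chrom_lengths named positive lengths (bp); every variant
#'   chromosome must be present.
#' @return List with `density` (data frame: `chrom`, `n`, `length_bp`,
#'   `snps_per_mb`), `chisq`, `df` and `undefined` (`TRUE` when fewer than
#'   two chromosomes make the statistic meaningless).
#' @export
chromosome_density <- function(calls, chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  bad <- setdiff(unique(calls$chrom), names(chrom_lengths))
  if (length(bad) > 0) {
    stop(sprintf("variant chromosome(s) absent from lengths: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  counts <- table(factor(calls$chrom, levels = names(chrom_lengths)))
  n <- sum(counts)
  k <- length(chrom_lengths)
  density <- data.frame(
    chrom = names(chrom_lengths),
    n = as.integer(counts),
    length_bp = as.numeric(chrom_lengths),
    snps_per_mb = as.numeric(counts) / (as.numeric(chrom_lengths) / 1e6),
    stringsAsFactors = FALSE
  )
  if (k < 2 || n == 0) {
    return(list(density = density, chisq = NA_real_, df = max(0L, k - 1L),
                undefined = TRUE))
  }
  expected <- n * as.numeric(chrom_lengths) / sum(as.numeric(chrom_lengths))
  chisq <- sum((as.numeric(counts) - expected)^2 / expected)
  list(density = density, chisq = chisq, df = k - 1L, undefined = FALSE)
}

#' Count transcripts containing at least one variant
#'
#' @param calls variant data frame with `chrom`, `pos`.
#' @param model a `gene_model`.
#' @return Integer count; each transcript counted once regardless of how
#'   many variants fall in it.
#' @export
genes_with_snps <- function(calls, model) {
  stopifnot(inherits(model, "gene_model"))
  if (nrow(calls) == 0 || length(model$transcripts) == 0) return(0L)
  v <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))
  sum(GenomicRanges::countOverlaps(model$transcripts, v, ignore.strand = TRUE) > 0)
}
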