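# Shared in-code fixtures; everything deterministic under explicit seeds.

# A function_profile directly from a named count vector (bypasses records).
profile_from_counts <- function(sample_id, level, counts) {
  counts <- counts[order(names(counts))]
  structure(
    list(sample_id = sample_id, level = as.integer(level),
         counts = counts, rel_abundance = counts / sum(counts),
         unknown_fraction = 0, total_known = sum(counts)),
    class = "function_profile"
  )
}

# Gene records over a tiny fixed 4-level hierarchy: two h1 roots, functions
# named by their full path for readability.
tiny_hierarchy <- function() generate_function_catalog(c(2, 3, 4, 8), seed = 99)

records_from <- function(hierarchy, fun, count, genome_id = NA_character_,
                         sample_id = "S1") {
  idx <- match(fun, hierarchy$paths$fun)
  data.frame(
    gene_id = sprintf("g%03d", seq_along(fun)),
    genome_id = genome_id,
    h1 = hierarchy$paths$h1[idx],
    h2 = hierarchy$paths$h2[idx],
    h3 = hierarchy$paths$h3[idx],
    fun = fun,
    sample_id = sample_id,
    count = as.integer(count),
    stringsAsFactors = FALSE
  )
}

# Hand-built single-transcript gene model on a hand-written chromosome,
# used for codon-level coding-effect checks.
# chrom "c1": 60 bp; CDS = positions 11..28 (+ strand) spelling
#   ATG GGA TAC CCT GAA TAA  (M G Y P E *)
hand_gene_model <- function(strand = "+") {
  pre <- "GGGGGGGGGG"                   # 1..10
  cds <- "ATGGGATACCCTGAATAA"           # 11..28
  post <- paste(rep("G", 32), collapse = "")
  seq <- paste0(pre, cds, post)
  if (strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    # after reverse complement the CDS occupies 60-28+1 .. 60-11+1 = 33..50
    cds_start <- 33L; cds_end <- 50L
  } else {
    cds_start <- 11L; cds_end <- 28L
  }
  ref <- Biostrings::DNAStringSet(c(c1 = seq))
  tx <- GenomicRanges::GRanges("c1", IRanges::IRanges(cds_start - 5L, cds_end + 5L),
                               strand = strand)
  S4Vectors::mcols(tx)$tx_id <- "tx001"
  cds_gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(cds_start, cds_end),
                                   strand = strand)
  S4Vectors::mcols(cds_gr)$phase <- 0L
  exon_gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(cds_start - 5L, cds_end + 5L),
                                    strand = strand)
  model <- structure(list(
    transcripts = tx,
    exons = GenomicRanges::GRangesList(tx001 = exon_gr),
    cds = GenomicRanges::GRangesList(tx001 = cds_gr),
    chrom_lengths = c(c1 = 60L)
  ), class = "gene_model")
  list(model = model, reference = ref, cds_start = cds_start, cds_end = cds_end)
}

# Full-CDS translation oracle: apply the variant to the genome, extract and
# translate the whole CDS of the containing transcript, compare proteins.
oracle_coding_effect <- function(v, model, reference) {
  hit <- NULL
  for (tx_id in names(model$cds)) {
    g <- model$cds[[tx_id]]
    if (as.character(GenomicRanges::seqnames(g))[1] == v$chrom &&
        any(v$pos >= GenomicRanges::start(g) & v$pos <= GenomicRanges::end(g))) {
      hit <- tx_id; break
    }
  }
  stopifnot(!is.null(hit))
  g <- model$cds[[hit]]
  strand <- as.character(GenomicRanges::strand(g))[1]
  ord <- order(GenomicRanges::start(g))
  extract <- function(ref_set) {
    pieces <- vapply(ord, function(j) {
      as.character(Biostrings::subseq(ref_set[[v$chrom]],
                                      GenomicRanges::start(g)[j],
                                      GenomicRanges::end(g)[j]))
    }, character(1))
    s <- paste(pieces, collapse = "")
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }
  mutated <- reference
  chrom_seq <- as.character(mutated[[v$chrom]])
  stopifnot(substr(chrom_seq, v$pos, v$pos) == v$ref)
  substr(chrom_seq, v$pos, v$pos) <- v$alt
  mutated_set <- Biostrings::DNAStringSet(stats::setNames(chrom_seq, v$chrom))

  # no.init.codon: score the first codon by the standard code, not as an
  # alternative initiator, matching codon-table semantics
  p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(extract(reference)),
                                              no.init.codon = TRUE))
  p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(extract(mutated_set)),
                                              no.init.codon = TRUE))
  diff <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(diff) == 0) return("synonymous")
  aa_ref <- substr(p_ref, diff[1], diff[1])
  aa_alt <- substr(p_alt, diff[1], diff[1])
  if (aa_alt == "*") "stopgain" else if (aa_ref == "*") "stoploss" else "nonsynonymous"
}

# Brute-force Spearman: average ranks by counting, Pearson by sums.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  if (den == 0) 0 else num / den
}
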