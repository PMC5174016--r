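## Readers and writers for the pipeline's standard formats.
## Coordinate conventions: VCF and GFF3 are 1-based inclusive, BED is
## 0-based half-open; all conversions are delegated to the Bioconductor
## importers/exporters used here, so package code only ever sees 1-based
## coordinates.

#' Write / read a paired-read alignment table (TSV)
#'
#' Five-column TSV: `read_id`, `mapq1`, `mapq2`, `target` and, optionally,
#' `truth` (the simulated origin label).
#'
#' @param alignments data frame from [simulate_read_pairs()] (or any with
#'   the first four columns).
#' @param path output file.
#' @param truth optional truth data frame (`read_id`, `origin`) merged in
#'   as a `truth` column.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path, truth = NULL) {
  out <- alignments
  if (!is.null(truth)) {
    out$truth <- truth$origin[match(out$read_id, truth$read_id)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_tsv
#' @export
read_alignment_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character"))
}

#' Read paired alignments from a SAM file
#'
#' Matches paired records by QNAME and returns one row per pair with the
#' two mates' mapping qualities. An unmapped or absent mate is encoded as
#' MAPQ 0, which fails the both-mates partition rule.
#'
#' @param path SAM (or BAM) file of reads aligned to the host genome.
#' @return Data frame `read_id`, `mapq1`, `mapq2`, `target = NA`.
#' @export
read_alignment_sam <- function(path) {
  bam <- if (grepl("\\.sam$", path)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("qname", "mapq", "flag")))[[1]]
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 0L
  unmapped <- bitwAnd(res$flag, 4L) > 0
  mapq[unmapped] <- 0L
  first <- bitwAnd(res$flag, 64L) > 0
  ids <- unique(res$qname)
  m1 <- stats::setNames(rep(0L, length(ids)), ids)
  m2 <- m1
  m1[res$qname[first]] <- mapq[first]
  m2[res$qname[!first]] <- mapq[!first]
  data.frame(read_id = ids, mapq1 = as.integer(m1[ids]), mapq2 = as.integer(m2[ids]),
             target = NA_character_, stringsAsFactors = FALSE)
}

#' Write / read a gene catalog table (TSV)
#'
#' Columns: `gene_id`, `genome_id`, `h1`, `h2`, `h3`, `function`,
#' `sample_id`, `count` — the layout of a subsystem-annotation export.
#' Unknown-function records carry empty path fields.
#'
#' @param records gene-record data frame (internal column `fun` maps to the
#'   file column `function`).
#' @param path file path.
#' @return `path` (writer) / the records data frame (reader).
#' @export
write_gene_catalog <- function(records, path) {
  out <- records[, c("gene_id", "genome_id", "h1", "h2", "h3", "fun", "sample_id", "count")]
  names(out)[names(out) == "fun"] <- "function"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_gene_catalog
#' @export
read_gene_catalog <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                         check.names = FALSE)
  names(d)[names(d) == "function"] <- "fun"
  d$genome_id <- as.character(d$genome_id)
  d
}

#' Write / read a per-genome mapped-read count table (TSV)
#'
#' @param counts named numeric vector (genome id -> mapped reads).
#' @param path file path.
#' @export
write_genome_read_counts <- function(counts, path) {
  utils::write.table(
    data.frame(genome_id = names(counts), reads = as.numeric(counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_read_counts
#' @export
read_genome_read_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$reads, d$genome_id)
}

#' Write / read SNV calls as VCF
#'
#' Uses the standard Bioconductor VCF writer; depth is carried in the `DP`
#' genotype field of a single synthetic sample column.
#'
#' @param calls data frame `chrom`, `pos`, `ref`, `alt`, `depth`.
#' @param path `.vcf` file path.
#' @param sample_name VCF sample column name.
#' @return `path` (writer) / a calls data frame (reader).
#' @export
write_variants_vcf <- function(calls, path, sample_name = "S1") {
  if (nrow(calls) == 0) {
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), path)
    return(invisible(path))
  }
  vr <- VariantAnnotation::VRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(calls$pos, width = 1L),
    ref = calls$ref, alt = calls$alt,
    totalDepth = as.integer(calls$depth),
    sampleNames = rep(sample_name, nrow(calls))
  )
  VariantAnnotation::writeVcf(vr, path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path) {
  if (all(startsWith(readLines(path), "#"))) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  }
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- as.character(unlist(VariantAnnotation::alt(v)))
  depth <- if ("DP" %in% names(VariantAnnotation::geno(v))) {
    as.integer(VariantAnnotation::geno(v)$DP[, 1])
  } else rep(NA_integer_, length(rr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt,
    depth = depth,
    stringsAsFactors = FALSE
  )
}

#' Write a gene model as GFF3 and BED12
#'
#' GFF3 carries gene/mRNA/exon/CDS features with CDS phase; BED12 encodes
#' each transcript with its exon blocks and CDS (thick) span.
#'
#' @param model a `gene_model`.
#' @param gff3_path,bed12_path output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_gene_model <- function(model, gff3_path = NULL, bed12_path = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (!is.null(gff3_path)) {
    rows <- list()
    for (tx_id in names(model$exons)) {
      tx <- model$transcripts[S4Vectors::mcols(model$transcripts)$tx_id == tx_id]
      add <- function(gr, type, id, parent, phase = NA_integer_) {
        g <- gr
        S4Vectors::mcols(g) <- NULL
        S4Vectors::mcols(g)$type <- type
        S4Vectors::mcols(g)$ID <- id
        S4Vectors::mcols(g)$Parent <- parent
        S4Vectors::mcols(g)$phase <- phase
        g
      }
      ex <- model$exons[[tx_id]]
      cds <- model$cds[[tx_id]]
      rows[[length(rows) + 1L]] <- add(tx, "gene", paste0(tx_id, ".g"), NA_character_)
      rows[[length(rows) + 1L]] <- add(tx, "mRNA", tx_id, paste0(tx_id, ".g"))
      rows[[length(rows) + 1L]] <- add(ex, "exon",
        sprintf("%s.e%d", tx_id, seq_along(ex)), rep(tx_id, length(ex)))
      rows[[length(rows) + 1L]] <- add(cds,
        "CDS", sprintf("%s.c%d", tx_id, seq_along(cds)), rep(tx_id, length(cds)),
        phase = S4Vectors::mcols(model$cds[[tx_id]])$phase)
    }
    all <- if (length(rows) > 0) do.call(c, rows) else GenomicRanges::GRanges()
    rtracklayer::export.gff3(all, gff3_path)
  }
  if (!is.null(bed12_path)) {
    if (length(model$exons) > 0) {
      bed <- rtracklayer::asBED(model$exons)
      rtracklayer::export(bed, bed12_path, format = "bed")
    } else {
      writeLines(character(0), bed12_path)
    }
  }
  invisible(list(gff3 = gff3_path, bed12 = bed12_path))
}

#' Read a gene model from GFF3
#'
#' Inverse of [write_gene_model()]: rebuilds transcripts, exons and CDS
#' (with phase) from mRNA/exon/CDS features keyed by `Parent`.
#'
#' @param path GFF3 file.
#' @param chrom_lengths named chromosome lengths (bp); kept alongside the
#'   ranges because GFF3 carries no sequence sizes.
#' @return A `gene_model`.
#' @export
read_gene_model_gff3 <- function(path, chrom_lengths) {
  g <- rtracklayer::import.gff3(path)
  mrna <- g[g$type == "mRNA"]
  if (length(mrna) == 0) return(empty_gene_model(chrom_lengths))
  tx_ids <- as.character(mrna$ID)
  transcripts <- GenomicRanges::granges(mrna)
  S4Vectors::mcols(transcripts)$tx_id <- tx_ids

  parent_of <- function(sub) as.character(unlist(sub$Parent))
  ex <- g[g$type == "exon"]
  cds <- g[g$type == "CDS"]
  exon_l <- lapply(tx_ids, function(id) {
    GenomicRanges::granges(ex[parent_of(ex) == id])
  })
  names(exon_l) <- tx_ids
  cds_l <- lapply(tx_ids, function(id) {
    sub <- cds[parent_of(cds) == id]
    out <- GenomicRanges::granges(sub)
    S4Vectors::mcols(out)$phase <- as.integer(sub$phase)
    out
  })
  names(cds_l) <- tx_ids

  structure(list(
    transcripts = transcripts,
    exons = GenomicRanges::GRangesList(exon_l),
    cds = GenomicRanges::GRangesList(cds_l),
    chrom_lengths = stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  ), class = "gene_model")
}

#' Write / read a reference FASTA
#'
#' @param reference `DNAStringSet`.
#' @param path `.fa` path.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a categories-by-samples profile matrix as TSV
#'
#' @param profiles list of `function_profile`s at one level.
#' @param path file path.
#' @param what `"rel_abundance"` or `"counts"`.
#' @export
write_profile_matrix <- function(profiles, path, what = c("rel_abundance", "counts")) {
  what <- match.arg(what)
  m <- if (what == "rel_abundance") profile_matrix(profiles) else {
    cats <- sort(Reduce(union, lapply(profiles, function(p) names(p$counts))))
    mm <- t(vapply(profiles, function(p) {
      v <- p$counts[cats]; v[is.na(v)] <- 0; as.numeric(v)
    }, numeric(length(cats))))
    rownames(mm) <- vapply(profiles, function(p) p$sample_id, character(1))
    colnames(mm) <- cats
    mm
  }
  out <- data.frame(category = colnames(m), t(m), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a flat key=value configuration file
#'
#' Lines are `key=value`; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return Named character vector of settings.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- lines[!grepl("=", lines, fixed = TRUE)]
  if (length(bad) > 0) {
    stop(sprintf("malformed config line(s) in %s: %s", path,
                 paste(bad, collapse = "; ")), call. = FALSE)
  }
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  stats::setNames(trimws(vapply(kv, `[`, character(1), 2)),
                  trimws(vapply(kv, `[`, character(1), 1)))
}

#' @rdname read_config
#' @param settings named character vector.
#' @export
write_config <- function(settings, path) {
  writeLines(paste0(names(settings), "=", unname(settings)), path)
  invisible(path)
}
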