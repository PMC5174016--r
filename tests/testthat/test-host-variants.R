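mkcalls <- function(chrom, pos, ref, alt, depth = 50L) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
             depth = rep_len(as.integer(depth), length(pos)),
             stringsAsFactors = FALSE)
}

test_that("consensus is the allele-aware exact intersection with min depth", {
  a <- mkcalls(c("chr1", "chr2"), c(100, 50), c("A", "C"), c("G", "T"), c(40, 35))
  b <- mkcalls("chr1", 100, "A", "G", 33)
  cons <- intersect_call_sets(a, b)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$pos, 100)
  expect_equal(cons$depth, 33)  # min of 40 and 33
  # same position, different alt alleles -> not consensus
  a2 <- mkcalls("chr1", 100, "A", "G")
  b2 <- mkcalls("chr1", 100, "A", "T")
  expect_equal(nrow(intersect_call_sets(a2, b2)), 0)
  # ref mismatch at a shared position -> warning + exclusion with count
  a3 <- mkcalls("chr1", 100, "A", "G")
  b3 <- mkcalls("chr1", 100, "C", "G")
  expect_warning(cons3 <- intersect_call_sets(a3, b3), "reference allele")
  expect_equal(nrow(cons3), 0)
  expect_equal(attr(cons3, "ref_mismatch_count"), 1L)
})

test_that("consensus properties hold and match a quadratic nested-loop oracle", {
  withr::with_seed(17, {
    rand_calls <- function(n) {
      mkcalls(sample(c("chr1", "chr2"), n, replace = TRUE),
              sample(1:400, n),  # positions unique within a callset
              "A", sample(c("C", "G", "T"), n, replace = TRUE),
              sample(10:80, n, replace = TRUE))
    }
    for (i in 1:3) {
      a <- rand_calls(300); b <- rand_calls(300)
      cons <- intersect_call_sets(a, b)
      # brute force: nested loop over all pairs
      hits <- 0L
      for (j in seq_len(nrow(a))) {
        match_b <- b$chrom == a$chrom[j] & b$pos == a$pos[j] &
          b$ref == a$ref[j] & b$alt == a$alt[j]
        hits <- hits + as.integer(any(match_b))
      }
      expect_equal(nrow(cons), hits)
      expect_lte(nrow(cons), min(nrow(a), nrow(b)))
      key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
      expect_true(all(key(cons) %in% key(a)) && all(key(cons) %in% key(b)))
      expect_false(is.unsorted(cons$pos[cons$chrom == "chr1"]))
    }
  })
})

test_that("depth filter is inclusive at the threshold", {
  calls <- mkcalls("chr1", 1:3, "A", "G", c(29, 30, 31))
  kept <- filter_min_depth(calls, 30)
  expect_equal(kept$depth, c(30, 31))
  expect_equal(nrow(filter_min_depth(calls, 0)), 3)
  expect_equal(nrow(filter_min_depth(calls, 100)), 0)
  calls$depth[1] <- -1
  expect_error(filter_min_depth(calls, 30), "negative")
})

test_that("region classes follow the declared precedence", {
  chrom_lengths <- c(chr1 = 100000L, chr2 = 80000L)
  model <- generate_gene_model(6, chrom_lengths, seed = 5)
  tx <- model$transcripts
  multi <- which(vapply(names(model$exons), function(id) length(model$exons[[id]]) > 1,
                        logical(1)))[1]
  tx_id <- names(model$exons)[multi]
  cds1 <- model$cds[[tx_id]][1]
  inside_cds <- GenomicRanges::start(cds1) + 1L
  ex <- model$exons[[tx_id]]
  intron_start <- GenomicRanges::end(ex)[1] + 1L
  intron_end <- GenomicRanges::start(ex)[2] - 1L
  deep_intron <- (intron_start + intron_end) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(cds1))
  # an intergenic position: first base not covered by any transcript (computed
  # directly from the transcript intervals, independently of classify_region)
  tx_chr <- tx[as.character(GenomicRanges::seqnames(tx)) == chrom]
  covered <- GenomicRanges::reduce(GenomicRanges::granges(tx_chr), ignore.strand = TRUE)
  outside <- setdiff(seq_len(chrom_lengths[[chrom]]),
                     unlist(mapply(seq, GenomicRanges::start(covered),
                                   GenomicRanges::end(covered), SIMPLIFY = FALSE)))[1]
  calls <- mkcalls(c(chrom, chrom, chrom, chrom),
                   c(min(inside_cds, GenomicRanges::end(cds1)),
                     intron_start, deep_intron, outside),
                   "A", "G")
  cls <- classify_region(calls, model)
  expect_equal(cls[1], "exonic")
  expect_equal(cls[2], "splicing")   # first 2 bp of the intron
  expect_equal(cls[3], "intronic")
  expect_equal(cls[4], "intergenic")
  expect_error(classify_region(mkcalls("chr1", 1e9, "A", "G"), model), "outside")
  expect_error(classify_region(mkcalls("chrX", 5, "A", "G"), model), "chrX")
})

test_that("the empty gene model classifies everything intergenic", {
  model0 <- generate_gene_model(0, c(chr1 = 1000L))
  calls <- mkcalls("chr1", c(10, 500), "A", "G")
  expect_equal(classify_region(calls, model0), rep("intergenic", 2))
  rd <- region_distribution(calls, model0)
  expect_equal(unname(rd["intergenic"]), 1)
  expect_equal(sum(rd), 1)
})

test_that("region distribution reproduces hand-placed fractions and flags empty input", {
  chrom_lengths <- c(chr1 = 50000L)
  model <- generate_gene_model(2, chrom_lengths, seed = 3)
  cls_of <- function(pos) classify_region(mkcalls("chr1", pos, "A", "G"), model)
  # scan for positions of each wanted class
  pool <- seq(1, 50000, by = 7)
  classes <- classify_region(mkcalls("chr1", pool, "A", "G"), model)
  pos <- c(pool[classes == "exonic"][1:2], pool[classes == "intronic"][1:3],
           pool[classes == "intergenic"][1:5])
  rd <- region_distribution(mkcalls("chr1", pos, "A", "G"), model)
  expect_equal(unname(rd[c("exonic", "intronic", "intergenic")]), c(0.2, 0.3, 0.5))
  empty <- region_distribution(mkcalls(character(0), integer(0), character(0), character(0)), model)
  expect_true(all(is.na(empty)))
  expect_true(attr(empty, "undefined"))
})

test_that("codon-table classification of the canonical examples", {
  hm <- hand_gene_model("+")
  # CDS 11..28 = ATG GGA TAC CCT GAA TAA
  # GGA -> GGG at pos 16 (third base of codon 2): synonymous
  expect_equal(classify_coding_effect(mkcalls("c1", 16, "A", "G"), hm$model, hm$reference),
               "synonymous")
  # ATG -> ATA at pos 13: nonsynonymous (Met -> Ile)
  expect_equal(classify_coding_effect(mkcalls("c1", 13, "G", "A"), hm$model, hm$reference),
               "nonsynonymous")
  # TAC -> TAA at pos 19 (third base of codon 3): stopgain
  expect_equal(classify_coding_effect(mkcalls("c1", 19, "C", "A"), hm$model, hm$reference),
               "stopgain")
  # TAA -> CAA at pos 26 (first base of the stop codon): stoploss
  expect_equal(classify_coding_effect(mkcalls("c1", 26, "T", "C"), hm$model, hm$reference),
               "stoploss")
  # non-exonic variant -> error
  expect_error(classify_coding_effect(mkcalls("c1", 2, "G", "A"), hm$model, hm$reference),
               "not exonic")
})

test_that("minus-strand effects equal the full-CDS translation oracle", {
  hm <- hand_gene_model("-")
  ref_seq <- as.character(hm$reference[["c1"]])
  for (pos in hm$cds_start:hm$cds_end) {
    ref <- substr(ref_seq, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- mkcalls("c1", pos, ref, alt)
      expect_equal(classify_coding_effect(v, hm$model, hm$reference),
                   oracle_coding_effect(v[1, ], hm$model, hm$reference),
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
    }
  }
})

test_that("chromosome density and uniformity statistic", {
  lens <- c(chr1 = 2e6, chr2 = 1e6)
  calls <- mkcalls(c(rep("chr1", 40), rep("chr2", 20)), 1:60, "A", "G")
  res <- chromosome_density(calls, lens)
  expect_equal(res$chisq, 0)            # counts exactly proportional to lengths
  expect_equal(res$density$snps_per_mb, c(20, 20))
  # all 100 SNPs on one of two equal chromosomes -> chi-square 100
  skew <- mkcalls(rep("chr1", 100), 1:100, "A", "G")
  res2 <- chromosome_density(skew, c(chr1 = 1e6, chr2 = 1e6))
  expect_equal(res2$chisq, 100)
  expect_equal(res2$df, 1L)
  # single chromosome: df 0, statistic undefined
  res1 <- chromosome_density(skew, c(chr1 = 1e6))
  expect_true(res1$undefined)
  expect_equal(res1$df, 0L)
  expect_error(chromosome_density(skew, c(chr9 = 1e6)), "chr1")
})

test_that("genes with SNPs counts transcripts once each", {
  model <- generate_gene_model(5, c(chr1 = 100000L), seed = 8)
  tx <- model$transcripts
  starts <- GenomicRanges::start(tx)
  chrom <- as.character(GenomicRanges::seqnames(tx))
  # 5 SNPs in the first gene only
  five <- mkcalls(chrom[1], starts[1] + 0:4, "A", "G")
  expect_equal(genes_with_snps(five, model), 1L)
  # none in genes
  expect_equal(genes_with_snps(mkcalls("chr1", 1, "A", "G"), model), 0L)
  # hand placement across 3 of 5 genes
  three <- mkcalls(chrom[1:3], starts[1:3], "A", "G")
  expect_equal(genes_with_snps(three, model), 3L)
  # transcripts are pairwise disjoint by construction (interval sweep)
  ord <- order(chrom, starts)
  for (i in seq_len(length(tx) - 1)) {
    a <- ord[i]; b <- ord[i + 1]
    if (chrom[a] == chrom[b]) {
      expect_lt(GenomicRanges::end(tx)[a], GenomicRanges::start(tx)[b])
    }
  }
})
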