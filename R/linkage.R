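#' Build a genome-by-function linkage database
#'
#' Records, for one sample, which genome each annotated gene originates from
#' together with per-genome mapped-read abundances, the substrate for all
#' dominance and functional-redundancy statistics. Gene records without an
#' assignable originating genome (`NA` genome id) are excluded from the
#' matrix but tracked as `unassigned_fraction`.
#'
#' @param records gene-record data frame with `genome_id`, the function path
#'   columns and `count`.
#' @param genome_read_counts named non-negative numeric vector of mapped
#'   reads per genome; every non-`NA` record genome must appear here.
#' @return A `linkage_db`: list with `records`, `genomes`, `read_counts`,
#'   `abundance` (read counts normalised over all mapped reads) and
#'   `unassigned_fraction`.
#' @export
build_linkage_db <- function(records, genome_read_counts) {
  stopifnot(is.data.frame(records), !is.null(names(genome_read_counts)))
  if (any(genome_read_counts < 0)) stop("negative read counts", call. = FALSE)
  if (nrow(records) > 0 && any(records$count < 0)) {
    stop("negative gene counts", call. = FALSE)
  }
  assigned <- !is.na(records$genome_id)
  unknown_genomes <- setdiff(unique(records$genome_id[assigned]), names(genome_read_counts))
  if (length(unknown_genomes) > 0) {
    stop(sprintf("record genome(s) absent from genome_read_counts: %s",
                 paste(unknown_genomes, collapse = ", ")), call. = FALSE)
  }
  total_reads <- sum(genome_read_counts)
  structure(
    list(
      records = records[assigned, , drop = FALSE],
      genomes = sort(names(genome_read_counts)),
      read_counts = genome_read_counts[sort(names(genome_read_counts))],
      abundance = if (total_reads > 0) {
        genome_read_counts[sort(names(genome_read_counts))] / total_reads
      } else stats::setNames(rep(0, length(genome_read_counts)), sort(names(genome_read_counts))),
      unassigned_fraction = if (nrow(records) > 0) {
        sum(records$count[!assigned]) / sum(records$count)
      } else NA_real_
    ),
    class = "linkage_db"
  )
}

#' Genome-by-category gene-count matrix at a hierarchy level
#'
#' `M[g, c]` is the number of gene sequences of category `c` originating
#' from genome `g`. Rows cover every genome in the database (all-zero rows
#' for genomes without annotated genes); columns cover the categories
#' observed at the level. Column sums equal the sample's functional counts
#' at that level, so the matrix is conservative with [build_profile()].
#'
#' @param db a `linkage_db`.
#' @param level hierarchy level 1..4.
#' @return Numeric matrix, genomes x categories (alphabetical).
#' @export
linkage_matrix <- function(db, level) {
  stopifnot(inherits(db, "linkage_db"))
  col <- level_column(level)
  r <- db$records[!is.na(db$records$fun), , drop = FALSE]
  cats <- sort(unique(r[[col]]))
  m <- matrix(0, nrow = length(db$genomes), ncol = length(cats),
              dimnames = list(db$genomes, cats))
  if (nrow(r) > 0) {
    agg <- stats::aggregate(r$count, by = list(g = r$genome_id, c = r[[col]]), FUN = sum)
    m[cbind(agg$g, agg$c)] <- agg$x
  }
  m
}

#' Top-k dominant genomes by mapped-read abundance
#'
#' Genomes ranked by relative mapped-read abundance; ties broken
#' lexicographically by genome id. Returns `min(k, n_genomes)` ids.
#'
#' @param db a `linkage_db`.
#' @param k how many (default 5, the conventional "top five").
#' @return Ordered character vector of genome ids.
#' @export
dominant_genomes <- function(db, k = 5L) {
  stopifnot(inherits(db, "linkage_db"))
  k <- assert_positive_int(k, "k")
  ord <- order(-db$abundance, db$genomes)
  db$genomes[ord][seq_len(min(k, length(db$genomes)))]
}

#' Top-k dominant functional categories by gene-sequence hits
#'
#' Categories at the chosen level ranked by total gene-sequence count
#' (column sums of the linkage matrix); ties broken lexicographically.
#'
#' @inheritParams linkage_matrix
#' @param k how many (default 5).
#' @return Ordered character vector of category names.
#' @export
dominant_functions <- function(db, level, k = 5L) {
  k <- assert_positive_int(k, "k")
  m <- linkage_matrix(db, level)
  tot <- colSums(m)
  ord <- order(-tot, colnames(m))
  colnames(m)[ord][seq_len(min(k, ncol(m)))]
}

#' Per-genome functional diversity fraction
#'
#' For each genome, the fraction of the microbiota's functions (categories
#' with at least one gene at the level) that the genome itself encodes.
#'
#' @inheritParams linkage_matrix
#' @return Named numeric vector in `[0, 1]`, one entry per genome.
#' @export
genome_function_diversity <- function(db, level) {
  m <- linkage_matrix(db, level)
  total <- sum(colSums(m) > 0)
  if (total == 0) stop("empty linkage database: no annotated functions", call. = FALSE)
  rowSums(m > 0) / total
}

#' Contribution of dominant genomes to each functional category
#'
#' For every category with at least one gene, the fraction of its gene
#' sequences originating from the top-k dominant genomes. Zero-total
#' categories are omitted and reported in `omitted`.
#'
#' @inheritParams linkage_matrix
#' @param k number of dominant genomes (default 5).
#' @return List with `contribution` (named fractions in `[0, 1]`), `range`
#'   (min-max across categories), `dominant` (the genome ids used) and
#'   `omitted` (zero-total categories).
#' @export
dominant_contribution <- function(db, level, k = 5L) {
  m <- linkage_matrix(db, level)
  dom <- dominant_genomes(db, k)
  tot <- colSums(m)
  keep <- tot > 0
  contrib <- colSums(m[dom, keep, drop = FALSE]) / tot[keep]
  list(contribution = contrib,
       range = if (any(keep)) range(contrib) else c(NA_real_, NA_real_),
       dominant = dom,
       omitted = colnames(m)[!keep])
}

#' Rank correlation between genome abundance and functional diversity
#'
#' Spearman correlation (average ranks for ties) between per-genome mapped-
#' read abundance and the functional diversity fraction at the level. A
#' positive value reproduces the trend that dominant genomes encode the
#' most diverse functions. When either variable is constant the statistic
#' is defined as 0.
#'
#' @inheritParams linkage_matrix
#' @return Single numeric in `[-1, 1]`.
#' @export
diversity_abundance_trend <- function(db, level) {
  stopifnot(inherits(db, "linkage_db"))
  if (length(db$genomes) < 3) stop("need at least 3 genomes", call. = FALSE)
  x <- as.numeric(db$abundance)
  y <- as.numeric(genome_function_diversity(db, level)[db$genomes])
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(0)
  stats::cor(rx, ry, method = "pearson")
}

#' How many genomes contribute to each functional category
#'
#' Breadth of origin per category (`|{g : M[g, c] > 0}|`) and its Spearman
#' correlation with the category's total gene count; a positive correlation
#' means dominant functions originate from a more diverse set of genomes.
#'
#' @inheritParams linkage_matrix
#' @return List with `breadth` (named integer vector) and `correlation`.
#' @export
originating_genome_breadth <- function(db, level) {
  m <- linkage_matrix(db, level)
  breadth <- colSums(m > 0)
  tot <- colSums(m)
  corr <- if (ncol(m) >= 3 && stats::sd(rank(tot)) > 0 && stats::sd(rank(breadth)) > 0) {
    stats::cor(tot, breadth, method = "spearman")
  } else NA_real_
  list(breadth = breadth, correlation = corr)
}
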