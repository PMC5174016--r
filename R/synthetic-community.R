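#' Configuration for a synthetic microbial community
#'
#' Describes a community of reference genomes with skewed abundances and
#' genome-specific functional repertoires. Repertoire size (the number of
#' distinct functions a genome encodes) is a monotone function of abundance
#' rank plus optional Gaussian noise, so that more abundant genomes can be
#' made to encode more diverse functions.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param abundance_law one of `"lognormal"`, `"dirichlet"`, `"manual"`.
#' @param abundance numeric vector of abundances, required (and only used)
#'   for `abundance_law = "manual"`; normalised to sum to 1.
#' @param meanlog,sdlog log-normal parameters (law `"lognormal"`).
#' @param dirichlet_alpha concentration parameter (law `"dirichlet"`).
#' @param repertoire_rule function mapping abundance rank (1 = most abundant)
#'   to a target repertoire size. The default decays with rank so dominant
#'   genomes encode the most functions.
#' @param repertoire_noise_sd standard deviation of Gaussian noise added to
#'   the rule's output (0 = deterministic sizes).
#' @param seed integer seed.
#' @return A `community_config` list.
#' @export
community_config <- function(n_genomes,
                             abundance_law = c("lognormal", "dirichlet", "manual"),
                             abundance = NULL,
                             meanlog = 0, sdlog = 1.2,
                             dirichlet_alpha = 1,
                             repertoire_rule = NULL,
                             repertoire_noise_sd = 0,
                             seed = 1L) {
  n_genomes <- assert_positive_int(n_genomes, "n_genomes")
  abundance_law <- match.arg(abundance_law)
  if (abundance_law == "manual") {
    if (is.null(abundance) || length(abundance) != n_genomes || any(abundance <= 0)) {
      stop("manual law requires `abundance` of length n_genomes, all > 0", call. = FALSE)
    }
  }
  if (repertoire_noise_sd < 0) stop("`repertoire_noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(n_genomes = n_genomes, abundance_law = abundance_law,
         abundance = abundance, meanlog = meanlog, sdlog = sdlog,
         dirichlet_alpha = dirichlet_alpha,
         repertoire_rule = repertoire_rule,
         repertoire_noise_sd = repertoire_noise_sd,
         seed = as.integer(seed)),
    class = "community_config"
  )
}

#' Generate a synthetic community: genome abundances and a gene catalog
#'
#' Draws genome relative abundances under the configured law and assigns each
#' genome a repertoire of distinct functions sampled from the catalog, of
#' size given by the repertoire rule evaluated at the genome's abundance rank
#' (1 = most abundant) plus noise. With a strictly decreasing rule and zero
#' noise, distinct-function counts are strictly increasing in abundance.
#'
#' @param cfg a [community_config()].
#' @param catalog a `function_hierarchy` from [generate_function_catalog()].
#' @return A `community` list with `abundance` (named, strictly positive,
#'   sums to 1), `genes` (data frame: `gene_id`, `genome_id`, `h1`, `h2`,
#'   `h3`, `fun`, `count = 1`) and `config`.
#' @examples
#' cat4 <- generate_function_catalog(c(2, 4, 8, 16), seed = 1)
#' cfg <- community_config(4, "manual", abundance = c(0.4, 0.3, 0.2, 0.1),
#'                         repertoire_rule = function(rank) floor(10 / rank))
#' com <- generate_community(cfg, cat4)
#' table(com$genes$genome_id)  # 10, 5, 3, 2 genes
#' @export
generate_community <- function(cfg, catalog) {
  stopifnot(inherits(cfg, "community_config"), inherits(catalog, "function_hierarchy"))
  n <- cfg$n_genomes
  genome_ids <- sprintf("genome%03d", seq_len(n))
  leafs <- catalog$levels$fun
  rule <- cfg$repertoire_rule %||%
    function(rank) pmax(2, floor(0.75 * length(leafs) / rank^0.7))

  withr::with_seed(cfg$seed, {
    ab <- switch(cfg$abundance_law,
      lognormal = rlnorm(n, cfg$meanlog, cfg$sdlog),
      dirichlet = rgamma(n, shape = cfg$dirichlet_alpha, rate = 1),
      manual    = as.numeric(cfg$abundance)
    )
    if (any(ab <= 0)) ab[ab <= 0] <- min(ab[ab > 0]) / 10
    ab <- ab / sum(ab)
    names(ab) <- genome_ids

    # Rank 1 = most abundant; ties broken by genome id for determinism.
    rk <- rank(-ab, ties.method = "first")
    sizes <- rule(rk)
    if (cfg$repertoire_noise_sd > 0) {
      sizes <- sizes + rnorm(n, 0, cfg$repertoire_noise_sd)
    }
    sizes <- pmin(length(leafs), pmax(1L, as.integer(round(sizes))))

    reps <- lapply(seq_len(n), function(i) sort(sample(leafs, sizes[i])))
    genes <- data.frame(
      genome_id = rep(genome_ids, lengths(reps)),
      fun = unlist(reps, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
    idx <- match(genes$fun, catalog$paths$fun)
    genes$h1 <- catalog$paths$h1[idx]
    genes$h2 <- catalog$paths$h2[idx]
    genes$h3 <- catalog$paths$h3[idx]
    genes$count <- 1L
    genes <- genes[, c("gene_id", "genome_id", "h1", "h2", "h3", "fun", "count")]

    structure(list(abundance = ab, genes = genes, config = cfg, catalog = catalog),
              class = "community")
  })
}

#' Draw a per-sample gene catalog from a community
#'
#' Emulates a per-sample annotation export: every community gene receives a
#' sample-specific hit count drawn around the abundance of its genome, a
#' chosen fraction of gene records is flagged unknown-function (path set to
#' `NA`), and (optionally) the relative abundance of categories listed in
#' `shift_categories` is multiplied by `fold`, with all other categories
#' shrunk proportionally so the shift is expressed on relative abundances
#' (a `fold`-times shift is then recoverable as `100 * (fold - 1)` percent
#' enrichment against an unshifted sample).
#'
#' @param community a `community`.
#' @param sample_id sample label attached to every record.
#' @param depth_scale expected total hit count across the catalog.
#' @param unknown_fraction fraction of records flagged unknown-function.
#' @param shift_categories character vector of category names to shift.
#' @param shift_level hierarchy level (1..4) at which `shift_categories` live.
#' @param fold multiplicative relative-abundance shift applied to those
#'   categories; their pre-shift share times `fold` must stay below 1.
#' @param seed integer seed.
#' @return A gene-record data frame (`gene_id`, `genome_id`, `h1`..`fun`,
#'   `sample_id`, `count`); unknown records have `NA` in `h1`..`fun`.
#' @export
sample_gene_catalog <- function(community, sample_id, depth_scale = 20000,
                                unknown_fraction = 0,
                                shift_categories = NULL, shift_level = 2,
                                fold = 1, seed = 1L) {
  stopifnot(inherits(community, "community"))
  unknown_fraction <- assert_proportion(unknown_fraction, "unknown_fraction")
  g <- community$genes
  lambda <- community$abundance[g$genome_id]
  lambda <- depth_scale * lambda / sum(lambda)
  if (!is.null(shift_categories) && fold != 1) {
    col <- level_column(shift_level)
    hit <- g[[col]] %in% shift_categories
    share <- sum(lambda[hit]) / sum(lambda)
    if (fold * share >= 1) {
      stop("shift infeasible: fold * category share must be < 1", call. = FALSE)
    }
    lambda[hit] <- lambda[hit] * fold
    lambda[!hit] <- lambda[!hit] * (1 - fold * share) / (1 - share)
  }

  withr::with_seed(seed, {
    g$count <- 1L + rpois(nrow(g), lambda)
    if (unknown_fraction > 0) {
      unk <- runif(nrow(g)) < unknown_fraction
      g$h1[unk] <- g$h2[unk] <- g$h3[unk] <- g$fun[unk] <- NA_character_
    }
    g$sample_id <- sample_id
    g[, c("gene_id", "genome_id", "h1", "h2", "h3", "fun", "sample_id", "count")]
  })
}
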