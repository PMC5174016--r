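#' Build a per-sample functional abundance profile at one hierarchy level
#'
#' Aggregates gene-record hit counts by the ancestor category of each
#' record's function at the requested level. Records flagged unknown-function
#' (`NA` path) are excluded from the counts and relative abundances but
#' reported as `unknown_fraction`, keeping profiles comparable across
#' samples with very different unknown rates.
#'
#' @param records gene-record data frame (`sample_id`, `h1`, `h2`, `h3`,
#'   `fun`, `count`); all rows must share one `sample_id`.
#' @param level hierarchy level 1..4 (4 = function level).
#' @return A `function_profile`: list with `sample_id`, `level`, `counts`
#'   and `rel_abundance` (named vectors over observed categories; relative
#'   abundances sum to 1), `unknown_fraction` (`NA` when no records) and
#'   `total_known`.
#' @export
build_profile <- function(records, level) {
  stopifnot(is.data.frame(records))
  col <- level_column(level)
  if (nrow(records) == 0) {
    return(structure(list(sample_id = NA_character_, level = as.integer(level),
                          counts = stats::setNames(numeric(0), character(0)),
                          rel_abundance = stats::setNames(numeric(0), character(0)),
                          unknown_fraction = NA_real_, total_known = 0),
                     class = "function_profile"))
  }
  sid <- unique(records$sample_id)
  if (length(sid) > 1) {
    stop(sprintf("records mix sample_ids: %s", paste(sid, collapse = ", ")), call. = FALSE)
  }
  if (any(records$count < 1)) stop("record counts must be >= 1", call. = FALSE)

  unknown <- is.na(records$fun)
  total <- sum(records$count)
  known <- records[!unknown, , drop = FALSE]
  counts <- if (nrow(known) > 0) {
    tab <- tapply(known$count, known[[col]], sum)
    stats::setNames(as.numeric(tab), names(tab))
  } else stats::setNames(numeric(0), character(0))
  counts <- counts[order(names(counts))]
  tk <- sum(counts)
  structure(
    list(sample_id = sid, level = as.integer(level), counts = counts,
         rel_abundance = if (tk > 0) counts / tk else counts,
         unknown_fraction = sum(records$count[unknown]) / total,
         total_known = tk),
    class = "function_profile"
  )
}

#' @export
print.function_profile <- function(x, ...) {
  cat(sprintf("function_profile: sample %s, level %d, %d categories, %d known hits\n",
              x$sample_id, x$level, length(x$counts), as.integer(x$total_known)))
  invisible(x)
}

#' Core and pan function sets across samples
#'
#' The functional core is the set of functions present in every sample's
#' microbiota; the pan set is their union. Gene-sequence counts pair each
#' set with the total number of gene hits it derives from: the across-sample
#' sum of counts of records annotated to core (respectively any) functions.
#'
#' @param profiles list of `function_profile`s, all at the same level
#'   (conventionally level 4, the function level).
#' @return List with `core`, `pan` (sorted character vectors),
#'   `core_gene_sequence_count` and `pan_gene_sequence_count`.
#' @examples
#' # sets {A,B,C}, {B,C,D}, {C,B} give core {B,C}, pan {A,B,C,D}
#' @export
core_functions <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "function_profile")))
  lv <- unique(vapply(profiles, function(p) p$level, integer(1)))
  if (length(lv) > 1) stop("profiles are at different levels", call. = FALSE)
  sets <- lapply(profiles, function(p) names(p$counts)[p$counts > 0])
  core <- sort(Reduce(intersect, sets))
  pan <- sort(Reduce(union, sets))
  core_n <- sum(vapply(profiles, function(p) sum(p$counts[names(p$counts) %in% core]),
                       numeric(1)))
  pan_n <- sum(vapply(profiles, function(p) sum(p$counts), numeric(1)))
  list(core = core, pan = pan,
       core_gene_sequence_count = core_n, pan_gene_sequence_count = pan_n)
}

#' Signed percent enrichment of one profile relative to another
#'
#' For every category present in either profile, computes
#' `100 * (RA_a - RA_b) / RA_b` on relative abundances, the signed
#' red/green signature used to compare microbiota. Categories present in
#' `a` but absent from `b` cannot be expressed as a percentage and are
#' flagged `exclusive_a` instead; categories below `min_abundance` in both
#' profiles are omitted.
#'
#' @param profile_a,profile_b `function_profile`s at the same level.
#' @param min_abundance omit categories whose relative abundance is below
#'   this in both profiles (default 0 = keep all).
#' @return Data frame with `category`, `ra_a`, `ra_b`, `enrichment_pct`
#'   (`NA` for exclusives) and `status` (`"ok"` or `"exclusive_a"`).
#' @export
enrichment_signature <- function(profile_a, profile_b, min_abundance = 0) {
  stopifnot(inherits(profile_a, "function_profile"),
            inherits(profile_b, "function_profile"))
  if (profile_a$level != profile_b$level) {
    stop("profiles are at different hierarchy levels", call. = FALSE)
  }
  cats <- sort(union(names(profile_a$rel_abundance), names(profile_b$rel_abundance)))
  ra <- function(p, cats) {
    v <- p$rel_abundance[cats]
    v[is.na(v)] <- 0
    stats::setNames(as.numeric(v), cats)
  }
  a <- ra(profile_a, cats); b <- ra(profile_b, cats)
  keep <- !(a < min_abundance & b < min_abundance)
  a <- a[keep]; b <- b[keep]; cats <- cats[keep]
  excl <- b == 0
  data.frame(
    category = cats, ra_a = a, ra_b = b,
    enrichment_pct = ifelse(excl, NA_real_, 100 * (a - b) / ifelse(excl, NA, b)),
    status = ifelse(excl, "exclusive_a", "ok"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Unique proteins of two groups within one pathway
#'
#' Counts the distinct functions under a pathway (a category at any
#' hierarchy level) observed in group a but not group b, and vice versa,
#' and their relative excess as a percentage.
#'
#' @param records_a,records_b gene-record data frames for the two groups.
#' @param pathway category name at any level of the hierarchy.
#' @param hierarchy the `function_hierarchy`.
#' @return List with `unique_to_a`, `unique_to_b` (function name vectors),
#'   `n_unique_a`, `n_unique_b`, `percent_excess`
#'   (`100 * (n_a - n_b) / n_b`; `NA` when undefined) and `status`
#'   (`"ok"`, `"exclusive_a"` when b has no unique functions but a does,
#'   `"undefined"` when neither group has any).
#' @export
pathway_unique_proteins <- function(records_a, records_b, pathway, hierarchy) {
  members <- functions_under(hierarchy, pathway)
  seen <- function(records) {
    f <- records$fun[!is.na(records$fun)]
    sort(unique(f[f %in% members]))
  }
  sa <- seen(records_a); sb <- seen(records_b)
  ua <- setdiff(sa, sb); ub <- setdiff(sb, sa)
  na <- length(ua); nb <- length(ub)
  if (nb > 0) {
    list(unique_to_a = ua, unique_to_b = ub, n_unique_a = na, n_unique_b = nb,
         percent_excess = 100 * (na - nb) / nb, status = "ok")
  } else if (na > 0) {
    list(unique_to_a = ua, unique_to_b = ub, n_unique_a = na, n_unique_b = nb,
         percent_excess = NA_real_, status = "exclusive_a")
  } else {
    list(unique_to_a = ua, unique_to_b = ub, n_unique_a = 0L, n_unique_b = 0L,
         percent_excess = NA_real_, status = "undefined")
  }
}

# Samples-by-categories relative-abundance matrix over the union universe.
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  lv <- unique(vapply(profiles, function(p) p$level, integer(1)))
  if (length(lv) > 1) stop("profiles are at different levels", call. = FALSE)
  cats <- sort(Reduce(union, lapply(profiles, function(p) names(p$rel_abundance))))
  m <- t(vapply(profiles, function(p) {
    v <- p$rel_abundance[cats]; v[is.na(v)] <- 0; as.numeric(v)
  }, numeric(length(cats))))
  rownames(m) <- vapply(profiles, function(p) p$sample_id, character(1))
  colnames(m) <- cats
  m
}

#' Ordinate functional profiles by principal component analysis
#'
#' PCA on centred (not scaled) relative-abundance vectors over the union
#' category universe, zero-filled for categories absent from a sample.
#' Coordinates are deterministic up to component sign.
#'
#' @param profiles list of >= 2 `function_profile`s at one level.
#' @param n_components number of components to return (default 2); must not
#'   exceed `min(n_samples, n_categories)`.
#' @return List with `coordinates` (data frame: `sample_id`, `PC1`, ...)
#'   and `explained_variance` (non-increasing fractions, summing to <= 1).
#' @export
ordinate_profiles <- function(profiles, n_components = 2L) {
  stopifnot(length(profiles) >= 2)
  m <- profile_matrix(profiles)
  n_components <- assert_positive_int(n_components, "n_components")
  if (n_components > min(nrow(m), ncol(m))) {
    stop("n_components exceeds min(samples, categories)", call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- as.data.frame(pc$x[, seq_len(k), drop = FALSE])
  # Degenerate case: fewer positive-variance axes than requested.
  if (k < n_components) {
    for (j in seq(k + 1L, n_components)) coords[[paste0("PC", j)]] <- 0
  }
  tot <- sum(pc$sdev^2)
  ev <- if (tot > 0) (pc$sdev^2 / tot) else rep(0, length(pc$sdev))
  ev <- c(ev, rep(0, max(0, n_components - length(ev))))[seq_len(n_components)]
  list(
    coordinates = cbind(data.frame(sample_id = rownames(m), stringsAsFactors = FALSE),
                        coords, row.names = NULL),
    explained_variance = ev
  )
}

#' Hierarchically cluster functional profiles
#'
#' Agglomerative clustering of samples from pairwise Euclidean distances
#' between relative-abundance vectors (union universe, zero-filled).
#'
#' @param profiles list of >= 2 `function_profile`s at one level.
#' @param linkage_rule agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An `hclust` object; convert with [dendrogram_newick()] to export.
#' @export
cluster_profiles <- function(profiles, linkage_rule = "average") {
  if (length(profiles) < 2) stop("need at least 2 profiles to cluster", call. = FALSE)
  m <- profile_matrix(profiles)
  stats::hclust(stats::dist(m, method = "euclidean"), method = linkage_rule)
}

#' Serialise a profile dendrogram as a Newick string
#'
#' @param hc an `hclust` from [cluster_profiles()].
#' @return Single Newick string with branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
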