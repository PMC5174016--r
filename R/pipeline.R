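## End-to-end orchestration from a flat key=value config file.

pipeline_known_keys <- c("seed", "out_dir", "samples", "mapq_threshold",
                         "min_depth", "top_k", "min_abundance", "profile_level",
                         "gene_model", "reference")
pipeline_key_prefixes <- c("alignments.", "catalog.", "calls_a.", "calls_b.")

#' Load and validate a pipeline configuration
#'
#' The configuration is a flat `key=value` file. Recognised keys: `seed`,
#' `out_dir`, `samples` (comma-separated `sample_id:group` with group `H`
#' or `C`), the thresholds `mapq_threshold` (default 100), `min_depth`
#' (default 30), `top_k` (default 5), `min_abundance` (default 0),
#' `profile_level` (default 2), the shared inputs `gene_model` (GFF3) and
#' `reference` (FASTA), and per-sample inputs `alignments.<id>`,
#' `catalog.<id>`, `calls_a.<id>`, `calls_b.<id>`. Unknown keys are errors
#' (a silent typo in a threshold would invalidate a run); relative paths
#' are resolved against the config file's directory.
#'
#' @param path config file path.
#' @return A `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  raw <- read_config(path)
  base <- dirname(normalizePath(path))
  known <- names(raw) %in% pipeline_known_keys |
    Reduce(`|`, lapply(pipeline_key_prefixes, function(p) startsWith(names(raw), p)))
  if (any(!known)) {
    stop(sprintf("unknown config key(s): %s", paste(names(raw)[!known], collapse = ", ")),
         call. = FALSE)
  }
  if (!"samples" %in% names(raw)) stop("config lacks `samples`", call. = FALSE)
  sm <- strsplit(strsplit(raw[["samples"]], ",")[[1]], ":")
  samples <- data.frame(
    sample_id = trimws(vapply(sm, `[`, character(1), 1)),
    group = trimws(vapply(sm, `[`, character(1), 2)),
    stringsAsFactors = FALSE
  )
  if (!all(samples$group %in% c("H", "C"))) {
    stop(sprintf("unknown sample group(s): %s",
                 paste(setdiff(samples$group, c("H", "C")), collapse = ", ")),
         call. = FALSE)
  }
  resolve <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  num <- function(key, default) {
    if (key %in% names(raw)) as.numeric(raw[[key]]) else default
  }
  path_for <- function(prefix, sid) {
    key <- paste0(prefix, sid)
    if (key %in% names(raw)) resolve(raw[[key]]) else NA_character_
  }
  cfg <- list(
    seed = as.integer(num("seed", 1)),
    out_dir = resolve(raw[["out_dir"]] %||% file.path(base, "results")),
    samples = samples,
    mapq_threshold = as.integer(num("mapq_threshold", 100)),
    min_depth = as.integer(num("min_depth", 30)),
    top_k = as.integer(num("top_k", 5)),
    min_abundance = num("min_abundance", 0),
    profile_level = as.integer(num("profile_level", 2)),
    gene_model = if ("gene_model" %in% names(raw)) resolve(raw[["gene_model"]]) else NA,
    reference = if ("reference" %in% names(raw)) resolve(raw[["reference"]]) else NA,
    alignments = stats::setNames(vapply(samples$sample_id, function(s) path_for("alignments.", s), character(1)), samples$sample_id),
    catalog = stats::setNames(vapply(samples$sample_id, function(s) path_for("catalog.", s), character(1)), samples$sample_id),
    calls_a = stats::setNames(vapply(samples$sample_id, function(s) path_for("calls_a.", s), character(1)), samples$sample_id),
    calls_b = stats::setNames(vapply(samples$sample_id, function(s) path_for("calls_b.", s), character(1)), samples$sample_id)
  )
  if (any(c(cfg$mapq_threshold, cfg$min_depth, cfg$top_k, cfg$min_abundance) < 0)) {
    stop("thresholds must be non-negative", call. = FALSE)
  }
  declared <- unlist(cfg[c("gene_model", "reference", "alignments", "catalog",
                           "calls_a", "calls_b")])
  declared <- declared[!is.na(declared)]
  missing <- declared[!file.exists(declared)]
  if (length(missing) > 0) {
    stop(sprintf("config references missing file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the whole-ecosystem pipeline
#'
#' Executes the stages in order for every sample with the relevant inputs:
#' read partition (host/microbial fractions and per-genome mapped-read
#' counts), functional profiling at levels 1-4, core/pan functions across
#' samples, group enrichment (H vs C), ordination and clustering of sample
#' profiles, per-sample genome-function linkage and dominance statistics,
#' and consensus host variant calling with region/effect classification.
#' Stages whose inputs are absent are skipped and listed in the report.
#' Result tables are written under `out_dir`; the pipeline itself draws no
#' random numbers, so identical config and inputs give an identical report.
#'
#' @param config a `pipeline_config` or the path to a config file.
#' @return A `run_report` list (also serialised to `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else load_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sids <- cfg$samples$sample_id
  skipped <- character(0)
  log_msg <- function(...) message(sprintf(...))

  ## --- partition stage ------------------------------------------------
  partition <- NULL
  genome_reads <- list()
  if (all(!is.na(cfg$alignments))) {
    rows <- lapply(sids, function(s) {
      aln <- read_alignment_tsv(cfg$alignments[[s]])
      pr <- partition_read_pairs(aln, threshold = cfg$mapq_threshold)
      mic <- aln[aln$read_id %in% pr$microbial_ids & !is.na(aln$target), , drop = FALSE]
      genome_reads[[s]] <<- table(mic$target)
      log_msg("partition[%s]: %d pairs in, %d host / %d microbial",
              s, pr$n, length(pr$host_ids), length(pr$microbial_ids))
      data.frame(sample_id = s, group = cfg$samples$group[cfg$samples$sample_id == s],
                 n_pairs = pr$n, host_fraction = pr$host_fraction,
                 microbial_fraction = pr$microbial_fraction,
                 stringsAsFactors = FALSE)
    })
    partition <- do.call(rbind, rows)
    utils::write.table(partition, file.path(cfg$out_dir, "partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else skipped <- c(skipped, "partition")

  ## --- profiles / core / enrichment / ordination ----------------------
  profiles_by_level <- NULL; core <- NULL; enrichment <- NULL
  ordination <- NULL; dendrogram <- NULL
  records_by_sample <- NULL
  if (all(!is.na(cfg$catalog))) {
    records_by_sample <- lapply(stats::setNames(sids, sids), function(s) {
      read_gene_catalog(cfg$catalog[[s]])
    })
    profiles_by_level <- lapply(1:4, function(lv) {
      lapply(records_by_sample, build_profile, level = lv)
    })
    for (lv in 1:4) {
      write_profile_matrix(profiles_by_level[[lv]],
                           file.path(cfg$out_dir, sprintf("profiles_level%d.tsv", lv)))
    }
    core <- core_functions(profiles_by_level[[4]])
    log_msg("profiles: core %d / pan %d functions", length(core$core), length(core$pan))

    groups <- split(cfg$samples$sample_id, cfg$samples$group)
    if (all(c("H", "C") %in% names(groups))) {
      pool <- function(g) {
        r <- do.call(rbind, records_by_sample[groups[[g]]])
        r$sample_id <- g
        build_profile(r, cfg$profile_level)
      }
      enrichment <- enrichment_signature(pool("H"), pool("C"),
                                         min_abundance = cfg$min_abundance)
      utils::write.table(enrichment, file.path(cfg$out_dir, "enrichment_H_vs_C.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(sids) >= 2) {
      prof <- profiles_by_level[[cfg$profile_level]]
      ordination <- ordinate_profiles(prof, n_components = 2)
      utils::write.table(ordination$coordinates,
                         file.path(cfg$out_dir, "ordination.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dendrogram <- dendrogram_newick(cluster_profiles(prof))
      writeLines(dendrogram, file.path(cfg$out_dir, "dendrogram.nwk"))
    }
  } else skipped <- c(skipped, "profiles")

  ## --- linkage stage ---------------------------------------------------
  dominance <- NULL
  if (!is.null(records_by_sample) && length(genome_reads) == length(sids)) {
    dominance <- lapply(stats::setNames(sids, sids), function(s) {
      counts <- genome_reads[[s]]
      rc <- stats::setNames(as.numeric(counts), names(counts))
      recs <- records_by_sample[[s]]
      recs$genome_id[!recs$genome_id %in% names(rc)] <- NA_character_
      db <- build_linkage_db(recs, rc)
      contrib <- dominant_contribution(db, level = 1, k = cfg$top_k)
      list(
        sample_id = s,
        dominant_genomes = dominant_genomes(db, cfg$top_k),
        dominant_functions = dominant_functions(db, level = 1, k = cfg$top_k),
        dominant_abundance_share = sum(db$abundance[dominant_genomes(db, cfg$top_k)]),
        contribution_range = contrib$range,
        diversity_trend = diversity_abundance_trend(db, level = 4),
        breadth_correlation = originating_genome_breadth(db, level = 4)$correlation
      )
    })
    dom_df <- do.call(rbind, lapply(dominance, function(d) {
      data.frame(sample_id = d$sample_id,
                 dominant_genomes = paste(d$dominant_genomes, collapse = ","),
                 dominant_abundance_share = d$dominant_abundance_share,
                 contribution_min = d$contribution_range[1],
                 contribution_max = d$contribution_range[2],
                 diversity_trend = d$diversity_trend,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(dom_df, file.path(cfg$out_dir, "dominance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else skipped <- c(skipped, "linkage")

  ## --- variants stage --------------------------------------------------
  variants <- NULL
  if (all(!is.na(cfg$calls_a)) && all(!is.na(cfg$calls_b)) && !is.na(cfg$gene_model)) {
    reference <- if (!is.na(cfg$reference)) read_reference_fasta(cfg$reference) else NULL
    chrom_lengths <- if (!is.null(reference)) {
      stats::setNames(Biostrings::width(reference),
                      sub("\\s.*$", "", names(reference)))
    } else stop("variants stage requires `reference` for chromosome lengths", call. = FALSE)
    model <- read_gene_model_gff3(cfg$gene_model, chrom_lengths)
    rows <- lapply(sids, function(s) {
      a <- read_variants_vcf(cfg$calls_a[[s]])
      b <- read_variants_vcf(cfg$calls_b[[s]])
      cons <- intersect_call_sets(a, b)
      deep <- filter_min_depth(cons, cfg$min_depth)
      rd <- region_distribution(cons, model)
      dens <- chromosome_density(cons, chrom_lengths)
      write_variants_vcf(cons, file.path(cfg$out_dir, sprintf("consensus_%s.vcf", s)),
                         sample_name = s)
      log_msg("variants[%s]: %d + %d calls in, %d consensus, %d at depth>=%d",
              s, nrow(a), nrow(b), nrow(cons), nrow(deep), cfg$min_depth)
      data.frame(sample_id = s, n_calls_a = nrow(a), n_calls_b = nrow(b),
                 n_consensus = nrow(cons), n_deep = nrow(deep),
                 exonic = rd[["exonic"]], intronic = rd[["intronic"]],
                 intergenic = rd[["intergenic"]],
                 genes_with_snps = genes_with_snps(cons, model),
                 density_chisq = dens$chisq, density_df = dens$df,
                 stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, rows)
    utils::write.table(variants, file.path(cfg$out_dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else skipped <- c(skipped, "variants")

  fingerprint <- paste0("salivalink ", as.character(utils::packageVersion("salivalink")),
                        " seed=", cfg$seed)
  report <- structure(list(
    partition = partition,
    core = core,
    enrichment = enrichment,
    ordination = ordination,
    dendrogram = dendrogram,
    dominance = dominance,
    variants = variants,
    skipped = skipped,
    fingerprint = fingerprint
  ), class = "run_report")
  json <- jsonlite::toJSON(report_body(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(cfg$out_dir, "report.json"))
  report
}

# Stable serialisable body of a run report (no handles, no timestamps).
report_body <- function(report) {
  list(
    partition = report$partition,
    core_size = length(report$core$core),
    pan_size = length(report$core$pan),
    core_gene_sequence_count = report$core$core_gene_sequence_count,
    pan_gene_sequence_count = report$core$pan_gene_sequence_count,
    enrichment = report$enrichment,
    ordination = report$ordination$coordinates,
    explained_variance = report$ordination$explained_variance,
    dendrogram = report$dendrogram,
    dominance = lapply(report$dominance, function(d) d[setdiff(names(d), "sample_id")]),
    variants = report$variants,
    skipped = report$skipped,
    fingerprint = report$fingerprint
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("salivalink run_report\n")
  if (!is.null(x$partition)) {
    cat(sprintf("  partition: %d samples, microbial fractions %s\n",
                nrow(x$partition),
                paste(sprintf("%.2f", x$partition$microbial_fraction), collapse = ", ")))
  }
  if (!is.null(x$core)) {
    cat(sprintf("  core %d / pan %d functions (%d / %d gene sequences)\n",
                length(x$core$core), length(x$core$pan),
                as.integer(x$core$core_gene_sequence_count),
                as.integer(x$core$pan_gene_sequence_count)))
  }
  if (length(x$skipped) > 0) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Generate the bundled four-sample demo dataset
#'
#' Emits a complete synthetic study emulating the design of a two healthy
#' ("H", host fraction 0.7, i.e. ~30% microbial reads) plus two
#' caries-active ("C", host fraction 0.45) saliva cohort: a shared
#' community of 20 genomes with log-normal abundances, per-sample alignment
#' tables, gene catalogs (the C group carries a 2x count shift on four
#' seeded level-2 categories), a toy host gene model with reference
#' sequence, and two noisy variant callsets per sample, plus a ready-to-run
#' pipeline config and the full ground truth.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of it.
#' @return Path of the written config file, invisibly; the truth labels are
#'   under `outdir/truth/`.
#' @export
make_demo_dataset <- function(outdir, seed = 42L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create '%s'", outdir), call. = FALSE)
  truth_dir <- file.path(outdir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  seed <- as.integer(seed)

  samples <- data.frame(
    sample_id = c("H105", "H114", "C201", "C218"),
    group = c("H", "H", "C", "C"),
    host_fraction = c(0.7, 0.7, 0.45, 0.45),
    stringsAsFactors = FALSE
  )

  catalog <- generate_function_catalog(c(6, 14, 32, 90), seed = derive_seed(seed, 1))
  community <- generate_community(
    community_config(20, "lognormal", sdlog = 1.2, seed = derive_seed(seed, 2)),
    catalog)
  shift_cats <- withr::with_seed(derive_seed(seed, 3),
                                 sample(catalog$levels$h2, 4))

  chrom_lengths <- c(chr1 = 150000L, chr2 = 150000L)
  reference <- generate_reference(chrom_lengths, seed = derive_seed(seed, 4))
  model <- generate_gene_model(12, chrom_lengths, seed = derive_seed(seed, 5))
  write_reference_fasta(reference, file.path(outdir, "reference.fa"))
  write_gene_model(model, gff3_path = file.path(outdir, "genes.gff3"),
                   bed12_path = file.path(outdir, "genes.bed"))

  settings <- c(seed = seed, out_dir = "results",
                samples = paste(samples$sample_id, samples$group, sep = ":", collapse = ","),
                mapq_threshold = 100, min_depth = 30, top_k = 5,
                min_abundance = 0, profile_level = 2,
                gene_model = "genes.gff3", reference = "reference.fa")

  for (i in seq_len(nrow(samples))) {
    s <- samples$sample_id[i]
    sim <- simulate_read_pairs(
      ecosystem_config(samples$host_fraction[i], 20000,
                       crossmap_rate = 0.01, seed = derive_seed(seed, 10 + i)),
      community$abundance)
    write_alignment_tsv(sim$alignments, file.path(outdir, sprintf("alignments_%s.tsv", s)),
                        truth = sim$truth)
    recs <- sample_gene_catalog(
      community, s, depth_scale = 20000, unknown_fraction = 0.35,
      shift_categories = if (samples$group[i] == "C") shift_cats else NULL,
      shift_level = 2, fold = 2,
      seed = derive_seed(seed, 20 + i))
    write_gene_catalog(recs, file.path(outdir, sprintf("catalog_%s.tsv", s)))

    vs <- simulate_variant_callsets(
      400, chrom_lengths, reference = reference,
      fp_rate_a = 1e-4, fn_rate_a = 0.1, fp_rate_b = 1e-4, fn_rate_b = 0.1,
      seed = derive_seed(seed, 30 + i))
    write_variants_vcf(vs$calls_a, file.path(outdir, sprintf("calls_a_%s.vcf", s)), s)
    write_variants_vcf(vs$calls_b, file.path(outdir, sprintf("calls_b_%s.vcf", s)), s)
    write_variants_vcf(vs$truth, file.path(truth_dir, sprintf("truth_variants_%s.vcf", s)), s)

    settings[paste0("alignments.", s)] <- sprintf("alignments_%s.tsv", s)
    settings[paste0("catalog.", s)] <- sprintf("catalog_%s.tsv", s)
    settings[paste0("calls_a.", s)] <- sprintf("calls_a_%s.vcf", s)
    settings[paste0("calls_b.", s)] <- sprintf("calls_b_%s.vcf", s)
  }
  writeLines(c(sprintf("# seeded shift categories (C group, 2x): %s",
                       paste(shift_cats, collapse = ",")),
               sprintf("# community abundances: %s",
                       paste(sprintf("%s=%.6f", names(community$abundance),
                                     community$abundance), collapse = ","))),
             file.path(truth_dir, "community_truth.txt"))

  cfg_path <- file.path(outdir, "config.ini")
  write_config(settings, cfg_path)
  invisible(cfg_path)
}
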