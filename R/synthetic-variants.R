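#' Simulate a truth SNV set and two noisy caller outputs
#'
#' Draws `truth_n` true single-nucleotide variants uniformly over the genome,
#' then derives two callsets (emulating two independent variant callers run
#' on the same alignments): each caller misses a true variant independently
#' with its false-negative rate, and adds false positives by visiting every
#' non-variant ("candidate") position independently with its false-positive
#' rate. The erroneous allele at a candidate position is a property of the
#' site (a deterministic transition of its reference base), emulating
#' systematic, alignment-driven errors; both callers therefore report an
#' identical record when they both stumble on the same site, and the number
#' of false positives surviving an intersection of the two callsets is
#' Binomial(n_candidates, fp_rate_a * fp_rate_b).
#'
#' @param truth_n number of true variants (>= 0).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param reference optional `DNAStringSet`; if supplied, reference alleles
#'   are read from it, otherwise drawn at random.
#' @param depth_fun function(n) returning n integer read depths; default is
#'   a negative binomial centred on 60x, matching the deep-site regime the
#'   depth >= 30 consensus filter targets.
#' @param fp_rate_a,fn_rate_a,fp_rate_b,fn_rate_b per-caller error rates in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @return List with data frames `truth`, `calls_a`, `calls_b`, each with
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `depth` (+ `caller` tag on the
#'   callsets), and `n_candidates`, the size of the non-variant space.
#' @export
simulate_variant_callsets <- function(truth_n, chrom_lengths, reference = NULL,
                                      depth_fun = function(n) rnbinom(n, mu = 60, size = 12) + 1L,
                                      fp_rate_a = 0, fn_rate_a = 0,
                                      fp_rate_b = 0, fn_rate_b = 0,
                                      seed = 1L) {
  truth_n <- assert_positive_int(truth_n, "truth_n", allow_zero = TRUE)
  for (r in c(fp_rate_a, fn_rate_a, fp_rate_b, fn_rate_b)) {
    if (!is.numeric(r) || r < 0 || r >= 1) {
      stop("error rates must lie in [0, 1)", call. = FALSE)
    }
  }
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  total <- sum(as.numeric(chrom_lengths))
  if (truth_n > total) stop("truth_n exceeds genome size", call. = FALSE)
  cum <- cumsum(as.numeric(chrom_lengths))

  linear_to_site <- function(idx) {
    ci <- findInterval(idx - 1, cum) + 1L
    chrom <- names(chrom_lengths)[ci]
    pos <- as.integer(idx - c(0, cum)[ci])
    list(chrom = chrom, pos = pos)
  }
  base_at <- function(chrom, pos) {
    if (is.null(reference)) return(NULL)
    vapply(seq_along(pos), function(i) {
      as.character(Biostrings::subseq(reference[[chrom[i]]], pos[i], pos[i]))
    }, character(1))
  }
  transition <- c(A = "G", G = "A", C = "T", T = "C")

  withr::with_seed(seed, {
    truth_idx <- sort(sample(total, truth_n))
    ts <- linear_to_site(truth_idx)
    ref_t <- base_at(ts$chrom, ts$pos) %||%
      sample(c("A", "C", "G", "T"), truth_n, replace = TRUE)
    alt_t <- vapply(ref_t, function(r) draw1(setdiff(c("A", "C", "G", "T"), r)),
                    character(1), USE.NAMES = FALSE)
    truth <- data.frame(chrom = ts$chrom, pos = ts$pos, ref = ref_t, alt = alt_t,
                        depth = as.integer(depth_fun(truth_n)),
                        stringsAsFactors = FALSE)

    keep_a <- runif(truth_n) >= fn_rate_a
    keep_b <- runif(truth_n) >= fn_rate_b

    # Candidate (non-variant) positions visited independently by each caller.
    n_cand <- total - truth_n
    fp_records <- function(rate_a, rate_b) {
      if (n_cand <= 0 || (rate_a == 0 && rate_b == 0)) {
        return(list(a = integer(0), b = integer(0)))
      }
      hit_a <- which(runif(n_cand) < rate_a)
      hit_b <- which(runif(n_cand) < rate_b)
      list(a = hit_a, b = hit_b)
    }
    fps <- fp_records(fp_rate_a, fp_rate_b)
    cand_idx <- setdiff(seq_len(total), truth_idx)  # candidate index -> linear
    fp_union <- sort(unique(c(fps$a, fps$b)))
    fp_lin <- cand_idx[fp_union]
    fs <- linear_to_site(fp_lin)
    ref_f <- base_at(fs$chrom, fs$pos) %||%
      sample(c("A", "C", "G", "T"), length(fp_lin), replace = TRUE)
    fp_tab <- data.frame(chrom = fs$chrom, pos = fs$pos, ref = ref_f,
                         alt = unname(transition[ref_f]),
                         stringsAsFactors = FALSE)
    rownames(fp_tab) <- as.character(fp_union)

    make_callset <- function(keep, fp_hits, tag) {
      tp <- truth[keep, c("chrom", "pos", "ref", "alt")]
      fp <- fp_tab[as.character(fp_hits), , drop = FALSE]
      cs <- rbind(tp, fp)
      cs$depth <- as.integer(depth_fun(nrow(cs)))
      cs$caller <- tag
      cs <- cs[order(cs$chrom, cs$pos), ]
      rownames(cs) <- NULL
      cs
    }
    list(
      truth = truth,
      calls_a = make_callset(keep_a, fps$a, "A"),
      calls_b = make_callset(keep_b, fps$b, "B"),
      n_candidates = n_cand
    )
  })
}
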