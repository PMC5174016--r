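#' Configuration for whole-ecosystem read-pair simulation
#'
#' @param host_fraction expected fraction of read pairs of host origin, in
#'   `[0, 1]`. The study's sample groups motivate the defaults used by the
#'   demo dataset: 0.7 for healthy ("H") hosts and 0.45 for caries-active
#'   ("C") hosts, i.e. microbial fractions of roughly 30 and 50-60 percent.
#' @param n_read_pairs number of read pairs to simulate (>= 1).
#' @param crossmap_rate probability that a pair's mapping-quality signature
#'   is swapped between origins (host pair looks microbial or vice versa);
#'   this makes the expected error rate of the MAPQ partition rule exactly
#'   `crossmap_rate`.
#' @param host_mapq MAPQ emitted for a confidently host-mapped mate
#'   (default 150, above the partition threshold of 100).
#' @param seed integer seed.
#' @return An `ecosystem_config` list.
#' @export
ecosystem_config <- function(host_fraction, n_read_pairs,
                             crossmap_rate = 0, host_mapq = 150L, seed = 1L) {
  host_fraction <- assert_proportion(host_fraction, "host_fraction")
  n_read_pairs <- assert_positive_int(n_read_pairs, "n_read_pairs")
  crossmap_rate <- assert_proportion(crossmap_rate, "crossmap_rate")
  structure(
    list(host_fraction = host_fraction, n_read_pairs = n_read_pairs,
         crossmap_rate = crossmap_rate, host_mapq = as.integer(host_mapq),
         seed = as.integer(seed)),
    class = "ecosystem_config"
  )
}

#' Simulate paired-read alignment records with known origin
#'
#' Each read pair is assigned a true origin (host or one of the community
#' genomes) by a multinomial draw with probabilities
#' `(host_fraction, (1 - host_fraction) * abundance)`. Mapping qualities
#' against the host genome follow a two-point mixture: a host pair emits
#' both mates at `host_mapq` (above the 100 threshold) with probability
#' `1 - crossmap_rate`, otherwise both mates uniform on 0..100; a microbial
#' pair does the reverse. Under this model the ">100 on both mates" rule
#' misclassifies a pair with probability exactly `crossmap_rate`.
#'
#' @param cfg an [ecosystem_config()].
#' @param abundance named numeric vector of genome relative abundances
#'   (a `community$abundance`); may be omitted when `host_fraction = 1`.
#' @return A list with `alignments` (data frame: `read_id`, `mapq1`,
#'   `mapq2`, `target` — genome id for microbial pairs, `NA` for host) and
#'   `truth` (data frame: `read_id`, `origin` with value `"host"` or a
#'   genome id).
#' @export
simulate_read_pairs <- function(cfg, abundance = NULL) {
  stopifnot(inherits(cfg, "ecosystem_config"))
  if (is.null(abundance)) {
    if (cfg$host_fraction < 1) {
      stop("`abundance` is required when host_fraction < 1", call. = FALSE)
    }
    abundance <- numeric(0)
  }
  n <- cfg$n_read_pairs
  origins_space <- c("host", names(abundance))
  probs <- c(cfg$host_fraction, (1 - cfg$host_fraction) * abundance / max(sum(abundance), 1e-300))

  withr::with_seed(cfg$seed, {
    origin <- if (length(origins_space) == 1L) rep("host", n) else {
      origins_space[sample.int(length(origins_space), n, replace = TRUE, prob = probs)]
    }
    is_host <- origin == "host"
    swapped <- runif(n) < cfg$crossmap_rate
    high <- is_host != swapped   # pairs that emit the above-threshold signature
    mapq1 <- integer(n); mapq2 <- integer(n)
    mapq1[high] <- cfg$host_mapq
    mapq2[high] <- cfg$host_mapq
    nlow <- sum(!high)
    mapq1[!high] <- sample(0:100, nlow, replace = TRUE)
    mapq2[!high] <- sample(0:100, nlow, replace = TRUE)

    read_id <- sprintf("rp%07d", seq_len(n))
    list(
      alignments = data.frame(
        read_id = read_id, mapq1 = mapq1, mapq2 = mapq2,
        target = ifelse(is_host, NA_character_, origin),
        stringsAsFactors = FALSE
      ),
      truth = data.frame(read_id = read_id, origin = origin, stringsAsFactors = FALSE)
    )
  })
}
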