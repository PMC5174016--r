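#' Partition paired reads into host- and microbiota-originating sets
#'
#' Applies the whole-ecosystem host-depletion rule: a read pair whose two
#' mates both have mapping quality against the host genome strictly
#' exceeding `threshold` (default 100) is labelled host-originating; every
#' other pair is labelled microbiota-originating. "Exceeding" is strict, so
#' a mate at exactly the threshold fails the rule. Pairs with a missing mate
#' (`NA` MAPQ) are treated as MAPQ 0 for that mate: absent evidence fails
#' the both-mates requirement and the pair is labelled microbial.
#'
#' @param pairs data frame with columns `read_id`, `mapq1`, `mapq2`
#'   (non-negative integers; `NA` = unmapped mate). Extra columns ignored.
#' @param threshold non-negative integer MAPQ cutoff (default 100).
#' @return A `partition_result`: list with `host_ids`, `microbial_ids`
#'   (disjoint, jointly exhaustive character vectors), `host_fraction`,
#'   `microbial_fraction` (summing to 1 for non-empty input; `NA` when
#'   empty) and `n`.
#' @examples
#' p <- data.frame(read_id = c("r1", "r2"), mapq1 = c(120, 100), mapq2 = c(105, 150))
#' partition_read_pairs(p)$host_ids  # "r1": 100 is not > 100
#' @export
partition_read_pairs <- function(pairs, threshold = 100L) {
  stopifnot(is.data.frame(pairs), all(c("read_id", "mapq1", "mapq2") %in% names(pairs)))
  threshold <- assert_positive_int(threshold, "threshold", allow_zero = TRUE)
  dup <- pairs$read_id[duplicated(pairs$read_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate read_id(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  m1 <- pairs$mapq1; m2 <- pairs$mapq2
  if (any(m1 < 0, na.rm = TRUE) || any(m2 < 0, na.rm = TRUE)) {
    stop("negative MAPQ values are not allowed", call. = FALSE)
  }
  m1[is.na(m1)] <- 0L
  m2[is.na(m2)] <- 0L

  is_host <- m1 > threshold & m2 > threshold
  n <- nrow(pairs)
  structure(
    list(
      host_ids = pairs$read_id[is_host],
      microbial_ids = pairs$read_id[!is_host],
      host_fraction = if (n > 0) sum(is_host) / n else NA_real_,
      microbial_fraction = if (n > 0) sum(!is_host) / n else NA_real_,
      n = n,
      threshold = threshold
    ),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition_result: %d pairs, host %.1f%%, microbial %.1f%% (MAPQ > %d on both mates)\n",
              x$n, 100 * x$host_fraction, 100 * x$microbial_fraction, x$threshold))
  invisible(x)
}

#' Compare a partition against simulation ground truth
#'
#' Scores the host/microbial labelling against known per-read origins,
#' treating "host" as the positive class.
#'
#' @param result a `partition_result`.
#' @param truth data frame with columns `read_id` and `origin` (`"host"` or
#'   a genome id); must cover every partitioned read.
#' @return List with `tp`, `fp`, `fn`, `tn`, `n`, `error_rate`
#'   (misclassified fraction; `NA` with `undefined = TRUE` on empty input).
#' @export
recovery_report <- function(result, truth) {
  stopifnot(inherits(result, "partition_result"), is.data.frame(truth),
            all(c("read_id", "origin") %in% names(truth)))
  ids <- c(result$host_ids, result$microbial_ids)
  missing <- setdiff(ids, truth$read_id)
  if (length(missing) > 0) {
    stop(sprintf("read id(s) missing from truth: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  origin <- truth$origin[match(ids, truth$read_id)]
  pred_host <- c(rep(TRUE, length(result$host_ids)),
                 rep(FALSE, length(result$microbial_ids)))
  true_host <- origin == "host"
  tp <- sum(pred_host & true_host)
  fp <- sum(pred_host & !true_host)
  fn <- sum(!pred_host & true_host)
  tn <- sum(!pred_host & !true_host)
  n <- length(ids)
  list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
       error_rate = if (n > 0) (fp + fn) / n else NA_real_,
       undefined = n == 0)
}
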