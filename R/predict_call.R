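# Read-level prediction, paired-probability filtering, and site-level calling
# with the two-step false-positive control (a conservative read-probability
# threshold, then coverage and modification-rate cutoffs per site).

#' Read-level modification predictions
#'
#' One prediction per instance: the softmax probability of the modified class
#' plus a provisional hard label at `read_threshold` (0.5 at this stage; the
#' conservative 0.95 threshold belongs to site calling, see [call_sites()]).
#'
#' @param model A fitted `poremod_model`.
#' @param instances A `poremod_instances` object.
#' @param read_threshold Probability at or above which the provisional label
#'   is `"modified"`.
#' @return Data frame: `read_id`, `transcript_id`, `position` (0-based),
#'   `motif`, `prob_modified`, `hard_label`.
#' @export
predict_reads <- function(model, instances, read_threshold = 0.5) {
  stopifnot(inherits(model, "poremod_model"),
            inherits(instances, "poremod_instances"))
  p <- predict(model, instances)[, "modified"]
  data.frame(read_id = instances$meta$read_id,
             transcript_id = instances$meta$transcript_id,
             position = instances$meta$position,
             motif = instances$meta$motif,
             prob_modified = p,
             hard_label = ifelse(p >= read_threshold, "modified", "unmodified"),
             stringsAsFactors = FALSE)
}

#' Paired probability cutoff
#'
#' Reads with probability strictly below `low` are labeled unmodified, those
#' strictly above `high` modified, and the uncertain middle (including values
#' exactly at either cutoff, unless `low == high`) is discarded. The
#' degenerate pair (0.5, 0.5) reduces to plain thresholding with nothing
#' discarded.
#'
#' @param preds Prediction data frame from [predict_reads()].
#' @param low,high Cutoffs with `0 < low <= high < 1`.
#' @return List with `predictions` (retained rows, relabeled), `n_discarded`
#'   and `n_total`.
#' @examples
#' # probabilities 0.05 / 0.5 / 0.95 with cutoffs (0.1, 0.9):
#' # unmodified, discarded, modified
#' @export
apply_paired_cutoff <- function(preds, low = 0.1, high = 0.9) {
  check_scalar(low, "low")
  check_scalar(high, "high")
  if (low > high) stop("`low` must be <= `high`", call. = FALSE)
  if (low <= 0 || high >= 1) stop("cutoffs must lie strictly inside (0, 1)", call. = FALSE)
  p <- preds$prob_modified
  if (low == high) {
    lab <- ifelse(p >= low, "modified", "unmodified")
    out <- preds
    out$hard_label <- lab
    return(list(predictions = out, n_discarded = 0L, n_total = nrow(preds)))
  }
  lab <- rep(NA_character_, length(p))
  lab[p < low] <- "unmodified"
  lab[p > high] <- "modified"
  keep <- !is.na(lab)
  out <- preds[keep, , drop = FALSE]
  out$hard_label <- lab[keep]
  rownames(out) <- NULL
  list(predictions = out, n_discarded = sum(!keep), n_total = nrow(preds))
}

#' Aggregate read predictions into site-level calls
#'
#' Per (transcript, position): coverage `n` is the number of retained reads, a
#' read counts as modified when its probability is at least `read_threshold`
#' (0.95 by default, deliberately conservative), and the modification rate is
#' `k/n`. A site passes the false-positive control when it has more than
#' `min_reads` supporting reads (strictly) and a rate of at least `min_rate`.
#' All sites are emitted with their `passed` flag. A read contributing several
#' instances at one site keeps only its highest-probability instance.
#'
#' @param preds Prediction data frame ([predict_reads()], possibly filtered by
#'   [apply_paired_cutoff()]).
#' @param read_threshold Inclusive per-read probability threshold.
#' @param min_reads Minimum coverage, exclusive (`n > min_reads`).
#' @param min_rate Minimum modification rate, inclusive.
#' @return Data frame: `transcript_id`, `position`, `motif`, `coverage`,
#'   `modified_count`, `rate`, `passed`.
#' @export
call_sites <- function(preds, read_threshold = 0.95, min_reads = 10L,
                       min_rate = 0.2) {
  check_scalar(read_threshold, "read_threshold")
  if (nrow(preds) == 0L) {
    return(data.frame(transcript_id = character(), position = integer(),
                      motif = character(), coverage = integer(),
                      modified_count = integer(), rate = numeric(),
                      passed = logical(), stringsAsFactors = FALSE))
  }
  # deduplicate multiple instances of one read at one site: keep max prob
  ord <- order(preds$transcript_id, preds$position, preds$read_id,
               -preds$prob_modified)
  p <- preds[ord, , drop = FALSE]
  dup <- duplicated(p[, c("transcript_id", "position", "read_id")])
  p <- p[!dup, , drop = FALSE]

  key <- paste(p$transcript_id, p$position)
  first <- !duplicated(key)
  n <- as.vector(tapply(rep(1L, nrow(p)), key, sum)[key[first]])
  k <- as.vector(tapply(p$prob_modified >= read_threshold, key, sum)[key[first]])
  out <- data.frame(transcript_id = p$transcript_id[first],
                    position = p$position[first],
                    motif = p$motif[first],
                    coverage = as.integer(n),
                    modified_count = as.integer(k),
                    rate = k / n,
                    stringsAsFactors = FALSE)
  out$passed <- out$coverage > min_reads & out$rate >= min_rate
  out <- out[order(out$transcript_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
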