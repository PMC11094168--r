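# Evaluation metrics (ROC/PR AUC via the rank formulation), Fisher's exact
# test for differential modification between conditions, stoichiometry-error
# summaries, and per-base feature-importance probing of a trained model.

#' ROC-AUC and PR-AUC
#'
#' ROC-AUC is computed with the rank (Mann-Whitney) formulation including tie
#' correction; PR-AUC by step integration of the precision-recall curve over
#' distinct score thresholds.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical (or 0/1) vector of true classes.
#' @return List with `roc_auc` and `pr_auc`.
#' @export
roc_pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be equal-length and free of NA", call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute ROC/PR AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  roc_auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # precision-recall over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord])
  fp <- cumsum(!labels[ord])
  # keep the last index of each tied block of scores
  s_ord <- scores[ord]
  block_end <- c(s_ord[-1L] != s_ord[-length(s_ord)], TRUE)
  tp <- tp[block_end]
  fp <- fp[block_end]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  pr_auc <- sum(diff(c(0, rec)) * prec)
  list(roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' The point probability of a table with cells `a, b / c, d` (rows =
#' conditions, columns = modified/unmodified) is the hypergeometric
#' `choose(a+b, a) * choose(c+d, c) / choose(a+b+c+d, a+c)`. The two-sided
#' p-value sums, over all tables with the same margins, the point
#' probabilities not exceeding the observed one (with a small relative
#' tolerance for floating-point ties); everything is computed in log space.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` may also be a length-4
#'   vector or 2 x 2 matrix.
#' @return List with `p_value` (two-sided) and `point_prob`.
#' @examples
#' fisher_exact(5, 5, 5, 5)$p_value        # 1
#' fisher_exact(1, 9, 9, 1)$point_prob     # 100 / 184756
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    x <- as.integer(a)
    if (length(x) != 4L) stop("expected 4 cell counts", call. = FALSE)
    a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  log_point <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  obs <- log_point(a)
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- log_point(support)
  keep <- lp <= obs + log(1 + 1e-7)
  p <- sum(exp(lp[keep]))
  list(p_value = min(1, p), point_prob = exp(obs))
}

#' Differential modification between two conditions
#'
#' For every site called in both conditions, a 2 x 2 table of (modified,
#' unmodified) read counts per condition is tested with [fisher_exact()].
#' Direction is the sign of `rateB - rateA`. No multiple-testing correction is
#' applied by default; Benjamini-Hochberg is available.
#'
#' @param sitesA,sitesB Site-call data frames from [call_sites()] for the two
#'   conditions.
#' @param alpha Significance level applied to the (possibly adjusted) p-value.
#' @param correction `"none"` (default) or `"BH"`.
#' @return Data frame: `transcript_id`, `position`, `motif`, `rateA`, `rateB`,
#'   `p_value`, `significant`, `direction` (-1, 0, 1).
#' @export
differential_sites <- function(sitesA, sitesB, alpha = 0.05,
                               correction = c("none", "BH")) {
  correction <- match.arg(correction)
  keyA <- paste(sitesA$transcript_id, sitesA$position)
  keyB <- paste(sitesB$transcript_id, sitesB$position)
  shared <- intersect(keyA, keyB)
  if (length(shared) == 0L) {
    warning("no shared sites between the two conditions")
    return(data.frame(transcript_id = character(), position = integer(),
                      motif = character(), rateA = numeric(),
                      rateB = numeric(), p_value = numeric(),
                      significant = logical(), direction = integer(),
                      stringsAsFactors = FALSE))
  }
  ia <- match(shared, keyA)
  ib <- match(shared, keyB)
  p <- mapply(function(kA, nA, kB, nB) {
    fisher_exact(kA, nA - kA, kB, nB - kB)$p_value
  }, sitesA$modified_count[ia], sitesA$coverage[ia],
     sitesB$modified_count[ib], sitesB$coverage[ib])
  padj <- if (correction == "BH") stats::p.adjust(p, "BH") else p
  rateA <- sitesA$rate[ia]
  rateB <- sitesB$rate[ib]
  out <- data.frame(transcript_id = sitesA$transcript_id[ia],
                    position = sitesA$position[ia],
                    motif = sitesA$motif[ia],
                    rateA = rateA, rateB = rateB, p_value = p,
                    significant = padj < alpha,
                    direction = as.integer(sign(rateB - rateA)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Stoichiometry recovery error
#'
#' Compares called per-site modification rates with ground-truth rates:
#' Pearson correlation, per-site errors (called minus truth), and the mean
#' absolute error grouped by truth level.
#'
#' @param called Numeric vector of called rates.
#' @param truth Numeric vector of true rates, matched to `called`.
#' @return List with `pearson_r`, `errors`, `mae_by_level` (named by truth
#'   level).
#' @export
stoichiometry_error <- function(called, truth) {
  if (length(called) != length(truth)) {
    stop("`called` and `truth` must have equal length", call. = FALSE)
  }
  errors <- called - truth
  r <- if (stats::sd(called) == 0 || stats::sd(truth) == 0) {
    NA_real_
  } else {
    stats::cor(called, truth)
  }
  mae <- tapply(abs(errors), truth, mean)
  list(pearson_r = r, errors = errors,
       mae_by_level = stats::setNames(as.numeric(mae), names(mae)))
}

#' Per-base feature importance by zero-ablation
#'
#' For each of the 5 window bases, all of that base's inputs (its `l`
#' resampled current values and its 6 base-level values) are set to 0 and the
#' instances re-scored; the importance of the base is the drop in accuracy
#' relative to the unablated baseline (hard labels at 0.5). Returns the 5
#' deltas in 5' to 3' order (positions -2..+2 around the center).
#'
#' @param model A fitted `poremod_model`.
#' @param instances Labeled `poremod_instances`.
#' @return Named numeric vector of length 5.
#' @export
feature_importance <- function(model, instances) {
  stopifnot(inherits(model, "poremod_model"),
            inherits(instances, "poremod_instances"))
  y <- instance_labels(instances)
  l <- model$spec$l
  if (ncol(instances$current) != 5L * l) {
    stop("instance shape does not match the model spec", call. = FALSE)
  }
  acc <- function(cur, base) {
    p <- forward_prob(model$params, model$spec, cur, base)
    mean((p >= 0.5) == (y == 2L))
  }
  baseline <- acc(instances$current, instances$base)
  deltas <- numeric(5L)
  for (bpos in 1:5) {
    cur <- instances$current
    base <- instances$base
    cur[, ((bpos - 1L) * l + 1L):(bpos * l)] <- 0
    base[, ((bpos - 1L) * 6L + 1L):(bpos * 6L)] <- 0
    deltas[bpos] <- baseline - acc(cur, base)
  }
  stats::setNames(deltas, c("-2", "-1", "0", "+1", "+2"))
}
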