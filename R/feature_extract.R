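# Feature extraction: per-read signal normalization, per-base statistics,
# linear-spline resampling to a fixed length, and assembly of 5-mer window
# instances (5 * l resampled current values + 30 base-level values).

#' Normalize the raw current samples of one read
#'
#' Normalization is applied per read over all of its samples at once (events
#' concatenated), which removes per-molecule/device current drift before any
#' event is sliced out. Three methods are supported; median/MAD ("mmad") is the
#' default used throughout the package. The MAD is the plain median absolute
#' deviation, without the 1.4826 normal-consistency constant.
#'
#' @param x Numeric vector: all raw current samples of one read (length >= 2,
#'   all finite).
#' @param method One of `"mmad"`, `"minmax"`, `"zscore"`.
#' @return Normalized numeric vector of the same length.
#' @examples
#' normalize_read(c(1, 2, 3, 4, 100))  # median 3, MAD 1
#' @export
normalize_read <- function(x, method = c("mmad", "minmax", "zscore")) {
  method <- match.arg(method)
  if (length(x) < 2L) stop("a read must have at least 2 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite current sample in read", call. = FALSE)
  switch(method,
    mmad = {
      med <- stats::median(x)
      mad0 <- stats::median(abs(x - med))
      if (mad0 == 0) {
        stop("degenerate read: median absolute deviation is 0", call. = FALSE)
      }
      (x - med) / mad0
    },
    minmax = {
      rng <- range(x)
      if (rng[1] == rng[2]) stop("degenerate read: constant signal", call. = FALSE)
      (x - rng[1]) / (rng[2] - rng[1])
    },
    zscore = {
      s <- stats::sd(x)
      if (s == 0) stop("degenerate read: zero standard deviation", call. = FALSE)
      (x - mean(x)) / s
    }
  )
}

#' Resample an event's samples to a fixed length
#'
#' First-order (linear) spline interpolation through the samples placed at
#' equally spaced knots, evaluated at `l` equally spaced points including both
#' endpoints, so the first and last values are preserved exactly. A
#' single-sample event is duplicated to length 2 rather than rejected, since
#' real resquiggles do emit 1-sample events.
#'
#' @param x Numeric vector of raw (or normalized) samples for one base.
#' @param l Target length (>= 2), 100 by default.
#' @return Numeric vector of length `l`.
#' @examples
#' resample_signal(c(0, 1), l = 5)  # 0, 0.25, 0.5, 0.75, 1
#' @export
resample_signal <- function(x, l = 100L) {
  if (l < 2L) stop("`l` must be >= 2", call. = FALSE)
  if (length(x) == 1L) x <- c(x, x)
  k <- length(x)
  stats::approx(x = seq(0, 1, length.out = k), y = x,
                xout = seq(0, 1, length.out = l))$y
}

#' Per-base signal statistics
#'
#' Summary features of one base's normalized signal slice: mean, population
#' standard deviation (divisor n), median, dwell (number of raw samples), the
#' basecall quality, and the integer-encoded reference base (A=0, C=1, G=2,
#' U=3).
#'
#' @param slice Numeric vector, the normalized samples of one base (non-empty).
#' @param base_quality Phred-scale quality of the base.
#' @param ref_base Reference base, one of A/C/G/U.
#' @return Named list with `mean`, `std`, `median`, `dwell`, `base_quality`,
#'   `base_code`.
#' @export
per_base_stats <- function(slice, base_quality, ref_base) {
  if (length(slice) == 0L) stop("empty signal slice", call. = FALSE)
  m <- mean(slice)
  list(mean = m,
       std = sqrt(mean((slice - m)^2)),
       median = stats::median(slice),
       dwell = length(slice),
       base_quality = base_quality,
       base_code = match(ref_base, RNA_BASES) - 1L)
}

#' Drop reads with too few aligned bases
#'
#' Classifier accuracy degrades on short reads (their signal quality is lower
#' at both ends), so a minimum aligned length of 600 bases is the recommended
#' default for real data. A cutoff of 0 is the identity.
#'
#' @param events Event data frame.
#' @param min_length Minimum number of aligned bases per read.
#' @return The filtered event data frame.
#' @export
filter_reads <- function(events, min_length = 600L) {
  if (min_length <= 0L || nrow(events) == 0L) return(events)
  counts <- table(events$read_id)
  keep <- names(counts)[counts >= min_length]
  out <- events[events$read_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_instances <- function(meta, current, base, l) {
  structure(list(meta = meta, current = current, base = base, l = as.integer(l)),
            class = "poremod_instances")
}

#' @export
print.poremod_instances <- function(x, ...) {
  labs <- table(x$meta$label, useNA = "ifany")
  cat(sprintf("poremod instances: %d windows (5 x %d current + %d base values)\n",
              nrow(x$meta), x$l, ncol(x$base)))
  if (nrow(x$meta)) {
    cat("  labels:", paste(sprintf("%s=%d", names(labs), labs), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset or combine instance sets
#'
#' @param x,... `poremod_instances` objects (`...` for [combine_instances()]).
#' @param i Index vector of windows to keep.
#' @return A `poremod_instances` object.
#' @export
subset_instances <- function(x, i) {
  stopifnot(inherits(x, "poremod_instances"))
  new_instances(x$meta[i, , drop = FALSE],
                x$current[i, , drop = FALSE],
                x$base[i, , drop = FALSE], x$l)
}

#' @rdname subset_instances
#' @export
combine_instances <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, logical(1L), "poremod_instances")))
  ls <- unique(vapply(xs, `[[`, integer(1L), "l"))
  if (length(ls) != 1L) stop("instance sets have different resample lengths", call. = FALSE)
  meta <- do.call(rbind, lapply(xs, `[[`, "meta"))
  rownames(meta) <- NULL
  new_instances(meta,
                do.call(rbind, lapply(xs, `[[`, "current")),
                do.call(rbind, lapply(xs, `[[`, "base")), ls)
}

#' Assemble 5-mer window instances from per-read events
#'
#' For every interior base with two aligned flanking bases on each side (and
#' no gap in the read's aligned positions across the window), one model
#' instance is emitted: the 5 bases' resampled signals concatenated 5' to 3'
#' (`5 * l` values) plus 6 base-level values per base (base code, quality,
#' mean, std, median, dwell; 30 values). Normalization happens once per read
#' over all of its samples; reads containing non-finite samples or with a
#' degenerate (constant) signal are skipped with a warning. Scaling into the
#' base vector: base code / 3, quality / `quality_cap`, dwell capped at
#' `dwell_cap` and divided by it; mean/std/median stay on the normalized
#' signal scale.
#'
#' @param events Event data frame ([simulate_reads()] / [read_event_table()]).
#' @param reference Named character vector of transcript sequences.
#' @param normalization Signal normalization method, see [normalize_read()].
#' @param l Resampled samples per base (default 100, giving 500 current values).
#' @param min_read_length Optional minimum aligned read length; `NULL` skips
#'   the filter (windows still need 5 consecutive bases).
#' @param labels `NULL` (unlabeled), a single string applied to every window
#'   (`"modified"`/`"unmodified"`), or a truth data frame
#'   (`read_id`, `transcript_id`, `position`, `modified`) to join per window.
#' @param center_base Optional base letter; only windows centered on that base
#'   are kept (e.g. `"C"` when training an m5C model).
#' @param dwell_cap,quality_cap Scaling caps for dwell and quality.
#' @return A `poremod_instances` object.
#' @export
extract_features <- function(events, reference,
                             normalization = c("mmad", "minmax", "zscore"),
                             l = 100L, min_read_length = NULL, labels = NULL,
                             center_base = NULL, dwell_cap = 200L,
                             quality_cap = 40) {
  normalization <- match.arg(normalization)
  if (!is.null(min_read_length)) events <- filter_reads(events, min_read_length)
  n_ev <- nrow(events)
  if (n_ev == 0L) {
    return(new_instances(
      data.frame(read_id = character(), transcript_id = character(),
                 position = integer(), motif = character(),
                 label = character(), stringsAsFactors = FALSE),
      matrix(numeric(), 0L, 5L * l), matrix(numeric(), 0L, 30L), l))
  }
  if (!is.null(center_base)) center_base <- match.arg(center_base, RNA_BASES)

  truth_key <- NULL
  if (is.data.frame(labels)) {
    truth_key <- paste(labels$read_id, labels$transcript_id, labels$position)
  }

  r <- rle(events$read_id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_meta <- vector("list", length(r$values))
  out_cur <- vector("list", length(r$values))
  out_base <- vector("list", length(r$values))

  for (g in seq_along(r$values)) {
    rows <- starts[g]:ends[g]
    read_id <- r$values[g]
    tx <- events$transcript_id[rows[1L]]
    if (!tx %in% names(reference)) {
      stop(sprintf("transcript '%s' not found in reference", tx), call. = FALSE)
    }
    seq <- reference[[tx]]
    tx_len <- nchar(seq)
    pos <- events$position[rows]
    samples <- events$samples[rows]
    raw <- unlist(samples, use.names = FALSE)
    if (any(!is.finite(raw))) {
      warning(sprintf("read '%s' skipped: non-finite current sample", read_id))
      next
    }
    norm <- tryCatch(normalize_read(raw, normalization), error = function(e) e)
    if (inherits(norm, "error")) {
      warning(sprintf("read '%s' skipped: %s", read_id, conditionMessage(norm)))
      next
    }
    dwell <- lengths(samples)
    slices <- unname(split(norm, rep.int(seq_along(rows), dwell)))
    nb <- length(rows)
    if (nb < 5L) next

    resampled <- matrix(0, nb, l)
    for (j in seq_len(nb)) resampled[j, ] <- resample_signal(slices[[j]], l)
    means <- vapply(slices, mean, numeric(1L))
    stds <- vapply(slices, function(s) sqrt(mean((s - mean(s))^2)), numeric(1L))
    medians <- vapply(slices, stats::median, numeric(1L))
    codes <- match(events$ref_base[rows], RNA_BASES) - 1L
    qual <- events$base_quality[rows]

    centers <- 3:(nb - 2L)
    contiguous <- vapply(centers, function(j) {
      all(pos[(j - 2L):(j + 2L)] == pos[j] + (-2L:2L))
    }, logical(1L))
    in_ref <- pos[centers] >= 2L & pos[centers] <= tx_len - 3L
    keep <- centers[contiguous & in_ref]
    if (!is.null(center_base)) {
      keep <- keep[events$ref_base[rows[keep]] == center_base]
    }
    if (length(keep) == 0L) next

    motifs <- substring(seq, pos[keep] - 1L, pos[keep] + 3L)
    mismatch <- substring(motifs, 3L, 3L) != events$ref_base[rows[keep]]
    if (any(mismatch)) {
      stop(sprintf("read '%s': ref_base disagrees with reference at position %d",
                   read_id, pos[keep][which(mismatch)[1L]]), call. = FALSE)
    }

    cur <- matrix(0, length(keep), 5L * l)
    basev <- matrix(0, length(keep), 30L)
    for (w in seq_along(keep)) {
      idx <- (keep[w] - 2L):(keep[w] + 2L)
      cur[w, ] <- as.vector(t(resampled[idx, , drop = FALSE]))
      basev[w, ] <- as.vector(rbind(codes[idx] / 3,
                                    qual[idx] / quality_cap,
                                    means[idx],
                                    stds[idx],
                                    medians[idx],
                                    pmin(dwell[idx], dwell_cap) / dwell_cap))
    }
    lab <- if (is.null(labels)) {
      NA_character_
    } else if (is.character(labels) && length(labels) == 1L) {
      rep(labels, length(keep))
    } else {
      key <- paste(read_id, tx, pos[keep])
      m <- match(key, truth_key)
      ifelse(is.na(m), NA_character_,
             ifelse(labels$modified[m], "modified", "unmodified"))
    }
    out_meta[[g]] <- data.frame(read_id = read_id, transcript_id = tx,
                                position = pos[keep], motif = motifs,
                                label = lab, stringsAsFactors = FALSE)
    out_cur[[g]] <- cur
    out_base[[g]] <- basev
  }

  keep_g <- !vapply(out_meta, is.null, logical(1L))
  if (!any(keep_g)) {
    return(new_instances(
      data.frame(read_id = character(), transcript_id = character(),
                 position = integer(), motif = character(),
                 label = character(), stringsAsFactors = FALSE),
      matrix(numeric(), 0L, 5L * l), matrix(numeric(), 0L, 30L), l))
  }
  meta <- do.call(rbind, out_meta[keep_g])
  rownames(meta) <- NULL
  new_instances(meta, do.call(rbind, out_cur[keep_g]),
                do.call(rbind, out_base[keep_g]), l)
}
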