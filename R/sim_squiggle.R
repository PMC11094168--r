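#' Build a synthetic 5-mer pore model
#'
#' A pore model assigns every 5-mer over the RNA alphabet a baseline current
#' level (in normalized units). Real nanopore current is determined by roughly
#' five bases residing in the pore at a time; the simulator reproduces that
#' sequence dependence with seeded random levels spanning a fixed range, so
#' that downstream normalization, feature extraction and classification can be
#' exercised against known ground truth.
#'
#' @param seed Integer seed; identical seeds give byte-identical level tables.
#' @param noise_sd Within-event Gaussian noise standard deviation (> 0).
#' @param dwell_mean Expected number of raw current samples per base (>= 2).
#' @param level_range Numeric length-2 range spanned by the 5-mer levels.
#'
#' @return An object of class `pore_model`: a list with `level_table` (named
#'   numeric of length 1024), `noise_sd`, `dwell_mean` and `seed`.
#' @examples
#' pore <- make_pore_model(seed = 1)
#' length(pore$level_table)  # 1024
#' @export
make_pore_model <- function(seed = 1L, noise_sd = 0.35, dwell_mean = 8,
                            level_range = c(-2, 2)) {
  check_scalar(noise_sd, "noise_sd", positive = TRUE)
  check_scalar(dwell_mean, "dwell_mean", min = 2)
  kmers <- all_kmers(5L)
  levels <- with_seed(seed, stats::runif(length(kmers),
                                         min = level_range[1],
                                         max = level_range[2]))
  names(levels) <- kmers
  structure(
    list(level_table = levels, noise_sd = noise_sd,
         dwell_mean = dwell_mean, seed = as.integer(seed)),
    class = "pore_model"
  )
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf(
    "Synthetic pore model: %d 5-mers, levels in [%.2f, %.2f], noise_sd = %.3g, dwell_mean = %.3g (seed %d)\n",
    length(x$level_table), min(x$level_table), max(x$level_table),
    x$noise_sd, x$dwell_mean, x$seed))
  invisible(x)
}

#' Describe the signal effect of a modification
#'
#' Modified bases perturb the nanopore signal of the base in the pore center:
#' a shift of the mean current level, a multiplicative change of the sample
#' noise, a multiplicative change of the dwell time, and a shift of the
#' basecalled quality. Directions differ between modification types in real
#' data (e.g. most methylations raise the mean level; some raise and some
#' lower the signal spread and dwell), so all four knobs are signed/free.
#'
#' @param mean_shift Added to the 5-mer level when the center base is modified.
#' @param sd_factor Positive multiplier on the within-event noise sd.
#' @param dwell_factor Positive multiplier on the expected dwell.
#' @param quality_shift Added to the phred base quality of modified bases
#'   (result clamped at 1).
#'
#' @return An object of class `mod_effect`.
#' @export
mod_effect <- function(mean_shift = 2, sd_factor = 1.25, dwell_factor = 1.3,
                       quality_shift = -2) {
  check_scalar(mean_shift, "mean_shift")
  check_scalar(sd_factor, "sd_factor", positive = TRUE)
  check_scalar(dwell_factor, "dwell_factor", positive = TRUE)
  check_scalar(quality_shift, "quality_shift")
  structure(
    list(mean_shift = mean_shift, sd_factor = sd_factor,
         dwell_factor = dwell_factor, quality_shift = quality_shift),
    class = "mod_effect"
  )
}

#' @export
print.mod_effect <- function(x, ...) {
  cat(sprintf(
    "Modification effect: mean %+0.3g, sd x%.3g, dwell x%.3g, quality %+0.3g\n",
    x$mean_shift, x$sd_factor, x$dwell_factor, x$quality_shift))
  invisible(x)
}

#' Generate composition-balanced synthetic reference transcripts
#'
#' Random transcripts with an exactly balanced base composition (each of
#' A/C/G/U makes up one quarter of every transcript, up to rounding), so that
#' simulation studies get a predictable number of candidate modification
#' sites per transcript regardless of the seed.
#'
#' @param n_transcripts Number of transcripts.
#' @param length Length of each transcript in bases.
#' @param seed Integer seed.
#' @return Named character vector (`tx1`, `tx2`, ...).
#' @export
synthetic_reference <- function(n_transcripts = 2L, length = 300L, seed = 1L) {
  stopifnot(n_transcripts >= 1L, length >= 8L)
  base_pool <- rep(RNA_BASES, length.out = length)
  with_seed(seed, {
    out <- vapply(seq_len(n_transcripts), function(i) {
      paste(sample(base_pool), collapse = "")
    }, character(1L))
    names(out) <- sprintf("tx%d", seq_len(n_transcripts))
    out
  })
}

# Shifted-geometric dwell: minimum 2 samples, mean `m` (>= 2).
draw_dwell <- function(n, m) {
  if (m <= 2) return(rep.int(2L, n))
  2L + stats::rgeom(n, prob = 1 / (m - 1))
}

# 5-mer context at every position of a transcript, edges padded with A.
kmer_context <- function(seq) {
  padded <- paste0("AA", seq, "AA")
  n <- nchar(seq)
  substring(padded, seq_len(n), seq_len(n) + 4L)
}

#' Simulate direct-RNA-sequencing event data with known modification truth
#'
#' Draws reads from reference transcripts and emits one event per covered base:
#' `dwell` raw current samples around the 5-mer level of the pore model, plus a
#' basecall quality. Each read is independently flagged modified with
#' probability `stoichiometry`; in modified reads every occurrence of
#' `mod_base` carries the modification, which perturbs that base's own samples
#' (and thereby, through the shared samples, every 5-mer window overlapping
#' it). A small seeded per-read offset and scale jitter emulates current drift
#' between molecules/devices, so that per-read normalization is non-trivial.
#'
#' @param reference Named character vector of transcript sequences (A/C/G/U;
#'   T accepted), e.g. from [read_fasta()].
#' @param n_reads Number of reads to simulate.
#' @param mod_base The canonical base carrying the modification ("A", "C",
#'   "G" or "U").
#' @param stoichiometry Fraction of modified reads, in `[0, 1]`.
#' @param pore A [make_pore_model()] object.
#' @param effect A [mod_effect()] object.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param full_length If `TRUE` (default) every read covers its whole
#'   transcript; otherwise a contiguous fragment of at least `fragment_min`
#'   bases is drawn uniformly.
#' @param fragment_min Minimum fragment length when `full_length = FALSE`.
#' @param offset_sd,scale_sd Standard deviations of the per-read additive
#'   offset and (log) multiplicative scale jitter emulating current drift;
#'   set both to 0 for jitter-free signal.
#'
#' @return A list with `events` (data frame: `read_id`, `transcript_id`,
#'   0-based `position`, `ref_base`, `base_quality`, and list-column
#'   `samples`) and `truth` (data frame with one row per `mod_base` occurrence
#'   per read: `read_id`, `transcript_id`, `position`, logical `modified`).
#' @examples
#' ref <- c(tx1 = "ACGUACGUACGUACGUACGU")
#' sim <- simulate_reads(ref, n_reads = 3, mod_base = "C",
#'                       stoichiometry = 0.5, seed = 7)
#' nrow(sim$events)
#' @export
simulate_reads <- function(reference, n_reads, mod_base = "C",
                           stoichiometry = 0.5,
                           pore = make_pore_model(),
                           effect = mod_effect(),
                           seed = 1L, full_length = TRUE, fragment_min = 50L,
                           offset_sd = 0.2, scale_sd = 0.05) {
  if (length(reference) == 0L || is.null(names(reference)) ||
      any(!nzchar(names(reference)))) {
    stop("`reference` must be a non-empty named character vector", call. = FALSE)
  }
  if (!is.numeric(stoichiometry) || length(stoichiometry) != 1L ||
      is.na(stoichiometry) || stoichiometry < 0 || stoichiometry > 1) {
    stop("`stoichiometry` must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(pore, "pore_model"), inherits(effect, "mod_effect"))
  mod_base <- match.arg(mod_base, RNA_BASES)
  reference <- as_rna(reference, "reference")
  contexts <- lapply(reference, kmer_context)
  bases <- lapply(reference, function(s) strsplit(s, "", fixed = TRUE)[[1L]])

  ev <- vector("list", n_reads)
  tr <- vector("list", n_reads)
  with_seed(seed, {
    tx_pick <- sample(length(reference), n_reads, replace = TRUE)
    for (i in seq_len(n_reads)) {
      tx <- tx_pick[i]
      tx_id <- names(reference)[tx]
      len <- nchar(reference[[tx]])
      if (full_length || len <= fragment_min) {
        from <- 1L
        to <- len
      } else {
        flen <- sample(fragment_min:len, 1L)
        from <- sample.int(len - flen + 1L, 1L)
        to <- from + flen - 1L
      }
      idx <- from:to
      b <- bases[[tx]][idx]
      read_modified <- stats::runif(1L) < stoichiometry
      is_mod <- read_modified & (b == mod_base)

      mu <- unname(pore$level_table[contexts[[tx]][idx]]) +
        ifelse(is_mod, effect$mean_shift, 0)
      sds <- pore$noise_sd * ifelse(is_mod, effect$sd_factor, 1)
      dwell <- ifelse(is_mod,
                      draw_dwell(length(idx), pore$dwell_mean * effect$dwell_factor),
                      draw_dwell(length(idx), pore$dwell_mean))
      offset <- if (offset_sd > 0) stats::rnorm(1L, 0, offset_sd) else 0
      scale <- if (scale_sd > 0) exp(stats::rnorm(1L, 0, scale_sd)) else 1
      grp <- rep.int(seq_along(idx), dwell)
      raw <- offset + scale * (mu[grp] + stats::rnorm(length(grp), 0, sds[grp]))
      qual <- round(stats::runif(length(idx), 12, 18) +
                      ifelse(is_mod, effect$quality_shift, 0), 1)
      qual <- pmax(qual, 1)

      read_id <- sprintf("read_%05d", i)
      df <- data.frame(
        read_id = read_id, transcript_id = tx_id,
        position = idx - 1L, ref_base = b, base_quality = qual,
        stringsAsFactors = FALSE
      )
      df$samples <- unname(split(raw, grp))
      ev[[i]] <- df
      mod_pos <- idx[b == mod_base]
      if (length(mod_pos)) {
        tr[[i]] <- data.frame(
          read_id = read_id, transcript_id = tx_id,
          position = mod_pos - 1L, modified = read_modified,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  events <- if (n_reads == 0L) {
    out <- data.frame(read_id = character(), transcript_id = character(),
                      position = integer(), ref_base = character(),
                      base_quality = numeric(), stringsAsFactors = FALSE)
    out$samples <- list()
    out
  } else {
    do.call(rbind, ev)
  }
  truth <- if (all(vapply(tr, is.null, logical(1L)))) {
    data.frame(read_id = character(), transcript_id = character(),
               position = integer(), modified = logical(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, tr[!vapply(tr, is.null, logical(1L))])
  }
  rownames(events) <- NULL
  rownames(truth) <- NULL
  list(events = events, truth = truth)
}
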