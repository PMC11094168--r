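# Readers and writers for the small text dialects used across the pipeline:
# the per-read event table (the product of an upstream basecall + resquiggle
# step), FASTA references, truth tables, instance files, read-level prediction
# tables and site-call tables. Positions are 0-based internally; user-facing
# prediction/site tables are written 1-based.

EVENT_COLUMNS <- c("read_id", "transcript_id", "position", "ref_base",
                   "base_quality", "samples")

#' Read reference transcripts from FASTA
#'
#' Sequences are upper-cased and DNA-style T is mapped to U; ids are taken up
#' to the first whitespace and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  seqs <- as.character(x)
  if (any(!nzchar(seqs))) stop("empty FASTA sequence", call. = FALSE)
  names(seqs) <- ids
  as_rna(seqs, "FASTA sequence")
}

#' Write reference transcripts to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), filepath = path)
  invisible(path)
}

#' Write an event table
#'
#' One row per aligned reference base of one read. The `samples` column holds
#' that base's raw current samples, comma-separated and serialized at full
#' precision so that a write/read round trip reproduces the values exactly.
#'
#' @param events Event data frame as produced by [simulate_reads()] or
#'   [read_event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste(EVENT_COLUMNS, collapse = "\t"), con)
  if (nrow(events)) {
    samp <- vapply(events$samples, function(s) {
      paste(sprintf("%.17g", s), collapse = ",")
    }, character(1L))
    writeLines(paste(events$read_id, events$transcript_id, events$position,
                     events$ref_base, sprintf("%.17g", events$base_quality),
                     samp, sep = "\t"), con)
  }
  invisible(path)
}

event_format_error <- function(line, msg) {
  stop(sprintf("event table format error at line %d: %s", line, msg),
       call. = FALSE)
}

#' Read an event table
#'
#' Reads the per-read event-table TSV. Rows belonging to one read must be
#' contiguous with strictly increasing positions; `ref_base` T is mapped to U.
#' With a `callback`, each read group is handed over as soon as it is
#' complete, so only one read needs to be held in memory at a time.
#'
#' @param path Path to an event-table TSV.
#' @param callback Optional `function(events_one_read)` invoked per read
#'   group. When supplied the function returns the number of reads processed
#'   (invisibly) instead of a data frame.
#' @param chunk_size Number of lines read per chunk.
#' @return Event data frame (all reads), or the read count when streaming.
#' @export
read_event_table <- function(path, callback = NULL, chunk_size = 5000L) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- file(path, open = "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (length(header) == 0L ||
      !identical(strsplit(header, "\t", fixed = TRUE)[[1L]], EVENT_COLUMNS)) {
    stop(sprintf("event table header must be: %s",
                 paste(EVENT_COLUMNS, collapse = ", ")), call. = FALSE)
  }
  groups <- list()
  n_groups <- 0L
  cur <- NULL        # accumulating rows (list of parsed fields) for one read
  cur_id <- NULL
  cur_lines <- integer()
  line_no <- 1L

  flush_group <- function() {
    pos <- vapply(cur, `[[`, integer(1L), "position")
    if (length(pos) > 1L && any(diff(pos) <= 0L)) {
      bad <- which(diff(pos) <= 0L)[1L] + 1L
      event_format_error(cur_lines[bad],
                         sprintf("positions within read '%s' must be strictly increasing", cur_id))
    }
    df <- data.frame(
      read_id = cur_id,
      transcript_id = vapply(cur, `[[`, character(1L), "transcript_id"),
      position = pos,
      ref_base = vapply(cur, `[[`, character(1L), "ref_base"),
      base_quality = vapply(cur, `[[`, numeric(1L), "base_quality"),
      stringsAsFactors = FALSE
    )
    df$samples <- lapply(cur, `[[`, "samples")
    if (is.null(callback)) {
      n_groups <<- n_groups + 1L
      groups[[n_groups]] <<- df
    } else {
      callback(df)
      n_groups <<- n_groups + 1L
    }
  }

  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    for (ln in lines) {
      line_no <- line_no + 1L
      if (!nzchar(ln)) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      # strsplit drops a trailing empty field; restore it so an empty
      # samples column is reported as such
      if (length(f) == 5L && endsWith(ln, "\t")) f <- c(f, "")
      if (length(f) != 6L) {
        event_format_error(line_no, sprintf("expected 6 tab-separated fields, got %d", length(f)))
      }
      position <- suppressWarnings(as.integer(f[3L]))
      if (is.na(position)) event_format_error(line_no, "non-integer position")
      qual <- suppressWarnings(as.numeric(f[5L]))
      if (is.na(qual)) event_format_error(line_no, "non-numeric base_quality")
      if (!nzchar(f[6L])) event_format_error(line_no, "empty samples field")
      samples <- suppressWarnings(as.numeric(strsplit(f[6L], ",", fixed = TRUE)[[1L]]))
      if (length(samples) == 0L || anyNA(samples)) {
        event_format_error(line_no, "non-numeric or empty current sample")
      }
      base <- toupper(f[4L])
      if (base == "T") base <- "U"
      if (!base %in% RNA_BASES) {
        event_format_error(line_no, sprintf("ref_base '%s' not in A/C/G/U/T", f[4L]))
      }
      row <- list(transcript_id = f[2L], position = position, ref_base = base,
                  base_quality = qual, samples = samples)
      if (is.null(cur_id) || f[1L] != cur_id) {
        if (!is.null(cur_id)) flush_group()
        cur <- list(row)
        cur_id <- f[1L]
        cur_lines <- line_no
      } else {
        cur[[length(cur) + 1L]] <- row
        cur_lines <- c(cur_lines, line_no)
      }
    }
  }
  if (!is.null(cur_id)) flush_group()
  if (!is.null(callback)) return(invisible(n_groups))
  if (n_groups == 0L) {
    out <- data.frame(read_id = character(), transcript_id = character(),
                      position = integer(), ref_base = character(),
                      base_quality = numeric(), stringsAsFactors = FALSE)
    out$samples <- list()
    return(out)
  }
  out <- do.call(rbind, groups[seq_len(n_groups)])
  rownames(out) <- NULL
  out
}

#' Write / read a truth table (BED-like)
#'
#' One row per potential modification site per read: transcript, 0-based
#' start, end = start + 1, read id, and the modified flag as 0/1. No header,
#' following BED convention.
#'
#' @param truth Truth data frame from [simulate_reads()].
#' @param path File path.
#' @return `path` (writer) or the truth data frame (reader).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(
    data.frame(truth$transcript_id, truth$position, truth$position + 1L,
               truth$read_id, as.integer(truth$modified)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("transcript_id", "start", "end",
                                        "read_id", "modified"))
  data.frame(read_id = df$read_id, transcript_id = df$transcript_id,
             position = as.integer(df$start), modified = df$modified == 1L,
             stringsAsFactors = FALSE)
}

#' Write / read read-level predictions
#'
#' Positions are emitted 1-based in the file and converted back to the 0-based
#' internal convention on reading.
#'
#' @param preds Prediction data frame from [predict_reads()].
#' @param path File path.
#' @return `path` (writer) or the prediction data frame (reader).
#' @export
write_predictions <- function(preds, path) {
  out <- data.frame(read_id = preds$read_id, transcript_id = preds$transcript_id,
                    position_1based = preds$position + 1L, motif = preds$motif,
                    prob_modified = sprintf("%.17g", preds$prob_modified),
                    hard_label = preds$hard_label, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  data.frame(read_id = df$read_id, transcript_id = df$transcript_id,
             position = as.integer(df$position_1based) - 1L, motif = df$motif,
             prob_modified = as.numeric(df$prob_modified),
             hard_label = df$hard_label, stringsAsFactors = FALSE)
}

#' Write / read site-level calls
#'
#' @param sites Site data frame from [call_sites()].
#' @param path File path.
#' @return `path` (writer) or the site data frame (reader).
#' @export
write_sites <- function(sites, path) {
  out <- data.frame(transcript_id = sites$transcript_id,
                    position_1based = sites$position + 1L, motif = sites$motif,
                    coverage = sites$coverage,
                    modified_count = sites$modified_count,
                    rate = sprintf("%.17g", sites$rate),
                    passed = as.integer(sites$passed), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  data.frame(transcript_id = df$transcript_id,
             position = as.integer(df$position_1based) - 1L, motif = df$motif,
             coverage = as.integer(df$coverage),
             modified_count = as.integer(df$modified_count),
             rate = as.numeric(df$rate), passed = df$passed == 1L,
             stringsAsFactors = FALSE)
}

#' Write / read model instances
#'
#' The instance file is a TSV with one row per 5-mer window: identifiers,
#' motif, optional label, then the 30 base-level values and the `5*l` resampled
#' current values, comma-separated and at full precision.
#'
#' @param instances A `poremod_instances` object from [extract_features()].
#' @param path File path.
#' @return `path` (writer) or a `poremod_instances` object (reader).
#' @export
write_instances <- function(instances, path) {
  stopifnot(inherits(instances, "poremod_instances"))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("read_id\ttranscript_id\tposition\tmotif\tlabel\tbase_features\tcurrent_signal", con)
  m <- instances$meta
  if (nrow(m)) {
    bf <- apply(instances$base, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
    cs <- apply(instances$current, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
    lab <- ifelse(is.na(m$label), ".", m$label)
    writeLines(paste(m$read_id, m$transcript_id, m$position, m$motif, lab,
                     bf, cs, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  n <- nrow(df)
  parse_rows <- function(col, what) {
    if (n == 0L) return(matrix(numeric(), nrow = 0L))
    rows <- lapply(strsplit(col, ",", fixed = TRUE), as.numeric)
    len <- unique(lengths(rows))
    if (length(len) != 1L) stop(sprintf("ragged %s vectors in instance file", what), call. = FALSE)
    matrix(unlist(rows), nrow = n, byrow = TRUE)
  }
  base <- parse_rows(df$base_features, "base_feature")
  current <- parse_rows(df$current_signal, "current_signal")
  label <- ifelse(df$label == ".", NA_character_, df$label)
  meta <- data.frame(read_id = df$read_id, transcript_id = df$transcript_id,
                     position = as.integer(df$position), motif = df$motif,
                     label = label, stringsAsFactors = FALSE)
  new_instances(meta, current, base,
                l = if (n > 0L) ncol(current) / 5L else 100L)
}
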