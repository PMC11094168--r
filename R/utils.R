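# Internal helpers shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# All 4^5 = 1024 5-mers over the RNA alphabet, in a fixed lexicographic order.
all_kmers <- function(k = 5L) {
  grid <- expand.grid(rep(list(RNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

check_scalar <- function(x, name, positive = FALSE, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  if (!is.null(min) && x < min) {
    stop(sprintf("`%s` must be >= %s", name, format(min)), call. = FALSE)
  }
  invisible(x)
}

# Map DNA-style sequences to the RNA alphabet and validate.
as_rna <- function(x, what = "sequence") {
  x <- chartr("tu", "TU", toupper(x))
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("%s contains letters outside the A/C/G/U(T) alphabet", what),
         call. = FALSE)
  }
  x
}
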