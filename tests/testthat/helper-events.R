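# Builders for small hand-made event tables and instance sets.

make_events <- function(read_id, transcript_id, positions, samples,
                        ref_base = NULL, base_quality = NULL) {
  n <- length(positions)
  if (is.null(ref_base)) ref_base <- rep("A", n)
  if (is.null(base_quality)) base_quality <- rep(15, n)
  df <- data.frame(read_id = rep(read_id, n),
                   transcript_id = rep(transcript_id, n),
                   position = as.integer(positions), ref_base = ref_base,
                   base_quality = base_quality, stringsAsFactors = FALSE)
  df$samples <- samples
  df
}

# Trivially separable synthetic instances built directly (no simulator):
# class "modified" shifts a block of the current vector and one base feature.
toy_instances <- function(n = 120, l = 10L, shift = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("unmodified", "modified"), length.out = n)
  cur <- matrix(rnorm(n * 5 * l), n)
  base <- matrix(runif(n * 30), n)
  base[, seq(1, 30, by = 6)] <- rep(c(0, 1/3, 2/3, 1, 1/3), each = n)
  mod <- y == "modified"
  cur[mod, (2 * l + 1):(3 * l)] <- cur[mod, (2 * l + 1):(3 * l)] + shift
  base[mod, 15] <- base[mod, 15] + shift / 3
  meta <- data.frame(read_id = sprintf("r%04d", seq_len(n)),
                     transcript_id = "toy", position = seq_len(n) + 4L,
                     motif = "ACGUA", label = y, stringsAsFactors = FALSE)
  poremod:::new_instances(meta, cur, base, l)
}

# independent piecewise-linear oracle (no stats::approx)
interp_oracle <- function(x, tq) {
  k <- length(x)
  tk <- seq(0, 1, length.out = k)
  vapply(tq, function(t) {
    if (t <= 0) return(x[1])
    if (t >= 1) return(x[k])
    i <- max(which(tk <= t))
    if (i == k) return(x[k])
    x[i] + (x[i + 1] - x[i]) * (t - tk[i]) / (tk[i + 1] - tk[i])
  }, numeric(1))
}

# brute-force all-pairs ROC oracle (half credit for score ties)
roc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

tiny_spec <- function(l = 10L) {
  model_spec(conv_channels = c(4L, 6L), pool = 3L, lstm_hidden_current = 6L,
             lstm_hidden_base = 4L, attention_dim = 4L, fc_sizes = c(8L, 2L),
             dropout_rate = 0, l = l)
}
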