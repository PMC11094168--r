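test_that("MMAD normalization matches the hand-computed example", {
  expect_equal(normalize_read(c(1, 2, 3, 4, 100)), c(-2, -1, 0, 1, 97))
})

test_that("MMAD and z-score are invariant to affine rescaling of the read", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 10)
    b <- runif(1, -5, 5)
    expect_equal(normalize_read(a * x + b, "mmad"), normalize_read(x, "mmad"),
                 tolerance = 1e-9)
    expect_equal(normalize_read(a * x + b, "zscore"),
                 normalize_read(x, "zscore"), tolerance = 1e-9)
  }
})

test_that("normalized reads have median 0 and MAD 1; min-max maps onto [0, 1]", {
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(30 + i, sd = runif(1, 0.5, 3))
    y <- normalize_read(x, "mmad")
    expect_equal(median(y), 0, tolerance = 1e-12)
    expect_equal(median(abs(y - median(y))), 1, tolerance = 1e-12)
    z <- normalize_read(x, "minmax")
    expect_equal(range(z), c(0, 1))
  }
})

test_that("degenerate reads are rejected with an informative error", {
  expect_error(normalize_read(rep(2, 10)), "median absolute deviation")
  expect_error(normalize_read(rep(2, 10), "minmax"), "constant")
  expect_error(normalize_read(rep(2, 10), "zscore"), "zero standard deviation")
  expect_error(normalize_read(3), "at least 2")
  expect_error(normalize_read(c(1, NA, 2)), "non-finite")
})

test_that("per-base statistics match hand computation", {
  s <- per_base_stats(c(1, 2, 3), base_quality = 14, ref_base = "G")
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$std, sqrt(2 / 3))
  expect_identical(s$dwell, 3L)
  expect_identical(s$base_code, 2L)

  expect_equal(per_base_stats(rep(4, 5), 10, "A")$std, 0)
  s1 <- per_base_stats(7, 10, "U")
  expect_identical(s1$dwell, 1L)
  expect_equal(s1$std, 0)
  expect_equal(s1$mean, 7)
  expect_equal(s1$median, 7)
  expect_error(per_base_stats(numeric(), 10, "A"), "empty")
})

test_that("resampling preserves constants, endpoints and the linear ramp", {
  expect_equal(resample_signal(c(5, 5, 5)), rep(5, 100))
  expect_equal(resample_signal(c(0, 1)), seq(0, 1, length.out = 100))
  expect_equal(resample_signal(c(0, 1), l = 5), c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(resample_signal(7), rep(7, 100))   # 1-sample event duplicated
  expect_error(resample_signal(c(1, 2), l = 1), ">= 2")
})

test_that("resampler agrees with the brute-force linear oracle on random slices", {
  set.seed(33)
  worst <- 0
  tq <- seq(0, 1, length.out = 100)
  for (i in 1:1000) {
    k <- sample(2:50, 1)
    x <- rnorm(k)
    d <- max(abs(resample_signal(x) - interp_oracle(x, tq)))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-9)
})

test_that("resampled signals correlate perfectly with the raw slice", {
  set.seed(34)
  # when the slice knots coincide with the resampling grid the round trip is
  # exact; otherwise the interpolation of the interpolant is still within
  # numerical noise of r = 1 for smooth slices
  for (k in c(2, 4, 10, 12, 34, 100)) {   # k - 1 divides 99
    x <- rnorm(k)
    y <- resample_signal(x)
    back <- interp_oracle(y, seq(0, 1, length.out = k))
    expect_equal(stats::cor(back, x), 1, tolerance = 1e-9)
  }
  for (i in 1:20) {
    k <- sample(3:99, 1)
    x <- cumsum(rnorm(k))
    back <- interp_oracle(resample_signal(x), seq(0, 1, length.out = k))
    expect_gt(stats::cor(back, x), 0.99)
  }
})

test_that("window assembly emits one instance per interior contiguous base", {
  ref <- c(tx = "ACGUACGUACGUAC")
  ev <- make_events("r1", "tx", 0:9,
                    lapply(1:10, function(i) rnorm(6)),
                    ref_base = strsplit(substr(ref, 1, 10), "")[[1]])
  inst <- extract_features(ev, ref)
  expect_identical(nrow(inst$meta), 6L)            # centers 2..7
  expect_identical(inst$meta$position, 2:7)
  expect_identical(ncol(inst$current), 500L)
  expect_identical(ncol(inst$base), 30L)
  # motif invariants
  expect_true(all(substr(inst$meta$motif, 3, 3) ==
                  strsplit(ref[[1]], "")[[1]][inst$meta$position + 1]))
  expect_true(all(grepl("^[ACGU]{5}$", inst$meta$motif)))

  short <- extract_features(ev[1:4, ], ref)
  expect_identical(nrow(short$meta), 0L)
})

test_that("windows spanning a gap in aligned positions are skipped", {
  ref <- c(tx = "ACGUACGUACGUAC")
  pos <- c(0:4, 6:10)                               # position 5 missing
  ev <- make_events("r1", "tx", pos,
                    lapply(seq_along(pos), function(i) rnorm(6)),
                    ref_base = strsplit(ref[[1]], "")[[1]][pos + 1])
  inst <- extract_features(ev, ref)
  expect_identical(inst$meta$position, c(2L, 8L))   # all others span the gap
})

test_that("instance labels come from a single string or a truth join", {
  ref <- synthetic_reference(1, 60, seed = 21)
  sim <- simulate_reads(ref, 4, "C", 0.5, seed = 22)
  all_lab <- extract_features(sim$events, ref, labels = "modified",
                              center_base = "C")
  expect_true(all(all_lab$meta$label == "modified"))
  joined <- extract_features(sim$events, ref, labels = sim$truth,
                             center_base = "C")
  key <- paste(joined$meta$read_id, joined$meta$position)
  tkey <- paste(sim$truth$read_id, sim$truth$position)
  expect_identical(joined$meta$label,
                   ifelse(sim$truth$modified[match(key, tkey)],
                          "modified", "unmodified"))
  expect_true(all(joined$meta$motif %in%
                  names(make_pore_model()$level_table)))
})

test_that("center-base filtering keeps only windows on that base", {
  ref <- synthetic_reference(1, 60, seed = 23)
  sim <- simulate_reads(ref, 2, "C", 0, seed = 24)
  inst <- extract_features(sim$events, ref, center_base = "G")
  expect_true(all(substr(inst$meta$motif, 3, 3) == "G"))
})

test_that("read length filter drops short reads; cutoff 0 is the identity", {
  ref <- synthetic_reference(1, 40, seed = 25)
  sim <- simulate_reads(ref, 10, "C", 0, seed = 26)
  ev <- sim$events
  # truncate half of the reads to 20 bases
  ids <- unique(ev$read_id)
  keep <- ev$read_id %in% ids[1:5] | ev$position < 20
  ev <- ev[keep, ]
  expect_identical(length(unique(filter_reads(ev, 40)$read_id)), 5L)
  expect_identical(filter_reads(ev, 0), ev)
  one <- make_events("r", "tx", 0:598, lapply(1:599, function(i) 0))
  expect_identical(nrow(filter_reads(one)), 0L)    # 599 < default 600
})

test_that("reads with non-finite samples or constant signal are skipped with a warning", {
  ref <- c(tx = "ACGUACGUACGUAC")
  bases <- strsplit(ref[[1]], "")[[1]]
  bad <- make_events("r1", "tx", 0:9, c(lapply(1:9, function(i) rnorm(4)),
                                        list(c(1, NaN))),
                     ref_base = bases[1:10])
  expect_warning(out <- extract_features(bad, ref), "non-finite")
  expect_identical(nrow(out$meta), 0L)
  const <- make_events("r2", "tx", 0:9, lapply(1:10, function(i) rep(1, 4)),
                       ref_base = bases[1:10])
  expect_warning(out2 <- extract_features(const, ref), "median absolute")
  expect_identical(nrow(out2$meta), 0L)
})

test_that("unknown transcripts raise a lookup error", {
  ev <- make_events("r1", "nope", 0:5, lapply(1:6, function(i) rnorm(3)))
  expect_error(extract_features(ev, c(tx = "ACGUACGU")), "not found")
})
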