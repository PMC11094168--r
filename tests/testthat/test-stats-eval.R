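test_that("ROC-AUC matches direct examples and the all-pairs oracle", {
  expect_equal(roc_pr_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$roc_auc, 1)
  expect_equal(roc_pr_auc(c(0.9, 0.8, 0.3), c(1, 0, 1))$roc_auc, 0.5)
  expect_error(roc_pr_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(71)
  for (i in 1:500) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)   # force ties
    labels <- as.logical(rbinom(n, 1, 0.5))
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_pr_auc(scores, labels)$roc_auc,
                 roc_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC-AUC agrees with pROC and is ~0.5 for label-independent scores", {
  skip_if_not_installed("pROC")
  set.seed(72)
  for (i in 1:20) {
    n <- 60
    scores <- rnorm(n)
    labels <- as.logical(rbinom(n, 1, 0.4))
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_pr_auc(scores, labels)$roc_auc, ref, tolerance = 1e-9)
  }
  set.seed(73)
  null_auc <- roc_pr_auc(rnorm(1e4), rbinom(1e4, 1, 0.5))$roc_auc
  expect_lt(abs(null_auc - 0.5), 0.02)
})

test_that("PR-AUC equals the rank-sum average-precision identity", {
  # for distinct scores, step-integrated PR-AUC is the mean over positives of
  # precision at each positive's rank
  ap_oracle <- function(scores, labels) {
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]
    ranks <- which(lab)
    mean(vapply(seq_along(ranks), function(i) i / ranks[i], numeric(1)))
  }
  set.seed(74)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    scores <- sample(seq_len(1000), n)         # distinct
    labels <- as.logical(rbinom(n, 1, 0.5))
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_pr_auc(scores, labels)$pr_auc, ap_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(roc_pr_auc(c(0.1, 0.9), c(0, 1))$pr_auc, 1)
})

test_that("Fisher point probability and two-sided p match direct evaluation", {
  expect_equal(fisher_exact(5, 5, 5, 5)$p_value, 1)
  expect_equal(fisher_exact(1, 9, 9, 1)$point_prob, 100 / 184756,
               tolerance = 1e-12)
  expect_equal(fisher_exact(10, 0, 0, 10)$p_value, 2 / 184756,
               tolerance = 1e-12)
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact(0, 0, 0, 0), "empty")
})

test_that("Fisher test equals enumeration over all small tables", {
  # independent oracle: hypergeometric point masses via dhyper
  oracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    support <- max(0, c1 - r2):min(r1, c1)
    pm <- dhyper(support, r1, r2, c1)
    obs <- dhyper(a, r1, r2, c1)
    sum(pm[pm <= obs * (1 + 1e-7)])
  }
  worst <- 0
  for (n in 1:15) {
    for (r1 in 0:n) {
      for (a in 0:r1) {
        r2 <- n - r1
        for (c_ in 0:r2) {
          if (r1 == 0 && r2 == 0) next
          p <- fisher_exact(a, r1 - a, c_, r2 - c_)$p_value
          worst <- max(worst, abs(p - min(1, oracle(a, r1 - a, c_, r2 - c_))))
        }
      }
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("Fisher test agrees with stats::fisher.test on random tables", {
  set.seed(75)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(2, 10, 40), 1))
    if (sum(cells) == 0) cells[1] <- 1
    mine <- fisher_exact(cells[1], cells[2], cells[3], cells[4])$p_value
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-7)
  }
})

test_that("differential testing flags large rate changes with direction", {
  sites <- function(k, n, pos = c(10L, 20L)) {
    data.frame(transcript_id = "tx", position = pos, motif = "AACAA",
               coverage = n, modified_count = k, rate = k / n,
               passed = TRUE, stringsAsFactors = FALSE)
  }
  same <- differential_sites(sites(c(5, 8), c(50, 50)), sites(c(5, 8), c(50, 50)))
  expect_equal(same$p_value, c(1, 1))
  expect_false(any(same$significant))
  expect_identical(same$direction, c(0L, 0L))

  ab <- differential_sites(sites(c(40, 10), c(50, 50)), sites(c(5, 10), c(50, 50)))
  expect_true(ab$significant[1])
  expect_lt(ab$p_value[1], 1e-10)
  expect_identical(ab$direction[1], -1L)

  none <- differential_sites(sites(c(40, 10), c(50, 50)),
                             sites(c(5, 10), c(50, 50)), alpha = 0)
  expect_false(any(none$significant))

  expect_warning(
    empty <- differential_sites(sites(5, 50, pos = 1L), sites(5, 50, pos = 2L)),
    "no shared sites")
  expect_identical(nrow(empty), 0L)
})

test_that("swapping conditions flips direction and preserves p", {
  set.seed(76)
  mk <- function(k, n) data.frame(transcript_id = "tx", position = 1:8,
                                  motif = "AACAA", coverage = n,
                                  modified_count = k, rate = k / n,
                                  passed = TRUE, stringsAsFactors = FALSE)
  kA <- rbinom(8, 40, 0.5); kB <- rbinom(8, 40, 0.2)
  d1 <- differential_sites(mk(kA, 40), mk(kB, 40))
  d2 <- differential_sites(mk(kB, 40), mk(kA, 40))
  expect_equal(d1$p_value, d2$p_value)
  expect_identical(d1$direction, -d2$direction)
})

test_that("stoichiometry errors report correlation and per-level MAE", {
  truth <- rep(c(0, 0.2, 0.4, 0.6), each = 5)
  ident <- stoichiometry_error(truth, truth)
  expect_equal(ident$pearson_r, 1)
  expect_true(all(ident$errors == 0))
  expect_true(all(ident$mae_by_level == 0))

  anti <- stoichiometry_error(1 - truth, truth)
  expect_equal(anti$pearson_r, -1)
  expect_error(stoichiometry_error(1:3, 1:4), "equal length")
})

test_that("feature importance isolates the signal-bearing center base", {
  # by construction only the center block differs between classes; the flank
  # blocks are class-free noise with mean zero, so zero-ablating them is a
  # near-null perturbation
  inst <- toy_instances(n = 400, shift = 4)
  fit <- train_model(inst, spec = tiny_spec(),
                     config = train_config(seed = 8, batch_size = 32L,
                                           max_epochs = 6L))
  ev <- toy_instances(n = 300, shift = 4, seed = 55)
  fi1 <- feature_importance(fit, ev)
  fi2 <- feature_importance(fit, ev)
  expect_identical(fi1, fi2)
  expect_length(fi1, 5L)
  expect_identical(names(fi1), c("-2", "-1", "0", "+1", "+2"))
  expect_identical(which.max(fi1), c(`0` = 3L))
  expect_true(all(fi1[-3] <= 0.05))
})
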