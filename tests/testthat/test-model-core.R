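test_that("softmax matches direct evaluation and is shift-invariant", {
  expect_equal(softmax_prob(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_prob(c(log(3), 0)), c(0.75, 0.25))
  z <- c(1.3, -0.2, 4)
  expect_equal(softmax_prob(z + 17), softmax_prob(z))
  m <- matrix(rnorm(10), 5)
  p <- softmax_prob(m)
  expect_equal(rowSums(p), rep(1, 5))
  expect_true(all(p > 0))
  expect_error(softmax_prob(c(Inf, 0)), "non-finite")
})

test_that("weighted cross-entropy equals a hand-rolled log-softmax oracle", {
  oracle <- function(z, y, w) {
    nll <- vapply(seq_len(nrow(z)), function(i) {
      -log(exp(z[i, y[i]]) / sum(exp(z[i, ])))
    }, numeric(1))
    sum(w[y] * nll) / sum(w[y])
  }
  set.seed(41)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    z <- matrix(rnorm(2 * n, sd = 3), n)
    y <- sample(1:2, n, replace = TRUE)
    w <- runif(2, 0.2, 5)
    expect_equal(cross_entropy_loss(z, y, w)$loss, oracle(z, y, w),
                 tolerance = 1e-6)
  }
})

test_that("cross-entropy gradient matches finite differences", {
  set.seed(42)
  z <- matrix(rnorm(8), 4)
  y <- c(1L, 2L, 2L, 1L)
  w <- c(0.7, 1.9)
  g <- cross_entropy_loss(z, y, w)$grad
  eps <- 1e-6
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (cross_entropy_loss(zp, y, w)$loss -
            cross_entropy_loss(zm, y, w)$loss) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("sampler weights are reciprocal class counts and balance draws", {
  expect_equal(class_sampler_weights(c(0, 0, 0, 1)), c(1/3, 1/3, 1/3, 1))
  expect_equal(class_sampler_weights(c("a", "b", "a", "b")), rep(0.5, 4))
  expect_error(class_sampler_weights(character()), "no labels")

  labels <- rep(c(0, 1), times = c(1000, 100))
  w <- class_sampler_weights(labels)
  set.seed(43)
  draws <- sample(labels, 1e5, replace = TRUE, prob = w)
  expect_lt(abs(mean(draws == 1) - 0.5), 0.02)
})

test_that("model construction is seed-deterministic with finite 2-logit output", {
  spec <- tiny_spec()
  m1 <- build_model(spec, seed = 5)
  m2 <- build_model(spec, seed = 5)
  m3 <- build_model(spec, seed = 6)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))

  inst <- toy_instances(n = 8)
  fw <- poremod:::model_forward(m1$params, spec, inst$current, inst$base)
  expect_identical(dim(fw$logits), c(8L, 2L))
  expect_true(all(is.finite(fw$logits)))
})

test_that("backpropagation matches finite differences through every block", {
  spec <- tiny_spec()
  m <- build_model(spec, seed = 5)
  p <- m$params
  set.seed(44)
  B <- 4L
  Xc <- matrix(rnorm(B * 50), B)
  Xb <- toy_instances(n = B)$base
  y <- c(1L, 2L, 1L, 2L)
  lossfun <- function(pp) {
    fw <- poremod:::model_forward(pp, spec, Xc, Xb, train = TRUE)
    cross_entropy_loss(fw$logits, y, c(1, 2))$loss
  }
  fw <- poremod:::model_forward(p, spec, Xc, Xb, train = TRUE)
  ls <- cross_entropy_loss(fw$logits, y, c(1, 2))
  g <- poremod:::model_backward(p, spec, fw$cache, ls$grad)
  eps <- 1e-5
  for (nm in names(p)) {
    idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
    for (i in idx) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      rel <- abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i]))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("training on separable toy data learns, reproducibly", {
  inst <- toy_instances(n = 240, shift = 4)
  cfg <- train_config(seed = 9, batch_size = 32L, max_epochs = 10L,
                      early_stop_patience = 10L)
  fit1 <- train_model(inst, spec = tiny_spec(), config = cfg)
  expect_gt(fit1$val_auc, 0.9)
  expect_lt(fit1$history$train_loss[3], fit1$history$train_loss[1])
  expect_identical(fit1$best_epoch, which.max(fit1$history$val_auc))

  fit2 <- train_model(inst, spec = tiny_spec(), config = cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
})

test_that("training rejects single-class or shape-mismatched data", {
  inst <- toy_instances(n = 40)
  inst$meta$label <- "modified"
  expect_error(train_model(inst, spec = tiny_spec(),
                           config = train_config()), "both classes")
  inst2 <- toy_instances(n = 40)
  expect_error(train_model(inst2, spec = model_spec(l = 100L),
                           config = train_config()), "expects")
})

test_that("checkpoints reload to an identical model with identical predictions", {
  inst <- toy_instances(n = 120, shift = 4)
  fit <- train_model(inst, spec = tiny_spec(),
                     config = train_config(seed = 2, batch_size = 32L,
                                           max_epochs = 3L))
  path <- withr::local_tempfile()
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(back$params, fit$params)
  expect_identical(back$history, fit$history)
  expect_identical(predict(back, inst), predict(fit, inst))
  expect_error(load_model(withr::local_tempfile(lines = "x")), "checkpoint")
})

test_that("transfer freezes the feature extractor bit-identically", {
  inst <- toy_instances(n = 160, shift = 4)
  pre <- train_model(inst, spec = tiny_spec(),
                     config = train_config(seed = 3, batch_size = 32L,
                                           max_epochs = 3L))
  inst2 <- toy_instances(n = 160, shift = 2, seed = 99)
  trf <- transfer_model(pre, inst2,
                        config = train_config(seed = 4, batch_size = 32L,
                                              max_epochs = 5L))
  frozen <- poremod:::FEATURE_PREFIXES
  for (nm in names(pre$params)) {
    if (any(startsWith(nm, frozen))) {
      expect_identical(trf$params[[nm]], pre$params[[nm]])
    }
  }
  expect_false(identical(trf$params$fc1_W, pre$params$fc1_W))
  expect_lt(length(trf$trainable), length(pre$params))
  expect_error(transfer_model(pre, inst2,
                              config = train_config(frozen = "nosuch",
                                                    mode = "transfer")),
               "names no model parameters")
})
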