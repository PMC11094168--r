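# The two-branch read classifier. Current branch: stacked 1D convolutions
# (ReLU, max pooling) over the 5 x l resampled signal, a bidirectional LSTM
# over the pooled sequence, and an additive attention unit producing a single
# context vector. Base branch: a bidirectional LSTM over the 5 bases' 6
# base-level features (final states of both directions). The concatenated
# representations feed a fully connected classifier ending in 2 logits
# (unmodified, modified).

CLASS_LEVELS <- c("unmodified", "modified")
FEATURE_PREFIXES <- c("conv", "lstmc", "attn", "lstmb")

#' Architecture specification for the read classifier
#'
#' All sizes are exposed; the defaults are compact enough that the bundled
#' simulation studies train in minutes on a single CPU core while keeping
#' every architectural element (convolutions, pooling, bidirectional LSTMs,
#' attention, dropout) of the full-size model.
#'
#' @param conv_channels Integer vector of channels per convolution stage; each
#'   stage is convolution + ReLU + max pooling.
#' @param conv_kernel Odd kernel width of the convolutions.
#' @param pool Kernel (= stride) of the non-overlapping max pooling.
#' @param lstm_hidden_current Hidden size per direction of the current-branch
#'   LSTM.
#' @param lstm_hidden_base Hidden size per direction of the base-branch LSTM.
#' @param attention_dim Size of the attention projection.
#' @param fc_sizes Widths of the fully connected stack; must end in 2.
#' @param dropout_rate Dropout rate in `[0, 1)`, applied before each fully
#'   connected layer.
#' @param l Resampled samples per base; must match the instances.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(conv_channels = c(16L, 32L), conv_kernel = 3L,
                       pool = 5L, lstm_hidden_current = 32L,
                       lstm_hidden_base = 24L, attention_dim = 16L,
                       fc_sizes = c(96L, 2L), dropout_rate = 0.3, l = 100L) {
  stopifnot(length(conv_channels) >= 1L, all(conv_channels >= 1L),
            conv_kernel >= 1L, conv_kernel %% 2L == 1L, pool >= 1L,
            lstm_hidden_current >= 1L, lstm_hidden_base >= 1L,
            attention_dim >= 1L, length(fc_sizes) >= 1L, all(fc_sizes >= 1L),
            dropout_rate >= 0, dropout_rate < 1, l >= 2L)
  if (fc_sizes[length(fc_sizes)] != 2L) {
    stop("`fc_sizes` must end in 2 (unmodified/modified logits)", call. = FALSE)
  }
  T_seq <- 5L * as.integer(l)
  for (i in seq_along(conv_channels)) T_seq <- T_seq %/% pool
  if (T_seq < 2L) {
    stop("pooling reduces the signal to fewer than 2 time steps; decrease `pool` or the number of conv stages",
         call. = FALSE)
  }
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel), pool = as.integer(pool),
                 lstm_hidden_current = as.integer(lstm_hidden_current),
                 lstm_hidden_base = as.integer(lstm_hidden_base),
                 attention_dim = as.integer(attention_dim),
                 fc_sizes = as.integer(fc_sizes), dropout_rate = dropout_rate,
                 l = as.integer(l), time_steps = T_seq),
            class = "model_spec")
}

#' Optimization settings for training and transfer learning
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param early_stop_patience Stop after this many epochs without improvement
#'   of the validation ROC-AUC; the best checkpoint is returned.
#' @param validation_fraction Held-out fraction (default 1/5, i.e. a 4:1
#'   train/validation split).
#' @param seed Seed governing the split, sampler, initialization and dropout.
#' @param class_weights Loss weights for (unmodified, modified). Balance is
#'   normally achieved by the weighted sampler, so the default is equal.
#' @param mode `"scratch"` or `"transfer"`.
#' @param frozen Character vector of parameter-name prefixes kept fixed during
#'   transfer; `NULL` means the default feature-extractor set (convolutions,
#'   both LSTMs, attention).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         max_epochs = 50L, early_stop_patience = 5L,
                         validation_fraction = 0.2, seed = 1L,
                         class_weights = c(1, 1),
                         mode = c("scratch", "transfer"), frozen = NULL) {
  mode <- match.arg(mode)
  check_scalar(learning_rate, "learning_rate", positive = TRUE)
  stopifnot(batch_size >= 1L, max_epochs >= 1L, early_stop_patience >= 1L,
            validation_fraction > 0, validation_fraction < 1,
            length(class_weights) == 2L, all(class_weights > 0))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), class_weights = class_weights,
                 mode = mode, frozen = frozen),
            class = "train_config")
}

# Seeded parameter initialization; LSTM forget-gate biases start at 1.
init_params <- function(spec) {
  p <- list()
  cin <- 1L
  for (i in seq_along(spec$conv_channels)) {
    cout <- spec$conv_channels[i]
    p[[sprintf("conv%d_W", i)]] <- glorot(cin * spec$conv_kernel, cout)
    p[[sprintf("conv%d_b", i)]] <- numeric(cout)
    cin <- cout
  }
  lstm_init <- function(D, H) {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1
    list(Wx = glorot(D, 4L * H), Wh = glorot(H, 4L * H), b = b)
  }
  Hc <- spec$lstm_hidden_current
  for (dir in c("f", "b")) {
    li <- lstm_init(cin, Hc)
    p[[sprintf("lstmc_%s_Wx", dir)]] <- li$Wx
    p[[sprintf("lstmc_%s_Wh", dir)]] <- li$Wh
    p[[sprintf("lstmc_%s_b", dir)]] <- li$b
  }
  p[["attn_W"]] <- glorot(2L * Hc, spec$attention_dim)
  p[["attn_v"]] <- as.vector(glorot(spec$attention_dim, 1L))
  # base branch input: one-hot base identity (4) + quality, mean, std,
  # median, dwell (5); the scalar base code of the instance file is expanded
  # to one-hot inside the forward pass
  Hb <- spec$lstm_hidden_base
  for (dir in c("f", "b")) {
    li <- lstm_init(9L, Hb)
    p[[sprintf("lstmb_%s_Wx", dir)]] <- li$Wx
    p[[sprintf("lstmb_%s_Wh", dir)]] <- li$Wh
    p[[sprintf("lstmb_%s_b", dir)]] <- li$b
  }
  din <- 2L * Hc + 2L * Hb
  for (i in seq_along(spec$fc_sizes)) {
    p[[sprintf("fc%d_W", i)]] <- glorot(din, spec$fc_sizes[i])
    p[[sprintf("fc%d_b", i)]] <- numeric(spec$fc_sizes[i])
    din <- spec$fc_sizes[i]
  }
  p
}

#' Build an untrained classifier
#'
#' @param spec A [model_spec()].
#' @param seed Seed for the deterministic parameter initialization.
#' @return A `poremod_model` with empty training history.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- with_seed(seed, init_params(spec))
  structure(list(spec = spec, params = params, config = NULL,
                 history = data.frame(epoch = integer(), train_loss = numeric(),
                                      val_auc = numeric()),
                 best_epoch = NA_integer_, val_auc = NA_real_,
                 classes = CLASS_LEVELS, seed = as.integer(seed)),
            class = "poremod_model")
}

# Full forward pass. Xc: (B x 5l) current matrix, Xb: (B x 30) base matrix.
model_forward <- function(params, spec, Xc, Xb, train = FALSE) {
  B <- nrow(Xc)
  cache <- list()
  T_cur <- 5L * spec$l
  A <- matrix(as.vector(Xc), ncol = 1L)   # (B*T) x 1, batch index fastest
  for (i in seq_along(spec$conv_channels)) {
    cv <- conv1d_forward(A, params[[sprintf("conv%d_W", i)]],
                         params[[sprintf("conv%d_b", i)]], spec$conv_kernel,
                         B, T_cur)
    rl <- relu_forward(cv$out)
    mp <- maxpool_forward(rl$out, spec$pool, B, T_cur, train = train)
    cache[[sprintf("conv%d", i)]] <- list(cv = cv$cache, relu = rl$cache,
                                          pool = mp$cache)
    A <- mp$out
    T_cur <- T_cur %/% spec$pool
  }
  lf <- lstm_forward(A, params$lstmc_f_Wx, params$lstmc_f_Wh, params$lstmc_f_b,
                     B, T_cur)
  lb <- lstm_forward(A, params$lstmc_b_Wx, params$lstmc_b_Wh, params$lstmc_b_b,
                     B, T_cur, reverse = TRUE)
  Hcat <- cbind(lf$out, lb$out)
  att <- attention_forward(Hcat, params$attn_W, params$attn_v, B, T_cur)
  cache$lstmc <- list(f = lf$cache, b = lb$cache, Hcat = Hcat,
                      att = att$cache, T_cur = T_cur)

  Xbm <- matrix(0, B * 5L, 9L)
  for (t in 1:5) {
    blk <- Xb[, ((t - 1L) * 6L + 1L):(t * 6L), drop = FALSE]
    rows <- step_rows(t, B)
    code <- as.integer(round(blk[, 1L] * 3))    # undo the /3 scaling
    onehot <- matrix(0, B, 4L)
    ok <- code >= 0L & code <= 3L
    onehot[cbind(which(ok), code[ok] + 1L)] <- 1
    Xbm[rows, 1:4] <- onehot
    Xbm[rows, 5:9] <- blk[, 2:6]
  }
  bf <- lstm_forward(Xbm, params$lstmb_f_Wx, params$lstmb_f_Wh,
                     params$lstmb_f_b, B, 5L)
  bb <- lstm_forward(Xbm, params$lstmb_b_Wx, params$lstmb_b_Wh,
                     params$lstmb_b_b, B, 5L, reverse = TRUE)
  cache$lstmb <- list(f = bf$cache, b = bb$cache)

  feat <- cbind(att$out, bf$last_h, bb$last_h)
  nfc <- length(spec$fc_sizes)
  cache$fc <- vector("list", nfc)
  X <- feat
  for (i in seq_len(nfc)) {
    dp <- dropout_forward(X, spec$dropout_rate, train)
    dn <- dense_forward(dp$out, params[[sprintf("fc%d_W", i)]],
                        params[[sprintf("fc%d_b", i)]])
    if (i < nfc) {
      rl <- relu_forward(dn$out)
      X <- rl$out
      cache$fc[[i]] <- list(drop = dp$cache, dense = dn$cache, relu = rl$cache)
    } else {
      X <- dn$out
      cache$fc[[i]] <- list(drop = dp$cache, dense = dn$cache, relu = NULL)
    }
  }
  list(logits = X, cache = cache)
}

model_backward <- function(params, spec, cache, dlogits) {
  g <- list()
  nfc <- length(spec$fc_sizes)
  dX <- dlogits
  for (i in nfc:1) {
    cc <- cache$fc[[i]]
    if (!is.null(cc$relu)) dX <- relu_backward(dX, cc$relu)
    dn <- dense_backward(dX, params[[sprintf("fc%d_W", i)]], cc$dense)
    g[[sprintf("fc%d_W", i)]] <- dn$dW
    g[[sprintf("fc%d_b", i)]] <- dn$db
    dX <- dropout_backward(dn$dX, cc$drop)
  }
  Hc <- spec$lstm_hidden_current
  Hb <- spec$lstm_hidden_base
  dctx <- dX[, 1:(2L * Hc), drop = FALSE]
  dbf_last <- dX[, (2L * Hc + 1L):(2L * Hc + Hb), drop = FALSE]
  dbb_last <- dX[, (2L * Hc + Hb + 1L):(2L * Hc + 2L * Hb), drop = FALSE]

  cb <- cache$lstmb
  B <- cb$f$B
  zeroH <- matrix(0, B * 5L, Hb)
  bfb <- lstm_backward(zeroH, params$lstmb_f_Wx, params$lstmb_f_Wh, cb$f,
                       dlast = dbf_last)
  bbb <- lstm_backward(zeroH, params$lstmb_b_Wx, params$lstmb_b_Wh, cb$b,
                       dlast = dbb_last)
  g$lstmb_f_Wx <- bfb$dWx; g$lstmb_f_Wh <- bfb$dWh; g$lstmb_f_b <- bfb$db
  g$lstmb_b_Wx <- bbb$dWx; g$lstmb_b_Wh <- bbb$dWh; g$lstmb_b_b <- bbb$db

  cl <- cache$lstmc
  ab <- attention_backward(dctx, cl$Hcat, params$attn_W, params$attn_v, cl$att)
  g$attn_W <- ab$dWa
  g$attn_v <- ab$dva
  dHf <- ab$dH[, 1:Hc, drop = FALSE]
  dHb2 <- ab$dH[, (Hc + 1L):(2L * Hc), drop = FALSE]
  lfb <- lstm_backward(dHf, params$lstmc_f_Wx, params$lstmc_f_Wh, cl$f)
  lbb <- lstm_backward(dHb2, params$lstmc_b_Wx, params$lstmc_b_Wh, cl$b)
  g$lstmc_f_Wx <- lfb$dWx; g$lstmc_f_Wh <- lfb$dWh; g$lstmc_f_b <- lfb$db
  g$lstmc_b_Wx <- lbb$dWx; g$lstmc_b_Wh <- lbb$dWh; g$lstmc_b_b <- lbb$db

  dA <- lfb$dX + lbb$dX
  for (i in rev(seq_along(spec$conv_channels))) {
    cc <- cache[[sprintf("conv%d", i)]]
    dA <- maxpool_backward(dA, cc$pool)
    dA <- relu_backward(dA, cc$relu)
    cb2 <- conv1d_backward(dA, params[[sprintf("conv%d_W", i)]], cc$cv)
    g[[sprintf("conv%d_W", i)]] <- cb2$dW
    g[[sprintf("conv%d_b", i)]] <- cb2$db
    dA <- cb2$dX
  }
  g
}

#' Per-instance weights for the class-balancing sampler
#'
#' Each instance gets weight `1 / n_class(label)`, so a sampler drawing with
#' replacement proportionally to these weights yields balanced classes in
#' expectation regardless of the raw class proportions.
#'
#' @param labels Vector of class labels (character/factor/integer).
#' @return Numeric weights, one per instance.
#' @examples
#' class_sampler_weights(c(0, 0, 0, 1))  # 1/3 1/3 1/3 1
#' @export
class_sampler_weights <- function(labels) {
  if (length(labels) == 0L) stop("no labels", call. = FALSE)
  counts <- table(labels)
  if (any(counts == 0L)) stop("a class has zero instances", call. = FALSE)
  unname(1 / as.numeric(counts[as.character(labels)]))
}

instance_labels <- function(instances) {
  lab <- instances$meta$label
  if (anyNA(lab)) stop("instances must be fully labeled for training", call. = FALSE)
  bad <- setdiff(unique(lab), CLASS_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  match(lab, CLASS_LEVELS)   # 1 = unmodified, 2 = modified
}

adam_step <- function(params, grads, state, trainable, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Shared training loop for scratch and transfer modes.
run_training <- function(params, spec, instances, config, trainable,
                         verbose = FALSE) {
  y <- instance_labels(instances)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- length(y)
  Xc <- instances$current
  Xb <- instances$base
  if (ncol(Xc) != 5L * spec$l) {
    stop(sprintf("instances have %d current values but the model expects %d",
                 ncol(Xc), 5L * spec$l), call. = FALSE)
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_auc = numeric())
  best <- list(auc = -Inf, params = params, epoch = NA_integer_)

  with_seed(config$seed + 1L, {
    idx <- sample.int(n)
    n_val <- max(1L, floor(n * config$validation_fraction))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    if (length(unique(y[tr_idx])) < 2L || length(unique(y[val_idx])) < 2L) {
      stop("train/validation split left a single-class partition; provide more data",
           call. = FALSE)
    }
    w <- class_sampler_weights(y[tr_idx])
    state <- list(t = 0L,
                  m = lapply(params, function(x) x * 0),
                  v = lapply(params, function(x) x * 0))
    wait <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      order <- sample(tr_idx, length(tr_idx), replace = TRUE, prob = w)
      losses <- numeric(0L)
      for (b0 in seq(1L, length(order), by = config$batch_size)) {
        bi <- order[b0:min(b0 + config$batch_size - 1L, length(order))]
        fw <- model_forward(params, spec, Xc[bi, , drop = FALSE],
                            Xb[bi, , drop = FALSE], train = TRUE)
        ls <- cross_entropy_loss(fw$logits, y[bi], config$class_weights)
        if (!is.finite(ls$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
               call. = FALSE)
        }
        losses <- c(losses, ls$loss)
        grads <- model_backward(params, spec, fw$cache, ls$grad)
        upd <- adam_step(params, grads, state, trainable, config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      val_prob <- forward_prob(params, spec, Xc[val_idx, , drop = FALSE],
                               Xb[val_idx, , drop = FALSE])
      val_auc <- roc_pr_auc(val_prob, y[val_idx] == 2L)$roc_auc
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_auc = val_auc))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, val ROC-AUC %.4f",
                        epoch, mean(losses), val_auc))
      }
      if (val_auc > best$auc) {
        best <- list(auc = val_auc, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
  })
  list(params = best$params, history = history, best_epoch = best$epoch,
       val_auc = best$auc)
}

# Batched forward pass in eval mode, returning P(modified).
forward_prob <- function(params, spec, Xc, Xb, batch_size = 1024L) {
  n <- nrow(Xc)
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, n)
    fw <- model_forward(params, spec, Xc[bi, , drop = FALSE],
                        Xb[bi, , drop = FALSE], train = FALSE)
    out[bi] <- softmax_prob(fw$logits)[, 2L]
  }
  out
}

#' Train the read classifier from scratch
#'
#' Splits the labeled instances 4:1 into training and validation, draws each
#' epoch's minibatches with the class-balancing weighted sampler, optimizes
#' the weighted cross-entropy with Adam, evaluates the validation ROC-AUC
#' after every epoch, and returns the checkpoint with the best validation
#' ROC-AUC (early stopping after `early_stop_patience` epochs without
#' improvement). Identical data, spec and config (seed) reproduce the training
#' history exactly.
#'
#' @param instances Labeled `poremod_instances` (labels `"modified"` /
#'   `"unmodified"`).
#' @param spec A [model_spec()]; its `l` must match the instances.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A fitted `poremod_model`.
#' @export
train_model <- function(instances, spec = model_spec(),
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(instances, "poremod_instances"),
            inherits(spec, "model_spec"), inherits(config, "train_config"))
  params <- with_seed(config$seed, init_params(spec))
  fit <- run_training(params, spec, instances, config,
                      trainable = names(params), verbose = verbose)
  structure(list(spec = spec, params = fit$params, config = config,
                 history = fit$history, best_epoch = fit$best_epoch,
                 val_auc = fit$val_auc, classes = CLASS_LEVELS,
                 n_instances = nrow(instances$meta), seed = config$seed),
            class = "poremod_model")
}

#' Transfer a trained model to a new modification type
#'
#' The feature-extracting layers of the pretrained model (convolutions and
#' pooling, both LSTMs and the attention unit, by default) are frozen
#' bit-identically; only the fully connected classifier is re-optimized on the
#' new task's labeled instances. This typically reaches a given accuracy with
#' far fewer labeled instances and epochs than training from scratch.
#'
#' @param pretrained A fitted `poremod_model`.
#' @param instances Labeled instances of the new modification type.
#' @param config A [train_config()]; `frozen` may name parameter prefixes
#'   (e.g. `"conv"`, `"lstmc"`, `"attn"`, `"lstmb"`, `"fc1"`), `NULL` uses the
#'   default feature-extractor set.
#' @param verbose Print per-epoch progress.
#' @return A fitted `poremod_model` (mode `"transfer"`).
#' @export
transfer_model <- function(pretrained, instances,
                           config = train_config(mode = "transfer"),
                           verbose = FALSE) {
  stopifnot(inherits(pretrained, "poremod_model"),
            inherits(instances, "poremod_instances"),
            inherits(config, "train_config"))
  config$mode <- "transfer"
  frozen <- if (is.null(config$frozen)) FEATURE_PREFIXES else config$frozen
  pnames <- names(pretrained$params)
  hit <- vapply(frozen, function(f) any(startsWith(pnames, f)), logical(1L))
  if (any(!hit)) {
    stop(sprintf("frozen set names no model parameters: %s",
                 paste(frozen[!hit], collapse = ", ")), call. = FALSE)
  }
  is_frozen <- Reduce(`|`, lapply(frozen, function(f) startsWith(pnames, f)),
                      accumulate = FALSE, right = FALSE,
                      init = rep(FALSE, length(pnames)))
  trainable <- pnames[!is_frozen]
  if (length(trainable) == 0L) {
    stop("all parameters are frozen; nothing to train", call. = FALSE)
  }
  fit <- run_training(pretrained$params, pretrained$spec, instances, config,
                      trainable = trainable, verbose = verbose)
  structure(list(spec = pretrained$spec, params = fit$params, config = config,
                 history = fit$history, best_epoch = fit$best_epoch,
                 val_auc = fit$val_auc, classes = CLASS_LEVELS,
                 n_instances = nrow(instances$meta), seed = config$seed,
                 frozen = frozen, trainable = trainable),
            class = "poremod_model")
}

#' Predict modification probabilities for instances
#'
#' @param object A fitted `poremod_model`.
#' @param instances A `poremod_instances` object.
#' @param type `"prob"` for the two-column probability matrix, `"class"` for
#'   hard labels at threshold 0.5.
#' @param ... Unused.
#' @return Matrix of probabilities (columns unmodified/modified) or a
#'   character vector of labels.
#' @export
predict.poremod_model <- function(object, instances, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  stopifnot(inherits(instances, "poremod_instances"))
  if (ncol(instances$current) != 5L * object$spec$l) {
    stop("instance shape does not match the model spec", call. = FALSE)
  }
  p_mod <- forward_prob(object$params, object$spec, instances$current,
                        instances$base)
  if (type == "class") {
    return(ifelse(p_mod >= 0.5, "modified", "unmodified"))
  }
  out <- cbind(unmodified = 1 - p_mod, modified = p_mod)
  out
}

n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

#' @export
print.poremod_model <- function(x, ...) {
  cat("poremod read classifier\n")
  cat(sprintf("  parameters: %d (%s)\n", n_parameters(x),
              if (is.null(x$config)) "untrained"
              else sprintf("trained, mode = %s", x$config$mode)))
  if (nrow(x$history)) {
    cat(sprintf("  epochs run: %d; best epoch %d with validation ROC-AUC %.4f\n",
                nrow(x$history), x$best_epoch, x$val_auc))
  }
  invisible(x)
}

#' @export
summary.poremod_model <- function(object, ...) {
  print(object)
  s <- object$spec
  cat(sprintf("  current branch: conv [%s] kernel %d, pool %d -> %d steps, biLSTM %d, attention %d\n",
              paste(s$conv_channels, collapse = ", "), s$conv_kernel, s$pool,
              s$time_steps, s$lstm_hidden_current, s$attention_dim))
  cat(sprintf("  base branch: biLSTM %d over 5 x 6 features\n", s$lstm_hidden_base))
  cat(sprintf("  classifier: fc [%s], dropout %.2f\n",
              paste(s$fc_sizes, collapse = ", "), s$dropout_rate))
  if (!is.null(object$frozen)) {
    cat(sprintf("  frozen (transfer): %s\n",
                paste(object$frozen, collapse = ", ")))
  }
  if (nrow(object$history)) {
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' Plot the training history
#'
#' @param x A fitted `poremod_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.poremod_model <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("model has no training history", call. = FALSE)
  old <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "Loss", ...)
  graphics::plot(h$epoch, h$val_auc, type = "b", xlab = "epoch",
                 ylab = "validation ROC-AUC", main = "Validation ROC-AUC", ...)
  graphics::abline(v = x$best_epoch, lty = 2L)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing, versioned single-file archive holding
#' the architecture spec, parameters, training config and history.
#'
#' @param model A `poremod_model`.
#' @param path Checkpoint path.
#' @return `path` (writer) or the restored `poremod_model` (reader).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "poremod_model"))
  saveRDS(list(format = "poremod_checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!is.list(x) || !identical(x$format, "poremod_checkpoint")) {
    stop("not a poremod checkpoint", call. = FALSE)
  }
  x$model
}
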