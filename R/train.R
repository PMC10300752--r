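#' Training configuration
#'
#' The training recipe: SGD with momentum 0.9, batch size 64, 120 epochs,
#' initial learning rate 0.1 divided by 10 every 30 epochs, cross-entropy
#' loss, weight decay 1e-4.  All models are trained from scratch.
#'
#' @param batch_size mini-batch size; the last incomplete batch is kept.
#' @param epochs number of passes over the training set.
#' @param momentum SGD momentum coefficient.
#' @param initial_lr learning rate at epoch 0.
#' @param lr_drop_factor factor the learning rate is divided by at each drop.
#' @param lr_drop_every epochs between drops (0-based epoch indexing: with
#'   the defaults the drops land at epochs 30, 60, 90).
#' @param weight_decay L2 penalty applied to all trainable parameters.
#' @param seed integer seed controlling shuffling (and weight initialisation
#'   when the caller lets the fitter build the model).
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(batch_size = 64L, epochs = 120L, momentum = 0.9,
                         initial_lr = 0.1, lr_drop_factor = 10,
                         lr_drop_every = 30L, weight_decay = 1e-4,
                         seed = NULL) {
  stopifnot(batch_size >= 1L, epochs >= 1L, initial_lr > 0,
            lr_drop_every >= 1L, lr_drop_factor > 0, momentum >= 0,
            weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
                 lr_drop_every = as.integer(lr_drop_every),
                 weight_decay = weight_decay, seed = seed),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat("SGD training configuration\n")
  cat(sprintf("  batch size %d, %d epochs, momentum %g, weight decay %g\n",
              x$batch_size, x$epochs, x$momentum, x$weight_decay))
  cat(sprintf("  lr %g divided by %g every %d epochs\n",
              x$initial_lr, x$lr_drop_factor, x$lr_drop_every))
  invisible(x)
}

#' Learning rate at a given epoch
#'
#' Step schedule: `initial_lr / lr_drop_factor^floor(epoch / lr_drop_every)`
#' with 0-based epochs, so with the defaults the rate is 0.1 for epochs
#' 0-29, 0.01 for 30-59, 0.001 for 60-89 and 0.0001 from epoch 90 on.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < config$epochs`.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
lr_at_epoch <- function(epoch, config) {
  stopifnot(inherits(config, "train_config"))
  if (any(epoch < 0L) || any(epoch >= config$epochs))
    stop("epoch must be in [0, ", config$epochs - 1L, "]")
  config$initial_lr * config$lr_drop_factor^(-(epoch %/% config$lr_drop_every))
}

# ---- SGD with momentum over the nested parameter structure -----------------

.zeros_like_model <- function(model) {
  vel_unit <- function(unit) {
    if (unit$type == "conv") return(list(dW = list(0 * unit$conv$W)))
    list(dW = lapply(unit$convs, function(cv) 0 * cv$W),
         dWp = if (!is.null(unit$proj)) 0 * unit$proj$W,
         dgamma = lapply(unit$bns, function(b) 0 * b$gamma),
         dbeta = lapply(unit$bns, function(b) 0 * b$beta))
  }
  list(units = lapply(model$units, vel_unit),
       bn_final = list(dgamma = 0 * model$bn_final$gamma,
                       dbeta = 0 * model$bn_final$beta),
       fc = list(dW = 0 * model$fc$W, db = 0 * model$fc$b))
}

# v <- mu v - lr (g + wd w);  w <- w + v
.sgd_pair <- function(w, g, v, lr, mu, wd) {
  v <- mu * v - lr * (g + wd * w)
  list(w = w + v, v = v)
}

.sgd_step <- function(model, grads, vel, lr, mu, wd) {
  for (u in seq_along(model$units)) {
    unit <- model$units[[u]]
    g <- grads$units[[u]]
    v <- vel$units[[u]]
    if (unit$type == "conv") {
      s <- .sgd_pair(unit$conv$W, g$dW[[1L]], v$dW[[1L]], lr, mu, wd)
      unit$conv$W <- s$w; v$dW[[1L]] <- s$v
    } else {
      for (i in 1:3) {
        s <- .sgd_pair(unit$convs[[i]]$W, g$dW[[i]], v$dW[[i]], lr, mu, wd)
        unit$convs[[i]]$W <- s$w; v$dW[[i]] <- s$v
        s <- .sgd_pair(unit$bns[[i]]$gamma, g$dgamma[[i]], v$dgamma[[i]],
                       lr, mu, wd)
        unit$bns[[i]]$gamma <- s$w; v$dgamma[[i]] <- s$v
        s <- .sgd_pair(unit$bns[[i]]$beta, g$dbeta[[i]], v$dbeta[[i]],
                       lr, mu, wd)
        unit$bns[[i]]$beta <- s$w; v$dbeta[[i]] <- s$v
      }
      if (!is.null(unit$proj)) {
        s <- .sgd_pair(unit$proj$W, g$dWp, v$dWp, lr, mu, wd)
        unit$proj$W <- s$w; v$dWp <- s$v
      }
    }
    model$units[[u]] <- unit
    vel$units[[u]] <- v
  }
  s <- .sgd_pair(model$bn_final$gamma, grads$bn_final$dgamma,
                 vel$bn_final$dgamma, lr, mu, wd)
  model$bn_final$gamma <- s$w; vel$bn_final$dgamma <- s$v
  s <- .sgd_pair(model$bn_final$beta, grads$bn_final$dbeta,
                 vel$bn_final$dbeta, lr, mu, wd)
  model$bn_final$beta <- s$w; vel$bn_final$dbeta <- s$v
  s <- .sgd_pair(model$fc$W, grads$fc$dW, vel$fc$dW, lr, mu, wd)
  model$fc$W <- s$w; vel$fc$dW <- s$v
  s <- .sgd_pair(model$fc$b, grads$fc$db, vel$fc$db, lr, mu, wd)
  model$fc$b <- s$w; vel$fc$db <- s$v
  list(model = model, vel = vel)
}

#' Train a network with mini-batch SGD
#'
#' Runs exactly `config$epochs` passes over shuffled mini-batches (the last
#' incomplete batch is kept), logging per-epoch mean loss, training accuracy
#' and the learning rate from [lr_at_epoch()].  Identical seed and data give
#' identical histories and final weights.
#'
#' @param model a [build_resnet()] model.
#' @param x training windows, `n x channels x length` array.
#' @param y integer class labels in `1..num_classes` (or a factor).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with elements `model` (trained) and `history` (data frame
#'   with columns epoch, loss, train_accuracy, lr).
#' @export
train_resnet <- function(model, x, y, config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "resnet1d"), inherits(config, "train_config"))
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  n <- dim(x)[1L]
  if (n == 0L) stop("empty training set")
  if (length(y) != n) stop("length(y) must match nrow(x)")
  K <- model$config$num_classes
  if (any(y < 1L | y > K)) stop("labels must lie in 1..", K)
  if (dim(x)[2L] != model$config$input_channels ||
      dim(x)[3L] != model$config$input_length)
    stop("window shape ", dim(x)[2L], "x", dim(x)[3L],
         " does not match the model input ",
         model$config$input_channels, "x", model$config$input_length)
  with_seed(config$seed, {
    vel <- .zeros_like_model(model)
    hist <- data.frame(epoch = seq_len(config$epochs) - 1L, loss = NA_real_,
                       train_accuracy = NA_real_, lr = NA_real_)
    for (ep in seq_len(config$epochs) - 1L) {
      lr <- lr_at_epoch(ep, config)
      ord <- sample.int(n)
      tot_loss <- 0
      tot_correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        nb <- length(idx)
        A <- windows_to_matrix(x[idx, , , drop = FALSE])
        fwd <- forward_net(model, A, nb, training = TRUE, with_cache = TRUE)
        model <- fwd$model
        ce <- cross_entropy(fwd$logits, y[idx])
        grads <- backward_net(model, fwd, ce$dZ, nb)
        st <- .sgd_step(model, grads, vel, lr, config$momentum,
                        config$weight_decay)
        model <- st$model
        vel <- st$vel
        tot_loss <- tot_loss + ce$loss * nb
        tot_correct <- tot_correct +
          sum(predict_class_index(fwd$logits) == y[idx])
      }
      hist$loss[ep + 1L] <- tot_loss / n
      hist$train_accuracy[ep + 1L] <- 100 * tot_correct / n
      hist$lr[ep + 1L] <- lr
      if (verbose)
        message(sprintf("epoch %3d  lr %.4g  loss %.4f  acc %.2f%%",
                        ep, lr, hist$loss[ep + 1L],
                        hist$train_accuracy[ep + 1L]))
    }
    list(model = model, history = hist)
  })
}
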