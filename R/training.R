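#' Soft Dice loss
#'
#' `1 - (2 * sum(h * k) + eps) / (sum(h^2) + sum(k^2) + eps)` computed over
#' the foreground (kidney) class, where `h` are the estimated foreground
#' probabilities and `k` the binary reference labels. The smoothing `eps`
#' makes the all-empty case well defined (loss 0 when both `h` and `k`
#' are empty). The value lies in `[0, 1]`, is symmetric in `h` and `k`,
#' and for binary `h` equals `1 - DSC`.
#'
#' @param h numeric array of foreground probabilities
#' @param k binary array of the same shape
#' @param eps smoothing constant added to numerator and denominator
#' @export
dice_loss <- function(h, k, eps = 1e-6) {
  if (!identical(dim(h), dim(k)) || length(h) != length(k))
    stop("dice_loss: shape mismatch")
  num <- 2 * sum(h * k) + eps
  den <- sum(h * h) + sum(k * k) + eps
  if (den == 0) return(0)
  1 - num / den
}

# Per-sample foreground Dice loss over a batch plus its gradient w.r.t.
# the classifier logits (softmax folded in, 2-class case).
dice_loss_batch <- function(probs, target, eps = 1e-6) {
  d <- dim(probs)
  N <- d[4]
  losses <- numeric(N)
  dz_fg <- array(0, c(d[1], d[2], 1, N))
  for (n in seq_len(N)) {
    h <- probs[, , 2, n]
    k <- target[, , n]
    num <- 2 * sum(h * k) + eps
    den <- sum(h * h) + sum(k * k) + eps
    losses[n] <- 1 - num / den
    dh <- -(2 * k * den - num * 2 * h) / den^2
    dz_fg[, , 1, n] <- dh * h * (1 - h) / N
  }
  dz <- array(0, d)
  dz[, , 2, ] <- dz_fg
  dz[, , 1, ] <- -dz_fg
  list(loss = mean(losses), dz = dz, per_sample = losses)
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: mini-batches of 16,
#' Adam with beta1 = 0.95 (the stated "momentum"), initial learning rate
#' 1e-3 dropping to 1e-4 once 30 epochs are completed, L2 weight decay
#' 1e-4, 50 epochs, and checkpoint selection by smallest loss.
#'
#' @param batch_size mini-batch size
#' @param lr_initial learning rate for epochs `1..lr_drop_epoch`
#' @param lr_after_drop learning rate afterwards
#' @param lr_drop_epoch last epoch that still uses `lr_initial`
#' @param adam_beta1,adam_beta2 Adam moment decays
#' @param weight_decay classical L2 penalty coupled into the update
#' @param max_epochs total epochs
#' @param seed seed for shuffling (weights are seeded at build time)
#' @param smoothing_eps Dice-loss smoothing constant
#' @param val_fraction fraction of samples held out; when positive, the
#'   checkpoint is selected on held-out loss instead of training loss
#' @export
train_config <- function(batch_size = 16L, lr_initial = 1e-3,
                         lr_after_drop = 1e-4, lr_drop_epoch = 30L,
                         adam_beta1 = 0.95, adam_beta2 = 0.999,
                         weight_decay = 1e-4, max_epochs = 50L,
                         seed = 1L, smoothing_eps = 1e-6,
                         val_fraction = 0) {
  stopifnot(batch_size >= 1, lr_initial > 0, lr_after_drop > 0,
            max_epochs >= 1, weight_decay >= 0, smoothing_eps > 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_after_drop = lr_after_drop,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), smoothing_eps = smoothing_eps,
                 val_fraction = val_fraction),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr_initial` for epochs up to and including `lr_drop_epoch` (epoch 30
#' still trains at the initial rate; the drop applies once 30 epochs are
#' completed), `lr_after_drop` for later epochs.
#'
#' @param epoch 1-based epoch index
#' @param cfg a [train_config()]
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  if (epoch < 1 || epoch > cfg$max_epochs)
    stop("epoch out of range [1, ", cfg$max_epochs, "]")
  if (epoch <= cfg$lr_drop_epoch) cfg$lr_initial else cfg$lr_after_drop
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, st, lr, beta1, beta2, wd, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) stop("missing gradient for parameter ", nm)
    # L2 decay on weight tensors only; biases and BN scales are excluded
    if (wd > 0 && endsWith(nm, ".w")) g <- g + wd * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

samples_to_arrays <- function(samples) {
  d <- dim(samples[[1]]$image)
  S <- length(samples)
  X <- array(0, c(d[1], d[2], 1, S))
  K <- array(0L, c(d[1], d[2], S))
  for (i in seq_len(S)) {
    X[, , 1, i] <- samples[[i]]$image
    K[, , i] <- samples[[i]]$mask
  }
  list(X = X, K = K)
}

#' Train a segmentation network with Dice loss
#'
#' Runs `max_epochs` epochs of mini-batch Adam (beta1 = `adam_beta1`,
#' classical L2 weight decay on weight tensors) under the two-phase
#' learning-rate schedule, and returns the weights from the epoch with
#' the smallest mean loss together with the full training log. With
#' `val_fraction > 0`, a seeded held-out split is used for checkpoint
#' selection instead of the training loss.
#'
#' @param model an `rdaunet_model` (see [build_rda_unet()])
#' @param samples list of [training_sample()]s (or any lists with
#'   `image`/`mask` matrices of equal, pooling-compatible size)
#' @param cfg a [train_config()]
#' @param max_steps optional cap on the total number of optimization
#'   steps (the run stops at the end of the step that reaches it)
#' @param verbose print per-epoch progress
#' @return list with `model` (best checkpoint), `final` (last state),
#'   `log` (data frame: epoch, loss, val_loss, lr, seconds) and
#'   `best_epoch`
#' @export
train <- function(model, samples, cfg = train_config(), max_steps = Inf,
                  verbose = FALSE) {
  if (length(samples) == 0) stop("training requires at least one sample")
  with_seed(cfg$seed, {
    idx <- seq_along(samples)
    val_idx <- integer(0)
    if (cfg$val_fraction > 0) {
      n_val <- max(1L, floor(cfg$val_fraction * length(samples)))
      val_idx <- sample(idx, n_val)
      idx <- setdiff(idx, val_idx)
      if (length(idx) == 0) stop("val_fraction leaves no training samples")
    }
    tr <- samples_to_arrays(samples[idx])
    va <- if (length(val_idx)) samples_to_arrays(samples[val_idx]) else NULL
    st <- adam_init(model$params)
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      val_loss = numeric(0), lr = numeric(0),
                      seconds = numeric(0))
    best <- list(loss = Inf, params = model$params, bn = model$bn, epoch = 0L)
    steps <- 0L
    n_tr <- dim(tr$X)[4]
    for (epoch in seq_len(cfg$max_epochs)) {
      t0 <- proc.time()[["elapsed"]]
      lr <- lr_schedule(epoch, cfg)
      ord <- sample(n_tr)
      batch_losses <- c()
      for (b0 in seq(1, n_tr, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1, n_tr)]
        xb <- tr$X[, , , bi, drop = FALSE]
        kb <- tr$K[, , bi, drop = FALSE]
        fw <- net_forward(model, xb, training = TRUE)
        model$bn <- fw$model$bn
        dl <- dice_loss_batch(fw$probs, kb, cfg$smoothing_eps)
        if (!is.finite(dl$loss))
          stop("non-finite loss at epoch ", epoch, ", step ", steps + 1,
               "; aborting (check learning rate / data scaling)")
        grads <- net_backward(model, fw$caches, dl$dz)
        up <- adam_step(model$params, grads, st, lr,
                        cfg$adam_beta1, cfg$adam_beta2, cfg$weight_decay)
        model$params <- up$params
        st <- up$st
        batch_losses <- c(batch_losses, dl$loss)
        steps <- steps + 1L
        if (steps >= max_steps) break
      }
      mean_loss <- mean(batch_losses)
      val_loss <- NA_real_
      if (!is.null(va)) {
        pv <- net_forward(model, va$X, training = FALSE)$probs
        val_loss <- dice_loss_batch(pv, va$K, cfg$smoothing_eps)$loss
      }
      sel <- if (!is.null(va)) val_loss else mean_loss
      if (sel < best$loss)
        best <- list(loss = sel, params = model$params, bn = model$bn,
                     epoch = epoch)
      log <- rbind(log, data.frame(
        epoch = epoch, loss = mean_loss, val_loss = val_loss, lr = lr,
        seconds = proc.time()[["elapsed"]] - t0))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f%s  lr %.0e", epoch, mean_loss,
                        if (is.na(val_loss)) "" else sprintf("  val %.4f", val_loss),
                        lr))
      if (steps >= max_steps) break
    }
    best_model <- structure(list(params = best$params, bn = best$bn,
                                 cfg = model$cfg), class = "rdaunet_model")
    list(model = best_model, final = model, log = log,
         best_epoch = best$epoch)
  })
}
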