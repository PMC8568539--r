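#' Network architecture configuration
#'
#' Describes the U-shaped encoder-bottleneck-decoder-classifier topology.
#' The encoder applies `depth` feature blocks, each followed by 2x2 max
#' pooling; channel width doubles per level starting at `base_channels`.
#' The bottleneck is two 3x3 convolution layers. The decoder mirrors the
#' encoder with 2x2 transposed-convolution upsampling and concatenation
#' skip connections to the same-level encoder output. The classifier is a
#' 1x1 convolution to `n_classes` followed by a per-pixel softmax. All
#' convolutions are zero-padded so spatial size is preserved; batch
#' normalization follows every convolution when `use_batch_norm`.
#'
#' @param depth number of pooling stages (input side must be divisible by
#'   `2^depth`)
#' @param base_channels channels of the first encoder block
#' @param in_channels input image channels
#' @param n_classes output classes (2: background / kidney)
#' @param use_batch_norm apply batch normalization after each convolution
#' @param arch `"rda"` for residual dual-attention blocks, `"unet"` for
#'   plain double-convolution blocks
#' @export
rdaunet_config <- function(depth = 4L, base_channels = 32L, in_channels = 1L,
                           n_classes = 2L, use_batch_norm = TRUE,
                           arch = c("rda", "unet")) {
  arch <- match.arg(arch)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 use_batch_norm = isTRUE(use_batch_norm),
                 arch = arch),
            class = "rdaunet_config")
}

init_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

channel_plan <- function(cfg) {
  enc_out <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)
  list(enc_in = c(cfg$in_channels, enc_out[-cfg$depth]),
       enc_out = enc_out,
       bott = cfg$base_channels * 2^cfg$depth)
}

init_block <- function(P, bn, cfg, prefix, cin, cout) {
  nm <- function(s) paste0(prefix, ".", s)
  P[[nm("conv1.w")]] <- init_conv(3, 3, cin, cout)
  P[[nm("conv1.b")]] <- numeric(cout)
  P[[nm("conv2.w")]] <- init_conv(3, 3, cout, cout)
  P[[nm("conv2.b")]] <- numeric(cout)
  if (cfg$use_batch_norm) {
    for (s in c("bn1", "bn2")) {
      P[[nm(paste0(s, ".g"))]] <- rep(1, cout)
      P[[nm(paste0(s, ".b"))]] <- numeric(cout)
      bn[[nm(s)]] <- list(rm = numeric(cout), rv = rep(1, cout))
    }
  }
  if (cfg$arch == "rda") {
    P[[nm("attn.q.w")]] <- init_conv(1, 1, cout, 1)
    P[[nm("attn.q.b")]] <- numeric(1)
    P[[nm("attn.p.w")]] <- matrix(rnorm(cout * cout, 0, sqrt(2 / cout)), cout, cout)
    P[[nm("attn.p.b")]] <- numeric(cout)
    if (cin != cout) {
      P[[nm("proj.w")]] <- init_conv(1, 1, cin, cout)
      P[[nm("proj.b")]] <- numeric(cout)
    }
  }
  list(P = P, bn = bn)
}

#' Build a residual dual-attention U-Net
#'
#' @param cfg an [rdaunet_config()] (its `arch` field is forced to
#'   `"rda"`)
#' @param seed seed for the He-normal weight initialization
#' @return an `rdaunet_model`: list with `params`, batch-norm running
#'   statistics `bn`, and `cfg`
#' @export
build_rda_unet <- function(cfg = rdaunet_config(), seed = 1L) {
  cfg$arch <- "rda"
  build_network(cfg, seed)
}

#' Build a plain U-Net baseline
#'
#' Identical topology with the residual dual-attention block replaced by a
#' plain double-convolution block; batch normalization is toggled by
#' `with_bn`.
#'
#' @param cfg an [rdaunet_config()]
#' @param with_bn include batch normalization
#' @param seed initialization seed
#' @export
build_unet_baseline <- function(cfg = rdaunet_config(), with_bn = TRUE,
                                seed = 1L) {
  cfg$arch <- "unet"
  cfg$use_batch_norm <- isTRUE(with_bn)
  build_network(cfg, seed)
}

build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "rdaunet_config"))
  with_seed(seed, {
    P <- list(); bn <- list()
    ch <- channel_plan(cfg)
    for (i in seq_len(cfg$depth)) {
      r <- init_block(P, bn, cfg, paste0("enc", i), ch$enc_in[i], ch$enc_out[i])
      P <- r$P; bn <- r$bn
    }
    # bottleneck: two conv(3x3)->BN->ReLU layers
    P[["bott.conv1.w"]] <- init_conv(3, 3, ch$enc_out[cfg$depth], ch$bott)
    P[["bott.conv1.b"]] <- numeric(ch$bott)
    P[["bott.conv2.w"]] <- init_conv(3, 3, ch$bott, ch$bott)
    P[["bott.conv2.b"]] <- numeric(ch$bott)
    if (cfg$use_batch_norm) {
      for (s in c("bott.bn1", "bott.bn2")) {
        P[[paste0(s, ".g")]] <- rep(1, ch$bott)
        P[[paste0(s, ".b")]] <- numeric(ch$bott)
        bn[[s]] <- list(rm = numeric(ch$bott), rv = rep(1, ch$bott))
      }
    }
    for (i in rev(seq_len(cfg$depth))) {
      above <- if (i == cfg$depth) ch$bott else ch$enc_out[i + 1]
      P[[paste0("dec", i, ".up.w")]] <- init_conv(2, 2, above, ch$enc_out[i])
      P[[paste0("dec", i, ".up.b")]] <- numeric(ch$enc_out[i])
      r <- init_block(P, bn, cfg, paste0("dec", i),
                      2L * ch$enc_out[i], ch$enc_out[i])
      P <- r$P; bn <- r$bn
    }
    P[["cls.w"]] <- init_conv(1, 1, ch$enc_out[1], cfg$n_classes)
    P[["cls.b"]] <- numeric(cfg$n_classes)
    structure(list(params = P, bn = bn, cfg = cfg), class = "rdaunet_model")
  })
}

#' Number of trainable parameters
#' @param model an `rdaunet_model`
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

block_fwd <- function(P, bn, cfg, prefix, x, training) {
  nm <- function(s) paste0(prefix, ".", s)
  use_bn <- cfg$use_batch_norm
  cache <- list()
  cbr <- function(h, conv, bnname, tag) {
    cv <- conv_fwd(h, P[[nm(paste0(conv, ".w"))]], P[[nm(paste0(conv, ".b"))]], 1L)
    cache[[paste0("c", tag)]] <<- cv$cache
    h <- cv$y
    if (use_bn) {
      r <- bn_fwd(h, P[[nm(paste0(bnname, ".g"))]], P[[nm(paste0(bnname, ".b"))]],
                  bn[[nm(bnname)]], training)
      h <- r$y
      cache[[paste0("b", tag)]] <<- r$cache
      bn[[nm(bnname)]] <<- r$state
    }
    r <- relu_fwd(h)
    cache[[paste0("r", tag)]] <<- r$cache
    r$y
  }
  h <- cbr(x, "conv1", "bn1", 1)
  h <- cbr(h, "conv2", "bn2", 2)
  if (cfg$arch == "rda") {
    att <- dual_attention(h, list(q.w = P[[nm("attn.q.w")]],
                                  q.b = P[[nm("attn.q.b")]],
                                  p.w = P[[nm("attn.p.w")]],
                                  p.b = P[[nm("attn.p.b")]]))
    cache$att <- att$cache
    gates <- list(q = att$q, p = att$p)
    if (!is.null(P[[nm("proj.w")]])) {
      pr <- conv_fwd(x, P[[nm("proj.w")]], P[[nm("proj.b")]], 0L)
      cache$proj <- pr$cache
      res <- pr$y
    } else res <- x
    pre <- att$y + res
    cache$rf <- pre > 0
    h <- pmax(pre, 0)
  } else gates <- NULL
  list(y = h, cache = cache, bn = bn, gates = gates)
}

add_grad <- function(G, name, g) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

block_bwd <- function(P, cfg, prefix, cache, dy, G) {
  nm <- function(s) paste0(prefix, ".", s)
  use_bn <- cfg$use_batch_norm
  if (cfg$arch == "rda") {
    dpre <- dy * cache$rf
    ab <- dual_attention_bwd(dpre, cache$att)
    add_grad(G, nm("attn.q.w"), ab$dq.w); add_grad(G, nm("attn.q.b"), ab$dq.b)
    add_grad(G, nm("attn.p.w"), ab$dp.w); add_grad(G, nm("attn.p.b"), ab$dp.b)
    dh <- ab$dx
    if (!is.null(cache$proj)) {
      pb <- conv_bwd(dpre, cache$proj)
      add_grad(G, nm("proj.w"), pb$dw); add_grad(G, nm("proj.b"), pb$db)
      dx_res <- pb$dx
    } else dx_res <- dpre
  } else {
    dh <- dy
    dx_res <- NULL
  }
  dh <- relu_bwd(dh, cache$r2)
  if (use_bn) {
    b <- bn_bwd(dh, cache$b2)
    add_grad(G, nm("bn2.g"), b$dgamma); add_grad(G, nm("bn2.b"), b$dbeta)
    dh <- b$dx
  }
  cb <- conv_bwd(dh, cache$c2)
  add_grad(G, nm("conv2.w"), cb$dw); add_grad(G, nm("conv2.b"), cb$db)
  dh <- cb$dx
  dh <- relu_bwd(dh, cache$r1)
  if (use_bn) {
    b <- bn_bwd(dh, cache$b1)
    add_grad(G, nm("bn1.g"), b$dgamma); add_grad(G, nm("bn1.b"), b$dbeta)
    dh <- b$dx
  }
  cb <- conv_bwd(dh, cache$c1)
  add_grad(G, nm("conv1.w"), cb$dw); add_grad(G, nm("conv1.b"), cb$db)
  dx <- cb$dx
  if (!is.null(dx_res)) dx <- dx + dx_res
  dx
}

#' Forward pass of a segmentation network
#'
#' @param model an `rdaunet_model`
#' @param x input, promoted to an (H, W, C, N) array; H and W must be
#'   divisible by `2^depth`
#' @param training use batch statistics for normalization and record the
#'   caches needed by [net_backward()]
#' @return list with `probs` (H, W, n_classes, N softmax output), `model`
#'   (with updated batch-norm running statistics when training) and, when
#'   training, `caches`
#' @export
net_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] %% 2^cfg$depth || d[2] %% 2^cfg$depth)
    stop(sprintf("input size %dx%d is not divisible by 2^depth = %d",
                 d[1], d[2], 2^cfg$depth))
  if (d[3] != cfg$in_channels)
    stop(sprintf("input has %d channels, config expects %d", d[3], cfg$in_channels))
  P <- model$params; bn <- model$bn
  caches <- list(enc = vector("list", cfg$depth),
                 dec = vector("list", cfg$depth))
  gates <- list()
  skips <- vector("list", cfg$depth)
  h <- x
  for (i in seq_len(cfg$depth)) {
    b <- block_fwd(P, bn, cfg, paste0("enc", i), h, training)
    bn <- b$bn
    skips[[i]] <- b$y
    p <- pool_fwd(b$y)
    if (training) caches$enc[[i]] <- list(block = b$cache, pool = p$cache)
    if (!is.null(b$gates)) gates[[paste0("enc", i)]] <- b$gates
    h <- p$y
  }
  bc <- list()
  for (k in 1:2) {
    cv <- conv_fwd(h, P[[paste0("bott.conv", k, ".w")]],
                   P[[paste0("bott.conv", k, ".b")]], 1L)
    bc[[paste0("c", k)]] <- cv$cache
    h <- cv$y
    if (cfg$use_batch_norm) {
      s <- paste0("bott.bn", k)
      r <- bn_fwd(h, P[[paste0(s, ".g")]], P[[paste0(s, ".b")]], bn[[s]], training)
      h <- r$y; bc[[paste0("b", k)]] <- r$cache; bn[[s]] <- r$state
    }
    r <- relu_fwd(h); h <- r$y; bc[[paste0("r", k)]] <- r$cache
  }
  if (training) caches$bott <- bc
  for (i in rev(seq_len(cfg$depth))) {
    up <- upconv_fwd(h, P[[paste0("dec", i, ".up.w")]],
                     P[[paste0("dec", i, ".up.b")]])
    cat_in <- concat_ch(up$y, skips[[i]])
    b <- block_fwd(P, bn, cfg, paste0("dec", i), cat_in, training)
    bn <- b$bn
    if (training) caches$dec[[i]] <- list(up = up$cache, block = b$cache,
                                          n_up = dim(up$y)[3])
    if (!is.null(b$gates)) gates[[paste0("dec", i)]] <- b$gates
    h <- b$y
  }
  cv <- conv_fwd(h, P[["cls.w"]], P[["cls.b"]], 0L)
  caches$cls <- cv$cache
  probs <- softmax_ch(cv$y)
  model$bn <- bn
  out <- list(probs = probs, logits = cv$y, model = model, gates = gates)
  if (training) out$caches <- caches
  out
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param model the model used in the forward pass
#' @param caches caches from `net_forward(..., training = TRUE)`
#' @param dz gradient of the loss w.r.t. the classifier logits
#' @return named list of gradients aligned with `model$params`
#' @export
net_backward <- function(model, caches, dz) {
  cfg <- model$cfg
  P <- model$params
  G <- new.env(parent = emptyenv())
  cb <- conv_bwd(dz, caches$cls)
  add_grad(G, "cls.w", cb$dw); add_grad(G, "cls.b", cb$db)
  dh <- cb$dx
  dskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    dc <- caches$dec[[i]]
    dcat <- block_bwd(P, cfg, paste0("dec", i), dc$block, dh, G)
    n_up <- dc$n_up
    dup <- dcat[, , seq_len(n_up), , drop = FALSE]
    dskips[[i]] <- dcat[, , n_up + seq_len(dim(dcat)[3] - n_up), , drop = FALSE]
    ub <- upconv_bwd(dup, dc$up)
    add_grad(G, paste0("dec", i, ".up.w"), ub$dw)
    add_grad(G, paste0("dec", i, ".up.b"), ub$db)
    dh <- ub$dx
  }
  for (k in 2:1) {
    bc <- caches$bott
    dh <- relu_bwd(dh, bc[[paste0("r", k)]])
    if (cfg$use_batch_norm) {
      b <- bn_bwd(dh, bc[[paste0("b", k)]])
      add_grad(G, paste0("bott.bn", k, ".g"), b$dgamma)
      add_grad(G, paste0("bott.bn", k, ".b"), b$dbeta)
      dh <- b$dx
    }
    cb <- conv_bwd(dh, bc[[paste0("c", k)]])
    add_grad(G, paste0("bott.conv", k, ".w"), cb$dw)
    add_grad(G, paste0("bott.conv", k, ".b"), cb$db)
    dh <- cb$dx
  }
  for (i in rev(seq_len(cfg$depth))) {
    ec <- caches$enc[[i]]
    denc <- pool_bwd(dh, ec$pool) + dskips[[i]]
    dh <- block_bwd(P, cfg, paste0("enc", i), ec$block, denc, G)
  }
  grads <- as.list(G)
  grads[names(model$params)]
}

#' Residual dual-attention block applied standalone
#'
#' Convenience wrapper running one RDA block (two 3x3 convolutions with
#' optional batch normalization, dual attention, identity residual, final
#' ReLU) outside a full network; used for unit-level verification.
#'
#' @param x input feature map
#' @param cin,cout channel counts
#' @param use_batch_norm include batch normalization
#' @param seed initialization seed
#' @param params optional explicit parameter list (names as produced by
#'   the initializer, prefix `blk`)
#' @export
rda_block <- function(x, cin = NULL, cout = NULL, use_batch_norm = FALSE,
                      seed = 1L, params = NULL) {
  x <- as_feature_map(x)
  if (is.null(cin)) cin <- dim(x)[3]
  if (is.null(cout)) cout <- cin
  cfg <- rdaunet_config(depth = 1L, base_channels = cout, in_channels = cin,
                        use_batch_norm = use_batch_norm, arch = "rda")
  if (is.null(params)) {
    r <- with_seed(seed, init_block(list(), list(), cfg, "blk", cin, cout))
    params <- r$P
    bn <- r$bn
  } else {
    bn <- list()
    if (use_batch_norm)
      for (s in c("blk.bn1", "blk.bn2"))
        bn[[s]] <- list(rm = numeric(cout), rv = rep(1, cout))
  }
  b <- block_fwd(params, bn, cfg, "blk", x, training = TRUE)
  list(y = b$y, params = params)
}

#' Predict class probabilities for images
#'
#' @param model trained `rdaunet_model`
#' @param images a matrix, an (H, W, N) array, or a list of matrices
#' @return (H, W, n_classes, N) array of per-pixel class probabilities
#' @export
predict_probs <- function(model, images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(unlist(images, use.names = FALSE), c(d[1], d[2], length(images)))
  } else x <- images
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  dim(x) <- c(dim(x)[1], dim(x)[2], 1L, dim(x)[3])
  net_forward(model, x, training = FALSE)$probs
}

#' Predict a binary kidney mask for one image
#'
#' Argmax of the softmax output (foreground = class 2).
#'
#' @param model trained `rdaunet_model`
#' @param image numeric matrix in `[0, 1]`
#' @return binary integer matrix
#' @export
predict_mask <- function(model, image) {
  p <- predict_probs(model, image)
  (p[, , 2, 1] > p[, , 1, 1]) + 0L
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture configuration, the parameters
#' and the batch-norm running statistics in R's native serialization
#' format.
#'
#' @param model an `rdaunet_model`
#' @param path file path (conventionally `.rds`)
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "rdaunet-checkpoint-1", cfg = model$cfg,
               params = model$params, bn = model$bn), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "rdaunet-checkpoint-1"))
    stop("not an rdaunet checkpoint: ", path)
  structure(list(params = ck$params, bn = ck$bn, cfg = ck$cfg),
            class = "rdaunet_model")
}

#' @export
print.rdaunet_model <- function(x, ...) {
  cat(sprintf("%s network: depth %d, base channels %d, %s, %s parameters\n",
              toupper(x$cfg$arch), x$cfg$depth, x$cfg$base_channels,
              if (x$cfg$use_batch_norm) "BN" else "no BN",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}
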