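test_that("dual attention with zero gate weights is the identity (0.5F + 0.5F)", {
  set.seed(1)
  f <- array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  params <- list(q.w = array(0, c(1, 1, 3, 1)), q.b = 0,
                 p.w = matrix(0, 3, 3), p.b = numeric(3))
  out <- dual_attention(f, params)
  expect_equal(out$y, f)
  expect_true(all(out$q == 0.5) && all(out$p == 0.5))
})

test_that("dual attention matches the scalar brute-force oracle", {
  set.seed(21)
  for (dims in list(c(2, 2, 1), c(4, 4, 2), c(3, 4, 2))) {
    f <- array(rnorm(prod(dims)), c(dims, 1))
    C <- dims[3]
    params <- list(q.w = array(rnorm(C), c(1, 1, C, 1)), q.b = rnorm(1),
                   p.w = matrix(rnorm(C * C), C, C), p.b = rnorm(C))
    got <- dual_attention(f, params)
    want <- oracle_dual_attention(f, params$q.w, params$q.b,
                                  params$p.w, params$p.b)
    expect_lt(max(abs(got$y - want$y)), 1e-6)
    expect_lt(max(abs(got$q[, , 1, 1] - want$q)), 1e-6)
    # attention gates stay strictly inside (0, 1)
    expect_true(all(got$q > 0 & got$q < 1))
    expect_true(all(got$p > 0 & got$p < 1))
    # hand case from the 2x2x1 grid [[1,2],[3,4]]
  }
  f <- array(c(1, 3, 2, 4), c(2, 2, 1, 1))
  params <- list(q.w = array(0.5, c(1, 1, 1, 1)), q.b = -1,
                 p.w = matrix(2, 1, 1), p.b = 0.25)
  got <- dual_attention(f, params)
  want <- oracle_dual_attention(f, params$q.w, params$q.b, params$p.w, params$p.b)
  expect_lt(max(abs(got$y - want$y)), 1e-12)
})

test_that("rda_block output is non-negative and respects the residual path", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  out <- rda_block(x, seed = 3)
  expect_identical(dim(out$y), dim(x))
  expect_true(all(out$y >= 0))
  # zero input with zero biases gives zero output
  z <- rda_block(array(0, c(8, 8, 4, 1)), seed = 3)
  expect_true(all(z$y == 0))
  # conv branch forced to zero: block reduces to ReLU(0 + x) = ReLU(x)
  p <- rda_block(x, seed = 3)$params
  for (nm in c("blk.conv1.w", "blk.conv1.b", "blk.conv2.w", "blk.conv2.b"))
    p[[nm]] <- p[[nm]] * 0
  out0 <- rda_block(x, params = p)
  expect_equal(out0$y, pmax(x, 0))
})

test_that("convolution kernels agree with a naive R convolution", {
  naive_conv <- function(x, w, b, pad) {
    d <- dim(x); dw <- dim(w)
    Ho <- d[1] + 2 * pad - dw[1] + 1; Wo <- d[2] + 2 * pad - dw[2] + 1
    xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
    y <- array(0, c(Ho, Wo, dw[4], d[4]))
    for (n in seq_len(d[4])) for (co in seq_len(dw[4]))
      for (oi in seq_len(Ho)) for (oj in seq_len(Wo))
        y[oi, oj, co, n] <- b[co] +
          sum(xp[oi:(oi + dw[1] - 1), oj:(oj + dw[2] - 1), , n] * w[, , , co])
    y
  }
  set.seed(9)
  x <- array(rnorm(6 * 5 * 3 * 2), c(6, 5, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  expect_lt(max(abs(rdaunet:::.conv2d_fwd(x, w, b, 1L) - naive_conv(x, w, b, 1))),
            1e-12)
  w1 <- array(rnorm(3 * 2), c(1, 1, 3, 2))
  expect_lt(max(abs(rdaunet:::.conv2d_fwd(x, w1, b[1:2], 0L) -
                      naive_conv(x, w1, b[1:2], 0))), 1e-12)
})

test_that("network preserves spatial shape and emits a per-pixel softmax", {
  cfg <- rdaunet_config(depth = 3, base_channels = 4)
  m <- build_rda_unet(cfg, seed = 2)
  for (side in c(32L, 48L)) {
    x <- array(runif(side * side), c(side, side, 1, 1))
    out <- net_forward(m, x)
    expect_identical(dim(out$probs), c(side, side, 2L, 1L))
    expect_lt(max(abs(out$probs[, , 1, 1] + out$probs[, , 2, 1] - 1)), 1e-6)
    expect_true(all(out$probs > 0 & out$probs < 1))
  }
  expect_error(net_forward(m, array(0, c(36, 36, 1, 1))), "divisible")
})

test_that("parameter counts order as expected across architectures", {
  cfg <- rdaunet_config(depth = 3, base_channels = 8)
  n_rda <- n_parameters(build_rda_unet(cfg, seed = 1))
  n_bn <- n_parameters(build_unet_baseline(cfg, with_bn = TRUE, seed = 1))
  n_plain <- n_parameters(build_unet_baseline(cfg, with_bn = FALSE, seed = 1))
  expect_lt(n_plain, n_bn)
  expect_gt(n_rda, n_bn)
})

test_that("analytic gradients match finite differences on a tiny network", {
  for (setting in list(list(arch = "rda", bn = TRUE),
                       list(arch = "rda", bn = FALSE),
                       list(arch = "unet", bn = TRUE))) {
    cfg <- rdaunet_config(depth = 2, base_channels = 3,
                          use_batch_norm = setting$bn, arch = setting$arch)
    m <- rdaunet:::build_network(cfg, seed = 7)
    set.seed(11)
    x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
    k <- array((array(runif(8 * 8 * 2), c(8, 8, 2)) > 0.6) + 0, c(8, 8, 2))
    fw <- net_forward(m, x, training = TRUE)
    dl <- rdaunet:::dice_loss_batch(fw$probs, k)
    gr <- net_backward(m, fw$caches, dl$dz)
    loss_of <- function(model) {
      f <- net_forward(model, x, training = TRUE)
      rdaunet:::dice_loss_batch(f$probs, k)$loss
    }
    set.seed(99)
    for (rep in 1:12) {
      nm <- sample(names(m$params), 1)
      i <- sample(length(m$params[[nm]]), 1)
      h <- 1e-5
      m1 <- m; m1$params[[nm]][i] <- m1$params[[nm]][i] + h
      m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] - h
      fd <- (loss_of(m1) - loss_of(m2)) / (2 * h)
      expect_lt(abs(fd - gr[[nm]][i]) / max(1e-6, abs(fd), abs(gr[[nm]][i])),
                2e-3)
    }
  }
})

test_that("every parameter receives gradient signal (no dead paths)", {
  cfg <- rdaunet_config(depth = 2, base_channels = 3)
  m <- build_rda_unet(cfg, seed = 4)
  set.seed(12)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  k <- array((array(runif(8 * 8 * 2), c(8, 8, 2)) > 0.5) + 0, c(8, 8, 2))
  fw <- net_forward(m, x, training = TRUE)
  dl <- rdaunet:::dice_loss_batch(fw$probs, k)
  gr <- net_backward(m, fw$caches, dl$dz)
  expect_setequal(names(gr), names(m$params))
  nonzero <- vapply(gr, function(g) any(g != 0), TRUE)
  expect_true(all(nonzero))
})

test_that("checkpoints round-trip through save_model/load_model", {
  dir <- withr::local_tempdir()
  m <- build_rda_unet(rdaunet_config(depth = 2, base_channels = 2), seed = 8)
  f <- file.path(dir, "ck.rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$params, m$params)
  expect_equal(m2$cfg, m$cfg)
  expect_error(load_model(file.path(dir, "absent.rds")), "not found")
})
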