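test_that("confusion counts match a per-pixel enumeration oracle", {
  true <- matrix(0L, 3, 3); true[1:2, ] <- 1L          # top 2 rows
  pred <- matrix(0L, 3, 3); pred[, 1:2] <- 1L; pred[2, 2] <- 1L
  expect_identical(confusion(pred, true), oracle_confusion(pred, true))
  # identical and all-background edge cases
  m <- matrix(0L, 4, 4); m[2:3, 2:3] <- 1L
  m10 <- matrix(0L, 5, 4); m10[1:5, 1:2] <- 1L
  expect_identical(confusion(m10, m10), list(sq = 10L, hq = 0L, hm = 0L))
  true7 <- matrix(0L, 3, 3); true7[1:3, 1:2] <- 1L; true7[1, 3] <- 1L
  expect_identical(confusion(matrix(0L, 3, 3), true7),
                   list(sq = 0L, hq = 0L, hm = 7L))
  set.seed(17)
  for (i in 1:20) {
    p <- matrix(sample(0:1, 35, replace = TRUE), 7, 5)
    t <- matrix(sample(0:1, 35, replace = TRUE), 7, 5)
    expect_identical(confusion(p, t), oracle_confusion(p, t))
  }
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("dsc follows 2|E^F|/(|E|+|F|) with the empty-empty convention", {
  m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L
  expect_identical(dsc(m, m), 1)
  disj <- matrix(0L, 4, 4); disj[3:4, 3:4] <- 1L
  expect_identical(dsc(m, disj), 0)
  # |E| = 8, |F| = 8, |E^F| = 6 -> 0.75
  e <- matrix(0L, 4, 4); e[1:2, ] <- 1L
  f <- matrix(0L, 4, 4); f[1:2, 1:3] <- 1L; f[3, 1:2] <- 1L
  expect_identical(sum(e), 8L); expect_identical(sum(f), 8L)
  expect_identical(sum(e & f), 6L)
  expect_identical(dsc(e, f), 0.75)
  expect_identical(dsc(matrix(0L, 2, 2), matrix(0L, 2, 2)), 1)
})

test_that("precision/recall arithmetic and empty-denominator conventions", {
  expect_equal(precision_recall(list(sq = 6, hq = 2, hm = 2)),
               c(precision = 0.75, recall = 0.75))
  expect_equal(precision_recall(list(sq = 3, hq = 1, hm = 0)),
               c(precision = 0.75, recall = 1))
  expect_equal(precision_recall(list(sq = 0, hq = 0, hm = 0)),
               c(precision = 1, recall = 1))
})

test_that("left/right split partitions the mask and matches phantom labels", {
  m <- matrix(0L, 6, 8); m[2:4, 2:3] <- 1L; m[3:5, 6:7] <- 1L
  sp <- split_left_right(m, dividing_column = 5L)
  expect_identical((sp$left | sp$right) + 0L, m)       # OR restores input
  expect_identical(sum(sp$left & sp$right), 0L)        # disjoint
  # mask entirely left of the dividing line
  only <- matrix(0L, 4, 6); only[, 1:2] <- 1L
  sp2 <- split_left_right(only, 4L)
  expect_identical(sp2$right, only)
  expect_identical(sum(sp2$left), 0L)
  # neurological convention swaps sides
  sp3 <- split_left_right(only, 4L, convention = "neurological")
  expect_identical(sp3$left, only)
  # phantom ground truth: split agrees with side labels on every pixel
  s <- generate_slice(tiny_spec(seed = 13L, n_cysts_per_kidney = 1L))
  sp4 <- split_left_right(s$mask, s$spine_column)
  expect_identical((sp4$left > 0) + 0L, (s$side_labels == 1L) + 0L)
  expect_identical((sp4$right > 0) + 0L, (s$side_labels == 2L) + 0L)
})

test_that("evaluate pools counts over slices and honors oracle predictors", {
  spec <- tiny_spec(seed = 3L)
  samples <- phantom_samples(spec, 1:3)
  div <- vapply(samples, function(s) s$spine, 0L)
  # a perfect oracle scores 1 everywhere
  masks <- lapply(samples, `[[`, "mask")
  i <- 0
  oracle <- function(img) { i <<- i + 1; masks[[i]] }
  rep <- evaluate(oracle, samples, dividing_column = div)
  for (side in c("left", "right")) {
    expect_identical(rep[[side]]$dsc, 1)
    expect_identical(rep[[side]]$precision, 1)
    expect_identical(rep[[side]]$recall, 1)
  }
  # the all-background predictor has zero recall
  rep0 <- evaluate(function(img) matrix(0L, nrow(img), ncol(img)),
                   samples, dividing_column = div)
  expect_identical(rep0$left$recall, 0)
  expect_identical(rep0$right$recall, 0)
  expect_error(evaluate(oracle, list()), "empty")
})

test_that("pooled metrics equal count-sum arithmetic on a hand-built set", {
  # slice 1: sq 4, hq 1, hm 2 on the left side; slice 2: sq 2, hq 3, hm 0
  t1 <- matrix(0L, 4, 8); t1[1:3, 6:7] <- 1L            # 6 left kidney px
  p1 <- matrix(0L, 4, 8); p1[1:2, 6:7] <- 1L; p1[4, 8] <- 1L
  t2 <- matrix(0L, 4, 8); t2[1, 6:7] <- 1L
  p2 <- matrix(0L, 4, 8); p2[1, 6:7] <- 1L; p2[2:4, 6] <- 1L
  samples <- list(list(image = t1 * 0, mask = t1), list(image = t2 * 0, mask = t2))
  preds <- list(p1, p2)
  i <- 0
  rep <- evaluate(function(img) { i <<- i + 1; preds[[i]] },
                  samples, dividing_column = 5L)
  sq <- 4 + 2; hq <- 1 + 3; hm <- 2 + 0
  expect_equal(rep$left$dsc, 2 * sq / (2 * sq + hq + hm))
  expect_equal(rep$left$precision, sq / (sq + hq))
  expect_equal(rep$left$recall, sq / (sq + hm))
  # micro != macro here, and the flag switches the headline number
  repm <- evaluate(function(img) { i <<- i - 1; preds[[i + 1]] },
                   samples[2:1], dividing_column = 5L, aggregate = "per_slice")
  expect_equal(repm$left$dsc, repm$left$dsc_macro)
})

test_that("metrics are invariant under a mirrored evaluation", {
  set.seed(23)
  n <- 10L
  pred <- matrix(sample(0:1, n * n, replace = TRUE, prob = c(0.8, 0.2)), n, n)
  true <- matrix(sample(0:1, n * n, replace = TRUE, prob = c(0.8, 0.2)), n, n)
  d <- 6L
  flip <- function(m) m[, n:1]
  orig <- split_left_right(pred, d)
  mirr <- split_left_right(flip(pred), n + 2L - d)
  truo <- split_left_right(true, d)
  trum <- split_left_right(flip(true), n + 2L - d)
  expect_identical(dsc(orig$left, truo$left), dsc(mirr$right, trum$right))
  expect_identical(dsc(orig$right, truo$right), dsc(mirr$left, trum$left))
  cc_o <- confusion(orig$left, truo$left)
  cc_m <- confusion(mirr$right, trum$right)
  expect_identical(cc_o, cc_m)
})

test_that("report_table lays out per-model rows", {
  s <- generate_slice(tiny_spec(seed = 4L))
  samples <- list(c(prepare_sample(s), list(spine = s$spine_column)))
  rep <- evaluate(function(img) s$mask, samples,
                  dividing_column = s$spine_column)
  tb <- report_table(list(oracle = rep))
  expect_identical(nrow(tb), 1L)
  expect_identical(tb$left_dsc, 1)
  expect_named(tb, c("model", "left_dsc", "left_precision", "left_recall",
                     "right_dsc", "right_precision", "right_recall"))
})
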