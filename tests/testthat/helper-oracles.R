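# Independent brute-force oracles used across tests. These deliberately
# use naive per-element loops so they share no code path with the
# implementation they check.

# Count grid pixels (1-based centers) inside an ellipse.
oracle_ellipse_pixels <- function(n, center_row, center_col, semi_row, semi_col) {
  count <- 0L
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if (((r - center_row) / semi_row)^2 + ((c - center_col) / semi_col)^2 <= 1)
      count <- count + 1L
  }
  count
}

# Per-pixel confusion tally by explicit double loop.
oracle_confusion <- function(pred, true) {
  sq <- hq <- hm <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] > 0; t <- true[i, j] > 0
    if (p && t) sq <- sq + 1L
    else if (p && !t) hq <- hq + 1L
    else if (!p && t) hm <- hm + 1L
  }
  list(sq = sq, hq = hq, hm = hm)
}

# Scalar-by-scalar evaluation of the dual-attention sum
# Y' = Q(F) * F + P(F) * F for a (H, W, C, 1) input.
oracle_dual_attention <- function(f, q_w, q_b, p_w, p_b) {
  d <- dim(f)
  H <- d[1]; W <- d[2]; C <- d[3]
  sig <- function(z) 1 / (1 + exp(-z))
  out <- array(0, d)
  # spatial mask Q: one value per position
  q <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- q_b
    for (c in seq_len(C)) acc <- acc + f[i, j, c, 1] * q_w[1, 1, c, 1]
    q[i, j] <- sig(acc)
  }
  # channel code P: one value per channel, from global average pooling
  p <- numeric(C)
  for (co in seq_len(C)) {
    acc <- p_b[co]
    for (ci in seq_len(C)) acc <- acc + mean(f[, , ci, 1]) * p_w[ci, co]
    p[co] <- sig(acc)
  }
  for (i in seq_len(H)) for (j in seq_len(W)) for (c in seq_len(C))
    out[i, j, c, 1] <- q[i, j] * f[i, j, c, 1] + p[c] * f[i, j, c, 1]
  list(y = out, q = q, p = p)
}

# Small phantom configuration used wherever tests need fast slices.
tiny_spec <- function(...) {
  args <- utils::modifyList(list(image_size = 64L, pixel_spacing_mm = 2.5),
                            list(...))
  do.call(phantom_spec, args)
}

# Build a labelled sample list for training/evaluation tests.
phantom_samples <- function(spec, seeds) {
  lapply(seeds, function(s) {
    sl <- generate_slice(spec, slice_seed = s)
    c(prepare_sample(sl), list(spine = sl$spine_column, side = sl$side_labels))
  })
}
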