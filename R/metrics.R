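#' Pixelwise confusion counts for a binary segmentation
#'
#' `sq` counts kidney pixels correctly predicted (true positives), `hq`
#' background pixels predicted as kidney (false positives), and `hm`
#' kidney pixels predicted as background (false negatives).
#'
#' @param pred_mask,true_mask binary arrays of equal shape
#' @return list with integer `sq`, `hq`, `hm`
#' @export
confusion <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask)))
    stop("confusion: mask shape mismatch")
  p <- pred_mask > 0
  t <- true_mask > 0
  list(sq = sum(p & t), hq = sum(p & !t), hm = sum(!p & t))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |E intersect F| / (|E| + |F|)` for prediction `E` and reference `F`;
#' defined as 1 when both masks are empty.
#'
#' @inheritParams confusion
#' @export
dsc <- function(pred_mask, true_mask) {
  cc <- confusion(pred_mask, true_mask)
  den <- 2 * cc$sq + cc$hq + cc$hm
  if (den == 0) return(1)
  2 * cc$sq / den
}

#' Precision and recall from confusion counts
#'
#' Precision `sq / (sq + hq)`, recall `sq / (sq + hm)`; each defined as 1
#' when its denominator is 0.
#'
#' @param counts list with `sq`, `hq`, `hm` (see [confusion()])
#' @return named numeric vector `c(precision, recall)`
#' @export
precision_recall <- function(counts) {
  pr <- if (counts$sq + counts$hq == 0) 1 else counts$sq / (counts$sq + counts$hq)
  rc <- if (counts$sq + counts$hm == 0) 1 else counts$sq / (counts$sq + counts$hm)
  c(precision = pr, recall = rc)
}

#' Split a mask into anatomical-left and anatomical-right halves
#'
#' The spine is used as the dividing line. Under the radiological display
#' convention the patient's anatomical left appears on the image right:
#' the anatomical-left mask keeps columns `>= dividing_column`, the
#' anatomical-right mask keeps columns `< dividing_column`. Under the
#' neurological convention the sides are swapped. OR-ing the two halves
#' restores the input.
#'
#' @param mask binary matrix
#' @param dividing_column 1-based column index of the spine center
#' @param convention display convention
#' @return list with binary matrices `left` and `right` (anatomical sides)
#' @export
split_left_right <- function(mask, dividing_column = ncol(mask) %/% 2 + 1L,
                             convention = c("radiological", "neurological")) {
  convention <- match.arg(convention)
  if (dividing_column < 1 || dividing_column > ncol(mask))
    stop("dividing_column outside the image")
  cols <- seq_len(ncol(mask))
  img_right <- mask * rep(as.integer(cols >= dividing_column), each = nrow(mask))
  img_left <- mask * rep(as.integer(cols < dividing_column), each = nrow(mask))
  if (convention == "radiological") list(left = img_right, right = img_left)
  else list(left = img_left, right = img_right)
}

#' Per-side kidney segmentation report
#'
#' Evaluates a model (or any predictor) on a test set, splitting both
#' prediction and reference at the spine column and pooling pixel counts
#' over all slices (micro-average). A per-slice macro-average of DSC is
#' also reported.
#'
#' @param model an `rdaunet_model`, or a function `image -> binary mask`
#'   (e.g. an oracle)
#' @param test_samples list of samples with `image` (normalized, network
#'   input scale) and `mask`; phantom samples prepared with
#'   [prepare_sample()] work directly
#' @param dividing_column spine column; default image midline. May be a
#'   vector (one per slice).
#' @param convention display convention, see [split_left_right()]
#' @param aggregate `"pooled"` (micro) or `"per_slice"` (macro) headline
#'   numbers
#' @return object of class `kidney_report`: list with one entry per side
#'   (`left`, `right`), each holding `dsc`, `precision`, `recall`,
#'   `counts`, `dsc_macro` and `n_slices`
#' @export
evaluate <- function(model, test_samples,
                     dividing_column = NULL,
                     convention = "radiological",
                     aggregate = c("pooled", "per_slice")) {
  aggregate <- match.arg(aggregate)
  if (length(test_samples) == 0) stop("evaluate: empty test set")
  n <- length(test_samples)
  dividing_column <- if (is.null(dividing_column))
    vapply(test_samples, function(s) ncol(s$image) %/% 2 + 1L, 0L)
  else rep_len(as.integer(dividing_column), n)
  predict_one <- if (is.function(model)) model
  else function(img) predict_mask(model, img)
  zero <- list(sq = 0, hq = 0, hm = 0)
  acc <- list(left = zero, right = zero)
  per_slice <- list(left = numeric(0), right = numeric(0))
  for (i in seq_len(n)) {
    s <- test_samples[[i]]
    pred <- predict_one(s$image)
    ps <- split_left_right(pred, dividing_column[i], convention)
    ts <- split_left_right(s$mask, dividing_column[i], convention)
    for (side in c("left", "right")) {
      cc <- confusion(ps[[side]], ts[[side]])
      acc[[side]] <- Map(`+`, acc[[side]], cc)
      per_slice[[side]] <- c(per_slice[[side]], dsc(ps[[side]], ts[[side]]))
    }
  }
  report <- lapply(c(left = "left", right = "right"), function(side) {
    cc <- acc[[side]]
    den <- 2 * cc$sq + cc$hq + cc$hm
    pooled_dsc <- if (den == 0) 1 else 2 * cc$sq / den
    pr <- precision_recall(cc)
    macro <- mean(per_slice[[side]])
    list(side = side,
         dsc = if (aggregate == "pooled") pooled_dsc else macro,
         dsc_pooled = pooled_dsc, dsc_macro = macro,
         precision = unname(pr["precision"]), recall = unname(pr["recall"]),
         counts = cc, n_slices = n)
  })
  structure(report, class = "kidney_report", aggregate = aggregate)
}

#' @export
print.kidney_report <- function(x, ...) {
  cat(sprintf("Kidney segmentation report (%d slices, %s aggregation)\n",
              x$left$n_slices, attr(x, "aggregate")))
  cat(sprintf("  %-6s %8s %10s %8s\n", "side", "DSC", "precision", "recall"))
  for (side in c("left", "right"))
    cat(sprintf("  %-6s %8.4f %10.4f %8.4f\n", side,
                x[[side]]$dsc, x[[side]]$precision, x[[side]]$recall))
  invisible(x)
}

#' Tabulate reports for several models
#'
#' @param reports named list of `kidney_report`s (one per model)
#' @return data frame with one row per model, columns per side and metric
#' @export
report_table <- function(reports) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm,
               left_dsc = r$left$dsc, left_precision = r$left$precision,
               left_recall = r$left$recall,
               right_dsc = r$right$dsc, right_precision = r$right$precision,
               right_recall = r$right$recall)
  })
  do.call(rbind, rows)
}
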