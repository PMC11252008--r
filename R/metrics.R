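## Voxel- and object-level validation of segmentations, plus the summary
## statistics used for the quantitative claims (Pearson r with Fisher-z CI,
## ordinary least squares with R^2 and a two-tailed t-test p value).

#' Voxel-wise Pearson correlation of two volumes
#'
#' @param a,b [Volume-class] objects (or numeric arrays) on the same grid
#'   with nonzero variance.
#' @return The correlation coefficient r.
#' @export
voxelPearson <- function(a, b) {
  if (is(a, "Volume")) a <- a@data
  if (is(b, "Volume")) b <- b@data
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(as.vector(a), as.vector(b))
}

#' Match object instances between two label maps
#'
#' All (reference, test) segment pairs with at least one overlapping voxel
#' are scored by IOU (intersection over union) and Dice; then, per reference
#' segment, only the pair with the larger IOU (or Dice, per
#' \code{criterion}) is retained, ties breaking toward the lower test label.
#'
#' @param ref,test [LabelMap-class] objects on the same grid.
#' @param criterion "iou" or "dice" (used for the per-reference tie rule).
#' @return data.frame(ref_id, test_id, overlap_voxels, ref_voxels,
#'   test_voxels, iou, dice), one row per retained pair.
#' @export
matchObjects <- function(ref, test, criterion = c("iou", "dice")) {
  criterion <- match.arg(criterion)
  if (is(ref, "LabelMap")) ref <- ref@data
  if (is(test, "LabelMap")) test <- test@data
  if (!identical(dim(ref), dim(test))) stop("grid mismatch")
  sel <- ref > 0L & test > 0L
  empty <- data.frame(ref_id = integer(), test_id = integer(),
    overlap_voxels = integer(), ref_voxels = integer(),
    test_voxels = integer(), iou = numeric(), dice = numeric())
  if (!any(sel)) return(empty)
  ov <- table(ref = ref[sel], test = test[sel])
  ovdf <- as.data.frame(ov, stringsAsFactors = FALSE)
  ovdf <- ovdf[ovdf$Freq > 0, , drop = FALSE]
  rsz <- table(ref[ref > 0L])
  tsz <- table(test[test > 0L])
  out <- data.frame(
    ref_id = as.integer(ovdf$ref), test_id = as.integer(ovdf$test),
    overlap_voxels = as.integer(ovdf$Freq))
  out$ref_voxels <- as.integer(rsz[as.character(out$ref_id)])
  out$test_voxels <- as.integer(tsz[as.character(out$test_id)])
  un <- out$ref_voxels + out$test_voxels - out$overlap_voxels
  out$iou <- out$overlap_voxels / un
  out$dice <- 2 * out$overlap_voxels / (out$ref_voxels + out$test_voxels)
  score <- if (criterion == "iou") out$iou else out$dice
  ## per reference segment keep the best pair; ties -> lowest test label
  ord <- order(out$ref_id, -score, out$test_id)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision/recall/F1 as a function of overlap threshold
#'
#' At each threshold t the retained matches with score >= t are the true
#' positives; false positives are the remaining test segments
#' (N_TP + N_FP = n_test) and false negatives the remaining reference
#' segments (N_TP + N_FN = n_ref). F1 = 2PR/(P+R), 0 when P + R = 0. The
#' headline F1 is conventionally read at t = 0.2.
#'
#' @param pairs Retained pairs from [matchObjects()].
#' @param nRef,nTest Total segment counts of the two maps.
#' @param thresholds Numeric vector of thresholds.
#' @param criterion "iou" or "dice": which score column is thresholded.
#' @param strict If TRUE, counts pairs with score strictly above t instead
#'   of >= t.
#' @return data.frame(threshold, n_tp, n_fp, n_fn, precision, recall, f1).
#' @export
prfCurve <- function(pairs, nRef, nTest, thresholds = seq(0.05, 0.95, 0.05),
                     criterion = c("iou", "dice"), strict = FALSE) {
  criterion <- match.arg(criterion)
  if (nRef == 0 || nTest == 0)
    warning("degenerate evaluation: empty reference or test map")
  score <- if (nrow(pairs)) pairs[[criterion]] else numeric()
  rows <- lapply(thresholds, function(t) {
    tp <- as.integer(if (strict) sum(score > t) else sum(score >= t))
    fp <- as.integer(nTest) - tp
    fn <- as.integer(nRef) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(threshold = t, n_tp = tp, n_fp = fp, n_fn = fn,
               precision = p, recall = r, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' z = atanh(r) is treated as normal with standard error 1/sqrt(n - 3);
#' the interval is tanh(z -/+ z_(1 - alpha/2)/sqrt(n - 3)).
#'
#' @param r Correlation coefficient, |r| < 1.
#' @param n Sample size, >= 4.
#' @param alpha Significance level (default 0.05 for a 95 percent CI).
#' @return Numeric length-2: lower and upper bound.
#' @export
#' @examples
#' pearsonCI(0.844, 30)  # upper bound 0.923
pearsonCI <- function(r, n, alpha = 0.05) {
  if (!is.finite(r) || abs(r) >= 1) stop("need |r| < 1")
  if (n < 4) stop("need n >= 4")
  z <- atanh(r)
  hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  c(lower = tanh(z - hw), upper = tanh(z + hw))
}

#' Ordinary least squares with correlation statistics
#'
#' Fits y = a + b x; reports slope, intercept, Pearson r, R^2 = r^2 and a
#' two-tailed p value from t = r sqrt((n-2)/(1-r^2)) on n - 2 df.
#'
#' @param x,y Numeric vectors, length >= 3, x non-constant.
#' @return list(slope, intercept, r, r_squared, p_two_tailed, n).
#' @export
linregStats <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0) stop("x is constant: regression undefined")
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  r2 <- r^2
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(slope = b, intercept = a, r = r, r_squared = r2,
       p_two_tailed = p, n = n)
}
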