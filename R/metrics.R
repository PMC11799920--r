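# Segmentation loss and evaluation metrics.
#
# Label maps are integer H x W matrices with values 0..C-1 (0 = background)
# and an associated pixel spacing in mm. Probability maps are C x H x W
# arrays that sum to 1 over classes at every pixel.

# Flatten a probability map (C x H x W array or n x C matrix) to n x C.
.probs_matrix <- function(probs) {
  if (is.matrix(probs)) return(probs)
  d <- dim(probs)
  if (length(d) != 3L) stop("probability map must be C x H x W or n x C")
  m <- aperm(probs, c(2L, 3L, 1L))
  dim(m) <- c(d[2L] * d[3L], d[1L])
  m
}

# One-hot encode an integer label vector/matrix against C classes.
one_hot <- function(labels, n_classes) {
  lab <- as.vector(labels)
  if (any(lab < 0L | lab >= n_classes)) {
    stop("labels must lie in 0..", n_classes - 1L)
  }
  G <- matrix(0, length(lab), n_classes)
  G[cbind(seq_along(lab), lab + 1L)] <- 1
  G
}

#' Dice similarity coefficient for one class
#'
#' Computes \code{2 TP / (2 TP + FP + FN)} for class \code{class} between a
#' predicted and a ground-truth label map. When the class is absent from
#' both maps the coefficient is undefined and \code{NA} is returned (callers
#' exclude such entries from averages); absence from exactly one map gives 0.
#'
#' @param pred,gt integer label matrices of identical dimensions.
#' @param class the class label to score.
#' @return DSC in [0, 1], or \code{NA} if undefined.
#' @export
dsc <- function(pred, gt, class) {
  if (!identical(dim(pred), dim(gt))) {
    stop("prediction and ground truth dimensions differ")
  }
  p <- pred == class
  g <- gt == class
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  if (tp + fp + fn == 0L) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

# Boundary pixels of a logical mask under 4-connectivity; the image border
# counts as outside, so a region touching the border contributes its rim.
boundary_coords <- function(mask) {
  d <- dim(mask)
  up    <- rbind(FALSE, mask[-d[1L], , drop = FALSE])
  down  <- rbind(mask[-1L, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, mask[, -d[2L], drop = FALSE])
  right <- cbind(mask[, -1L, drop = FALSE], FALSE)
  b <- mask & !(up & down & left & right)
  which(b, arr.ind = TRUE)
}

#' Average symmetric surface distance for one class
#'
#' Extracts the boundary point sets of the predicted and true masks
#' (4-connectivity, image border counts as outside) and averages, over both
#' directions, the Euclidean distance from each boundary point to the
#' nearest point of the other boundary, scaled by the pixel spacing.
#' Symmetric in its arguments. If either boundary set is empty the metric
#' is undefined and \code{NA} is returned.
#'
#' @param pred,gt integer label matrices of identical dimensions.
#' @param class the class label to score.
#' @param spacing pixel spacing (row, col) in mm.
#' @return ASSD in mm (>= 0), or \code{NA} if undefined.
#' @export
assd <- function(pred, gt, class, spacing = c(1, 1)) {
  if (!identical(dim(pred), dim(gt))) {
    stop("prediction and ground truth dimensions differ")
  }
  b1 <- boundary_coords(pred == class)
  b2 <- boundary_coords(gt == class)
  if (nrow(b1) == 0L || nrow(b2) == 0L) return(NA_real_)
  P1 <- cbind(b1[, 1L] * spacing[1L], b1[, 2L] * spacing[2L])
  P2 <- cbind(b2[, 1L] * spacing[1L], b2[, 2L] * spacing[2L])
  d2 <- outer(rowSums(P1^2), rowSums(P2^2), `+`) - 2 * tcrossprod(P1, P2)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  (sum(apply(D, 1L, min)) + sum(apply(D, 2L, min))) / (nrow(P1) + nrow(P2))
}

#' Fused Dice + cross-entropy segmentation loss
#'
#' The training loss is the sum of a pixel-averaged cross-entropy and a
#' negated soft-Dice term over all classes (background included):
#' \deqn{L = -\frac{1}{n}\sum_i\sum_j G_{ij}\log O_{ij}
#'       - \frac{2}{|C|}\sum_j \frac{\sum_i O_{ij}G_{ij}}
#'                                  {\sum_i O_{ij}+\sum_i G_{ij}}}
#' Probabilities are clamped to \code{[1e-7, 1]} before the logarithm and a
#' smoothing constant 1e-6 is added to the Dice denominator. The minimum is
#' -1, attained at the exact one-hot ground truth when every class is
#' present.
#'
#' @param probs probability map, C x H x W array or n x C matrix.
#' @param gt ground truth: an integer label matrix, or a one-hot array of
#'   the same shape as \code{probs}.
#' @return scalar loss.
#' @export
fused_loss <- function(probs, gt) {
  Om <- .probs_matrix(probs)
  C <- ncol(Om)
  Gm <- if (is.array(gt) && length(dim(gt)) == length(dim(probs)) &&
            all(dim(gt) == dim(probs))) {
    .probs_matrix(gt)
  } else {
    one_hot(gt, C)
  }
  if (!all(dim(Gm) == dim(Om))) stop("probability and ground truth shapes differ")
  if (any(Om < -1e-9)) stop("probabilities must be non-negative")
  n <- nrow(Om)
  ce <- -sum(Gm * log(pmin(pmax(Om, 1e-7), 1))) / n
  S <- colSums(Om * Gm)
  D <- colSums(Om) + colSums(Gm) + 1e-6
  ce - (2 / C) * sum(S / D)
}

# Gradient of the fused loss with respect to the *logits* that produced
# `Om = softmax(logits)` row-wise. Used by the training loop.
fused_loss_grad_logits <- function(Om, Gm) {
  n <- nrow(Om)
  C <- ncol(Om)
  S <- colSums(Om * Gm)
  D <- colSums(Om) + colSums(Gm) + 1e-6
  # d(dice term)/dO
  gd <- -(2 / C) * (Gm * rep(D, each = n) - rep(S, each = n)) /
    rep(D^2, each = n)
  # chain through softmax: dlogit = O * (g - rowSums(g * O))
  dl_dice <- Om * (gd - rowSums(gd * Om))
  dl_ce <- (Om - Gm) / n
  dl_ce + dl_dice
}

row_softmax <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}

#' Average defined metric entries
#'
#' Averages the defined (non-\code{NA}) entries of a metric vector,
#' reporting how many undefined entries were excluded. Undefined entries
#' arise when a class is absent from both maps (DSC) or a boundary set is
#' empty (ASSD); the policy is exclusion, never zero-filling.
#'
#' @param x numeric vector possibly containing \code{NA} sentinels.
#' @return list with \code{mean}, \code{n_used} and \code{n_excluded}.
#' @export
class_average <- function(x) {
  defined <- x[!is.na(x)]
  if (length(defined) == 0L) stop("all metric entries are undefined")
  list(mean = mean(defined), n_used = length(defined),
       n_excluded = sum(is.na(x)))
}
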