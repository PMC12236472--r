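#' Weighted cross-entropy loss
#'
#' Mean over voxels of `-w_k * log softmax(x)_k` at the true class: the
#' multi-task training criterion, computed per task. This is the plain-array
#' entry point used in tests and logging; the trainer uses the same kernel
#' through the autodiff tape.
#'
#' @param logits numeric matrix `K x N` (classes x voxels) or a `K x dims`
#'   array.
#' @param labels integer vector/array of true classes in `0..K-1`, length N.
#' @param class_weights numeric length-K vector of class weights `w_k`
#'   (default all 1).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(logits, labels, class_weights = NULL) {
  if (is.array(logits) && length(dim(logits)) > 2L)
    logits <- matrix(as.numeric(logits), nrow = dim(logits)[1])
  if (!is.matrix(logits)) logits <- matrix(logits, ncol = 1L)
  K <- nrow(logits)
  labels <- as.integer(labels)
  if (length(labels) != ncol(logits))
    stop("weighted_cross_entropy: one label per voxel required")
  if (any(labels < 0L | labels >= K))
    stop("weighted_cross_entropy: label out of range [0, ", K - 1L, "]")
  if (is.null(class_weights)) class_weights <- rep(1, K)
  m <- apply(logits, 2L, max)
  lse <- m + log(colSums(exp(sweep(logits, 2L, m))))
  li <- cbind(labels + 1L, seq_len(ncol(logits)))
  mean(class_weights[labels + 1L] * (lse - logits[li]))
}

#' Combine the three task losses
#'
#' `L = lambda_b * L_backbone + lambda_c * L_calpha + lambda_a * L_amino`,
#' with the weights required to sum to 1.
#'
#' @param l_b,l_c,l_a scalar task losses (backbone, C-alpha, amino acid).
#' @param lambda numeric length-3 weight vector `(lambda_b, lambda_c,
#'   lambda_a)`.
#' @return Scalar total loss.
#' @export
total_loss <- function(l_b, l_c, l_a, lambda) {
  lambda <- as.numeric(lambda)
  if (length(lambda) != 3L || abs(sum(lambda) - 1) > 1e-6)
    stop("total_loss: lambda must have 3 components summing to 1")
  lambda[1] * l_b + lambda[2] * l_c + lambda[3] * l_a
}

#' Task-weight schedule
#'
#' Early epochs prioritize backbone-atom prediction with weights
#' (0.6, 0.3, 0.1); from epoch 25 on the weights are (0.25, 0.4, 0.35),
#' shifting emphasis to C-alpha and amino-acid prediction. The transition is
#' a linear ramp over epochs 20-25 (any smooth schedule matching the two
#' endpoints is admissible; the endpoints are the contract).
#'
#' @param epoch epoch number (>= 0; fractional values interpolate).
#' @param ramp numeric length-2, start/end epoch of the transition.
#' @return Numeric length-3 weights `(lambda_b, lambda_c, lambda_a)`,
#'   summing to 1.
#' @export
lambda_schedule <- function(epoch, ramp = c(20, 25)) {
  stopifnot(epoch >= 0)
  early <- c(0.6, 0.3, 0.1)
  late <- c(0.25, 0.4, 0.35)
  if (epoch <= ramp[1]) return(early)
  if (epoch >= ramp[2]) return(late)
  f <- (epoch - ramp[1]) / (ramp[2] - ramp[1])
  (1 - f) * early + f * late
}

#' Inverse-frequency class weights
#'
#' Default `w_k` for [weighted_cross_entropy()]: `N / (K * count_k)`,
#' computed over the labels of a training set, with classes absent from the
#' data given weight 1. Heavily imbalanced voxel tasks (background dominates)
#' need this to keep the minority structure classes from being ignored.
#'
#' @param labels integer vector/array of class labels `0..K-1`.
#' @param K number of classes.
#' @param cap upper bound on any weight (default 100).
#' @return Numeric length-K weights.
#' @export
class_weights_from_labels <- function(labels, K, cap = 100) {
  cnt <- tabulate(as.integer(labels) + 1L, nbins = K)
  w <- ifelse(cnt > 0L, length(labels) / (K * cnt), 1)
  pmin(w, cap)
}
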