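# Training loss: weighted cross-entropy combined with soft Dice loss.

#' Inverse-frequency class weights
#'
#' Weights proportional to the inverse frequency of each class over a
#' collection of label grids, normalized to sum to 1. Counters the heavy
#' class imbalance between background and the two structure classes.
#'
#' @param label_grids a [label_grid()] or list of them.
#' @return A `class_weights` numeric vector (background, helix, sheet).
#' @export
compute_class_weights <- function(label_grids) {
  if (inherits(label_grids, "label_grid")) label_grids <- list(label_grids)
  counts <- Reduce(`+`, lapply(label_grids, function(g)
    tabulate(as.integer(g$labels) + 1L, nbins = 3L)))
  cls <- c("background", "helix", "sheet")
  if (any(counts == 0L))
    stop("no voxels of class: ", paste(cls[counts == 0L], collapse = ", "))
  freq <- counts / sum(counts)
  w <- (1 / freq) / sum(1 / freq)
  structure(stats::setNames(w, cls), class = "class_weights")
}

# Loss on flat matrices: probs (n x 3), truth integer vector in 0:2.
# Returns loss and, if grad = TRUE, d(loss)/d(logits) for softmax probs.
loss_core <- function(probs, truth, weights, dice_weight, grad = FALSE) {
  n <- nrow(probs)
  t1 <- truth + 1L
  onehot <- matrix(0, n, 3L)
  onehot[cbind(seq_len(n), t1)] <- 1

  wv <- weights[t1]
  wsum <- sum(wv)
  p_true <- probs[cbind(seq_len(n), t1)]
  ce <- sum(wv * -log(pmax(p_true, 1e-12))) / wsum

  inter <- colSums(probs * onehot)
  denom <- colSums(probs) + colSums(onehot)
  dice_per_class <- ifelse(denom > 0, 2 * inter / denom, 1)
  dice_loss <- mean(1 - dice_per_class)

  loss <- (1 - dice_weight) * ce + dice_weight * dice_loss
  if (!grad) return(list(loss = loss, ce = ce, dice = dice_loss))

  # cross-entropy through softmax: w_t (p - onehot) / sum(w)
  dlogits_ce <- wv * (probs - onehot) / wsum
  # dice wrt probs, then through softmax
  dprobs <- matrix(0, n, 3L)
  for (c in 1:3) {
    if (denom[c] > 0)
      dprobs[, c] <- -(2 * onehot[, c] * denom[c] - 2 * inter[c]) /
        (3 * denom[c]^2)
  }
  dot <- rowSums(dprobs * probs)
  dlogits_dice <- probs * (dprobs - dot)
  list(loss = loss, ce = ce, dice = dice_loss,
       dlogits = (1 - dice_weight) * dlogits_ce + dice_weight * dlogits_dice)
}

#' Combined weighted cross-entropy and Dice loss
#'
#' `loss = (1 - dice_weight) * CE + dice_weight * Dice`, where CE is
#' cross-entropy weighted per voxel by the true class's weight (normalized by
#' the total weight, so equal weights reduce to the plain mean) and the Dice
#' term is `1 - 2 * sum(p * t) / (sum(p) + sum(t))` averaged over the three
#' classes. Zero exactly for a one-hot prediction equal to the truth.
#'
#' @param probs a [probability_grid()].
#' @param truth a [label_grid()] on the same lattice.
#' @param weights a `class_weights` vector from [compute_class_weights()]
#'   (default: equal weights).
#' @param dice_weight fraction of the Dice term in the mixture, in [0, 1].
#' @return A list with `loss`, `ce` and `dice` components.
#' @export
combined_loss <- function(probs, truth, weights = NULL, dice_weight = 0.5) {
  stopifnot(inherits(probs, "probability_grid"), inherits(truth, "label_grid"))
  if (dice_weight < 0 || dice_weight > 1) stop("`dice_weight` must be in [0, 1]")
  if (!identical(dim(probs$probs)[1:3], dim(truth$labels)))
    stop("probability grid and label grid are on different lattices")
  if (is.null(weights)) weights <- rep(1 / 3, 3)
  loss_core(vol2mat(probs$probs), as.integer(truth$labels), as.numeric(weights),
            dice_weight)[c("loss", "ce", "dice")]
}
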