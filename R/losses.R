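# The loss ledger: plain numeric implementations of every term of the
# objective. Training uses the differentiable counterparts in ops.R; these
# exported forms define the arithmetic contract and are what the tests and
# the brute-force oracles check against.

#' Loss weights for the generator composite
#'
#' @param omega_e weight of the multi-level edge loss (>= 0).
#' @param omega_s weight of the Dice loss (>= 0).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(omega_e = 1, omega_s = 1) {
  if (!is.finite(omega_e) || !is.finite(omega_s) || omega_e < 0 || omega_s < 0)
    stop("loss weights must be finite and nonnegative")
  structure(list(omega_e = omega_e, omega_s = omega_s), class = "loss_weights")
}

#' Adversarial loss
#'
#' Absolute difference between the critic's batch-mean scores on predicted
#' and real masked regions: `L_a = |D(x*yhat) - D(x*y)|`.
#'
#' @param score_fake,score_real batch-mean critic scores.
#' @return nonnegative scalar.
#' @export
adversarial_loss <- function(score_fake, score_real) {
  abs(score_fake - score_real)
}

#' Self-balancing positive-class weight
#'
#' `N_neg / N_pos` when the label has positives, otherwise 1. Compensates
#' the extreme foreground/background imbalance of nodule masks.
#'
#' @param label binary matrix/array.
#' @return scalar weight.
#' @export
balanced_positive_weight <- function(label) {
  npos <- sum(label)
  if (npos > 0) (length(label) - npos) / npos else 1
}

#' Class-weighted binary cross-entropy on logits (per level)
#'
#' `-sum_i [w * y_i * log(sigmoid(z_i)) + (1 - y_i) * log(1 - sigmoid(z_i))]`,
#' summed over pixels (not averaged), with numerically stabilised
#' log-sigmoid terms.
#'
#' @param logits numeric matrix of pre-sigmoid side-output values.
#' @param label binary matrix of the same shape.
#' @param weight positive-class weight (see [balanced_positive_weight()]).
#' @return nonnegative scalar.
#' @export
weighted_bce_level <- function(logits, label, weight = 1) {
  if (!all(dim(logits) == dim(label)))
    stop("weighted_bce_level: logits and label shapes differ")
  -sum(weight * label * stable_logsigmoid(logits) +
         (1 - label) * stable_logsigmoid(-logits))
}

#' Aggregated multi-level mask loss (deep supervision)
#'
#' Sum over the four pyramid levels of the class-weighted BCE between the
#' native side-output logits and the max-pooled mask labels, with the
#' balance weight recomputed per level.
#'
#' @param side_logits list of 4 numeric matrices (native side outputs, fine
#'   to coarse).
#' @param pyramid a `label_pyramid` of kind `"mask"` (or any list of 4
#'   binary matrices under `$levels`).
#' @return list with `L_ds`, `per_level` and `balance_weights`.
#' @export
aggregated_mask_loss <- function(side_logits, pyramid) {
  lv <- if (inherits(pyramid, "label_pyramid")) pyramid$levels else pyramid
  if (length(side_logits) != length(lv))
    stop("aggregated_mask_loss: level count mismatch")
  w <- vapply(lv, balanced_positive_weight, numeric(1))
  per <- vapply(seq_along(lv), function(k)
    weighted_bce_level(side_logits[[k]], lv[[k]], w[k]), numeric(1))
  list(L_ds = sum(per), per_level = per, balance_weights = w)
}

#' Critic loss
#'
#' `L_d = -L_a - L_ds`: minimising it maximises the adversarial separation
#' (and, in the literal bookkeeping, the supervised multi-level term).
#'
#' @param L_a adversarial loss.
#' @param L_ds aggregated multi-level mask loss.
#' @return scalar (<= 0 for nonnegative inputs).
#' @export
discriminator_loss <- function(L_a, L_ds) {
  -L_a - L_ds
}

#' Aggregated multi-level edge loss
#'
#' Same form as [aggregated_mask_loss()] but against the edge label pyramid
#' (boundaries of the ground-truth mask, max-pool downsampled).
#'
#' @param side_logits list of 4 numeric matrices.
#' @param pyramid a `label_pyramid` of kind `"edge"`.
#' @return list with `L_ge`, `per_level` and `balance_weights`.
#' @export
edge_loss <- function(side_logits, pyramid) {
  out <- aggregated_mask_loss(side_logits, pyramid)
  list(L_ge = out$L_ds, per_level = out$per_level,
       balance_weights = out$balance_weights)
}

#' Dice loss
#'
#' `1 - (2 sum(y*p) + eps) / (sum(y) + sum(p) + eps)`; the smoothing
#' constant keeps the empty-prediction/empty-truth case defined (loss 0).
#'
#' @param pred probability matrix in `[0, 1]`.
#' @param truth binary matrix of the same shape.
#' @param eps smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, eps = 1e-6) {
  if (!all(dim(pred) == dim(truth)))
    stop("dice_loss: shape mismatch")
  1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)
}

#' Generator composite loss
#'
#' `L_g = L_a + omega_e * L_ge + omega_s * L_gs`.
#'
#' @param L_a adversarial loss.
#' @param L_ge multi-level edge loss.
#' @param L_gs Dice loss.
#' @param weights a [loss_weights()].
#' @return scalar.
#' @export
generator_loss <- function(L_a, L_ge, L_gs, weights = loss_weights()) {
  L_a + weights$omega_e * L_ge + weights$omega_s * L_gs
}
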