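# Training objective: DICE + cross-entropy segmentation loss, level-set MSE,
# curvature loss, and their weighted total. Analytic gradients with respect
# to the segmentation logits and the predicted level set are provided for
# the training loop and are verified against finite differences in the
# test suite.

#' Loss weights for the combined objective
#'
#' Weights of the three terms of the total loss
#' `lambda1 * seg + lambda2 * levelset_mse + lambda3 * curvature`.
#' Defaults follow the training setting of the method: (1, 0.1, 0.0001).
#' The regression terms are deliberately down-weighted: the regression head
#' exists to inject shape priors into the shared features, not to be the
#' primary output.
#'
#' @param lambda1,lambda2,lambda3 Nonnegative weights for the segmentation,
#'   level-set MSE and curvature terms.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 0.1, lambda3 = 1e-4) {
  w <- c(lambda1, lambda2, lambda3)
  if (any(w < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

#' DICE loss
#'
#' Soft DICE loss `1 - 2 * sum(p * y) / sum(p + y)` with the sums running
#' jointly over all pixels and classes (a single global ratio, not a
#' per-class average). Zero for a perfect prediction, one for disjoint
#' binary prediction and truth.
#'
#' @param p Probability array `H x W x C` (softmax output).
#' @param y One-hot ground truth of the same shape.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(p, y) {
  check_same_dim(p, y)
  1 - 2 * sum(p * y) / sum(p + y)
}

#' Cross-entropy loss
#'
#' `-(1 / (H * W * C)) * sum(y * log(p))`. Note the `1/C` in the
#' normalization: the mean is taken over all array entries, not over pixels,
#' so with C classes the uniform-prediction value is `log(C) / C`.
#' Probabilities are clipped at `clip` before the logarithm.
#'
#' @inheritParams dice_loss
#' @param clip Lower clip applied to `p` before `log`.
#' @return Scalar loss, nonnegative.
#' @export
cross_entropy_loss <- function(p, y, clip = 1e-12) {
  check_same_dim(p, y)
  0 - mean(y * log(pmax(p, clip)))   # the leading 0 normalizes -0 to 0
}

#' Segmentation loss (DICE + cross-entropy)
#'
#' @inheritParams dice_loss
#' @return Scalar: `dice_loss(p, y) + cross_entropy_loss(p, y)`.
#' @export
segmentation_loss <- function(p, y) {
  dice_loss(p, y) + cross_entropy_loss(p, y)
}

#' Level-set regression loss
#'
#' Mean squared error between predicted and ground-truth level-set maps,
#' averaged over all pixels and classes.
#'
#' @param phi_pred,phi_true Level-set arrays of identical shape.
#' @return Scalar MSE.
#' @export
levelset_mse <- function(phi_pred, phi_true) {
  check_same_dim(phi_pred, phi_true)
  mean((phi_pred - phi_true)^2)
}

#' Curvature loss
#'
#' Sharpens both level sets ([sharpen_levelset()]), computes their curvature
#' fields ([curvature_map()]) and returns the mean absolute difference over
#' all pixels and classes. Because every operation involved is smooth, the
#' loss is differentiable with respect to `phi_pred`; the analytic gradient
#' used during training is `curvature_loss_grad()`.
#'
#' @inheritParams levelset_mse
#' @param scale Sharpening factor passed to [sharpen_levelset()].
#' @param eps Stabilizer passed to [curvature_map()].
#' @return Scalar, nonnegative.
#' @export
curvature_loss <- function(phi_pred, phi_true, scale = 1000, eps = 1e-8) {
  check_same_dim(phi_pred, phi_true)
  k_t <- curvature_map(sharpen_levelset(phi_true, scale), eps)
  k_p <- curvature_map(sharpen_levelset(phi_pred, scale), eps)
  mean(abs(k_t - k_p))
}

#' Weighted total training loss
#'
#' Combines the segmentation loss, level-set MSE and curvature loss into
#' `lambda1 * seg + lambda2 * mse + lambda3 * curv` and reports every
#' component. When `phi_pred` is `NULL` (no regression head) the regression
#' terms are zero.
#'
#' @inheritParams dice_loss
#' @param phi_pred,phi_true Predicted and ground-truth level sets (or `NULL`).
#' @param weights A [loss_weights] object.
#' @param scale,eps Curvature-loss parameters.
#' @return A `loss_report` list with fields `dice_loss`, `ce_loss`,
#'   `seg_loss`, `levelset_mse`, `curvature_loss`, `total`.
#' @export
total_loss <- function(p, y, phi_pred = NULL, phi_true = NULL,
                       weights = loss_weights(), scale = 1000, eps = 1e-8) {
  dl <- if (is.null(p)) 0 else dice_loss(p, y)
  cl <- if (is.null(p)) 0 else cross_entropy_loss(p, y)
  seg <- dl + cl
  mse <- if (is.null(phi_pred)) 0 else levelset_mse(phi_pred, phi_true)
  curv <- if (is.null(phi_pred)) 0 else
    curvature_loss(phi_pred, phi_true, scale, eps)
  structure(list(dice_loss = dl, ce_loss = cl, seg_loss = seg,
                 levelset_mse = mse, curvature_loss = curv,
                 total = weights$lambda1 * seg + weights$lambda2 * mse +
                   weights$lambda3 * curv),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(paste0("loss: total %.6g (seg %.6g = dice %.6g + ce %.6g, ",
                     "mse %.6g, curvature %.6g)\n"),
              x$total, x$seg_loss, x$dice_loss, x$ce_loss,
              x$levelset_mse, x$curvature_loss))
  invisible(x)
}

#' Serialize loss reports to CSV
#'
#' One row per training step with columns
#' `step, seg, dice, ce, mse, curv, total`.
#'
#' @param reports List of `loss_report`s (or a data.frame from training).
#' @param path Output CSV path.
#' @export
write_loss_csv <- function(reports, path) {
  df <- if (is.data.frame(reports)) reports else
    do.call(rbind, lapply(seq_along(reports), function(i) {
      r <- reports[[i]]
      data.frame(step = i, seg = r$seg_loss, dice = r$dice_loss,
                 ce = r$ce_loss, mse = r$levelset_mse,
                 curv = r$curvature_loss, total = r$total)
    }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# -- gradients ---------------------------------------------------------------

# Gradient of segmentation_loss with respect to the softmax *logits*.
# p must be the softmax of the logits; y one-hot.
seg_loss_grad_logits <- function(p, y, clip = 1e-12) {
  S <- sum(p + y)
  I <- sum(p * y)
  gp_dice <- (2 * I - 2 * y * S) / S^2
  gp_ce <- -(y / pmax(p, clip)) / length(p)
  gp <- gp_dice + gp_ce
  # softmax chain: dz_j = p_j * (gp_j - sum_k gp_k p_k) per pixel
  C <- dim(p)[3]
  w <- gp * p
  s <- w[, , 1]
  if (C > 1) for (k in 2:C) s <- s + w[, , k]
  dz <- p * (gp - array(rep(s, C), dim(p)))
  dz
}

# Gradient of levelset_mse with respect to phi_pred.
levelset_mse_grad <- function(phi_pred, phi_true) {
  2 * (phi_pred - phi_true) / length(phi_pred)
}

curvature_grad_channel <- function(phi, dK, scale, eps) {
  s <- sharpen_levelset(phi, scale)
  d <- spatial_derivatives(s)
  M <- 1 + d$ga^2 + d$gb^2
  den <- 2 * M^1.5 + eps
  num <- (1 + d$ga^2) * d$gbb + (1 + d$gb^2) * d$gaa - 2 * d$ga * d$gb * d$gab
  dga <- dK * ((2 * d$ga * d$gbb - 2 * d$gb * d$gab) / den -
                 num * 6 * d$ga * sqrt(M) / den^2)
  dgb <- dK * ((2 * d$gb * d$gaa - 2 * d$ga * d$gab) / den -
                 num * 6 * d$gb * sqrt(M) / den^2)
  dgaa <- dK * (1 + d$gb^2) / den
  dgbb <- dK * (1 + d$ga^2) / den
  dgab <- dK * (-2 * d$ga * d$gb) / den
  ds <- adj_deriv_a(dga) + adj_deriv_b(dgb) +
    adj_deriv_aa(dgaa) + adj_deriv_bb(dgbb) +
    adj_deriv_b(adj_deriv_a(dgab))   # gab = Da(Db f) => adjoint Db^T Da^T
  ds * s * (1 - s) * (-scale)
}

#' Gradient of the curvature loss with respect to the predicted level set
#'
#' Analytic vector-Jacobian product through sharpening, the derivative
#' stencils and the curvature expression. Exposed so the training loop (and
#' gradient-check tests) can use it directly.
#'
#' @inheritParams curvature_loss
#' @return Array of the same shape as `phi_pred`.
#' @export
curvature_loss_grad <- function(phi_pred, phi_true, scale = 1000, eps = 1e-8) {
  xp <- as_chw_array(phi_pred)
  xt <- as_chw_array(phi_true)
  out <- array(0, dim(xp))
  n <- length(xp)
  for (k in seq_len(dim(xp)[3])) {
    k_t <- curvature_channel(sharpen_levelset(xt[, , k], scale), eps)
    k_p <- curvature_channel(sharpen_levelset(xp[, , k], scale), eps)
    dK <- -sign(k_t - k_p) / n
    out[, , k] <- curvature_grad_channel(xp[, , k], dK, scale, eps)
  }
  if (is.matrix(phi_pred)) out <- out[, , 1]
  out
}

# As curvature_loss_grad but against precomputed truth curvature channels
# (training-time fast path; truth curvature is fixed per image).
curvature_loss_grad_cached <- function(phi_pred, k_true, scale, eps) {
  xp <- as_chw_array(phi_pred)
  out <- array(0, dim(xp))
  n <- length(xp)
  for (k in seq_len(dim(xp)[3])) {
    k_p <- curvature_channel(sharpen_levelset(xp[, , k], scale), eps)
    dK <- -sign(k_true[, , k] - k_p) / n
    out[, , k] <- curvature_grad_channel(xp[, , k], dK, scale, eps)
  }
  out
}

curvature_loss_cached <- function(phi_pred, k_true, scale, eps) {
  xp <- as_chw_array(phi_pred)
  tot <- 0
  for (k in seq_len(dim(xp)[3])) {
    k_p <- curvature_channel(sharpen_levelset(xp[, , k], scale), eps)
    tot <- tot + sum(abs(k_true[, , k] - k_p))
  }
  tot / length(xp)
}
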