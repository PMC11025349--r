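#' Loss configuration for the two-phase training schedule
#'
#' Training runs in two phases: an initial phase with a weighted sum of
#' focal loss and soft Dice loss (robust to the extreme foreground/background
#' imbalance of calcification masks), followed by fine-tuning with a
#' Hausdorff-distance surrogate loss that penalises boundary errors and
#' stray predictions far from any lesion.
#'
#' @param focal_alpha positive-class weight in (0,1), default 0.25.
#' @param focal_gamma focusing exponent >= 0, default 2.
#' @param phase1_weights `c(w_focal, w_dice)`, both >= 0, not both zero.
#' @param hd_alpha exponent on the distance transforms in the HD surrogate.
#' @param smooth Dice smoothing constant.
#' @return a `loss_config` list.
#' @export
loss_config <- function(focal_alpha = 0.25, focal_gamma = 2,
                        phase1_weights = c(1, 1), hd_alpha = 2,
                        smooth = 1e-6) {
  stopifnot(focal_alpha > 0, focal_alpha < 1, focal_gamma >= 0,
            length(phase1_weights) == 2, all(phase1_weights >= 0),
            sum(phase1_weights) > 0, hd_alpha >= 0, smooth >= 0)
  structure(list(focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 phase1_weights = phase1_weights, hd_alpha = hd_alpha,
                 smooth = smooth), class = "loss_config")
}

EPS_P <- 1e-7

check_pair <- function(probs, target) {
  if (!all(dim(probs) == dim(target)))
    stop("loss: probs and target shapes differ")
  if (!is_binary(target)) stop("loss: target must be binary")
}

#' Focal loss
#'
#' Mean over pixels of `-alpha_t (1 - p_t)^gamma log(p_t)` where `p_t` is
#' the predicted probability of the true class and `alpha_t` is `alpha` for
#' lesion pixels and `1 - alpha` for background. Probabilities are clamped
#' to `[1e-7, 1 - 1e-7]` before logs. With `gamma = 0` and `alpha = 0.5`
#' this is half the binary cross-entropy.
#'
#' @param probs predicted probabilities (any numeric array).
#' @param target binary ground truth of the same shape.
#' @param alpha,gamma focal parameters.
#' @param grad if TRUE also return the gradient w.r.t. `probs`.
#' @return scalar loss, or list(loss, grad).
#' @export
focal_loss <- function(probs, target, alpha = 0.25, gamma = 2,
                       grad = FALSE) {
  check_pair(probs, target)
  p <- pmin(pmax(probs, EPS_P), 1 - EPS_P)
  t <- target
  pt <- ifelse(t == 1, p, 1 - p)
  at <- ifelse(t == 1, alpha, 1 - alpha)
  loss <- mean(-at * (1 - pt)^gamma * log(pt))
  if (!grad) return(loss)
  n <- length(p)
  # dL/dp via p_t: dp_t/dp = +1 for t=1, -1 for t=0
  dlpt <- at * (gamma * (1 - pt)^pmax(gamma - 1, 0) * log(pt) -
                  (1 - pt)^gamma / pt)
  if (gamma == 0) dlpt <- -at / pt
  g <- ifelse(t == 1, dlpt, -dlpt) / n
  dim(g) <- dim(probs)
  list(loss = loss, grad = g)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p t) + s) / (sum(p) + sum(t) + s)` on raw probabilities
#' (no thresholding), zero iff prediction equals a binary target.
#'
#' @inheritParams focal_loss
#' @param smooth smoothing constant `s`.
#' @return scalar in \[0,1\], or list(loss, grad).
#' @export
dice_loss <- function(probs, target, smooth = 1e-6, grad = FALSE) {
  check_pair(probs, target)
  p <- probs
  t <- target
  num <- 2 * sum(p * t) + smooth
  den <- sum(p) + sum(t) + smooth
  loss <- 1 - num / den
  if (!grad) return(loss)
  g <- -(2 * t * den - num) / den^2
  dim(g) <- dim(probs)
  list(loss = loss, grad = g)
}

# unsigned Euclidean distance to the nearest positive pixel; for an empty
# point set the distance is taken as the image diagonal
dist_to_set <- function(mask) {
  if (sum(mask) == 0)
    return(matrix(sqrt(nrow(mask)^2 + ncol(mask)^2), nrow(mask), ncol(mask)))
  as.matrix(EBImage::distmap(1 - mask))
}

#' Hausdorff-distance surrogate loss
#'
#' Distance-transform weighting of the squared prediction error:
#' `mean((p - t)^2 * (D_t^alpha + D_p^alpha))`, where `D_t` and `D_p` are
#' the unsigned Euclidean distance transforms of the target and of the
#' binarized prediction. The weights are treated as constants in the
#' gradient (exact Hausdorff distance is not differentiable). Both masks
#' empty is defined as 0.
#'
#' @inheritParams focal_loss
#' @param hd_alpha distance exponent.
#' @param threshold binarization threshold for the prediction side.
#' @return scalar >= 0, or list(loss, grad).
#' @export
hd_loss <- function(probs, target, hd_alpha = 2, threshold = 0.5,
                    grad = FALSE) {
  check_pair(probs, target)
  p <- as.matrix(probs)
  t <- as.matrix(target)
  pb <- (p > threshold) * 1
  if (sum(t) == 0 && sum(pb) == 0) {
    if (!grad) return(0)
    return(list(loss = 0, grad = array(0, dim(probs))))
  }
  w <- dist_to_set(t)^hd_alpha + dist_to_set(pb)^hd_alpha
  loss <- mean((p - t)^2 * w)
  if (!grad) return(loss)
  g <- 2 * (p - t) * w / length(p)
  dim(g) <- dim(probs)
  list(loss = loss, grad = g)
}

#' Phase-1 combined loss: `w_focal * focal + w_dice * dice`
#'
#' @inheritParams focal_loss
#' @param config a [loss_config()].
#' @return scalar, or list(loss, grad).
#' @export
phase1_loss <- function(probs, target, config = loss_config(),
                        grad = FALSE) {
  w <- config$phase1_weights
  if (!grad) {
    return(w[1] * focal_loss(probs, target, config$focal_alpha,
                             config$focal_gamma) +
           w[2] * dice_loss(probs, target, config$smooth))
  }
  f <- focal_loss(probs, target, config$focal_alpha, config$focal_gamma,
                  grad = TRUE)
  d <- dice_loss(probs, target, config$smooth, grad = TRUE)
  list(loss = w[1] * f$loss + w[2] * d$loss,
       grad = w[1] * f$grad + w[2] * d$grad)
}

# hd_loss over a (H, W, 1, N) batch; returns summed loss and gradient array
hd_loss_batch <- function(probs, target, hd_alpha = 2) {
  d <- dim(probs)
  g <- array(0, d)
  total <- 0
  for (n in seq_len(d[4])) {
    r <- hd_loss(probs[, , 1, n], target[, , 1, n], hd_alpha, grad = TRUE)
    total <- total + r$loss
    g[, , 1, n] <- r$grad
  }
  list(loss = total / d[4], grad = g / d[4])
}
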