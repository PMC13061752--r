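# The two training-loss contracts: binary cross-entropy on logits for
# disc masks, and Kullback-Leibler divergence for normalized density
# maps.

#' Binary cross-entropy loss on logits
#'
#' Mean over pixels of the logistic cross-entropy between
#' `sigmoid(pred_logits)` and a 0/1 target, computed in the numerically
#' stable logits form `max(z,0) - z t + log(1 + exp(-|z|))`.
#'
#' @param pred_logits Numeric matrix (or vector) of unnormalized scores.
#' @param target Matrix/vector of the same shape with values in \{0, 1\}
#'   (a `binary_mask` is also accepted).
#' @return Scalar loss.
#' @export
loss_bce <- function(pred_logits, target) {
  if (inherits(target, "binary_mask")) target <- target$raster
  z <- as.numeric(pred_logits); t <- as.numeric(target)
  if (length(z) != length(t)) stop("prediction and target shapes differ", call. = FALSE)
  if (!all(t %in% c(0, 1))) stop("BCE target must be binary (0/1)", call. = FALSE)
  mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
}

# d(loss_bce)/d(logits)
grad_bce <- function(pred_logits, target) {
  z <- as.numeric(pred_logits); t <- as.numeric(target)
  (stats::plogis(z) - t) / length(z)
}

#' Kullback-Leibler divergence loss for density maps
#'
#' `KL(target || pred) = sum target * (log target - pred_log_density)`
#' with the convention `0 * log 0 = 0`. The prediction must be a
#' log-probability map normalized over all pixels (a log-softmax of the
#' flattened raster) and the target a density map summing to 1.
#'
#' @param pred_log_density Numeric matrix/vector of log-probabilities;
#'   `sum(exp(.))` must be 1 within 1e-4.
#' @param target Non-negative matrix/vector summing to 1 within 1e-6
#'   (a normalized `density_mask` is also accepted).
#' @return Scalar loss (>= 0, zero iff the distributions coincide).
#' @export
loss_kldiv <- function(pred_log_density, target) {
  if (inherits(target, "density_mask")) {
    if (!isTRUE(target$normalized)) stop("density target must be normalized", call. = FALSE)
    target <- target$raster
  }
  lp <- as.numeric(pred_log_density); t <- as.numeric(target)
  if (length(lp) != length(t)) stop("prediction and target shapes differ", call. = FALSE)
  if (any(t < 0) || abs(sum(t) - 1) > 1e-6) {
    stop("KL target must be a distribution (non-negative, summing to 1)", call. = FALSE)
  }
  lse <- log_sum_exp(lp)
  if (abs(lse) > 1e-4) {
    stop(sprintf("prediction is not log-normalized (logsumexp = %.3g)", lse), call. = FALSE)
  }
  pos <- t > 0
  sum(t[pos] * (log(t[pos]) - lp[pos]))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# log-softmax over a flattened raster of logits
log_softmax <- function(z) z - log_sum_exp(z)

# d(KL)/d(logits) when pred_log_density = log_softmax(logits):
# softmax(z) - target
grad_kldiv_logits <- function(logits, target) {
  z <- as.numeric(logits)
  p <- exp(z - log_sum_exp(z))
  p - as.numeric(target)
}
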