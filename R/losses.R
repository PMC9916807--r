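#' Loss configuration
#'
#' Mixing and smoothing constants of the training objective
#' `L_total = c1 * L_slide + c2 * L_patch`, where `L_slide` is the
#' slide-level cross-entropy and `L_patch` the smooth-SVM clustering
#' loss averaged over the `2 * k_sample` pseudo-labeled instances.
#'
#' @param alpha Margin of the multi-class SVM loss, `>= 0`.
#' @param tau Temperature of the smooth SVM loss, `> 0`. As `tau -> 0`
#'   the smooth loss converges to the hinge loss; at `alpha = 0`,
#'   `tau = 1` it equals the cross-entropy.
#' @param c1,c2 Non-negative mixing weights of the slide and patch
#'   losses (defaults 0.7 / 0.3).
#' @param k_sample Pseudo-labeled instances per pole (default 8).
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(alpha = 1, tau = 1, c1 = 0.7, c2 = 0.3,
                        k_sample = 8L) {
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  if (tau <= 0) stop("'tau' must be > 0", call. = FALSE)
  if (c1 < 0 || c2 < 0) stop("'c1' and 'c2' must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, tau = tau, c1 = c1, c2 = c2,
                 k_sample = as.integer(k_sample)), class = "loss_config")
}

#' Multi-class SVM hinge loss
#'
#' `l(s, y) = max(max_{j != y} (s_j + alpha) - s_y, 0)`: penalizes the
#' classifier linearly when the best competing score comes within the
#' margin `alpha` of the true-class score.
#'
#' @param s Length-N score vector, N >= 2.
#' @param y True class index in `1..N`.
#' @param alpha Margin.
#' @return Scalar loss.
#' @export
svm_hinge <- function(s, y, alpha = 1) {
  n <- length(s)
  if (n < 2) stop("need at least two classes", call. = FALSE)
  if (!is.numeric(y) || y < 1 || y > n || y != round(y))
    stop("invalid class label 'y'", call. = FALSE)
  max(max(s[-y] + alpha) - s[y], 0)
}

#' Smooth multi-class SVM loss
#'
#' Temperature-smoothed variant of the hinge loss:
#' `L_{1,tau}(s, y) = tau * log sum_j exp((alpha * 1[j != y] + s_j -
#' s_y) / tau)`, evaluated with a numerically stable log-sum-exp. It
#' upper-bounds the hinge loss for every `s`, converges to it as
#' `tau -> 0`, and reduces exactly to the cross-entropy at `alpha = 0`,
#' `tau = 1`.
#'
#' @inheritParams svm_hinge
#' @param tau Temperature, `> 0`.
#' @return Scalar loss (always positive for finite `tau`).
#' @export
svm_smooth <- function(s, y, alpha = 1, tau = 1) {
  if (tau <= 0) stop("'tau' must be > 0", call. = FALSE)
  n <- length(s)
  if (!is.numeric(y) || y < 1 || y > n || y != round(y))
    stop("invalid class label 'y'", call. = FALSE)
  v <- (alpha * (seq_len(n) != y) + s - s[y]) / tau
  tau * logsumexp(v)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Slide-level cross-entropy loss
#'
#' Negative log softmax probability of the true class given the
#' unnormalized slide scores.
#'
#' @param s_slide Length-N score vector.
#' @param y True class index in `1..N`.
#' @return Scalar loss.
#' @export
slide_loss <- function(s_slide, y) {
  n <- length(s_slide)
  if (!is.numeric(y) || y < 1 || y > n || y != round(y))
    stop("invalid class label 'y'", call. = FALSE)
  logsumexp(s_slide) - s_slide[y]
}

#' Instance clustering loss
#'
#' Mean binary smooth-SVM loss of the sampled instances' cluster
#' scores against their pseudo-cluster labels.
#'
#' @param p_rows n x 2 matrix of cluster scores (column 1: negative,
#'   column 2: positive) for the sampled instances.
#' @param pseudo_labels Length-n vector of 0/1 pseudo labels.
#' @param alpha Margin.
#' @param tau Temperature.
#' @return Scalar mean loss.
#' @export
patch_loss <- function(p_rows, pseudo_labels, alpha = 1, tau = 1) {
  p_rows <- matrix(p_rows, ncol = 2)
  n <- nrow(p_rows)
  if (n < 1L) stop("empty instance sample", call. = FALSE)
  if (length(pseudo_labels) != n)
    stop("score rows and pseudo labels must have equal counts", call. = FALSE)
  mean(vapply(seq_len(n), function(i)
    svm_smooth(p_rows[i, ], pseudo_labels[i] + 1L, alpha, tau),
    numeric(1)))
}

#' Combined training objective
#'
#' `L_total = c1 * L_slide + c2 * L_patch`.
#'
#' @param slide_l Slide-level loss value.
#' @param patch_l Instance clustering loss value.
#' @param c1,c2 Non-negative mixing weights.
#' @return Scalar.
#' @export
total_loss <- function(slide_l, patch_l, c1 = 0.7, c2 = 0.3) {
  if (c1 < 0 || c2 < 0) stop("'c1' and 'c2' must be >= 0", call. = FALSE)
  c1 * slide_l + c2 * patch_l
}

# Loss of one bag given a forward pass; pseudo labels come from the
# ground-truth class's attention row, and only that class's clustering
# head is supervised. Returns the pieces the backward pass needs.
bag_loss <- function(fwd, y, loss_cfg) {
  sl <- slide_loss(fwd$s_slide, y)
  ps <- assign_pseudo_labels(fwd$a[y, ], loss_cfg$k_sample)
  idx <- c(ps$top, ps$bottom)
  labs <- c(rep(1L, length(ps$top)), rep(0L, length(ps$bottom)))
  pl <- patch_loss(fwd$p_inst[[y]][idx, , drop = FALSE], labs,
                   loss_cfg$alpha, loss_cfg$tau)
  list(total = total_loss(sl, pl, loss_cfg$c1, loss_cfg$c2),
       slide = sl, patch = pl, idx = idx, labs = labs)
}
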