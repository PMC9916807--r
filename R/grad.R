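# Analytic gradients of the combined objective with respect to every
# model parameter, matching mil_forward()'s computation graph exactly
# (including inverted-dropout masks when the forward was run in train
# mode). Pseudo-label selection is treated as constant (a
# stop-gradient), as in standard practice for top-k supervision.

#' Backward pass of the attention-MIL objective
#'
#' Computes the gradient of `L_total = c1 * L_slide + c2 * L_patch`
#' with respect to all parameters, given a forward pass and the
#' pseudo-label sample. Verified against central finite differences in
#' the test suite.
#'
#' @param fwd A [mil_forward()] result (its caches are reused).
#' @param y True class index in `1..N`.
#' @param params [mil_params()].
#' @param loss_cfg [loss_config()].
#' @param sample_idx Indices of the pseudo-labeled instances (as chosen
#'   by [assign_pseudo_labels()] on class y's attention row).
#' @param sample_labs 0/1 pseudo labels aligned with `sample_idx`.
#' @return List of gradients with the same shapes as the parameters
#'   (`W1`, `Va`, `Ua`, `Wa`, `Wc`, `Winst`).
#' @export
mil_backward <- function(fwd, y, params, loss_cfg, sample_idx,
                         sample_labs) {
  cc <- fwd$cache
  h <- fwd$h                       # K x m (post-dropout in train mode)
  k <- nrow(h); m <- ncol(h); n <- params$n_classes
  a <- fwd$a                       # N x K

  # slide cross-entropy: dL/ds = c1 * (softmax(s) - onehot(y))
  ds <- loss_cfg$c1 * (fwd$probs - as.numeric(seq_len(n) == y))
  dWc <- ds * fwd$h_slide                         # N x m (row scaling)
  dhs <- ds * params$Wc                           # N x m
  dH <- t(a) %*% dhs                              # pooling: dH[k,] += a[i,k] dhs[i,]
  da <- dhs %*% t(h)                              # N x K

  # softmax backward per class row
  dE <- matrix(0, k, n)                           # K x N logit grads
  for (i in seq_len(n)) {
    ai <- a[i, ]
    dE[, i] <- ai * (da[i, ] - sum(ai * da[i, ]))
  }
  dWa <- t(dE) %*% cc$gate                        # N x q
  dgate <- dE %*% params$Wa                       # K x q
  dud <- dgate * cc$gd
  dgd <- dgate * cc$ud
  du <- if (is.null(cc$mu)) dud else dud * cc$mu
  dg <- if (is.null(cc$mg)) dgd else dgd * cc$mg
  dU0 <- du * (1 - cc$u^2)
  dG0 <- dg * cc$g * (1 - cc$g)
  dVa <- t(dU0) %*% h
  dUa <- t(dG0) %*% h
  dH <- dH + dU0 %*% params$Va + dG0 %*% params$Ua

  # instance clustering loss through the ground-truth class head
  dWinst <- lapply(seq_len(n), function(i) matrix(0, 2, m))
  ns <- length(sample_idx)
  if (ns > 0 && loss_cfg$c2 > 0) {
    dP <- matrix(0, k, 2)
    for (j in seq_len(ns)) {
      row <- fwd$p_inst[[y]][sample_idx[j], ]
      t_lab <- sample_labs[j] + 1L
      v <- (loss_cfg$alpha * (c(1L, 2L) != t_lab) + row) / loss_cfg$tau
      q <- exp(v - logsumexp(v))
      dP[sample_idx[j], ] <- dP[sample_idx[j], ] +
        (loss_cfg$c2 / ns) * (q - as.numeric(c(1L, 2L) == t_lab))
    }
    dWinst[[y]] <- t(dP) %*% h
    dH <- dH + dP %*% params$Winst[[y]]
  }

  dH0 <- if (is.null(cc$m1)) dH else dH * cc$m1
  dW1 <- t(dH0) %*% cc$z
  list(W1 = dW1, Va = dVa, Ua = dUa, Wa = dWa, Wc = dWc, Winst = dWinst)
}

# Flatten / unflatten parameters for optimizer state and checks
flatten_params <- function(params) {
  c(as.vector(params$W1), as.vector(params$Va), as.vector(params$Ua),
    as.vector(params$Wa), as.vector(params$Wc),
    unlist(lapply(params$Winst, as.vector)))
}

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 0L
  take <- function(mat) {
    v <- theta[(pos + 1L):(pos + length(mat))]
    pos <<- pos + length(mat)
    matrix(v, nrow(mat), ncol(mat))
  }
  out$W1 <- take(template$W1); out$Va <- take(template$Va)
  out$Ua <- take(template$Ua); out$Wa <- take(template$Wa)
  out$Wc <- take(template$Wc)
  out$Winst <- lapply(template$Winst, take)
  out
}
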