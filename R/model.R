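#' Initialize attention-MIL model parameters
#'
#' The model projects each D-dimensional patch embedding z_k to an
#' m-dimensional instance vector h_k = W1 z_k, scores each instance for
#' each class through a gated attention branch
#' Wa_i (tanh(Va h_k) * sigmoid(Ua h_k)), pools instances per class by
#' the softmax-normalized attention into a class-specific slide
#' representation, scores it with a class-specific linear classifier
#' Wc_i, and additionally scores every instance with a per-class binary
#' clustering head Winst_i used by the auxiliary objective.
#'
#' Two size profiles are provided: `"paper"` mirrors the full-scale
#' architecture (D = 1024, hidden m = 512, attention q = 256) and
#' `"small"` shrinks every shape proportionally (16 / 8 / 4) for fast
#' experimentation and exact finite-difference checking.
#'
#' @param profile `"paper"` or `"small"`, or `NULL` to use explicit
#'   dims.
#' @param n_classes Number of classes N (default 2: mutation-positive
#'   vs mutation-negative).
#' @param dims Optional explicit `c(input, hidden, attention)` dims.
#' @param dropout_p Dropout probability applied (training mode only)
#'   after the shared projection and after each gate activation
#'   (default 0.25).
#' @param init_sd If `NULL`, layer weights use scaled Gaussian
#'   initialization (sd = 1/sqrt(fan-in)); otherwise a fixed sd.
#' @param seed Integer seed for the initialization.
#' @return Object of class `mil_params`: list of weight matrices `W1`
#'   (m x D), `Va`, `Ua` (q x m), `Wa` (N x q), `Wc` (N x m), `Winst`
#'   (list of N 2 x m matrices), plus `dims`, `n_classes`, `dropout_p`.
#' @export
mil_params <- function(profile = c("paper", "small"), n_classes = 2L,
                       dims = NULL, dropout_p = 0.25, init_sd = NULL,
                       seed = 1L) {
  if (is.null(dims)) {
    profile <- match.arg(profile)
    dims <- if (profile == "paper") c(1024L, 512L, 256L) else c(16L, 8L, 4L)
  }
  d <- dims[1]; m <- dims[2]; q <- dims[3]
  set.seed(as.integer(seed))
  init <- function(nr, nc) {
    sd <- if (is.null(init_sd)) 1 / sqrt(nc) else init_sd
    matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  }
  structure(list(
    W1 = init(m, d), Va = init(q, m), Ua = init(q, m),
    Wa = init(n_classes, q), Wc = init(n_classes, m),
    Winst = lapply(seq_len(n_classes), function(i) init(2L, m)),
    dims = as.integer(dims), n_classes = as.integer(n_classes),
    dropout_p = dropout_p), class = "mil_params")
}

#' Project patch embeddings to instance vectors
#'
#' Applies the shared linear squeeze h_k = W1 z_k row-wise. Dropout is
#' applied only inside the training forward pass, never here.
#'
#' @param features K x D matrix of patch embeddings.
#' @param params [mil_params()].
#' @return K x m matrix of instance vectors.
#' @export
project_instances <- function(features, params) {
  if (ncol(features) != params$dims[1])
    stop("feature dimension ", ncol(features),
         " does not match model input dim ", params$dims[1], call. = FALSE)
  features %*% t(params$W1)
}

#' Gated attention scores for one class
#'
#' Attention logit of instance k for class i is
#' `Wa_i (tanh(Va h_k) * sigmoid(Ua h_k))`; the returned scores are the
#' softmax over the K instances, a proper distribution.
#'
#' @param h K x m instance matrix.
#' @param params [mil_params()].
#' @param class_i Class index in `1..N`.
#' @return Length-K non-negative vector summing to 1.
#' @export
attention_scores <- function(h, params, class_i) {
  logits <- attention_logits(h, params)[, class_i]
  softmax_vec(logits)
}

# K x N matrix of attention logits for all classes at once
attention_logits <- function(h, params) {
  u <- tanh(h %*% t(params$Va))
  g <- sigmoid(h %*% t(params$Ua))
  (u * g) %*% t(params$Wa)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Attention pooling
#'
#' Slide-level representation as the attention-weighted sum of
#' instance vectors — a convex combination, so each coordinate of the
#' result lies between the per-coordinate min and max over instances.
#'
#' @param h K x m instance matrix.
#' @param a_row Length-K attention distribution.
#' @return Length-m pooled vector.
#' @export
attention_pool <- function(h, a_row) {
  if (length(a_row) != nrow(h))
    stop("attention length ", length(a_row),
         " does not match instance count ", nrow(h), call. = FALSE)
  as.vector(t(h) %*% a_row)
}

#' Slide-level scores and probabilities
#'
#' Each class i is scored by its own classifier on its own pooled
#' representation, s_i = Wc_i . h_slide_i; class probabilities are the
#' softmax of the scores.
#'
#' @param h_slide N x m matrix of per-class pooled representations.
#' @param params [mil_params()].
#' @return List with `scores` (length N) and `probs` (softmax).
#' @export
slide_scores <- function(h_slide, params) {
  s <- rowSums(params$Wc * h_slide)
  list(scores = s, probs = softmax_vec(s))
}

#' Instance clustering scores for one class
#'
#' Linear scores `Winst_i h_k` for the binary
#' (negative-instance vs positive-instance) clustering task of class i.
#'
#' @param h K x m instance matrix.
#' @param params [mil_params()].
#' @param class_i Class index in `1..N`.
#' @return K x 2 score matrix (column 1: negative, column 2: positive).
#' @export
instance_cluster_scores <- function(h, params, class_i) {
  h %*% t(params$Winst[[class_i]])
}

#' Assign pseudo-cluster labels from attention
#'
#' The `k_sample` most strongly attended instances are pseudo-labeled
#' positive (1) and the `k_sample` most weakly attended pseudo-labeled
#' negative (0); the two sets are disjoint. Ties are broken by lower
#' index first; the bottom set is drawn after excluding the top set so
#' the disjointness holds even under exact ties.
#'
#' @param a_row Length-K attention vector.
#' @param k_sample Instances per pole; if `2 * k_sample > K` it is
#'   reduced to `floor(K / 2)` with a warning.
#' @return List with integer index vectors `top` and `bottom`
#'   (1-based).
#' @export
assign_pseudo_labels <- function(a_row, k_sample) {
  k <- length(a_row)
  if (2 * k_sample > k) {
    k_sample <- k %/% 2L
    warning("k_sample too large for bag of size ", k,
            "; reduced to ", k_sample)
  }
  if (k_sample < 1L) stop("bag too small for pseudo-labeling", call. = FALSE)
  top <- order(-a_row)[seq_len(k_sample)]
  rest <- setdiff(order(a_row), top)
  bottom <- rest[seq_len(k_sample)]
  list(top = top, bottom = bottom)
}

#' Full forward pass of the attention-MIL model
#'
#' Composes projection, gated attention, pooling, slide scoring and the
#' per-class instance clustering heads for all N classes. In `"eval"`
#' mode dropout is disabled and the output is deterministic; in
#' `"train"` mode inverted dropout masks are drawn from the current RNG
#' stream and returned so the backward pass can reuse them. Slide-level
#' outputs are invariant to any permutation of the bag rows.
#'
#' @param bag A [feature_bag()] or bare K x D feature matrix.
#' @param params [mil_params()].
#' @param mode `"eval"` (default) or `"train"`.
#' @return List of class `mil_forward`: `h` (K x m, post-dropout in
#'   train mode), `a` (N x K attention matrix, rows sum to 1),
#'   `h_slide` (N x m), `s_slide` (length N), `probs` (length N),
#'   `p_inst` (list of N K x 2 matrices), plus training caches.
#' @export
mil_forward <- function(bag, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  z <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  n <- params$n_classes
  k <- nrow(z)
  h0 <- project_instances(z, params)
  p <- if (mode == "train") params$dropout_p else 0
  drop_mask <- function(nr, nc) {
    if (p <= 0) return(NULL)
    matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
  }
  m1 <- drop_mask(k, ncol(h0))
  h <- if (is.null(m1)) h0 else h0 * m1
  u0 <- h %*% t(params$Va); u <- tanh(u0)
  g0 <- h %*% t(params$Ua); g <- sigmoid(g0)
  mu <- drop_mask(k, ncol(u)); mg <- drop_mask(k, ncol(g))
  ud <- if (is.null(mu)) u else u * mu
  gd <- if (is.null(mg)) g else g * mg
  gate <- ud * gd
  logits <- gate %*% t(params$Wa)            # K x N
  a <- apply(logits, 2, softmax_vec)
  a <- matrix(a, nrow = k, ncol = n)         # keep shape when K = 1
  h_slide <- t(a) %*% h                      # N x m
  ss <- slide_scores(h_slide, params)
  p_inst <- lapply(seq_len(n), function(i) h %*% t(params$Winst[[i]]))
  structure(list(h = h, a = t(a), h_slide = h_slide,
                 s_slide = ss$scores, probs = ss$probs, p_inst = p_inst,
                 cache = list(z = z, h0 = h0, u = u, g = g, ud = ud,
                              gd = gd, gate = gate, m1 = m1, mu = mu,
                              mg = mg, mode = mode)),
            class = "mil_forward")
}
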