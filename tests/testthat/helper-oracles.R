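# Independent scalar-loop oracles for the forward pass and losses.
# These deliberately avoid matrix algebra and any code path shared with
# the package implementation: everything is explicit elementwise loops.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

oracle_matvec <- function(W, v) {
  out <- numeric(nrow(W))
  for (r in seq_len(nrow(W))) {
    s <- 0
    for (c in seq_len(ncol(W))) s <- s + W[r, c] * v[c]
    out[r] <- s
  }
  out
}

# Eq.-by-eq. forward pass for one bag: attention logits/scores per
# class, pooled representations, slide scores, softmax probabilities,
# instance cluster scores.
oracle_forward <- function(z, params) {
  k <- nrow(z)
  n <- params$n_classes
  h <- t(vapply(seq_len(k), function(r) oracle_matvec(params$W1, z[r, ]),
                numeric(nrow(params$W1))))
  a <- matrix(0, n, k)
  for (i in seq_len(n)) {
    logits <- numeric(k)
    for (r in seq_len(k)) {
      u <- tanh(oracle_matvec(params$Va, h[r, ]))
      g <- oracle_sigmoid(oracle_matvec(params$Ua, h[r, ]))
      s <- 0
      for (qd in seq_along(u)) s <- s + params$Wa[i, qd] * u[qd] * g[qd]
      logits[r] <- s
    }
    e <- exp(logits - max(logits))
    a[i, ] <- e / sum(e)
  }
  h_slide <- matrix(0, n, ncol(h))
  for (i in seq_len(n))
    for (r in seq_len(k))
      h_slide[i, ] <- h_slide[i, ] + a[i, r] * h[r, ]
  s_slide <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (c in seq_len(ncol(h_slide))) s <- s + params$Wc[i, c] * h_slide[i, c]
    s_slide[i] <- s
  }
  e <- exp(s_slide - max(s_slide))
  probs <- e / sum(e)
  p_inst <- lapply(seq_len(n), function(i)
    t(vapply(seq_len(k), function(r)
      oracle_matvec(params$Winst[[i]], h[r, ]), numeric(2))))
  list(h = h, a = a, h_slide = h_slide, s_slide = s_slide,
       probs = probs, p_inst = p_inst)
}

oracle_svm_smooth <- function(s, y, alpha, tau) {
  total <- 0
  for (j in seq_along(s))
    total <- total + exp((alpha * (j != y) + s[j] - s[y]) / tau)
  tau * log(total)
}

oracle_cross_entropy <- function(s, y) {
  -log(exp(s[y]) / sum(exp(s)))
}

# Trapezoidal AUROC from first principles (all positive/negative pairs)
oracle_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

make_small_params <- function(seed = 1, n_classes = 2L)
  mil_params(profile = "small", n_classes = n_classes, seed = seed)

make_random_bag <- function(k, d = 16L, seed = 1) {
  set.seed(seed)
  matrix(rnorm(k * d), k, d)
}
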