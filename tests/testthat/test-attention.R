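test_that("instance projection is the linear map it claims to be", {
  params <- make_small_params(seed = 1)
  z0 <- matrix(0, 3, 16)
  expect_equal(project_instances(z0, params), matrix(0, 3, 8))

  # selector weights: h equals the first 8 coordinates of z
  sel <- params
  sel$W1 <- cbind(diag(8), matrix(0, 8, 8))
  z <- make_random_bag(4, seed = 2)
  expect_equal(project_instances(z, sel), z[, 1:8])

  # random weights against the explicit dot-product oracle
  h <- project_instances(z, params)
  for (r in 1:4)
    expect_equal(unname(h[r, ]), oracle_matvec(params$W1, z[r, ]))

  expect_error(project_instances(matrix(0, 2, 7), params), "dim")
})

test_that("gated attention scores form the stated softmax distribution", {
  params <- make_small_params(seed = 3)
  h1 <- matrix(rnorm(8), 1, 8)
  expect_equal(attention_scores(h1, params, 1), 1.0)

  h_same <- matrix(rep(rnorm(8), each = 6), 6, 8)
  expect_equal(attention_scores(h_same, params, 2), rep(1 / 6, 6))

  z <- make_random_bag(5, seed = 4)
  h <- project_instances(z, params)
  ora <- oracle_forward(z, params)
  for (i in 1:2)
    expect_equal(attention_scores(h, params, i), unname(ora$a[i, ]),
                 tolerance = 1e-12)
})

test_that("attention pooling is the weighted instance sum", {
  params <- make_small_params(seed = 5)
  h <- project_instances(make_random_bag(6, seed = 6), params)
  expect_equal(attention_pool(h, rep(1 / 6, 6)), unname(colMeans(h)))
  onehot <- c(0, 0, 1, 0, 0, 0)
  expect_equal(attention_pool(h, onehot), unname(h[3, ]))
  set.seed(7)
  a <- softmax <- exp(rnorm(6)); a <- a / sum(a)
  manual <- numeric(8)
  for (k in 1:6) manual <- manual + a[k] * h[k, ]
  expect_equal(attention_pool(h, a), manual)
  expect_error(attention_pool(h, c(0.5, 0.5)), "match")
})

test_that("slide scoring uses class-specific classifiers and softmax", {
  params <- make_small_params(seed = 8)
  hs <- matrix(rnorm(16), 2, 8)
  zero <- params; zero$Wc <- matrix(0, 2, 8)
  expect_equal(slide_scores(hs, zero)$probs, c(0.5, 0.5))

  # binary softmax identity: probs = (sigmoid(t), 1 - sigmoid(t))
  s <- slide_scores(hs, params)$scores
  t_diff <- s[1] - s[2]
  expect_equal(slide_scores(hs, params)$probs,
               c(1 / (1 + exp(-t_diff)), 1 - 1 / (1 + exp(-t_diff))))

  for (i in 1:2)
    expect_equal(s[i], sum(vapply(1:8, function(c)
      params$Wc[i, c] * hs[i, c], numeric(1))))
})

test_that("instance cluster scores are the linear head outputs", {
  params <- make_small_params(seed = 9)
  h <- project_instances(make_random_bag(5, seed = 10), params)
  zero <- params; zero$Winst[[1]] <- matrix(0, 2, 8)
  expect_equal(instance_cluster_scores(h, zero, 1), matrix(0, 5, 2))
  expect_equal(instance_cluster_scores(matrix(0, 3, 8), params, 2),
               matrix(0, 3, 2))
  p <- instance_cluster_scores(h, params, 2)
  for (k in 1:5)
    expect_equal(unname(p[k, ]), oracle_matvec(params$Winst[[2]], h[k, ]))
})

test_that("pseudo-labels pick disjoint top and bottom attention poles", {
  ps <- assign_pseudo_labels(c(0.7, 0.2, 0.1), 1)
  expect_equal(ps$top, 1)
  expect_equal(ps$bottom, 3)

  # exact ties: lower index first, bottom drawn after excluding top
  tie <- assign_pseudo_labels(rep(0.25, 4), 1)
  expect_equal(tie$top, 1)
  expect_equal(tie$bottom, 2)

  set.seed(11)
  a <- runif(20)
  ps2 <- assign_pseudo_labels(a, 4)
  expect_equal(sort(ps2$top), sort(order(a, decreasing = TRUE)[1:4]))
  expect_equal(sort(ps2$bottom), sort(order(a)[1:4]))
  expect_length(intersect(ps2$top, ps2$bottom), 0)

  expect_warning(ps3 <- assign_pseudo_labels(runif(5), 4), "reduced")
  expect_length(ps3$top, 2)
})

test_that("full forward pass matches the scalar loop oracle", {
  for (seed in 1:10) {
    params <- make_small_params(seed = seed)
    k <- sample(1:10, 1)
    z <- make_random_bag(k, seed = 100 + seed)
    fwd <- mil_forward(z, params, mode = "eval")
    ora <- oracle_forward(z, params)
    expect_equal(fwd$probs, ora$probs, tolerance = 1e-9)
    expect_equal(unname(fwd$a), ora$a, tolerance = 1e-9)
    expect_equal(unname(fwd$h_slide), ora$h_slide, tolerance = 1e-9)
    for (i in 1:2)
      expect_equal(unname(fwd$p_inst[[i]]), unname(ora$p_inst[[i]]),
                   tolerance = 1e-9)
  }
})

test_that("slide-level outputs are invariant to bag permutation", {
  for (seed in 1:5) {
    params <- make_small_params(seed = seed)
    z <- make_random_bag(12, seed = 200 + seed)
    perm <- sample(12)
    f1 <- mil_forward(z, params, mode = "eval")
    f2 <- mil_forward(z[perm, ], params, mode = "eval")
    expect_equal(f2$probs, f1$probs)
    expect_equal(f2$h_slide, f1$h_slide)
    expect_equal(f2$a[, seq_len(12)], f1$a[, perm])
  }
})

test_that("attention rows are distributions and pooling stays in the hull", {
  for (seed in 1:8) {
    params <- make_small_params(seed = seed)
    z <- make_random_bag(sample(2:15, 1), seed = 300 + seed)
    fwd <- mil_forward(z, params, mode = "eval")
    expect_true(all(fwd$a >= 0))
    expect_equal(unname(rowSums(fwd$a)), rep(1, 2), tolerance = 1e-6)
    expect_equal(sum(fwd$probs), 1, tolerance = 1e-12)
    h <- fwd$h
    for (i in 1:2) {
      expect_true(all(fwd$h_slide[i, ] >= apply(h, 2, min) - 1e-12))
      expect_true(all(fwd$h_slide[i, ] <= apply(h, 2, max) + 1e-12))
    }
  }
})

test_that("K = 1 bags pool to the single instance for every class", {
  params <- make_small_params(seed = 13)
  z <- make_random_bag(1, seed = 14)
  fwd <- mil_forward(z, params, mode = "eval")
  expect_equal(unname(fwd$a), matrix(1, 2, 1))
  for (i in 1:2) expect_equal(fwd$h_slide[i, ], fwd$h[1, ])
})

test_that("eval mode is deterministic, train mode applies dropout", {
  params <- make_small_params(seed = 15)
  z <- make_random_bag(8, seed = 16)
  f1 <- mil_forward(z, params, mode = "eval")
  f2 <- mil_forward(z, params, mode = "eval")
  expect_identical(f1$probs, f2$probs)
  set.seed(1)
  t1 <- mil_forward(z, params, mode = "train")
  expect_false(isTRUE(all.equal(t1$h, f1$h)))
  expect_true(any(t1$h == 0))  # dropped units
})
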