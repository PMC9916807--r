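test_that("hinge loss matches the printed max-margin form", {
  expect_equal(svm_hinge(c(0, 2), 1, alpha = 1), 3.0)
  expect_equal(svm_hinge(c(10, 0), 1, alpha = 1), 0.0)
  set.seed(21)
  for (rep in 1:20) {
    s <- rnorm(5, sd = 3)
    y <- sample(5, 1)
    competing <- -Inf
    for (j in seq_len(5)) if (j != y) competing <- max(competing, s[j] + 1.3)
    expect_equal(svm_hinge(s, y, alpha = 1.3), max(competing - s[y], 0))
  }
  expect_error(svm_hinge(c(0, 1), 3), "label")
  expect_error(svm_hinge(0, 1), "two classes")
})

test_that("smooth SVM loss has its closed-form values and hinge limit", {
  expect_equal(svm_smooth(c(0, 0), 1, alpha = 0, tau = 1), log(2))
  expect_equal(svm_smooth(c(0, 2), 1, alpha = 1, tau = 1e-4), 3.0,
               tolerance = 1e-3)
  expect_equal(svm_smooth(c(10, 0), 1, alpha = 1, tau = 1),
               log(1 + exp(-9)))
  set.seed(22)
  for (rep in 1:20) {
    s <- rnorm(4, sd = 2); y <- sample(4, 1)
    expect_equal(svm_smooth(s, y, 0.5, 0.7),
                 oracle_svm_smooth(s, y, 0.5, 0.7))
  }
  expect_error(svm_smooth(c(0, 1), 1, tau = 0), "tau")
})

test_that("smooth SVM upper-bounds the hinge and converges as tau -> 0", {
  set.seed(23)
  for (rep in 1:50) {
    s <- rnorm(sample(2:6, 1), sd = 4)
    y <- sample(length(s), 1)
    hinge <- svm_hinge(s, y, alpha = 1)
    prev <- Inf
    for (tau in c(1, 0.1, 0.01, 1e-4)) {
      sm <- svm_smooth(s, y, alpha = 1, tau = tau)
      expect_gte(sm - hinge, -1e-12)  # analytic bound, machine precision
      expect_lte(sm, prev + 1e-12)
      prev <- sm
    }
    expect_lt(abs(prev - hinge), 1e-3)
  }
})

test_that("smooth SVM equals cross-entropy at alpha = 0, tau = 1", {
  set.seed(24)
  for (rep in 1:100) {
    s <- rnorm(sample(2:5, 1), sd = 3)
    y <- sample(length(s), 1)
    expect_equal(svm_smooth(s, y, alpha = 0, tau = 1), slide_loss(s, y),
                 tolerance = 1e-9)
  }
})

test_that("slide loss is the negative log softmax", {
  expect_equal(slide_loss(c(0, 0), 1), log(2))
  expect_lt(slide_loss(c(50, 0), 1), 1e-12)
  set.seed(25)
  for (rep in 1:20) {
    s <- rnorm(3); y <- sample(3, 1)
    expect_equal(slide_loss(s, y), oracle_cross_entropy(s, y))
  }
})

test_that("losses stay finite and stable for extreme scores", {
  big <- c(1e4, -1e4, 0)
  for (y in 1:3) {
    expect_true(is.finite(svm_smooth(big, y, alpha = 1, tau = 1)))
    expect_true(is.finite(svm_hinge(big, y)))
    expect_true(is.finite(slide_loss(big, y)))
  }
  expect_equal(slide_loss(big, 1), 0)
  expect_equal(svm_smooth(big, 2, alpha = 1, tau = 1), 2e4 + 1,
               tolerance = 1e-9)
})

test_that("patch loss averages the binary smooth SVM over the sample", {
  # symmetric zero scores: every instance contributes tau*log(1+e^(a/tau))
  p0 <- matrix(0, 4, 2)
  expect_equal(patch_loss(p0, c(1, 0, 1, 0), alpha = 2, tau = 0.5),
               0.5 * log(1 + exp(2 / 0.5)))
  # perfectly separated scores are nearly free
  psep <- rbind(c(-10, 10), c(10, -10))
  expect_lt(patch_loss(psep, c(1, 0), alpha = 1, tau = 1), 1e-3)
  # identical rows with opposite labels: symmetric per-instance losses
  prow <- rbind(c(1, 1), c(1, 1))
  l1 <- patch_loss(prow[1, , drop = FALSE], 1)
  l0 <- patch_loss(prow[2, , drop = FALSE], 0)
  expect_equal(l1, l0)
  expect_equal(patch_loss(prow, c(1, 0)), (l1 + l0) / 2)
  expect_error(patch_loss(matrix(0, 0, 2), integer(0)), "empty")
  expect_error(patch_loss(p0, c(1, 0)), "equal counts")
})

test_that("total loss is the stated weighted sum", {
  expect_equal(total_loss(1.7, 99, c1 = 1, c2 = 0), 1.7)
  expect_equal(total_loss(1.0, 2.0, c1 = 0.7, c2 = 0.3), 1.3)
  set.seed(26)
  for (rep in 1:10) {
    sl <- runif(1, 0, 5); pl <- runif(1, 0, 5)
    c1 <- runif(1); c2 <- runif(1)
    expect_equal(total_loss(sl, pl, c1, c2), c1 * sl + c2 * pl)
  }
  expect_error(total_loss(1, 1, c1 = -0.1, c2 = 0.5), "c1")
})

test_that("loss config validates its fields", {
  cfg <- loss_config()
  expect_equal(cfg$alpha, 1)
  expect_equal(cfg$c1 + cfg$c2, 1)
  expect_error(loss_config(tau = 0), "tau")
  expect_error(loss_config(alpha = -1), "alpha")
  expect_error(loss_config(c2 = -0.2), "c1")
})
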