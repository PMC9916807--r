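sep_bags <- function(n, seed, dim = 8L, prevalence = 0.5) {
  simulate_bags(bag_sim_spec(
    n_bags = n, prevalence = prevalence, witness_rate = 0.2,
    bag_size_range = c(10L, 25L), dim = dim, mu_background = 0,
    mu_signal = 3, sigma = 1, seed = seed))
}

fast_cfg <- function(max_epochs, patience = 20L, seed = 1L)
  train_config(lr = 1e-3, max_epochs = max_epochs, patience = patience,
               seed = seed)

test_that("metric formulas reproduce their worked confusion matrices", {
  # an all-positive caller: perfect sensitivity, zero specificity
  m <- suppressWarnings(compute_metrics(tp = 32, tn = 0, fp = 7, fn = 0))
  expect_equal(m$sensitivity, 1.00)
  expect_equal(m$specificity, 0.00)
  expect_equal(m$mean_ss, 0.50)

  # sensitivity 0.91 / specificity 0.71 average to mean SS 0.81
  expect_equal(round((0.91 + 0.71) / 2, 2), 0.81)
  m2 <- compute_metrics(tp = 29, fn = 3, tn = 5, fp = 2)
  expect_equal(round(m2$accuracy, 2), 0.87)
  expect_equal(round(m2$precision, 2), 0.94)
  expect_equal(round(m2$sensitivity, 2), 0.91)
  expect_equal(round(m2$specificity, 2), 0.71)
  expect_equal(round(m2$mean_ss, 2), 0.81)
  expect_equal(m2$mean_ss, (m2$sensitivity + m2$specificity) / 2)

  perfect <- compute_metrics(tp = 10, tn = 5, fp = 0, fn = 0)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mean_ss, 1)
})

test_that("zero denominators surface as NaN with a warning, never 0", {
  expect_warning(m <- compute_metrics(tp = 0, tn = 5, fp = 0, fn = 1),
                 "precision undefined")
  expect_true(is.nan(m$precision))
  expect_warning(m2 <- compute_metrics(tp = 0, tn = 5, fp = 1, fn = 0),
                 "sensitivity undefined")
  expect_true(is.nan(m2$sensitivity))
  expect_error(compute_metrics(tp = 0, tn = 0, fp = 0, fn = 0), "positive")
})

test_that("accuracy is the prevalence-weighted mix of sens and spec", {
  set.seed(33)
  for (rep in 1:20) {
    cm <- as.list(stats::setNames(sample(1:30, 4, replace = TRUE),
                                  c("tp", "tn", "fp", "fn")))
    m <- compute_metrics(cm)
    n_pos <- cm$tp + cm$fn; n_neg <- cm$tn + cm$fp
    expect_equal(m$accuracy,
                 (n_pos * m$sensitivity + n_neg * m$specificity) /
                   (n_pos + n_neg))
  }
})

test_that("training improves validation loss and selects the best epoch", {
  bags <- sep_bags(70, seed = 41)
  sp <- split_bags(bags, 50, 20, 0, seed = 41)
  fit <- mil_fit(sp$train, sp$val, profile = "small", dims = c(8, 8, 4),
                 loss_cfg = loss_config(k_sample = 2),
                 train_cfg = fast_cfg(25, seed = 41))
  expect_lt(fit$log$val_loss[fit$best_epoch], fit$log$val_loss[1])
  expect_equal(fit$best_epoch, which.min(fit$log$val_loss))
  expect_equal(fit$best_val_loss, min(fit$log$val_loss))
})

test_that("patience 0 stops after the first non-improving epoch", {
  bags <- sep_bags(20, seed = 43)
  sp <- split_bags(bags, 14, 6, 0, seed = 43)
  fit <- mil_fit(sp$train, sp$val, dims = c(8, 8, 4),
                 loss_cfg = loss_config(k_sample = 2),
                 train_cfg = fast_cfg(50, patience = 0L, seed = 43))
  stalls <- which(diff(fit$log$val_loss) >= 0)
  if (length(stalls) > 0) {
    expect_equal(nrow(fit$log), stalls[1] + 1L)
  } else {
    # strict improvement throughout: training ran to the epoch cap
    expect_equal(nrow(fit$log), 50L)
  }
})

test_that("training is reproducible given the seed", {
  bags <- sep_bags(24, seed = 47)
  sp <- split_bags(bags, 16, 8, 0, seed = 47)
  f1 <- mil_fit(sp$train, sp$val, dims = c(8, 8, 4),
                loss_cfg = loss_config(k_sample = 2),
                train_cfg = fast_cfg(5, seed = 47))
  f2 <- mil_fit(sp$train, sp$val, dims = c(8, 8, 4),
                loss_cfg = loss_config(k_sample = 2),
                train_cfg = fast_cfg(5, seed = 47))
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
})

test_that("empty splits and NaN losses are configuration errors", {
  bags <- sep_bags(10, seed = 49)
  expect_error(mil_fit(list(), bags, dims = c(8, 8, 4)), "nonempty")
  expect_error(mil_fit(bags, list(), dims = c(8, 8, 4)), "nonempty")
})

test_that("evaluation maps argmax predictions to a metrics report", {
  bags <- sep_bags(60, seed = 51)
  sp <- split_bags(bags, 36, 12, 12, seed = 51)
  fit <- mil_fit(sp$train, sp$val, dims = c(8, 8, 4),
                 loss_cfg = loss_config(k_sample = 2),
                 train_cfg = fast_cfg(30, seed = 51))
  ev1 <- evaluate_model(fit, sp$test)
  ev2 <- evaluate_model(fit, sp$test)
  expect_identical(ev1$metrics, ev2$metrics)
  expect_equal(nrow(ev1$predictions), 12)
  expect_gte(ev1$metrics$accuracy, 0.9)  # trivially separable geometry
  preds <- ev1$predictions
  expect_true(all(preds$pred == (preds$prob_1 > preds$prob_0)))
})

test_that("an all-positive predictor shows the degenerate metric pattern", {
  # train on bags relabeled all-positive: cross-entropy drives every
  # slide score toward the positive class, the classic majority-class
  # collapse under extreme imbalance
  bags <- sep_bags(50, seed = 53, prevalence = 0.82)
  all_pos <- lapply(bags[1:30], function(b) { b$label <- 1L; b })
  fit <- mil_fit(all_pos, all_pos[1:10], dims = c(8, 8, 4),
                 loss_cfg = loss_config(k_sample = 2),
                 train_cfg = train_config(lr = 5e-3, max_epochs = 40,
                                          seed = 53))
  ev <- suppressWarnings(evaluate_model(fit, bags))
  expect_equal(ev$metrics$sensitivity, 1.00)
  expect_equal(ev$metrics$specificity, 0.00)
  expect_equal(ev$metrics$mean_ss, 0.50)
})

test_that("checkpoints round-trip and the best checkpoint honours history", {
  bags <- sep_bags(24, seed = 57)
  sp <- split_bags(bags, 16, 8, 0, seed = 57)
  fit <- mil_fit(sp$train, sp$val, dims = c(8, 8, 4),
                 loss_cfg = loss_config(k_sample = 2),
                 train_cfg = fast_cfg(6, seed = 57))
  # early stopping never returns a checkpoint beaten by a later epoch
  expect_true(all(fit$log$val_loss >= fit$best_val_loss))
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$params$W1, fit$params$W1)
  expect_equal(back$params$Winst[[2]], fit$params$Winst[[2]])
  p1 <- predict(fit, sp$val)
  p2 <- predict(back, sp$val)
  expect_equal(p1$prob_1, p2$prob_1)
})

test_that("attention recovery agrees with a first-principles AUROC", {
  bags <- sep_bags(40, seed = 59)
  sp <- split_bags(bags, 26, 8, 6, seed = 59)
  fit <- mil_fit(sp$train, sp$val, dims = c(8, 8, 4),
                 loss_cfg = loss_config(k_sample = 2),
                 train_cfg = fast_cfg(30, seed = 59))
  auc_pkg <- attention_auroc(fit, sp$test)
  # recompute with the explicit pairwise-comparison oracle
  aucs <- c()
  for (bag in sp$test) {
    if (bag$label != 1 || all(bag$signal) || !any(bag$signal)) next
    a <- mil_forward(bag$features, fit$params)$a[2, ]
    aucs <- c(aucs, oracle_auc(a, as.integer(bag$signal)))
  }
  expect_equal(auc_pkg, mean(aucs), tolerance = 1e-12)
})
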