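#' Training configuration
#'
#' Optimization protocol: Adam with learning rate 2e-4, weight decay
#' 1e-5, beta1 0.9, beta2 0.999, epsilon 1e-8, dropout 0.25, one slide
#' (bag) per optimization step, and early stopping when the validation
#' loss has not improved for `patience` consecutive validation epochs.
#' The checkpoint with the smallest validation loss is kept.
#'
#' @param lr Learning rate.
#' @param weight_decay L2 weight decay added to the gradient.
#' @param beta1,beta2,adam_eps Adam moment decays and epsilon.
#' @param dropout Dropout probability during training.
#' @param patience Validation epochs without improvement before
#'   stopping.
#' @param max_epochs Hard cap on epochs (default 200).
#' @param max_instances Per-bag instance cap during training: bags
#'   larger than this are randomly subsampled each step (default 512);
#'   evaluation always uses all instances.
#' @param seed Integer seed controlling initialization, shuffling,
#'   dropout and subsampling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 2e-4, weight_decay = 1e-5, beta1 = 0.9,
                         beta2 = 0.999, adam_eps = 1e-8, dropout = 0.25,
                         patience = 20L, max_epochs = 200L,
                         max_instances = 512L, seed = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, beta1 > 0, beta2 > 0,
            adam_eps > 0, patience >= 0, max_epochs >= 1)
  structure(list(lr = lr, weight_decay = weight_decay, beta1 = beta1,
                 beta2 = beta2, adam_eps = adam_eps, dropout = dropout,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 max_instances = as.integer(max_instances),
                 seed = as.integer(seed)), class = "train_config")
}

adam_init <- function(theta) {
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step <- function(theta, grad, state, cfg) {
  grad <- grad + cfg$weight_decay * theta
  state$t <- state$t + 1L
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  mhat <- state$m / (1 - cfg$beta1^state$t)
  vhat <- state$v / (1 - cfg$beta2^state$t)
  theta <- theta - cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps)
  list(theta = theta, state = state)
}

#' Fit the clustering-constrained attention-MIL model
#'
#' Trains the gated attention model on labeled feature bags with the
#' combined objective (slide cross-entropy plus smooth-SVM instance
#' clustering loss under attention-derived pseudo labels), one bag per
#' Adam step. Validation slide-level cross-entropy is tracked each
#' epoch; training stops once it has not improved for
#' `train_cfg$patience` consecutive epochs, and the parameters with the
#' smallest validation loss are returned. The whole run is reproducible
#' given `train_cfg$seed`.
#'
#' @param train_bags,val_bags Lists of labeled [feature_bag()]s
#'   (labels in `0..N-1`); both must be nonempty.
#' @param n_classes Number of classes N.
#' @param profile Model size profile, `"small"` or `"paper"` (see
#'   [mil_params()]).
#' @param dims Optional explicit `c(input, hidden, attention)` dims
#'   overriding the profile.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @return Object of class `mil_fit`: best `params`, `best_epoch`,
#'   `best_val_loss`, `log` (data frame of epoch, train_loss,
#'   val_loss), and the configurations.
#' @export
mil_fit <- function(train_bags, val_bags, n_classes = 2L,
                    profile = "small", dims = NULL,
                    loss_cfg = loss_config(),
                    train_cfg = train_config()) {
  if (length(train_bags) == 0 || length(val_bags) == 0)
    stop("train and validation splits must be nonempty", call. = FALSE)
  labs <- vapply(train_bags, function(b) b$label, numeric(1))
  if (anyNA(labs)) stop("all training bags must carry a label", call. = FALSE)

  set.seed(train_cfg$seed)
  params <- mil_params(profile = profile, n_classes = n_classes,
                       dims = dims, dropout_p = train_cfg$dropout,
                       seed = train_cfg$seed)
  theta <- flatten_params(params)
  state <- adam_init(theta)

  best <- list(val = Inf, theta = theta, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  stall <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample.int(length(train_bags))
    tr_loss <- 0
    for (b in ord) {
      bag <- train_bags[[b]]
      z <- bag$features
      if (nrow(z) > train_cfg$max_instances)
        z <- z[sample.int(nrow(z), train_cfg$max_instances), , drop = FALSE]
      y <- bag$label + 1L
      fwd <- mil_forward(z, params, mode = "train")
      bl <- suppressWarnings(bag_loss(fwd, y, loss_cfg))
      if (!is.finite(bl$total))
        stop("NaN/Inf loss at epoch ", epoch, ", bag ", bag$slide_id,
             ": aborting", call. = FALSE)
      grads <- mil_backward(fwd, y, params, loss_cfg, bl$idx, bl$labs)
      upd <- adam_step(theta, flatten_params(grads), state, train_cfg)
      theta <- upd$theta; state <- upd$state
      params <- unflatten_params(theta, params)
      tr_loss <- tr_loss + bl$total
    }
    val_loss <- mean(vapply(val_bags, function(bag) {
      fwd <- mil_forward(bag$features, params, mode = "eval")
      slide_loss(fwd$s_slide, bag$label + 1L)
    }, numeric(1)))
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = tr_loss / length(train_bags),
                                 val_loss = val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, theta = theta, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > train_cfg$patience) break
    }
  }
  structure(list(params = unflatten_params(best$theta, params),
                 best_epoch = best$epoch, best_val_loss = best$val,
                 log = log, n_classes = as.integer(n_classes),
                 loss_cfg = loss_cfg, train_cfg = train_cfg),
            class = "mil_fit")
}

#' @export
print.mil_fit <- function(x, ...) {
  cat("Clustering-constrained attention-MIL model\n")
  cat(sprintf("  classes: %d, dims: %s\n", x$n_classes,
              paste(x$params$dims, collapse = "/")))
  cat(sprintf("  epochs run: %d, best epoch: %d (val loss %.4f)\n",
              nrow(x$log), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.mil_fit <- function(object, ...) {
  p <- length(flatten_params(object$params))
  cat("Clustering-constrained attention-MIL model\n")
  cat(sprintf("  parameters: %d (dims %s, %d classes)\n", p,
              paste(object$params$dims, collapse = "/"), object$n_classes))
  cat(sprintf("  objective: %.2f * slide CE + %.2f * patch smooth-SVM",
              object$loss_cfg$c1, object$loss_cfg$c2),
      sprintf("(alpha=%.2g, tau=%.2g, k_sample=%d)\n",
              object$loss_cfg$alpha, object$loss_cfg$tau,
              object$loss_cfg$k_sample))
  cat(sprintf("  training: Adam lr=%.2g, wd=%.2g, patience=%d\n",
              object$train_cfg$lr, object$train_cfg$weight_decay,
              object$train_cfg$patience))
  cat(sprintf("  best epoch %d of %d, validation loss %.4f\n",
              object$best_epoch, nrow(object$log), object$best_val_loss))
  invisible(object)
}

#' @export
coef.mil_fit <- function(object, ...) object$params

#' Predict slide labels for feature bags
#'
#' @param object A fitted [mil_fit()] model.
#' @param bags List of [feature_bag()]s (labels ignored).
#' @param ... Unused.
#' @return Data frame with `slide_id`, one probability column per
#'   class, and `pred` (argmax class in `0..N-1`).
#' @export
predict.mil_fit <- function(object, bags, ...) {
  if (inherits(bags, "feature_bag")) bags <- list(bags)
  rows <- lapply(bags, function(bag) {
    fwd <- mil_forward(bag$features, object$params, mode = "eval")
    data.frame(slide_id = bag$slide_id,
               t(stats::setNames(fwd$probs,
                                 paste0("prob_", seq_len(object$n_classes) - 1L))),
               pred = which.max(fwd$probs) - 1L)
  })
  do.call(rbind, rows)
}

#' @export
plot.mil_fit <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train (total)", "validation (slide CE)"),
                   lty = 1, col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, sensitivity, specificity, and their balanced
#' mean (mean SS = (sensitivity + specificity) / 2). A metric whose
#' denominator is zero is reported as `NaN` with a warning, never
#' silently 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion-matrix counts (or a list
#'   with those fields as the first argument).
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `mean_ss`, `counts`.
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) { cm <- tp; tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || sum(counts) == 0)
    stop("confusion matrix must hold non-negative counts with a positive total",
         call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  structure(list(accuracy = (tp + tn) / sum(counts),
                 precision = safe_div(tp, tp + fp, "precision"),
                 sensitivity = sens, specificity = spec,
                 mean_ss = (sens + spec) / 2,
                 counts = counts), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  sensitivity %.3f  specificity %.3f  mean SS %.3f\n",
              x$accuracy, x$precision, x$sensitivity, x$specificity,
              x$mean_ss))
  invisible(x)
}

#' Evaluate a fitted model on a test split
#'
#' Predicted class is the argmax of the slide probabilities; the
#' confusion matrix is taken with respect to the positive class
#' (label 1).
#'
#' @param fit A [mil_fit()] model.
#' @param test_bags Nonempty list of labeled [feature_bag()]s.
#' @return List with `metrics` ([compute_metrics()] report) and
#'   `predictions` (the [predict.mil_fit()] data frame plus `label`).
#' @export
evaluate_model <- function(fit, test_bags) {
  if (length(test_bags) == 0) stop("test split is empty", call. = FALSE)
  labs <- vapply(test_bags, function(b) b$label, numeric(1))
  if (anyNA(labs)) stop("test bags must carry labels", call. = FALSE)
  preds <- predict(fit, test_bags)
  preds$label <- labs
  cm <- list(tp = sum(preds$pred == 1 & labs == 1),
             tn = sum(preds$pred == 0 & labs == 0),
             fp = sum(preds$pred == 1 & labs == 0),
             fn = sum(preds$pred == 0 & labs == 1))
  list(metrics = compute_metrics(cm), predictions = preds)
}

#' Identify the model's evidence branch
#'
#' With a softmax over class scores, only score differences are
#' identified, so for a presence/absence task the witness-seeking
#' attention may end up in either class branch depending on
#' initialization: one branch raises its score on witness instances,
#' or the other lowers its own. The evidence branch is identified
#' without any instance-level ground truth as the branch whose pooled
#' slide representation separates positive from negative bags the
#' most (largest Euclidean distance between the class-conditional
#' means of `h_slide_i`): the branch pooling witnesses differs across
#' slide labels, a branch pooling background does not.
#'
#' @param fit A [mil_fit()] model.
#' @param bags Labeled bags (typically the validation split; instance
#'   flags are not used).
#' @return Branch index in `1..N`.
#' @export
evidence_branch <- function(fit, bags) {
  labs <- vapply(bags, function(b) b$label, numeric(1))
  if (length(unique(labs)) < 2)
    stop("need bags of both classes to identify the evidence branch",
         call. = FALSE)
  hs <- lapply(bags, function(b)
    mil_forward(b$features, fit$params, mode = "eval")$h_slide)
  n <- fit$n_classes
  gap <- vapply(seq_len(n), function(i) {
    mp <- Reduce(`+`, lapply(hs[labs == 1], function(m) m[i, ])) /
      sum(labs == 1)
    mn <- Reduce(`+`, lapply(hs[labs == 0], function(m) m[i, ])) /
      sum(labs == 0)
    sqrt(sum((mp - mn)^2))
  }, numeric(1))
  which.max(gap)
}

#' Attention recovery score on positive bags
#'
#' For each positive test bag with ground-truth instance flags, the
#' AUROC of the attention scores against the flags is computed; the
#' mean over bags measures how well attention concentrates on true
#' signal instances.
#'
#' @param fit A [mil_fit()] model.
#' @param bags Bags carrying `signal` flags (from [simulate_bags()]).
#' @param positive_class Class index in `1..N` whose attention row is
#'   scored; defaults to the positive branch of the binary model. For
#'   presence/absence tasks the witness-seeking branch is not
#'   identified by the softmax objective — select it with
#'   [evidence_branch()] on validation bags first.
#' @return Mean per-bag AUROC over positive bags with both instance
#'   classes present.
#' @export
attention_auroc <- function(fit, bags, positive_class = 2L) {
  aucs <- c()
  for (bag in bags) {
    if (is.na(bag$label) || bag$label != 1 || is.null(bag$signal)) next
    if (all(bag$signal) || !any(bag$signal)) next
    fwd <- mil_forward(bag$features, fit$params, mode = "eval")
    a <- fwd$a[positive_class, ]
    roc <- pROC::roc(response = as.integer(bag$signal), predictor = a,
                     quiet = TRUE, direction = "<")
    aucs <- c(aucs, as.numeric(pROC::auc(roc)))
  }
  if (length(aucs) == 0) stop("no positive bags with instance flags", call. = FALSE)
  mean(aucs)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a schema version and shape manifest;
#' weights are stored in full precision JSON so checkpoints are plain
#' text and portable.
#'
#' @param fit A [mil_fit()] model.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(fit, path) {
  p <- fit$params
  obj <- list(schema = 1L,
              shapes = list(dims = p$dims, n_classes = p$n_classes),
              dropout_p = p$dropout_p,
              weights = list(W1 = p$W1, Va = p$Va, Ua = p$Ua, Wa = p$Wa,
                             Wc = p$Wc, Winst = p$Winst),
              best_epoch = fit$best_epoch,
              best_val_loss = fit$best_val_loss,
              log = fit$log, loss_cfg = unclass(fit$loss_cfg),
              train_cfg = unclass(fit$train_cfg))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- obj$weights
  params <- structure(list(
    W1 = as.matrix(w$W1), Va = as.matrix(w$Va), Ua = as.matrix(w$Ua),
    Wa = as.matrix(w$Wa), Wc = as.matrix(w$Wc),
    Winst = if (is.list(w$Winst)) lapply(w$Winst, as.matrix)
            else apply(w$Winst, 1, function(m) as.matrix(m), simplify = FALSE),
    dims = as.integer(obj$shapes$dims),
    n_classes = as.integer(obj$shapes$n_classes),
    dropout_p = obj$dropout_p), class = "mil_params")
  structure(list(params = params, best_epoch = obj$best_epoch,
                 best_val_loss = obj$best_val_loss,
                 log = as.data.frame(obj$log),
                 n_classes = params$n_classes,
                 loss_cfg = do.call(loss_config, as.list(obj$loss_cfg)),
                 train_cfg = do.call(train_config, as.list(obj$train_cfg))),
            class = "mil_fit")
}

#' Stratified train/validation/test split of a bag dataset
#'
#' @param bags A `bag_dataset`.
#' @param n_train,n_val,n_test Sizes of the three splits; must not
#'   exceed the dataset and must not overlap.
#' @param seed Integer seed.
#' @return List of `train`, `val`, `test` bag lists.
#' @export
split_bags <- function(bags, n_train, n_val, n_test, seed = 1L) {
  n <- length(bags)
  if (n_train + n_val + n_test > n)
    stop("split sizes exceed dataset size", call. = FALSE)
  set.seed(as.integer(seed))
  labs <- vapply(bags, function(b) b$label, numeric(1))
  # proportional-rank interleave: shuffle within each class, give the
  # i-th member of a class of size p the key (i - u)/p, and order all
  # bags by key — every prefix is then near-proportionally stratified,
  # so consecutive blocks give exact split sizes with balanced classes
  key <- numeric(n)
  for (l in unique(labs)) {
    pool <- which(labs == l)
    pool <- pool[sample.int(length(pool))]
    key[pool] <- (seq_along(pool) - stats::runif(length(pool))) /
      length(pool)
  }
  idx <- order(key)
  list(train = bags[idx[seq_len(n_train)]],
       val = bags[idx[n_train + seq_len(n_val)]],
       test = bags[idx[n_train + n_val + seq_len(n_test)]])
}
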