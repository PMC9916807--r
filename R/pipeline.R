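#' Default pipeline configuration
#'
#' Run configuration for [run_pipeline()]. Unknown keys in a supplied
#' config are rejected before any stage runs.
#'
#' @param out_dir Artifacts directory.
#' @param seed Global seed driving every stage.
#' @param n_slides Toy cohort size.
#' @param prevalence Fraction of positive slides.
#' @param slide_size Toy slide edge length in pixels.
#' @param patch_size Tiling patch edge length.
#' @param min_fg Minimum patch foreground fraction.
#' @param encoder_dim Patch embedding dimensionality.
#' @param model_dims `c(input, hidden, attention)` model dims;
#'   `encoder_dim` must equal `model_dims[1]`.
#' @param n_train,n_val,n_test Split sizes (slides).
#' @param loss [loss_config()] fields as a list.
#' @param training [train_config()] fields as a list.
#' @param heatmap_class Attention branch rendered for the first test
#'   slide.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("wsimil_run_"), seed = 1L,
                       n_slides = 20L, prevalence = 0.5,
                       slide_size = 512L, patch_size = 128L,
                       min_fg = 0.5, encoder_dim = 16L,
                       model_dims = c(16L, 8L, 4L),
                       n_train = 12L, n_val = 4L, n_test = 4L,
                       loss = list(), training = list(),
                       heatmap_class = 2L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_slides = as.integer(n_slides), prevalence = prevalence,
              slide_size = as.integer(slide_size),
              patch_size = as.integer(patch_size), min_fg = min_fg,
              encoder_dim = as.integer(encoder_dim),
              model_dims = as.integer(model_dims),
              n_train = as.integer(n_train), n_val = as.integer(n_val),
              n_test = as.integer(n_test), loss = loss,
              training = training, heatmap_class = as.integer(heatmap_class))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  known <- names(formals(run_config))
  extra <- setdiff(names(unclass(cfg)), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  if (cfg$encoder_dim != cfg$model_dims[1])
    stop("'encoder_dim' must equal model input dim", call. = FALSE)
  if (cfg$n_train + cfg$n_val + cfg$n_test > cfg$n_slides)
    stop("train/val/test sizes exceed the cohort: splits would overlap",
         call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  extra <- setdiff(names(vals), names(formals(run_config)))
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

#' Run the full weakly supervised pipeline on a toy cohort
#'
#' Executes every stage in order — simulate toy slides, segment and
#' tile each slide, extract patch features with the desk encoder,
#' train the attention-MIL model, evaluate on the held-out test
#' slides, and render an attention heatmap for the first test slide.
#' All artifacts are written under `cfg$out_dir`, stamped with the
#' config hash and seed; a rerun with the same config reproduces the
#' metrics JSON exactly.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `metrics`, `fit`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("simulate", simulate_toy_cohort(
    n_slides = cfg$n_slides, prevalence = cfg$prevalence,
    width = cfg$slide_size, height = cfg$slide_size, seed = cfg$seed))

  encoder <- desk_encoder(seed = cfg$seed, output_dim = cfg$encoder_dim)
  bags <- stage("segment-tile-extract", lapply(cohort, function(sl) {
    seg <- segment_foreground(sl$image)
    ts <- tile_patches(c(dim(sl$image)[2], dim(sl$image)[1]), seg$mask,
                       patch_size = cfg$patch_size,
                       min_foreground_fraction = cfg$min_fg,
                       downsample = seg$downsample, slide_id = sl$slide_id)
    if (nrow(ts$coords) == 0)
      ts <- tile_patches(c(dim(sl$image)[2], dim(sl$image)[1]), NULL,
                         patch_size = cfg$patch_size,
                         min_foreground_fraction = 0,
                         slide_id = sl$slide_id)
    extract_features(sl$image, ts, encoder, label = sl$label)
  }))

  sp <- split_bags(structure(bags, class = "bag_dataset"),
                   cfg$n_train, cfg$n_val, cfg$n_test, seed = cfg$seed)
  loss_cfg <- do.call(loss_config, cfg$loss)
  train_cfg <- do.call(train_config,
                       utils::modifyList(list(seed = cfg$seed), cfg$training))
  fit <- stage("train", mil_fit(sp$train, sp$val, n_classes = 2L,
                                dims = cfg$model_dims, loss_cfg = loss_cfg,
                                train_cfg = train_cfg))
  save_checkpoint(fit, file.path(cfg$out_dir, "checkpoint.json"))
  utils::write.csv(fit$log, file.path(cfg$out_dir, "training_log.csv"),
                   row.names = FALSE)

  ev <- stage("evaluate", evaluate_model(fit, sp$test))
  utils::write.csv(ev$predictions, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)

  first <- sp$test[[1]]
  slide_img <- cohort[[which(vapply(cohort, `[[`, "", "slide_id") ==
                               first$slide_id)]]$image
  ts <- tile_patches(c(dim(slide_img)[2], dim(slide_img)[1]), NULL,
                     patch_size = cfg$patch_size, min_foreground_fraction = 0,
                     slide_id = first$slide_id)
  fwd <- mil_forward(first$features, fit$params, mode = "eval")
  hm <- stage("heatmap", render_heatmap(
    slide_img,
    structure(list(slide_id = first$slide_id, patch_size = cfg$patch_size,
                   level = 0L, downsample = 1L, coords = first$coords,
                   fg_fraction = rep(1, nrow(first$coords))),
              class = "tile_set"),
    fwd$a[cfg$heatmap_class, ],
    heatmap_spec(class_index = cfg$heatmap_class)))
  write_heatmap(hm, file.path(cfg$out_dir, "heatmap.png"))

  cfg_for_hash <- unclass(cfg); cfg_for_hash$out_dir <- NULL
  metrics <- list(config_hash = config_hash(cfg_for_hash), seed = cfg$seed,
                  n_train = length(sp$train), n_val = length(sp$val),
                  n_test = length(sp$test),
                  best_epoch = fit$best_epoch,
                  best_val_loss = fit$best_val_loss,
                  accuracy = ev$metrics$accuracy,
                  precision = ev$metrics$precision,
                  sensitivity = ev$metrics$sensitivity,
                  specificity = ev$metrics$specificity,
                  mean_ss = ev$metrics$mean_ss)
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, fit = fit, out_dir = cfg$out_dir))
}

# Deterministic short hash of the config (rolling polynomial hash over
# its serialized form)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", h)
}
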