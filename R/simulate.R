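#' Specification for a synthetic multiple-instance bag dataset
#'
#' Describes a Gaussian-mixture bag simulation: each bag is a set of
#' instance feature vectors; positive bags contain a minority of
#' "signal" instances whose mean is shifted from the background,
#' negative bags contain background instances only. This is the
#' standard witness-rate benchmark geometry for weakly supervised
#' multiple instance learning: the slide-level label is observable,
#' instance-level flags are kept only as ground truth for evaluating
#' attention.
#'
#' @param n_bags Number of bags (slides) to simulate.
#' @param prevalence Fraction of positive bags in `[0, 1]`. The default
#'   0.82 mirrors a strongly imbalanced cohort (82% positive, 18%
#'   negative slides).
#' @param bag_size_range Integer vector `c(min, max)`: instances per bag
#'   are drawn uniformly from this range.
#' @param witness_rate Fraction of signal instances within a positive
#'   bag, in `(0, 1]`. Every positive bag receives
#'   `ceiling(witness_rate * K)` signal instances.
#' @param dim Embedding dimensionality of each instance.
#' @param mu_background Scalar mean of background instance features
#'   (applied to every coordinate).
#' @param mu_signal Scalar mean of signal instance features.
#' @param sigma Common standard deviation (isotropic), must be `> 0`.
#' @param seed Integer seed; the same seed and spec reproduce the
#'   dataset exactly. Each bag draws from its own substream so earlier
#'   bags are unchanged when `n_bags` grows.
#'
#' @return An object of class `bag_sim_spec`.
#' @seealso [simulate_bags()]
#' @export
bag_sim_spec <- function(n_bags = 100, prevalence = 0.82,
                         bag_size_range = c(30L, 120L),
                         witness_rate = 0.1, dim = 1024L,
                         mu_background = 0, mu_signal = 1,
                         sigma = 1, seed = 1L) {
  spec <- list(n_bags = as.integer(n_bags), prevalence = prevalence,
               bag_size_range = as.integer(bag_size_range),
               witness_rate = witness_rate, dim = as.integer(dim),
               mu_background = mu_background, mu_signal = mu_signal,
               sigma = sigma, seed = as.integer(seed))
  validate_bag_sim_spec(spec)
  class(spec) <- "bag_sim_spec"
  spec
}

validate_bag_sim_spec <- function(spec) {
  if (!is.finite(spec$n_bags) || spec$n_bags < 1)
    stop("invalid 'n_bags': must be a positive integer", call. = FALSE)
  if (!is.numeric(spec$prevalence) || spec$prevalence < 0 || spec$prevalence > 1)
    stop("invalid 'prevalence': must lie in [0, 1]", call. = FALSE)
  if (length(spec$bag_size_range) != 2L || spec$bag_size_range[1] < 1 ||
      spec$bag_size_range[2] < spec$bag_size_range[1])
    stop("invalid 'bag_size_range': need c(min, max) with min >= 1", call. = FALSE)
  if (!is.numeric(spec$witness_rate) || spec$witness_rate <= 0 || spec$witness_rate > 1)
    stop("invalid 'witness_rate': must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(spec$sigma) || spec$sigma <= 0)
    stop("invalid 'sigma': must be > 0", call. = FALSE)
  if (spec$dim < 1)
    stop("invalid 'dim': must be >= 1", call. = FALSE)
  invisible(spec)
}

# Substream seed for bag b under global seed s; kept below 2^31 - 1.
bag_substream_seed <- function(seed, b) {
  as.integer((as.double(seed) %% 2147483647 * 69621 + b * 104729) %% 2147483647)
}

#' Simulate a labeled collection of feature bags
#'
#' Draws `n_bags` bags per the spec. Exactly `round(n_bags * prevalence)`
#' bags are positive. In a positive bag of size K, `ceiling(witness_rate
#' * K)` instances are "signal" with mean `mu_signal` in every
#' coordinate; all remaining instances (and every instance of a negative
#' bag) are background with mean `mu_background`. Features are i.i.d.
#' Normal with isotropic standard deviation `sigma`. Instances are
#' assigned synthetic grid coordinates so bags are structurally
#' identical to bags extracted from real slides.
#'
#' Per-instance signal flags are returned for attention-recovery
#' evaluation only; the training path never sees them.
#'
#' @param spec A [bag_sim_spec()].
#' @return A list of class `bag_dataset`: each element is a feature bag
#'   (list with `slide_id`, `features` K x D matrix, `coords` K x 2
#'   matrix, `label` 0/1, and `signal` logical ground-truth flags).
#' @export
simulate_bags <- function(spec) {
  validate_bag_sim_spec(spec)
  n <- spec$n_bags
  n_pos <- round(n * spec$prevalence)
  # positive bags chosen by ranking per-bag substream uniforms: stable
  # content per bag, exact positive count
  u <- vapply(seq_len(n), function(b) {
    set.seed(bag_substream_seed(spec$seed, b))
    stats::runif(1)
  }, numeric(1))
  labels <- integer(n)
  labels[order(u)[seq_len(n_pos)]] <- 1L

  bags <- vector("list", n)
  for (b in seq_len(n)) {
    set.seed(bag_substream_seed(spec$seed, b))
    stats::runif(1)  # consume the label-ranking draw
    k <- sample(seq(spec$bag_size_range[1], spec$bag_size_range[2]), 1L)
    signal <- rep(FALSE, k)
    if (labels[b] == 1L) {
      n_sig <- ceiling(spec$witness_rate * k)
      signal[sample.int(k, n_sig)] <- TRUE
    }
    mu <- ifelse(signal, spec$mu_signal, spec$mu_background)
    feats <- matrix(stats::rnorm(k * spec$dim, mean = rep(mu, spec$dim),
                                 sd = spec$sigma),
                    nrow = k, ncol = spec$dim)
    g <- ceiling(sqrt(k))
    coords <- cbind(x = ((seq_len(k) - 1L) %% g) * 256L,
                    y = ((seq_len(k) - 1L) %/% g) * 256L)
    bags[[b]] <- feature_bag(slide_id = sprintf("sim_%04d", b),
                             features = feats, coords = coords,
                             label = labels[b], signal = signal)
  }
  structure(bags, class = "bag_dataset", spec = spec)
}

#' Construct a feature bag
#'
#' The unit of weak supervision: K patch embeddings with their level-0
#' patch coordinates and one slide-level label.
#'
#' @param slide_id Slide identifier string.
#' @param features K x D numeric matrix of patch embeddings.
#' @param coords K x 2 matrix of level-0 top-left patch corners
#'   (0-based, half-open boxes), rows aligned with `features`.
#' @param label Slide-level class in `0, ..., N-1` (may be `NA` for
#'   unlabeled inference bags).
#' @param signal Optional logical ground-truth flags (simulation only).
#' @return Object of class `feature_bag`.
#' @export
feature_bag <- function(slide_id, features, coords, label = NA_integer_,
                        signal = NULL) {
  features <- as.matrix(features)
  coords <- as.matrix(coords)
  if (nrow(features) < 1L) stop("feature bag must contain at least one instance")
  if (nrow(coords) != nrow(features))
    stop("'coords' rows must align with 'features' rows")
  if (!is.null(signal) && length(signal) != nrow(features))
    stop("'signal' flags must align with 'features' rows")
  structure(list(slide_id = slide_id, features = features,
                 coords = coords, label = label, signal = signal),
            class = "feature_bag")
}

#' Specification for a toy slide image
#'
#' A bright, glass-like background with rectangular "tissue" blobs,
#' used to exercise foreground segmentation and tiling without real
#' slides.
#'
#' @param width,height Image size in pixels.
#' @param background_intensity Gray level of the background in `[0, 1]`,
#'   near white by default.
#' @param blob_boxes List of rectangles `c(x, y, w, h)` (0-based,
#'   half-open, level-0 pixels) painted as tissue; must lie within the
#'   image.
#' @param blob_color Length-3 RGB color of tissue pixels; saturated and
#'   darker than the background by default (a Papanicolaou-like pink).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed for the noise.
#' @return An object of class `toy_slide_spec`.
#' @export
toy_slide_spec <- function(width, height, background_intensity = 0.94,
                           blob_boxes = list(),
                           blob_color = c(0.78, 0.42, 0.62),
                           noise_sd = 0.01, seed = 1L) {
  if (width < 1 || height < 1)
    stop("invalid image size: 'width' and 'height' must be >= 1", call. = FALSE)
  for (bb in blob_boxes) {
    if (length(bb) != 4L) stop("each blob box must be c(x, y, w, h)", call. = FALSE)
    if (bb[1] < 0 || bb[2] < 0 || bb[1] + bb[3] > width || bb[2] + bb[4] > height)
      stop("blob box ", paste(bb, collapse = ","),
           " lies outside image bounds", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_intensity = background_intensity,
                 blob_boxes = blob_boxes, blob_color = blob_color,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "toy_slide_spec")
}

#' Render a toy slide and its ground-truth foreground mask
#'
#' @param spec A [toy_slide_spec()].
#' @return List with `image` (height x width x 3 array in `[0, 1]`,
#'   row = y, column = x) and `mask` (logical height x width matrix,
#'   exactly the union of the blob boxes).
#' @export
render_toy_slide <- function(spec) {
  stopifnot(inherits(spec, "toy_slide_spec"))
  h <- spec$height; w <- spec$width
  img <- array(spec$background_intensity, dim = c(h, w, 3))
  mask <- matrix(FALSE, nrow = h, ncol = w)
  for (bb in spec$blob_boxes) {
    rows <- (bb[2] + 1L):(bb[2] + bb[4])   # y -> rows
    cols <- (bb[1] + 1L):(bb[1] + bb[3])   # x -> cols
    for (ch in 1:3) img[rows, cols, ch] <- spec$blob_color[ch]
    mask[rows, cols] <- TRUE
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  list(image = img, mask = mask)
}

#' Simulate a small cohort of labeled toy slides
#'
#' Convenience generator for end-to-end pipeline runs: every slide gets
#' background-tissue blobs; positive slides additionally get blobs in a
#' distinct "lesion" color so that the slide label is recoverable from
#' patch appearance alone.
#'
#' @param n_slides Number of slides.
#' @param prevalence Fraction of positive slides.
#' @param width,height Slide size in pixels.
#' @param seed Integer seed.
#' @return List of elements `slide_id`, `image`, `mask`, `label`,
#'   `signal_mask` (logical matrix marking lesion blobs).
#' @export
simulate_toy_cohort <- function(n_slides = 20, prevalence = 0.5,
                                width = 512, height = 512, seed = 1L) {
  n_pos <- round(n_slides * prevalence)
  labels <- c(rep(1L, n_pos), rep(0L, n_slides - n_pos))
  lesion_color <- c(0.35, 0.25, 0.55)  # dark violet, distinct hue
  lapply(seq_len(n_slides), function(i) {
    set.seed(bag_substream_seed(seed, i))
    n_blob <- sample(2:4, 1)
    boxes <- lapply(seq_len(n_blob), function(j) {
      bw <- sample(seq(width %/% 4, width %/% 2), 1)
      bh <- sample(seq(height %/% 4, height %/% 2), 1)
      c(sample(0:(width - bw), 1), sample(0:(height - bh), 1), bw, bh)
    })
    spec <- toy_slide_spec(width, height, blob_boxes = boxes,
                           noise_sd = 0.01,
                           seed = bag_substream_seed(seed, i))
    out <- render_toy_slide(spec)
    signal_mask <- matrix(FALSE, height, width)
    if (labels[i] == 1L) {
      lesion <- boxes[[1]]
      rows <- (lesion[2] + 1L):(lesion[2] + lesion[4])
      cols <- (lesion[1] + 1L):(lesion[1] + lesion[3])
      for (ch in 1:3) out$image[rows, cols, ch] <- lesion_color[ch]
      signal_mask[rows, cols] <- TRUE
    }
    list(slide_id = sprintf("toy_%03d", i), image = out$image,
         mask = out$mask, label = labels[i], signal_mask = signal_mask)
  })
}
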