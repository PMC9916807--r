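#' Construct a patch encoder
#'
#' An encoder maps a list of RGB patch arrays to a matrix of fixed-size
#' embeddings, one row per patch. Encoders are deterministic in
#' inference mode: the same patch always yields the same row, and the
#' output dimension never changes across calls. Any encoder honouring
#' this contract can be plugged into [extract_features()] — including
#' an adapter around a pretrained convolutional trunk truncated at its
#' 1024-channel stage.
#'
#' @param name Encoder name.
#' @param output_dim Embedding dimensionality.
#' @param apply Function `(list of h x w x 3 arrays) -> n x output_dim`
#'   matrix.
#' @return Object of class `patch_encoder`.
#' @export
patch_encoder <- function(name, output_dim, apply) {
  stopifnot(is.function(apply), output_dim >= 1)
  structure(list(name = name, output_dim = as.integer(output_dim),
                 apply = apply),
            class = "patch_encoder")
}

#' Desk-scale default encoder
#'
#' A small, fully deterministic stand-in encoder for offline use: each
#' patch is block-averaged to an 8 x 8 x 3 thumbnail, flattened, and
#' passed through a fixed seeded random projection followed by tanh.
#' It preserves coarse color/intensity structure — enough for the
#' synthetic fixtures — but it is NOT a pretrained convolutional
#' feature extractor and makes no claim to histological feature
#' quality.
#'
#' @param seed Integer seed for the projection weights.
#' @param output_dim Embedding dimensionality (default 1024).
#' @return A [patch_encoder()].
#' @export
desk_encoder <- function(seed = 1L, output_dim = 1024L) {
  in_dim <- 8L * 8L * 3L
  set.seed(as.integer(seed))
  proj <- matrix(stats::rnorm(output_dim * in_dim, sd = 1 / sqrt(in_dim)),
                 nrow = output_dim, ncol = in_dim)
  apply_fn <- function(patches) {
    feats <- vapply(patches, function(p) {
      tanh(as.vector(proj %*% thumbnail_vector(p)))
    }, numeric(output_dim))
    t(matrix(feats, nrow = output_dim))
  }
  patch_encoder(name = "desk", output_dim = output_dim, apply = apply_fn)
}

# Block-average a patch to 8x8x3 and flatten; pads by pixel replication
# when the patch edge is not a multiple of 8.
thumbnail_vector <- function(patch) {
  h <- dim(patch)[1]; w <- dim(patch)[2]
  ri <- pmin(h, ceiling(seq_len(h) / (h / 8)))
  ci <- pmin(w, ceiling(seq_len(w) / (w / 8)))
  out <- numeric(8 * 8 * 3)
  idx <- 1L
  for (ch in 1:3) {
    m <- patch[, , ch]
    agg <- rowsum(t(rowsum(m, ri)), ci)  # 8 x 8 sums (transposed)
    cnt <- rowsum(t(rowsum(matrix(1, h, w), ri)), ci)
    out[idx:(idx + 63L)] <- as.vector(t(agg / cnt))
    idx <- idx + 64L
  }
  out
}

#' Extract a feature bag from a slide
#'
#' Runs the encoder over every tile of the tile set, in batches, and
#' assembles the K x D feature matrix row-aligned with the tile
#' coordinates. The result is independent of `batch_size`.
#'
#' @param image Slide array (row = y) or TIFF path.
#' @param tileset A [tile_patches()] result; must be nonempty.
#' @param encoder A [patch_encoder()].
#' @param batch_size Number of patches encoded per call (default 64).
#' @param label Optional slide-level label to attach.
#' @return A [feature_bag()].
#' @export
extract_features <- function(image, tileset, encoder, batch_size = 64,
                             label = NA_integer_) {
  stopifnot(inherits(tileset, "tile_set"), inherits(encoder, "patch_encoder"))
  if (is.character(image)) image <- read_slide_image(image)
  k <- nrow(tileset$coords)
  if (k < 1L) stop("tile set is empty; nothing to encode", call. = FALSE)
  rows <- vector("list", ceiling(k / batch_size))
  for (b in seq_along(rows)) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, k)
    patches <- lapply(idx, function(i)
      read_patch(image, tileset$coords[i, 1], tileset$coords[i, 2],
                 tileset$patch_size))
    emb <- encoder$apply(patches)
    if (ncol(emb) != encoder$output_dim)
      stop("encoder returned dimension ", ncol(emb),
           " but contract promises ", encoder$output_dim, call. = FALSE)
    rows[[b]] <- emb
  }
  feature_bag(slide_id = tileset$slide_id,
              features = do.call(rbind, rows),
              coords = tileset$coords, label = label)
}

#' Write / read a per-slide feature bag archive
#'
#' Each bag is stored as a directory named after the slide with three
#' plain files: `features.tsv` (K x D matrix, full precision),
#' `coords.tsv` (K x 2), and `meta.json` (`slide_id`, `label`, `dim`,
#' schema version). The layout round-trips losslessly.
#'
#' @param bag A [feature_bag()].
#' @param dir Parent directory of per-slide archives.
#' @return `write_bag` the bag directory, invisibly; `read_bag` the
#'   `feature_bag`; `read_bag_dir` a `bag_dataset` list of all bags
#'   under `dir`.
#' @export
write_bag <- function(bag, dir) {
  out <- file.path(dir, bag$slide_id)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # %.17g round-trips IEEE doubles exactly through text
  feat_txt <- data.table::as.data.table(
    matrix(sprintf("%.17g", bag$features), nrow = nrow(bag$features)))
  data.table::fwrite(feat_txt, file.path(out, "features.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(bag$coords),
                     file.path(out, "coords.tsv"), sep = "\t")
  jsonlite::write_json(list(schema = 1L, slide_id = bag$slide_id,
                            label = bag$label, dim = ncol(bag$features)),
                       file.path(out, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out)
}

#' @rdname write_bag
#' @export
read_bag <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  feats <- as.matrix(data.table::fread(file.path(dir, "features.tsv")))
  dimnames(feats) <- NULL
  if (ncol(feats) != meta$dim)
    stop("archive schema error: feature dimension ", ncol(feats),
         " does not match recorded dim ", meta$dim, call. = FALSE)
  coords <- as.matrix(data.table::fread(file.path(dir, "coords.tsv")))
  colnames(coords) <- c("x", "y")
  label <- if (is.null(meta$label) || is.na(meta$label)) NA_integer_
           else as.integer(meta$label)
  feature_bag(slide_id = meta$slide_id, features = feats,
              coords = coords, label = label)
}

#' @rdname write_bag
#' @export
read_bag_dir <- function(dir) {
  dirs <- list.dirs(dir, recursive = FALSE)
  structure(lapply(dirs, read_bag), class = "bag_dataset")
}
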