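#' Segment slide foreground
#'
#' Separates tissue from bright, unsaturated glass. The image is first
#' downsampled so the working mask plane stays small, then the chroma
#' channel (max minus min over RGB, equal to HSV saturation times
#' value) is median-blurred and Otsu-thresholded; morphological closing
#' fills cracks, holes are filled, and connected components below a
#' minimum area are dropped. Chroma rather than raw HSV saturation is
#' used because it is numerically stable on dark pixels and exactly
#' invariant under color inversion.
#'
#' @param image Height x width x 3 numeric array in `[0, 1]` (row = y),
#'   or a path to a TIFF file.
#' @param max_mask_pixels Working-resolution budget: the image is
#'   downsampled by an integer factor so the mask plane has at most
#'   this many pixels (default 4e6).
#' @param blur_size Median filter radius in working pixels (default 3).
#' @param close_size Diameter of the disc brush for morphological
#'   closing (default 5).
#' @param min_area Minimum connected-component area in working pixels;
#'   smaller specks are removed (default 64).
#' @return List with `mask` (logical matrix at working resolution) and
#'   `downsample` (integer factor relative to the input image).
#' @export
segment_foreground <- function(image, max_mask_pixels = 4e6,
                               blur_size = 3, close_size = 5,
                               min_area = 64) {
  if (is.character(image)) image <- read_slide_image(image)
  if (is.null(dim(image)) || length(dim(image)) != 3L || any(dim(image) == 0))
    stop("unreadable or empty slide image", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  ds <- 1L
  while ((h %/% ds) * (w %/% ds) > max_mask_pixels) ds <- ds * 2L
  if (ds > 1L) {
    image <- image[seq(1, h, by = ds), seq(1, w, by = ds), , drop = FALSE]
  }
  chroma <- pmax(image[, , 1], image[, , 2], image[, , 3]) -
    pmin(image[, , 1], image[, , 2], image[, , 3])
  chroma <- EBImage::medianFilter(chroma, size = blur_size)
  # an (almost) achromatic slide carries no tissue signal: Otsu on pure
  # noise would hallucinate a foreground class
  if (max(chroma) < 0.05) {
    warning("no tissue detected: slide appears to be all background")
    return(list(mask = matrix(FALSE, nrow(chroma), ncol(chroma)),
                downsample = ds))
  }
  thr <- EBImage::otsu(EBImage::Image(chroma), range = c(0, 1))
  mask <- chroma > thr
  brush <- EBImage::makeBrush(close_size, shape = "disc")
  mask <- EBImage::closing(EBImage::Image(mask * 1), brush)
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas >= min_area])
  mask <- matrix(as.vector(lab) %in% keep, nrow = nrow(lab), ncol = ncol(lab))
  if (!any(mask)) warning("no tissue detected: slide appears to be all background")
  list(mask = mask, downsample = ds)
}

#' Tile a slide into fixed-size foreground patches
#'
#' Lays a non-overlapping grid anchored at (0, 0) with stride equal to
#' `patch_size` over the slide and keeps every fully-inside patch whose
#' foreground fraction under `mask` is at least
#' `min_foreground_fraction`. Coordinates are level-0, 0-based top-left
#' corners of half-open boxes, sorted row-major (y, then x).
#'
#' @param slide_dims Integer `c(width, height)` in level-0 pixels.
#' @param mask Logical foreground matrix (row = y) at `downsample`
#'   resolution, or `NULL` to treat the whole slide as foreground.
#' @param patch_size Patch edge length in level-0 pixels (default 256,
#'   minimum 32).
#' @param min_foreground_fraction Retention threshold in `[0, 1]`
#'   (default 0.5); 0 keeps every grid patch.
#' @param downsample Integer factor relating `mask` to level 0.
#' @param slide_id Identifier stored in the tile set.
#' @return Object of class `tile_set`: list with `slide_id`,
#'   `patch_size`, `level`, `downsample`, `coords` (n x 2 matrix of x,
#'   y), `fg_fraction` (per-patch foreground fraction).
#' @export
tile_patches <- function(slide_dims, mask = NULL, patch_size = 256,
                         min_foreground_fraction = 0.5, downsample = 1L,
                         slide_id = "slide") {
  if (patch_size < 32) stop("'patch_size' must be >= 32", call. = FALSE)
  w <- slide_dims[1]; h <- slide_dims[2]
  nx <- w %/% patch_size; ny <- h %/% patch_size
  if (nx < 1 || ny < 1) {
    warning("patch_size larger than slide: empty tile set")
    return(empty_tile_set(slide_id, patch_size, downsample))
  }
  grid <- expand.grid(x = (seq_len(nx) - 1L) * patch_size,
                      y = (seq_len(ny) - 1L) * patch_size)
  # row-major: y varies slowest
  grid <- grid[order(grid$y, grid$x), , drop = FALSE]
  frac <- vapply(seq_len(nrow(grid)), function(i) {
    if (is.null(mask)) return(1)
    x0 <- grid$x[i] %/% downsample; y0 <- grid$y[i] %/% downsample
    ps <- max(1L, patch_size %/% downsample)
    rows <- (y0 + 1L):min(y0 + ps, nrow(mask))
    cols <- (x0 + 1L):min(x0 + ps, ncol(mask))
    mean(mask[rows, cols])
  }, numeric(1))
  keep <- frac >= min_foreground_fraction
  coords <- as.matrix(grid[keep, , drop = FALSE])
  storage.mode(coords) <- "integer"
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(slide_id = slide_id, patch_size = as.integer(patch_size),
                 level = 0L, downsample = as.integer(downsample),
                 coords = coords,
                 fg_fraction = frac[keep]),
            class = "tile_set")
}

empty_tile_set <- function(slide_id, patch_size, downsample) {
  structure(list(slide_id = slide_id, patch_size = as.integer(patch_size),
                 level = 0L, downsample = as.integer(downsample),
                 coords = matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))),
                 fg_fraction = numeric(0)),
            class = "tile_set")
}

#' Write / read a tile set
#'
#' Serialized as a TSV of coordinates plus a JSON sidecar of the tiling
#' parameters; the round trip is lossless.
#'
#' @param tileset A [tile_patches()] result.
#' @param dir Output directory (created if needed).
#' @return `write_tile_set` the directory, invisibly; `read_tile_set`
#'   the `tile_set`.
#' @export
write_tile_set <- function(tileset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dt <- data.table::data.table(x = tileset$coords[, 1],
                               y = tileset$coords[, 2],
                               fg_fraction = tileset$fg_fraction)
  data.table::fwrite(dt, file.path(dir, "coords.tsv"), sep = "\t")
  jsonlite::write_json(tileset[c("slide_id", "patch_size", "level",
                                 "downsample")],
                       file.path(dir, "tileset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_tile_set
#' @export
read_tile_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "tileset.json"),
                              simplifyVector = TRUE)
  dt <- data.table::fread(file.path(dir, "coords.tsv"))
  coords <- as.matrix(dt[, c("x", "y")])
  storage.mode(coords) <- "integer"
  structure(list(slide_id = meta$slide_id,
                 patch_size = as.integer(meta$patch_size),
                 level = as.integer(meta$level),
                 downsample = as.integer(meta$downsample),
                 coords = coords, fg_fraction = dt$fg_fraction),
            class = "tile_set")
}

#' Read / write a slide image as TIFF
#'
#' Thin reader contract for the toy tiled-RGB-TIFF slides used at desk
#' scale; returns a height x width x 3 array in `[0, 1]`.
#'
#' @param path TIFF file path.
#' @param image Height x width x 3 array in `[0, 1]`.
#' @export
read_slide_image <- function(path) {
  if (!file.exists(path)) stop("cannot read slide image: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_slide_image
#' @export
write_slide_image <- function(image, path) {
  tiff::writeTIFF(image, path)
  invisible(path)
}

#' Read one patch from a slide image
#'
#' @param image Slide array (row = y).
#' @param x,y 0-based top-left corner at level 0.
#' @param patch_size Patch edge length.
#' @return `patch_size` x `patch_size` x 3 array.
#' @export
read_patch <- function(image, x, y, patch_size) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (x < 0 || y < 0 || x + patch_size > w || y + patch_size > h)
    stop(sprintf("patch read failure at coordinate (%d, %d)", x, y),
         call. = FALSE)
  image[(y + 1L):(y + patch_size), (x + 1L):(x + patch_size), , drop = FALSE]
}
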