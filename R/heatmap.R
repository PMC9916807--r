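#' Heatmap rendering specification
#'
#' @param class_index Attention branch to visualize (1-based; default
#'   2, the positive branch in the binary model).
#' @param colormap Name of the diverging colormap; `"blue_red"`
#'   (default) renders weakly attended patches blue and strongly
#'   attended patches red.
#' @param alpha_blend Overlay opacity in `[0, 1]` (default 0.6).
#' @param downsample Integer rendering scale (default 1).
#' @return Object of class `heatmap_spec`.
#' @export
heatmap_spec <- function(class_index = 2L, colormap = "blue_red",
                         alpha_blend = 0.6, downsample = 1L) {
  if (alpha_blend < 0 || alpha_blend > 1)
    stop("'alpha_blend' must lie in [0, 1]", call. = FALSE)
  structure(list(class_index = as.integer(class_index),
                 colormap = colormap, alpha_blend = alpha_blend,
                 downsample = as.integer(downsample)),
            class = "heatmap_spec")
}

#' Render an attention heatmap
#'
#' Attention scores are min-max normalized to `[0, 1]` across the
#' slide (rank-preserving), mapped through a diverging colormap, and
#' painted over each patch footprint; regions outside the tile set are
#' left untouched. If the attention is constant the normalization is
#' degenerate and every patch is mapped to 0.5 with a warning.
#'
#' @param slide Slide array (row = y) to blend over, or integer
#'   `c(width, height)` dims for a blank white canvas.
#' @param tileset A [tile_patches()] result.
#' @param attention_row Raw attention scores, one per tile.
#' @param spec A [heatmap_spec()].
#' @return List with `image` (RGB array at `dims / downsample`) and
#'   `scores` (data frame of `x`, `y`, `raw`, `normalized`).
#' @export
render_heatmap <- function(slide, tileset, attention_row,
                           spec = heatmap_spec()) {
  k <- nrow(tileset$coords)
  if (length(attention_row) != k)
    stop("attention length ", length(attention_row),
         " does not match tile count ", k, call. = FALSE)
  if (is.null(dim(slide))) {
    w <- slide[1]; h <- slide[2]
    canvas <- array(1, dim = c(h %/% spec$downsample,
                               w %/% spec$downsample, 3))
  } else {
    h <- dim(slide)[1]; w <- dim(slide)[2]
    sel_r <- seq(1, h, by = spec$downsample)
    sel_c <- seq(1, w, by = spec$downsample)
    canvas <- slide[sel_r, sel_c, , drop = FALSE]
    w <- dim(slide)[2]; h <- dim(slide)[1]
  }
  rng <- range(attention_row)
  if (diff(rng) == 0) {
    warning("constant attention: degenerate normalization, all patches at 0.5")
    norm <- rep(0.5, k)
  } else {
    norm <- (attention_row - rng[1]) / diff(rng)
  }
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  ps <- max(1L, tileset$patch_size %/% spec$downsample)
  for (i in seq_len(k)) {
    col <- ramp(norm[i])[1, ] / 255
    x0 <- tileset$coords[i, 1] %/% spec$downsample
    y0 <- tileset$coords[i, 2] %/% spec$downsample
    rows <- (y0 + 1L):min(y0 + ps, dim(canvas)[1])
    cols <- (x0 + 1L):min(x0 + ps, dim(canvas)[2])
    for (ch in 1:3)
      canvas[rows, cols, ch] <- (1 - spec$alpha_blend) * canvas[rows, cols, ch] +
        spec$alpha_blend * col[ch]
  }
  list(image = canvas,
       scores = data.frame(x = tileset$coords[, 1], y = tileset$coords[, 2],
                           raw = attention_row, normalized = norm))
}

#' Write a rendered heatmap to disk
#'
#' PNG overlay plus a CSV of raw and normalized per-patch scores.
#'
#' @param hm A [render_heatmap()] result.
#' @param png_path Output PNG path.
#' @param csv_path Optional CSV path (defaults next to the PNG).
#' @export
write_heatmap <- function(hm, png_path,
                          csv_path = sub("\\.png$", ".csv", png_path)) {
  png::writePNG(hm$image, png_path)
  utils::write.csv(hm$scores, csv_path, row.names = FALSE)
  invisible(png_path)
}
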