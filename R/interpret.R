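#' Convert attention scores to percentages
#'
#' Applies a softmax to raw attention scores (or logits) and scales to
#' percentages, so the K values are nonnegative and sum to 100.
#'
#' @param scores Numeric vector of K raw attention scores.
#' @param coords Optional K x 2 patch coordinates carried along.
#' @param head_id Optional head label.
#' @return An object of class `attention_map`: list with `percentages`
#'   (summing to 100), `coords`, `head_id`.
#' @export
attention_percentages <- function(scores, coords = NULL, head_id = 1L) {
  if (length(scores) == 0L) stop("empty attention scores")
  if (!all(is.finite(scores))) stop("scores must be finite")
  pct <- softmax(scores) * 100
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != length(scores)) stop("coords must align with scores")
  }
  structure(list(percentages = pct, coords = coords,
                 head_id = head_id),
            class = "attention_map")
}

#' Cool-to-warm colormap
#'
#' Monotone blue -> white -> red ramp used for attention heatmaps.
#'
#' @param values Numeric values in `[0, 1]`.
#' @return n x 3 matrix of RGB values in `[0, 1]`.
#' @export
cool_warm <- function(values) {
  stopifnot(all(values >= 0 & values <= 1))
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  ramp(values) / 255
}

#' Render an attention heatmap over a slide footprint
#'
#' Paints each patch footprint with the cool-to-warm colormap value at
#' its min-max-normalized attention percentage; untiled background stays
#' neutral grey.  Output dimensions are the slide dimensions divided by
#' `downsample`.  Optionally alpha-blends the map over a slide thumbnail.
#'
#' @param map An [attention_map] with patch `coords`.
#' @param slide_dim Integer `c(height, width)` of the level-0 slide.
#' @param patch_size Patch edge length in level-0 pixels.
#' @param downsample Integer downsample factor (default 16).
#' @param image Optional level-0 H x W x 3 slide image to blend under
#'   the map.
#' @param alpha Blend weight of the heatmap over the image
#'   (default 0.5).
#' @return H/downsample x W/downsample x 3 RGB array in `[0, 1]`.
#' @export
render_heatmap <- function(map, slide_dim, patch_size = 256L,
                           downsample = 16L, image = NULL, alpha = 0.5) {
  stopifnot(inherits(map, "attention_map"))
  if (is.null(map$coords)) stop("attention map carries no coordinates")
  h <- as.integer(slide_dim[1] %/% downsample)
  w <- as.integer(slide_dim[2] %/% downsample)
  co <- map$coords
  bad <- which(co[, 1] < 0 | co[, 2] < 0 |
                 co[, 1] + patch_size > slide_dim[2] |
                 co[, 2] + patch_size > slide_dim[1])
  if (length(bad) > 0) {
    stop("patch coords outside slide bounds at rows: ",
         paste(bad, collapse = ", "))
  }
  pct <- map$percentages
  rng <- range(pct)
  norm <- if (diff(rng) == 0) rep(0.5, length(pct)) else
    (pct - rng[1]) / diff(rng)
  cols <- cool_warm(norm)
  out <- array(0.85, dim = c(h, w, 3))        # neutral background
  pm <- max(1L, as.integer(patch_size %/% downsample))
  for (k in seq_len(nrow(co))) {
    x0 <- as.integer(co[k, 1] %/% downsample)
    y0 <- as.integer(co[k, 2] %/% downsample)
    rows <- (y0 + 1L):min(y0 + pm, h)
    colsr <- (x0 + 1L):min(x0 + pm, w)
    for (ch in 1:3) out[rows, colsr, ch] <- cols[k, ch]
  }
  if (!is.null(image)) {
    thumb <- thumbnail(image, h, w)
    out <- alpha * out + (1 - alpha) * thumb
  }
  out
}

# nearest-neighbour thumbnail of an RGB array
thumbnail <- function(image, h, w) {
  H <- dim(image)[1]; W <- dim(image)[2]
  ri <- pmin(H, ceiling(seq_len(h) * H / h))
  ci <- pmin(W, ceiling(seq_len(w) * W / w))
  image[ri, ci, , drop = FALSE]
}

#' Write an RGB array to PNG
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  storage.mode(image) <- "double"
  png::writePNG(image, target = path)
  invisible(path)
}

#' Read a PNG image as an RGB array
#'
#' Greyscale and RGBA inputs are expanded/truncated to 3 channels.
#'
#' @param path PNG path.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
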