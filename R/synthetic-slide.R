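#' Render a synthetic tissue slide with ground-truth mask
#'
#' Draws `n_blobs` non-overlapping saturated elliptical "tissue" regions
#' on a uniform near-white background and returns the image together
#' with the exact foreground mask and the ellipse parameters used.
#' Serves as a fixture with known truth for tissue segmentation.
#'
#' @param width,height Image dimensions in pixels (each `>= 64`).
#' @param n_blobs Number of elliptical tissue regions (`>= 0`).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_slide`: list with `image`
#'   (H x W x 3 array, 8-bit quantized values in `[0, 1]`), `tissue_mask`
#'   (H x W 0/1 matrix, 1 exactly on rendered tissue pixels) and
#'   `blob_params` (data frame of centers, semi-axes, rotation).
#' @examples
#' s <- generate_tissue_image(128, 128, n_blobs = 2, seed = 3)
#' sum(s$tissue_mask)
#' @export
generate_tissue_image <- function(width, height, n_blobs = 3L, seed = 1L) {
  if (width < 64 || height < 64) stop("width and height must be >= 64")
  if (n_blobs < 0) stop("n_blobs must be >= 0")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  bg <- c(0.94, 0.94, 0.94)           # uniform near-white, saturation 0
  img <- array(rep(bg, each = height * width), dim = c(height, width, 3))
  mask <- matrix(0L, height, width)
  params <- data.frame(cx = numeric(0), cy = numeric(0), rx = numeric(0),
                       ry = numeric(0), angle = numeric(0))
  if (n_blobs > 0) {
    rmax <- min(width, height) / 6
    rmin <- min(width, height) / 14
    placed <- 0L; attempts <- 0L
    while (placed < n_blobs && attempts < 2000L) {
      attempts <- attempts + 1L
      rx <- stats::runif(1, rmin, rmax)
      ry <- stats::runif(1, rmin, rmax)
      ang <- stats::runif(1, 0, pi)
      rr <- max(rx, ry)
      cx <- stats::runif(1, rr + 2, width - rr - 2)
      cy <- stats::runif(1, rr + 2, height - rr - 2)
      # keep blobs disjoint so the analytic area is exact
      if (nrow(params) > 0) {
        dd <- sqrt((params$cx - cx)^2 + (params$cy - cy)^2)
        if (any(dd < pmax(params$rx, params$ry) + rr + 3)) next
      }
      params <- rbind(params, data.frame(cx = cx, cy = cy, rx = rx,
                                         ry = ry, angle = ang))
      placed <- placed + 1L
    }
    if (placed < n_blobs) {
      warning("could only place ", placed, " of ", n_blobs,
              " non-overlapping blobs")
    }
    # rasterize: pixel centers at (col - 0.5, row - 0.5)
    xs <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
    ys <- matrix(rep(seq_len(height) - 0.5, width), height, width)
    for (b in seq_len(nrow(params))) {
      ca <- cos(params$angle[b]); sa <- sin(params$angle[b])
      dx <- xs - params$cx[b]; dy <- ys - params$cy[b]
      xr <- ca * dx + sa * dy
      yr <- -sa * dx + ca * dy
      inside <- (xr / params$rx[b])^2 + (yr / params$ry[b])^2 <= 1
      mask[inside] <- 1L
      # saturated pink-magenta tissue tint, slight per-blob variation
      col <- c(0.78 + 0.1 * stats::runif(1), 0.25 + 0.1 * stats::runif(1),
               0.55 + 0.1 * stats::runif(1))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inside] <- col[ch]
        img[, , ch] <- plane
      }
    }
  }
  img <- round(img * 255) / 255   # 8-bit quantization
  out <- list(image = img, tissue_mask = mask, blob_params = params)
  class(out) <- "synthetic_slide"
  out
}

#' Analytic total area of a slide's ellipses
#'
#' @param slide A `synthetic_slide`.
#' @return Sum of `pi * rx * ry` over the slide's (disjoint) ellipses.
#' @export
blob_area <- function(slide) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (nrow(slide$blob_params) == 0) return(0)
  sum(pi * slide$blob_params$rx * slide$blob_params$ry)
}
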