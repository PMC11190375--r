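#' Patch-feature bag for one slide
#'
#' The multiple-instance unit of computation: K instance-feature vectors
#' extracted from a slide's tissue patches, aligned with the patch
#' coordinates they came from.
#'
#' @param slide_id Slide identifier.
#' @param features K x D numeric matrix, one row per patch.
#' @param coords K x 2 integer matrix of level-0 top-left patch corners.
#' @param extractor_id Identifier of the feature extractor that produced
#'   the rows.
#' @param patch_size Patch edge length in level-0 pixels (default 256).
#' @return An object of class `patch_bag`.
#' @export
patch_bag <- function(slide_id, features, coords,
                      extractor_id = "unknown", patch_size = 256L) {
  features <- as.matrix(features)
  coords <- as.matrix(coords)
  if (nrow(features) < 1L) stop("a bag needs at least one instance")
  if (nrow(coords) != nrow(features)) {
    stop("coords rows must align with feature rows")
  }
  if (ncol(coords) != 2L) stop("coords must be K x 2")
  if (!all(is.finite(features))) stop("features must be finite")
  out <- list(slide_id = as.character(slide_id), features = features,
              coords = coords, extractor_id = as.character(extractor_id),
              patch_size = as.integer(patch_size))
  class(out) <- "patch_bag"
  out
}

#' @export
print.patch_bag <- function(x, ...) {
  cat(sprintf("Patch bag '%s': %d instances x %d features (extractor: %s)\n",
              x$slide_id, nrow(x$features), ncol(x$features),
              x$extractor_id))
  invisible(x)
}

#' Combine several bags into one patient-level bag
#'
#' Patients with multiple slides are pooled by concatenating their bags'
#' instances before attention pooling.
#'
#' @param bags List of `patch_bag`s with a common feature dimension.
#' @param slide_id Identifier for the combined bag.
#' @return A single `patch_bag`.
#' @export
combine_bags <- function(bags, slide_id = "combined") {
  stopifnot(length(bags) >= 1L)
  dims <- vapply(bags, function(b) ncol(b$features), integer(1))
  if (length(unique(dims)) != 1L) stop("bags differ in feature dimension")
  patch_bag(slide_id,
            do.call(rbind, lapply(bags, `[[`, "features")),
            do.call(rbind, lapply(bags, `[[`, "coords")),
            extractor_id = bags[[1]]$extractor_id,
            patch_size = bags[[1]]$patch_size)
}

# ---- feature extractor contract ---------------------------------------

#' Define a patch-feature extractor
#'
#' An extractor maps one `P x P x 3` RGB patch to a fixed-length numeric
#' vector.  The default dimension contract is 1024, matching features
#' taken from an earlier convolution stage of ResNet50 with global
#' average pooling; any callable honouring the contract can be plugged
#' in.
#'
#' @param fn Function of one patch (H x W x 3 array in `[0, 1]`)
#'   returning a numeric vector of length `dim`.
#' @param dim Advertised output dimension.
#' @param id Extractor identifier recorded in bags.
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(fn, dim, id) {
  stopifnot(is.function(fn), dim >= 1)
  structure(list(fn = fn, dim = as.integer(dim), id = as.character(id)),
            class = "feature_extractor")
}

#' Deterministic stub patch-feature extractor
#'
#' Hashes the patch's 8-bit pixel bytes into an RNG seed and emits a
#' standard-normal vector from that seed, so identical patches always
#' map to identical features and distinct patches map to effectively
#' independent ones.  Used throughout the test stack in place of a
#' pretrained convolutional backbone.
#'
#' @param dim Output dimension (default 1024).
#' @return A [feature_extractor].
#' @export
stub_extractor <- function(dim = 1024L) {
  dim <- as.integer(dim)
  fn <- function(patch) {
    bytes <- as.integer(round(as.numeric(patch) * 255))
    # polynomial rolling hash mod a prime below 2^31
    h <- 0
    mod <- 2147483629
    mult <- 31
    # chunked Horner scheme keeps this O(n) without bignum
    for (start in seq(1, length(bytes), by = 4096)) {
      chunk <- bytes[start:min(start + 4095, length(bytes))]
      h <- (h * 97 + sum((chunk + 1) * (seq_along(chunk) %% 251 + 1))) %% mod
    }
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(h))
    stats::rnorm(dim)
  }
  feature_extractor(fn, dim, sprintf("stub-%d", dim))
}

# ---- tissue segmentation ----------------------------------------------

#' Segment tissue from a slide image by HSV saturation
#'
#' Foreground is the set of pixels whose HSV saturation exceeds
#' `saturation_threshold` after median filtering; the binary mask is
#' then morphologically closed and connected components smaller than
#' `min_area` pixels are dropped.  Contours are traced from the final
#' mask.  A fully background image yields an empty mask.
#'
#' @param image H x W x 3 RGB array with values in `[0, 1]`.
#' @param saturation_threshold Saturation cut in `[0, 1]`
#'   (default `8/255`).
#' @param median_kernel Median filter window width in pixels (odd;
#'   default 7).
#' @param close_kernel Morphological closing kernel size (default 4).
#' @param min_area Minimum connected-component area in pixels
#'   (default 512).
#' @param downsample_factor Downsample of this raster relative to the
#'   level-0 slide (default 1).
#' @return An object of class `tissue_mask`: list with `mask`
#'   (H x W 0/1 matrix), `downsample_factor`, and `contours` (list of
#'   n x 2 matrices of (x, y) boundary coordinates, 0-based).
#' @export
segment_tissue <- function(image, saturation_threshold = 8 / 255,
                           median_kernel = 7L, close_kernel = 4L,
                           min_area = 512L, downsample_factor = 1) {
  if (is.null(dim(image)) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 RGB array")
  }
  if (any(dim(image)[1:2] == 0)) stop("empty image")
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)

  # EBImage uses x (width) as the first dimension: transpose in and out
  sat_img <- EBImage::Image(t(sat))
  radius <- max(1L, as.integer(median_kernel) %/% 2L)
  sat_f <- EBImage::medianFilter(sat_img, size = radius)
  bin <- sat_f > saturation_threshold

  brush_size <- as.integer(close_kernel)
  if (brush_size %% 2L == 0L) brush_size <- brush_size + 1L
  kern <- EBImage::makeBrush(max(3L, brush_size), shape = "disc")
  closed <- EBImage::closing(bin, kern)

  lab <- EBImage::bwlabel(closed)
  keep <- lab
  if (max(lab) > 0) {
    areas <- tabulate(as.integer(EBImage::imageData(lab)))
    drop <- which(areas < min_area)
    if (length(drop) > 0) {
      dat <- EBImage::imageData(keep)
      dat[dat %in% drop] <- 0L
      EBImage::imageData(keep) <- dat
    }
  }
  final <- EBImage::imageData(keep) > 0
  contours <- if (any(final)) {
    lapply(EBImage::ocontour(EBImage::bwlabel(EBImage::Image(final * 1))),
           function(m) { colnames(m) <- c("x", "y"); m })
  } else list()

  out <- list(mask = t(final) * 1L, downsample_factor = downsample_factor,
              contours = contours)
  class(out) <- "tissue_mask"
  out
}

#' Render a tissue mask as an RGB image
#'
#' Foreground pixels become a saturated tissue colour, background a
#' uniform near-white; convenient for round-trip checks of the
#' segmenter.
#'
#' @param mask H x W 0/1 matrix.
#' @return H x W x 3 RGB array in `[0, 1]`.
#' @export
mask_to_image <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0.94, dim = c(h, w, 3))
  col <- c(0.8, 0.3, 0.55)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask > 0] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Binary matrices of identical dimension.
#' @return IoU in `[0, 1]` (1 when both are empty).
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# ---- grid tiling ------------------------------------------------------

#' Tile a tissue mask into a grid of candidate patches
#'
#' Scans the level-0 grid of `patch_size`-aligned, fully contained
#' patches and keeps those whose tissue fraction (mask pixels inside the
#' patch footprint over the patch area) reaches `min_tissue_fraction`.
#' Coordinates are 0-based top-left corners, half-open
#' `[x, x + P) x [y, y + P)`, emitted in row-major order (x fastest).
#'
#' @param mask A [tissue_mask] (or plain 0/1 matrix at downsample 1).
#' @param patch_size Patch edge length in level-0 pixels (default 256).
#' @param min_tissue_fraction Inclusion threshold in `[0, 1]`
#'   (default 0.5).
#' @return An object of class `patch_grid`: list with `coords`
#'   (n x 2 integer matrix, columns `x`, `y`), `tissue_fraction`,
#'   `patch_size`.
#' @export
tile_grid <- function(mask, patch_size = 256L, min_tissue_fraction = 0.5) {
  if (inherits(mask, "tissue_mask")) {
    ds <- mask$downsample_factor
    m <- mask$mask
  } else {
    ds <- 1
    m <- mask
  }
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) stop("patch_size must be >= 1")
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1) {
    stop("min_tissue_fraction must lie in [0, 1]")
  }
  pm <- patch_size / ds             # patch edge in mask pixels
  if (pm != round(pm)) stop("patch_size must be a multiple of the downsample")
  pm <- as.integer(pm)
  h <- nrow(m); w <- ncol(m)
  nx <- w %/% pm; ny <- h %/% pm
  xs <- integer(0); ys <- integer(0); fr <- numeric(0)
  for (iy in seq_len(ny)) {          # row-major: y outer, x inner
    rows <- ((iy - 1L) * pm + 1L):(iy * pm)
    for (ix in seq_len(nx)) {
      cols <- ((ix - 1L) * pm + 1L):(ix * pm)
      f <- sum(m[rows, cols] > 0) / (pm * pm)
      if (f >= min_tissue_fraction) {
        xs <- c(xs, (ix - 1L) * patch_size)
        ys <- c(ys, (iy - 1L) * patch_size)
        fr <- c(fr, f)
      }
    }
  }
  out <- list(coords = cbind(x = xs, y = ys), tissue_fraction = fr,
              patch_size = patch_size)
  class(out) <- "patch_grid"
  out
}

# ---- bag assembly -----------------------------------------------------

#' Extract a patch-feature bag from a slide image
#'
#' Applies a [feature_extractor] independently to each patch of a
#' [tile_grid] result, preserving grid order, and assembles the rows
#' into a [patch_bag].
#'
#' @param image H x W x 3 RGB array (level-0 pixels).
#' @param grid A `patch_grid` over the image.
#' @param extractor A [feature_extractor] (default [stub_extractor]).
#' @param slide_id Identifier stored in the bag.
#' @return A [patch_bag] with one row per grid patch.
#' @export
extract_features <- function(image, grid, extractor = stub_extractor(),
                             slide_id = "slide") {
  stopifnot(inherits(grid, "patch_grid"),
            inherits(extractor, "feature_extractor"))
  K <- nrow(grid$coords)
  if (K == 0L) stop("grid is empty")
  P <- grid$patch_size
  feats <- matrix(NA_real_, K, extractor$dim)
  for (k in seq_len(K)) {
    x0 <- grid$coords[k, 1]; y0 <- grid$coords[k, 2]
    patch <- image[(y0 + 1L):(y0 + P), (x0 + 1L):(x0 + P), , drop = FALSE]
    v <- extractor$fn(patch)
    if (length(v) != extractor$dim) {
      stop(sprintf("extractor returned length %d for patch %d, expected %d",
                   length(v), k, extractor$dim))
    }
    feats[k, ] <- v
  }
  patch_bag(slide_id, feats, grid$coords,
            extractor_id = extractor$id, patch_size = P)
}
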