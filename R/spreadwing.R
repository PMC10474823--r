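#' Wing image and binary mask containers
#'
#' A `wing_image` is a grayscale raster (numeric matrix, conventionally
#' 0-255, row 1 = top of the image) with a spatial calibration in pixels
#' per cm. A `binary_mask` is the logical raster produced by segmentation,
#' carrying the same calibration.
#'
#' @param pixels Numeric matrix of intensities (`wing_image`) or logical
#'   matrix (`binary_mask`).
#' @param scale Pixels per cm; must be positive.
#' @return An object of class `wing_image` or `binary_mask`.
#' @export
wing_image <- function(pixels, scale) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  }
  check_positive(scale = scale, .what = "scale")
  structure(list(pixels = pixels, scale = scale), class = "wing_image")
}

#' @rdname wing_image
#' @export
binary_mask <- function(pixels, scale) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  check_positive(scale = scale, .what = "scale")
  structure(list(pixels = pixels > 0, scale = scale), class = "binary_mask")
}

#' @export
print.wing_image <- function(x, ...) {
  cat("<wing_image> ", nrow(x$pixels), "x", ncol(x$pixels), " px @ ",
      x$scale, " px/cm\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", nrow(x$pixels), "x", ncol(x$pixels), " px @ ",
      x$scale, " px/cm, ", sum(x$pixels), " foreground px\n", sep = "")
  invisible(x)
}

#' Read a grayscale wing photograph
#'
#' Reads a PNG or TIFF image, collapses any color channels to their mean,
#' and rescales intensities to 0-255.
#'
#' @param path Image file (`.png`, `.tif`, `.tiff`).
#' @param scale Pixels per cm, from the ruler in the image.
#' @return A [wing_image()].
#' @export
read_wing_image <- function(path, scale) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("package 'png' is required to read PNG images", call. = FALSE)
      }
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("package 'tiff' is required to read TIFF images", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:min(3, dim(px)[3])], c(1, 2), mean)
  wing_image(px * 255, scale = scale)
}

#' Threshold a wing image into a binary mask
#'
#' Segments the (dark) wing from the (light) background. Pixels strictly
#' below the threshold become foreground; `threshold = "auto"` selects the
#' cut by Otsu's between-class variance criterion, a deterministic stand-in
#' for interactive thresholding.
#'
#' @param image A [wing_image()].
#' @param threshold Intensity cut on the image's own scale, or `"auto"`.
#' @param dark_object If `TRUE` (default) the wing is darker than the
#'   background; set `FALSE` for light-on-dark images.
#' @return A [binary_mask()]. A mask that is entirely foreground or
#'   entirely background triggers a degenerate-segmentation warning.
#' @export
binarize <- function(image, threshold = "auto", dark_object = TRUE) {
  stopifnot(inherits(image, "wing_image"))
  px <- image$pixels
  if (identical(threshold, "auto") || identical(threshold, "AUTO")) {
    rng <- range(px)
    if (diff(rng) == 0) {
      threshold <- rng[1]  # flat image: everything on one side
    } else {
      norm <- (px - rng[1]) / diff(rng)
      threshold <- rng[1] +
        EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng)
    }
  }
  mask <- if (dark_object) px < threshold else px > threshold
  if (all(mask) || !any(mask)) {
    warning("degenerate segmentation: mask is entirely ",
            if (all(mask)) "foreground" else "background", call. = FALSE)
  }
  out <- binary_mask(mask, scale = image$scale)
  attr(out, "threshold") <- threshold
  out
}

#' Fill enclosed holes in a binary mask
#'
#' Background regions not connected to the raster border become foreground;
#' border-connected background is untouched. Foreground uses 4-connectivity
#' and background 8-connectivity (the standard complementary pair), so
#' diagonal pixel chains cannot leak a hole to the border.
#'
#' @param mask A [binary_mask()].
#' @return A [binary_mask()] with holes filled; never removes foreground.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  filled <- EBImage::fillHull(EBImage::Image(mask$pixels * 1))
  binary_mask(EBImage::imageData(filled) > 0, scale = mask$scale)
}

#' Area of the largest connected foreground component
#'
#' Labels 4-connected foreground components and returns the pixel count of
#' the largest one divided by `scale^2`, i.e. the wing area in cm^2 (small
#' disconnected specks are ignored, as when selecting the particle of
#' interest).
#'
#' @param mask A [binary_mask()].
#' @return Area in cm^2.
#' @export
largest_component_area <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$pixels)) {
    stop("no object: mask has no foreground pixels", call. = FALSE)
  }
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask$pixels * 1)))
  max(tabulate(labels[labels > 0])) / mask$scale^2
}

#' Total wing area from a spread-wing measurement
#'
#' Reconstructs the area of both wings plus the intervening body from a
#' single spread wing: `2 * wing_area + root_chord * (wingspan - 2 * extent)`.
#' The second term is the root box between the two wing roots.
#'
#' @param wing_area Projected area of the single spread wing, cm^2.
#' @param root_chord Chord at the wing root (body junction), cm.
#' @param wingspan Wingtip-to-wingtip span, cm.
#' @param extent Wing extent: wingtip to root chord distance, cm.
#' @param policy `"strict"` errors when `wingspan < 2 * extent`;
#'   `"clamp"` zeroes the root box instead.
#' @return Total wing area in cm^2.
#' @examples
#' total_area_spread(100, root_chord = 10, wingspan = 60, extent = 25) # 300
#' @export
total_area_spread <- function(wing_area, root_chord, wingspan, extent,
                              policy = c("strict", "clamp")) {
  policy <- match.arg(policy)
  check_positive(wing_area = wing_area, wingspan = wingspan,
                 extent = extent)
  if (!is.numeric(root_chord) || any(!is.finite(root_chord)) ||
      any(root_chord < 0)) {
    stop("invalid measurement: `root_chord` must be non-negative",
         call. = FALSE)
  }
  width <- wingspan - 2 * extent
  if (any(width < 0)) {
    if (policy == "strict") {
      stop("geometry violation: wingspan < 2 * wing extent; ",
           "use policy = \"clamp\" to zero the root box", call. = FALSE)
    }
    width[width < 0] <- 0
  }
  2 * wing_area + root_chord * width
}

#' Spread-wing workflow: image to total wing area
#'
#' Convenience wrapper running the full traditional pipeline:
#' threshold, fill holes, measure the largest particle, and reconstruct the
#' total area from the root chord, wingspan, and wing extent.
#'
#' @inheritParams binarize
#' @inheritParams total_area_spread
#' @param mask_overlay Optional externally edited [binary_mask()] used in
#'   place of the automatic segmentation (e.g. manual feather repairs).
#' @return A list with `single_wing_area`, `total_area` (cm^2), the
#'   `mask` used, and the resolved `threshold`.
#' @export
measure_spread_wing <- function(image, root_chord, wingspan, extent,
                                threshold = "auto", dark_object = TRUE,
                                mask_overlay = NULL,
                                policy = c("strict", "clamp")) {
  policy <- match.arg(policy)
  if (is.null(mask_overlay)) {
    raw <- binarize(image, threshold, dark_object)
    mask <- fill_holes(raw)
    thr <- attr(raw, "threshold")
  } else {
    stopifnot(inherits(mask_overlay, "binary_mask"))
    mask <- mask_overlay
    thr <- NA_real_
  }
  a <- largest_component_area(mask)
  list(single_wing_area = a,
       total_area = total_area_spread(a, root_chord, wingspan, extent,
                                      policy = policy),
       mask = mask, threshold = thr)
}
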