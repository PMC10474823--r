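#' Shoelace area of a simple closed polygon
#'
#' Gauss's shoelace formula, `|sum(x_i * y_{i+1} - x_{i+1} * y_i)| / 2`.
#' The polygon need not repeat its first vertex.
#'
#' @param x,y Vertex coordinates in order around the boundary.
#' @return Enclosed area (same squared units as the coordinates).
#' @export
polygon_area <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  j <- c(seq_along(x)[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

planform_height <- function(xs, WL, S1, WS, f) {
  x0 <- WS / 2 - WL
  h <- rep(S1, length(xs))
  outside <- abs(xs) > WS / 2
  hand <- abs(xs) > x0 & !outside
  u <- (abs(xs[hand]) - x0) / WL
  h[hand] <- S1 * (f * sqrt(pmax(0, 1 - u^2)) + (1 - f) * (1 - u))
  h[outside] <- 0
  h
}

#' Synthetic wing planform with exact reference areas
#'
#' Builds a parametric full-planform outline: a straight leading edge, a
#' medial rectangle of width `WS - 2*WL` and height `S1`, and two mirrored
#' hand-wings, each a quarter-ellipse occupying the fraction `f` of `S1`
#' stacked on a right triangle occupying the remainder (curvature on the
#' trailing edge). Closed-form component areas are attached, so the object
#' doubles as a ground-truth oracle for both the folded-wing estimators
#' and the raster pipeline.
#'
#' @param WL Hand-wing extent (cm).
#' @param S1 Wing width (cm).
#' @param WS Wingspan (cm); requires `WS >= 2 * WL`.
#' @param f Ellipse fraction in `[0, 1]`.
#' @param n_vertices Number of outline vertices (ellipse arcs are sampled
#'   in angle, so the shoelace area converges quadratically).
#' @return A list of class `synthetic_planform`: `WL`, `S1`, `WS`, `f`,
#'   `outline` (two-column matrix), `true_total_area`, `true_hand_area`,
#'   `true_box_area` (cm^2).
#' @examples
#' p <- make_planform(WL = 10, S1 = 5, WS = 40, f = 1)
#' p$true_total_area  # pi/2 * 50 + 100
#' @export
make_planform <- function(WL, S1, WS, f, n_vertices = 2048L) {
  WL <- unname(WL); S1 <- unname(S1); WS <- unname(WS); f <- unname(f)
  check_positive(WL = WL, S1 = S1, WS = WS)
  if (WS < 2 * WL) {
    stop("invalid geometry: wingspan must be >= 2 * wing length",
         call. = FALSE)
  }
  if (f < 0 || f > 1) stop("f must be in [0, 1]", call. = FALSE)
  x0 <- WS / 2 - WL
  m <- max(8L, as.integer(n_vertices / 2))  # vertices per hand curve
  theta <- seq(0, pi / 2, length.out = m)
  # right-wing trailing edge, tip (theta = 0) to wing root (theta = pi/2)
  xr <- x0 + WL * cos(theta)
  yr <- S1 * (f * sin(theta) + (1 - f) * (1 - cos(theta)))
  outline <- rbind(
    cbind(c(-WS / 2, WS / 2), c(0, 0)),     # leading edge
    cbind(xr, yr),                          # right hand trailing edge
    cbind(-rev(xr), rev(yr))                # mirrored left hand
  )
  hand <- WL * S1 * (f * pi / 2 + (1 - f))
  box <- (WS - 2 * WL) * S1
  structure(list(WL = WL, S1 = S1, WS = WS, f = f, outline = outline,
                 true_total_area = hand + box, true_hand_area = hand,
                 true_box_area = box),
            class = "synthetic_planform")
}

#' @export
print.synthetic_planform <- function(x, ...) {
  cat("<synthetic_planform> WL =", x$WL, "S1 =", x$S1, "WS =", x$WS,
      "f =", signif(x$f, 4), "| total area", signif(x$true_total_area, 6),
      "cm^2\n")
  invisible(x)
}

#' Rasterize a synthetic planform into an image and reference mask
#'
#' Renders the planform on a pixel grid at a given resolution: a binary
#' stencil (pixel centers strictly inside the shape) and a grayscale
#' photograph-like image (dark wing on a light background, no
#' anti-aliasing). The pixel-count area converges to the true area as the
#' resolution grows, with error on the order of perimeter / `px_per_cm`.
#'
#' @param planform A [make_planform()] object.
#' @param px_per_cm Resolution (pixels per cm).
#' @param xlim Optional horizontal crop in cm, e.g. `c(2, WS/2)` to render
#'   a single spread wing cut at a body half-width of 2 cm.
#' @param fg,bg Grayscale intensities (0-255) of wing and background.
#' @param max_pixels Resource cap on the raster size.
#' @return A list with `image` (a [wing_image()]), `mask` (the reference
#'   [binary_mask()]), and `pixel_area` (mask area in cm^2).
#' @export
rasterize_planform <- function(planform, px_per_cm, xlim = NULL,
                               fg = 40, bg = 230, max_pixels = 4e7) {
  stopifnot(inherits(planform, "synthetic_planform"))
  check_positive(px_per_cm = px_per_cm, .what = "scale")
  if (is.null(xlim)) xlim <- c(-planform$WS / 2, planform$WS / 2)
  margin <- 2 / px_per_cm
  nx <- ceiling((diff(xlim) + 2 * margin) * px_per_cm)
  ny <- ceiling((planform$S1 + 2 * margin) * px_per_cm)
  if (as.double(nx) * ny > max_pixels) {
    stop("raster of ", nx, "x", ny, " px exceeds max_pixels cap",
         call. = FALSE)
  }
  xs <- xlim[1] - margin + (seq_len(nx) - 0.5) / px_per_cm
  ys <- -margin + (seq_len(ny) - 0.5) / px_per_cm
  h <- planform_height(xs, planform$WL, planform$S1, planform$WS,
                       planform$f)
  h[xs < xlim[1] | xs > xlim[2]] <- 0   # crop outside the window
  # mask[i, j]: row i = y (top row = leading edge), col j = x
  inside <- outer(ys, h, function(y, hh) y >= 0 & y <= hh)
  img <- matrix(bg, ny, nx)
  img[inside] <- fg
  list(image = wing_image(img, scale = px_per_cm),
       mask = binary_mask(inside, scale = px_per_cm),
       pixel_area = sum(inside) / px_per_cm^2)
}

#' Spread-wing reference measurements of a synthetic planform
#'
#' The quantities the traditional workflow needs for a single wing cut at
#' a given body half-width: the root chord (equal to `S1` while the cut is
#' inside the medial box), the wing extent (tip to root chord), and the
#' wingspan. With the single-wing area measured from
#' `rasterize_planform(..., xlim = c(body_halfwidth, WS/2))`, the
#' reconstruction `2*a + c*(WS - 2*e)` recovers the planform's exact total
#' area.
#'
#' @param planform A [make_planform()] object.
#' @param body_halfwidth Half-width of the body, cm; must leave the cut
#'   inside the medial box (`body_halfwidth <= WS/2 - WL`).
#' @return A list with `root_chord`, `extent`, `wingspan`, and
#'   `single_wing_true_area` (cm^2).
#' @export
spread_reference <- function(planform, body_halfwidth) {
  stopifnot(inherits(planform, "synthetic_planform"))
  x0 <- planform$WS / 2 - planform$WL
  if (body_halfwidth < 0 || body_halfwidth > x0) {
    stop("body_halfwidth must lie within the medial box [0, ",
         format(x0), "]", call. = FALSE)
  }
  a <- planform$true_hand_area / 2 +
    (x0 - body_halfwidth) * planform$S1
  list(root_chord = planform$S1,
       extent = planform$WS / 2 - body_halfwidth,
       wingspan = planform$WS,
       single_wing_true_area = a)
}

## multiplicative log-normal jitter with unit mean and given CV
lognormal_jitter <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Simulate a paired folded-/spread-wing dataset
#'
#' Generates a cohort of specimens by jittering the base dimensions
#' (`WL`, `S1`, `WS`) with multiplicative log-normal variation of a given
#' coefficient of variation (specimen-to-specimen biological variation),
#' then computes the "spread" value as the exact area of each specimen's
#' planform (fraction `f`) and the "folded" value from the chosen
#' estimator applied to (optionally error-contaminated) linear
#' measurements. With `measurement_cv = 0` and an estimator matching `f`,
#' the two methods agree exactly.
#'
#' @param n Number of specimens (>= 2).
#' @param WL,S1,WS Base dimensions in cm.
#' @param f True planform ellipse fraction.
#' @param model Folded-wing estimator, a [planform_model()] or name.
#' @param specimen_cv Between-specimen CV of each dimension (proportion,
#'   e.g. 0.06).
#' @param measurement_cv Per-measurement error CV applied to the folded
#'   measurements only (proportion).
#' @param quantity `"area"` or `"aspect_ratio"` for the paired values.
#' @param species Species label for the cohort.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list with `pairs` (a [paired_estimates()] table) and `table`
#'   (a morphometric data frame with the folded measurements, in cm).
#' @export
make_paired_dataset <- function(n, WL, S1, WS, f = 1,
                                model = "ellipse",
                                specimen_cv = 0.06,
                                measurement_cv = 0,
                                quantity = c("area", "aspect_ratio"),
                                species = "Synthetica exempli",
                                seed = NULL) {
  quantity <- match.arg(quantity)
  if (n < 2L) stop("need n >= 2 specimens", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  model <- planform_model(model)
  WLs <- WL * lognormal_jitter(n, specimen_cv)
  S1s <- S1 * lognormal_jitter(n, specimen_cv)
  WSs <- pmax(WS * lognormal_jitter(n, specimen_cv), 2 * WLs)
  true_area <- vapply(seq_len(n), function(i) {
    make_planform(WLs[i], S1s[i], WSs[i], f)$true_total_area
  }, 0)
  mWL <- WLs * lognormal_jitter(n, measurement_cv)
  mS1 <- S1s * lognormal_jitter(n, measurement_cv)
  mWS <- pmax(WSs * lognormal_jitter(n, measurement_cv), 2 * mWL)
  folded_area <- total_wing_area(model, WS = mWS, WL = mWL,
                                 S1 = mS1)$total_area
  vs <- switch(quantity, area = true_area,
               aspect_ratio = aspect_ratio(WSs, true_area))
  vf <- switch(quantity, area = folded_area,
               aspect_ratio = aspect_ratio(mWS, folded_area))
  ids <- sprintf("SYN%03d", seq_len(n))
  list(
    pairs = paired_estimates(ids, species, vs, vf, quantity = quantity),
    table = data.frame(specimen_id = ids, species = species,
                       wingspan = mWS, wing_length = mWL, s1 = mS1,
                       units = "cm", stringsAsFactors = FALSE)
  )
}

#' Simulate traits under lambda-scaled Brownian motion on a tree
#'
#' Draws tip values from a multivariate normal with mean `root` and
#' covariance `sigma2 * lambda_transform(phylo_vcv(tree), lambda)`.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param sigma2 Brownian rate (variance per unit branch length), >= 0.
#' @param root Root (ancestral) state.
#' @param seed Optional integer seed.
#' @param nsim Number of replicate draws.
#' @return A named vector (one tip value per species) for `nsim = 1`, or
#'   an `nsim x ntip` matrix with species as column names.
#' @export
simulate_lambda_brownian <- function(tree, lambda = 1, sigma2 = 1,
                                     root = 0, seed = NULL, nsim = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  V <- lambda_transform(phylo_vcv(tree), lambda)
  ntip <- nrow(V)
  if (sigma2 == 0) {
    out <- matrix(root, nsim, ntip)
  } else {
    out <- MASS::mvrnorm(nsim, mu = rep(root, ntip), Sigma = sigma2 * V)
    if (nsim == 1L) out <- matrix(out, 1L)
  }
  colnames(out) <- rownames(V)
  if (nsim == 1L) out[1L, ] else out
}
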