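#' Planform models for the hand-wing
#'
#' A planform model describes the assumed geometric shape of the hand-wing
#' (the distal portion of the wing bearing the primaries) as a mixture of a
#' quarter-ellipse and a right triangle. The mixture is parameterized by the
#' ellipse fraction `f`, the proportion of the wing width `S1` occupied by
#' the elliptical portion of the shape:
#'
#' * `f = 0` — **triangle**: the hand-wing is a right triangle with legs
#'   `WL` (hand-wing extent) and `S1` (wing width).
#' * `f = 1` — **ellipse**: half-ellipse (semi-major axis `WL`, minor axis
#'   `S1`) or, equivalently for area, a quarter-ellipse with semi-axes `WL`
#'   and `S1`; both yield the same hand-wing area `(pi/2) * WL * S1` for the
#'   two wings combined.
#' * `f = 2/3` — **ellipse-triangle**: the elliptical portion occupies
#'   two-thirds of `S1`, giving hand area `((pi + 1)/3) * WL * S1`.
#'
#' Any other `f` in `[0, 1]` is accepted as an explicit `"mixture"` model,
#' an extension beyond the three named shapes; such fits are tagged
#' `extension = TRUE` in the model object.
#'
#' @param model Model name: `"triangle"`, `"ellipse"`, `"ellipse-triangle"`,
#'   or `"mixture"`. Partial matching and `_` for `-` are accepted.
#' @param f Ellipse fraction in `[0, 1]`. Required for `"mixture"`; for the
#'   named models it is fixed (0, 1, 2/3) and must not be supplied.
#' @return An object of class `planform_model` with fields `name` and `f`.
#' @examples
#' planform_model("ellipse-triangle")
#' planform_model("mixture", f = 0.5)
#' @export
planform_model <- function(model = c("ellipse-triangle", "triangle",
                                     "ellipse", "mixture"),
                           f = NULL) {
  if (inherits(model, "planform_model")) {
    return(model)
  }
  model <- gsub("_", "-", tolower(model[1]))
  model <- match.arg(model, c("ellipse-triangle", "triangle", "ellipse",
                              "mixture"))
  fixed <- c(triangle = 0, ellipse = 1, `ellipse-triangle` = 2 / 3)
  if (model == "mixture") {
    if (is.null(f)) {
      stop("model 'mixture' requires an explicit ellipse fraction `f`",
           call. = FALSE)
    }
  } else {
    if (!is.null(f) && abs(f - fixed[[model]]) > 1e-12) {
      stop("`f` is fixed at ", format(fixed[[model]]), " for model '",
           model, "'; use model = 'mixture' for other fractions",
           call. = FALSE)
    }
    f <- fixed[[model]]
  }
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    stop("ellipse fraction `f` must be a single number in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(name = model, f = as.numeric(f),
         extension = model == "mixture" &&
           min(abs(f - c(0, 2 / 3, 1))) > 1e-12),
    class = "planform_model"
  )
}

#' @export
print.planform_model <- function(x, ...) {
  cat("<planform_model> ", x$name, " (ellipse fraction f = ",
      format(x$f, digits = 6), ")",
      if (isTRUE(x$extension)) " [mixture extension]", "\n", sep = "")
  invisible(x)
}

check_positive <- function(..., .what = "measurement") {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("invalid ", .what, ": `", nm, "` must be positive and finite",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Combined hand-wing area under a planform model
#'
#' Area of both hand-wings combined, from the folded-wing measurements
#' `WL` (wrist to tip of the longest primary) and `S1` (wrist to tip of the
#' first secondary). For ellipse fraction `f` the closed form is
#' `WL * S1 * (f * pi/2 + (1 - f))`, which reduces to `WL * S1` (triangle),
#' `(pi/2) * WL * S1` (ellipse), and `((pi + 1)/3) * WL * S1`
#' (ellipse-triangle).
#'
#' @param model A [planform_model()] or a model name.
#' @param WL Wing length in cm (vectorized).
#' @param S1 Wing width in cm (vectorized).
#' @param f Ellipse fraction, for `model = "mixture"`.
#' @return Hand-wing area of both wings combined, in cm^2.
#' @examples
#' hand_wing_area("triangle", WL = 10, S1 = 5)  # 50
#' hand_wing_area("ellipse", WL = 10, S1 = 5)   # pi/2 * 50
#' @export
hand_wing_area <- function(model, WL, S1, f = NULL) {
  model <- planform_model(model, f = f)
  check_positive(WL = WL, S1 = S1)
  WL * S1 * (model$f * pi / 2 + (1 - model$f))
}

#' Area of the medial box
#'
#' The medial (root) box is the rectangle spanning the body and the proximal
#' wings between the two hand-wings: width `WS - 2 * WL`, height `S1`.
#' A wingspan shorter than twice the wing length makes the box degenerate;
#' by default this raises an error, while `policy = "clamp"` returns a zero
#' box area (the record should then be flagged downstream).
#'
#' @param WS Wingspan in cm (vectorized).
#' @param WL Wing length in cm.
#' @param S1 Wing width in cm.
#' @param policy `"strict"` (default) errors when `WS < 2 * WL`;
#'   `"clamp"` sets the box area to zero instead.
#' @param specimen_id Optional ids used in the strict-policy error message.
#' @return Medial box area in cm^2 (zero allowed).
#' @export
medial_box_area <- function(WS, WL, S1, policy = c("strict", "clamp"),
                            specimen_id = NULL) {
  policy <- match.arg(policy)
  check_positive(WS = WS, WL = WL, S1 = S1)
  width <- WS - 2 * WL
  bad <- width < 0
  if (any(bad)) {
    if (policy == "strict") {
      who <- if (!is.null(specimen_id)) {
        paste0(" (specimen ", paste(specimen_id[bad], collapse = ", "), ")")
      } else ""
      stop("geometry violation: wingspan < 2 * wing length", who,
           "; use policy = \"clamp\" to zero the medial box", call. = FALSE)
    }
    width[bad] <- 0
  }
  width * S1
}

#' Total wing area from folded-wing measurements
#'
#' Combines the hand-wing area of the chosen planform model with the medial
#' box: for ellipse fraction `f`,
#' `A = WL * S1 * (f * pi/2 + 1 - f) + (WS - 2 * WL) * S1`.
#' For the triangle model this simplifies algebraically to
#' `(WS - WL) * S1`.
#'
#' @inheritParams hand_wing_area
#' @inheritParams medial_box_area
#' @return A data frame of class `wing_area_estimate` with columns
#'   `total_area`, `hand_area`, `box_area` (cm^2), plus attributes `model`
#'   (the [planform_model()]) and `clamped` (logical vector marking records
#'   whose box was clamped to zero).
#' @examples
#' total_wing_area("ellipse", WS = 40, WL = 10, S1 = 5)
#' @export
total_wing_area <- function(model, WS, WL, S1, f = NULL,
                            policy = c("strict", "clamp"),
                            specimen_id = NULL) {
  model <- planform_model(model, f = f)
  policy <- match.arg(policy)
  hand <- hand_wing_area(model, WL, S1)
  box <- medial_box_area(WS, WL, S1, policy = policy,
                         specimen_id = specimen_id)
  out <- data.frame(total_area = hand + box, hand_area = hand,
                    box_area = box)
  attr(out, "model") <- model
  attr(out, "clamped") <- (WS - 2 * WL) < 0
  class(out) <- c("wing_area_estimate", class(out))
  out
}

#' Wing aspect ratio
#'
#' Aspect ratio of the wing pair: squared wingspan divided by total wing
#' area, `AR = WS^2 / A`. Dimensionless; higher values indicate elongated,
#' aerodynamically more efficient wings.
#'
#' @param WS Wingspan in cm.
#' @param area Total wing area in cm^2 (same length as `WS` or scalar).
#' @return Aspect ratio (vectorized).
#' @examples
#' aspect_ratio(WS = 10, area = 25)  # 4
#' @export
aspect_ratio <- function(WS, area) {
  check_positive(WS = WS)
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0)) {
    stop("invalid area: must be positive and finite", call. = FALSE)
  }
  WS^2 / area
}

#' Augment a morphometric table with model areas and aspect ratios
#'
#' Applies the three named planform models (and optionally extra mixture
#' fractions) to every row of a folded-wing measurement table, appending
#' `area_<model>` and `aspect_ratio_<model>` columns.
#'
#' @param data Data frame with columns `wingspan`, `wing_length`, `s1`
#'   (cm), e.g. from [read_morphometrics()].
#' @param models Character vector of model names to apply.
#' @param policy Medial-box policy, see [medial_box_area()].
#' @return `data` with appended estimate columns; clamped rows are marked
#'   in a logical `box_clamped` column when `policy = "clamp"`.
#' @export
estimate_wing_areas <- function(data,
                                models = c("triangle", "ellipse",
                                           "ellipse-triangle"),
                                policy = c("strict", "clamp")) {
  policy <- match.arg(policy)
  needed <- c("wingspan", "wing_length", "s1")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (m in models) {
    est <- total_wing_area(m, WS = data$wingspan, WL = data$wing_length,
                           S1 = data$s1, policy = policy,
                           specimen_id = data$specimen_id)
    tag <- gsub("-", "_", planform_model(m)$name)
    data[[paste0("area_", tag)]] <- est$total_area
    data[[paste0("aspect_ratio_", tag)]] <-
      aspect_ratio(data$wingspan, est$total_area)
    if (policy == "clamp") data$box_clamped <- attr(est, "clamped")
  }
  data
}
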