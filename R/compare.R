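#' Log10 discrepancy between paired folded- and spread-wing estimates
#'
#' Sum over specimens of `log10(folded) - log10(spread)`: an aggregate
#' signed disagreement on a body-size-free scale. The folded-minus-spread
#' orientation makes a model that underestimates area come out negative.
#' Because the aspect ratio is `WS^2 / A` with a shared wingspan, the
#' discrepancy of aspect ratios is exactly minus the discrepancy of areas.
#'
#' @param folded,spread Positive estimate vectors, matched per specimen.
#' @return A single dimensionless number.
#' @examples
#' log10_discrepancy(c(100, 10), c(100, 10))  # 0
#' log10_discrepancy(100, 10)                 # 1 (one decade)
#' @export
log10_discrepancy <- function(folded, spread) {
  if (length(folded) != length(spread)) {
    stop("`folded` and `spread` must be matched per specimen", call. = FALSE)
  }
  check_positive(folded = folded, spread = spread, .what = "estimate")
  sum(log10(folded) - log10(spread))
}

#' Percent difference of the folded-wing mean from the spread-wing mean
#'
#' `100 * (folded_mean - spread_mean) / spread_mean`: the mean difference
#' between methods as a percentage of the spread-wing mean. Note the
#' orientation is fixed (folded vs spread) and the measure is not
#' symmetric under swapping the methods.
#'
#' @param folded_mean,spread_mean Method means; `spread_mean` must be > 0.
#' @return Percent difference.
#' @export
percent_difference <- function(folded_mean, spread_mean) {
  if (any(!is.finite(spread_mean)) || any(spread_mean <= 0)) {
    stop("`spread_mean` must be positive", call. = FALSE)
  }
  100 * (folded_mean - spread_mean) / spread_mean
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation. Requires
#' at least two values and a positive mean.
#'
#' @param values Numeric vector, `length >= 2`.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    stop("insufficient data: CV needs at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("CV undefined: mean must be positive", call. = FALSE)
  }
  100 * stats::sd(values) / m
}

#' Paired method estimates for one or more specimens
#'
#' Assembles per-specimen paired values from the spread-wing method and a
#' folded-wing model into the table consumed by the comparison statistics.
#'
#' @param id Specimen identifiers.
#' @param species Species names.
#' @param value_spread,value_folded Positive estimates, one pair per
#'   specimen.
#' @param quantity `"area"` or `"aspect_ratio"`.
#' @return A data frame of class `paired_estimates`.
#' @export
paired_estimates <- function(id, species, value_spread, value_folded,
                             quantity = c("area", "aspect_ratio")) {
  quantity <- match.arg(quantity)
  check_positive(value_spread = value_spread, value_folded = value_folded,
                 .what = "estimate")
  n <- length(value_spread)
  if (length(value_folded) != n) {
    stop("both methods must be present for every specimen", call. = FALSE)
  }
  out <- data.frame(id = as.character(id), species = as.character(species),
                    value_spread = value_spread, value_folded = value_folded,
                    quantity = quantity, stringsAsFactors = FALSE)
  class(out) <- c("paired_estimates", class(out))
  out
}

#' Intraspecific accuracy and precision summary
#'
#' For a single-species cohort of paired estimates, computes the per-method
#' means and sample standard deviations, coefficients of variation, and the
#' percent difference between methods — the layout used to report
#' intraspecific accuracy (percent difference) and precision (CV).
#'
#' @param pairs A [paired_estimates()] table for one species, `n >= 2`.
#' @param model Optional [planform_model()] (or name) recorded in the
#'   output.
#' @param diff_mode `"ratio-of-means"` (default): percent difference of the
#'   method means; `"mean-of-ratios"`: mean of per-specimen percent
#'   differences.
#' @return A one-row data frame with `species`, `n`, `mean_spread`,
#'   `mean_folded`, `sd_spread`, `sd_folded`, `cv_spread`, `cv_folded`,
#'   `pct_diff`, `discrepancy`, and `model`.
#' @export
intraspecific_summary <- function(pairs, model = NULL,
                                  diff_mode = c("ratio-of-means",
                                                "mean-of-ratios")) {
  diff_mode <- match.arg(diff_mode)
  stopifnot(inherits(pairs, "paired_estimates"))
  if (length(unique(pairs$species)) != 1L) {
    stop("grouping error: `pairs` must contain a single species; ",
         "use compare_methods() for grouped tables", call. = FALSE)
  }
  if (nrow(pairs) < 2L) {
    stop("insufficient data: need >= 2 specimens of the species",
         call. = FALSE)
  }
  pct <- switch(diff_mode,
    `ratio-of-means` = percent_difference(mean(pairs$value_folded),
                                          mean(pairs$value_spread)),
    `mean-of-ratios` = mean(percent_difference(pairs$value_folded,
                                               pairs$value_spread))
  )
  data.frame(
    species = pairs$species[1L],
    n = nrow(pairs),
    mean_spread = mean(pairs$value_spread),
    mean_folded = mean(pairs$value_folded),
    sd_spread = stats::sd(pairs$value_spread),
    sd_folded = stats::sd(pairs$value_folded),
    cv_spread = coefficient_of_variation(pairs$value_spread),
    cv_folded = coefficient_of_variation(pairs$value_folded),
    pct_diff = pct,
    discrepancy = log10_discrepancy(pairs$value_folded, pairs$value_spread),
    model = if (is.null(model)) NA_character_ else planform_model(model)$name,
    stringsAsFactors = FALSE
  )
}

#' Grouped method comparison
#'
#' Splits a [paired_estimates()] table by species and applies
#' [intraspecific_summary()] to every group with at least two specimens.
#'
#' @inheritParams intraspecific_summary
#' @return A data frame with one summary row per species.
#' @export
compare_methods <- function(pairs, model = NULL,
                            diff_mode = c("ratio-of-means",
                                          "mean-of-ratios")) {
  diff_mode <- match.arg(diff_mode)
  stopifnot(inherits(pairs, "paired_estimates"))
  groups <- split(pairs, pairs$species)
  groups <- groups[vapply(groups, nrow, 1L) >= 2L]
  if (!length(groups)) {
    stop("insufficient data: no species with >= 2 specimens", call. = FALSE)
  }
  res <- lapply(groups, function(g) {
    class(g) <- class(pairs)
    intraspecific_summary(g, model = model, diff_mode = diff_mode)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Round half away from zero
#'
#' Report-time rounding used for percent columns: ties go away from zero
#' (2.35 -> 2.4, -2.35 -> -2.4), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
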