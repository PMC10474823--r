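#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the expected covariance between two tips is the
#' summed branch length from the root to their most recent common ancestor;
#' the diagonal holds root-to-tip distances. Computed with
#' [ape::vcv.phylo()] after validating the tree.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Square symmetric matrix, rows/columns in `tree$tip.label` order.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("invalid tree: branch lengths are required", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("invalid tree: negative branch length", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("invalid tree: duplicate tip labels", call. = FALSE)
  }
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda` while leaving the
#' diagonal untouched. `lambda = 1` keeps the Brownian structure,
#' `lambda = 0` removes all phylogenetic covariance (star phylogeny).
#'
#' @param V Phylogenetic covariance matrix from [phylo_vcv()].
#' @param lambda Signal multiplier in `[0, 1]`.
#' @return Transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

## Cholesky-based GLS core: returns coefficients, RSS in the V metric,
## log|V|, and (X' V^-1 X)^-1. V must be positive definite.
gls_core <- function(X, y, V) {
  L <- tryCatch(chol(V), error = function(e) {
    stop("linear-algebra error: covariance matrix is not positive ",
         "definite (condition: ", format(kappa(V)), ")", call. = FALSE)
  })
  # whiten: solve L' z = v  =>  z = L'^-1 v, so z_x' z_y = x' V^-1 y
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    stop("linear-algebra error: design matrix is collinear", call. = FALSE)
  }
  beta <- solve(qrX, crossprod(Xw, yw))
  resid <- yw - Xw %*% beta
  list(beta = drop(beta), rss = drop(crossprod(resid)),
       logdetV = 2 * sum(log(diag(L))), XtXinv = solve(XtX),
       n = length(y))
}

gls_loglik <- function(rss, logdetV, n, p, reml = FALSE, logdetXtX = 0) {
  if (reml) {
    df <- n - p
    -0.5 * (df * log(2 * pi) + df * log(rss / df) + df +
              logdetV + logdetXtX)
  } else {
    -0.5 * (n * log(2 * pi) + n * log(rss / n) + n + logdetV)
  }
}

#' Generalized least squares fit at a fixed covariance structure
#'
#' Fits `y = X b + e`, `e ~ N(0, sigma^2 V)` by the GLS normal equations
#' `b = (X' V^-1 X)^-1 X' V^-1 y`, with `X = [x]` when fitting through the
#' origin or `[1, x]` otherwise. Standard errors use
#' `sigma_hat^2 = RSS_V / (n - p)`; the log-likelihood is the multivariate
#' normal density at the fit with `sigma^2` profiled out.
#'
#' `r2` is `1 - RSS_V / TSS_V` where `TSS_V` is the V-metric residual sum
#' of squares of the null model: the GLS intercept-only model when an
#' intercept is present, and the zero function (uncentered) for
#' through-origin fits, where a centered total sum of squares would be
#' incoherent.
#'
#' @param x Predictor vector.
#' @param y Response vector, same order as `x`.
#' @param V Covariance structure (e.g. a lambda-transformed [phylo_vcv()]);
#'   use `diag(length(y))` for ordinary least squares.
#' @param through_origin Fit without an intercept (slope-only)?
#' @param reml Use the REML criterion for the reported log-likelihood?
#' @return A list of class `pgls_fit`: `coefficients` (named), `se`,
#'   `sigma2`, `rss`, `tss`, `r2`, `logLik`, `n`, `p` (regression
#'   coefficients), `through_origin`, `fitted`, `residuals`.
#' @export
gls_fit <- function(x, y, V, through_origin = TRUE, reml = FALSE) {
  n <- length(y)
  stopifnot(length(x) == n, nrow(V) == n, ncol(V) == n)
  X <- if (through_origin) cbind(x = x) else cbind(`(Intercept)` = 1, x = x)
  fit <- gls_core(X, y, V)
  p <- ncol(X)
  sigma2 <- fit$rss / (n - p)
  se <- sqrt(sigma2 * diag(fit$XtXinv))
  tss <- if (through_origin) {
    drop(crossprod(backsolve(chol(V), y, transpose = TRUE)))
  } else {
    gls_core(cbind(rep(1, n)), y, V)$rss
  }
  ll <- gls_loglik(fit$rss, fit$logdetV, n, p, reml = reml,
                   logdetXtX = determinant(crossprod(
                     backsolve(chol(V), X, transpose = TRUE)))$modulus)
  beta <- fit$beta
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  structure(list(
    coefficients = beta, se = se, sigma2 = sigma2, rss = fit$rss,
    tss = tss, r2 = 1 - fit$rss / tss, logLik = as.numeric(ll),
    n = n, p = p, through_origin = through_origin, reml = reml,
    fitted = drop(X %*% beta), residuals = y - drop(X %*% beta)
  ), class = "pgls_fit")
}

#' Sample-size-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size.
#' @return AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0) {
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Phylogenetic GLS with maximum-likelihood Pagel's lambda
#'
#' Profiles the likelihood of Pagel's lambda on `[0, 1]` (bounded
#' one-dimensional optimization plus explicit endpoint checks) and returns
#' the GLS fit at the maximum-likelihood lambda. Species are matched
#' between the data and the tree by name after normalizing spaces to
#' underscores; unmatched tips are pruned with a message.
#'
#' The AICc parameter count defaults to the number of regression
#' coefficients plus one for `sigma^2` and one for `lambda`; pass `k` to
#' use a different accounting convention.
#'
#' @param x,y Named numeric vectors (names = species) or unnamed vectors
#'   already in `tree$tip.label` order.
#' @param tree A rooted `phylo` with branch lengths, >= 3 tips.
#' @param through_origin Fit without an intercept? Default `TRUE` (the
#'   slope is then read as a bias factor: 1 means no bias).
#' @param lambda Fix lambda instead of estimating it (optional).
#' @param reml Optimize the REML rather than ML criterion.
#' @param k Parameter count for AICc; default `p + 2`.
#' @return A `pgls_fit` augmented with `lambda`, `aicc`, `k`,
#'   `lambda_profile` (grid of `(lambda, logLik)` used for the sanity
#'   check), and `tree_tips_used`.
#' @export
fit_pgls_ml <- function(x, y, tree, through_origin = TRUE, lambda = NULL,
                        reml = FALSE, k = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 3L) {
    stop("lambda estimation needs >= 3 tips", call. = FALSE)
  }
  norm <- function(s) gsub("[ ]+", "_", trimws(s))
  if (!is.null(names(x)) && !is.null(names(y))) {
    names(x) <- norm(names(x)); names(y) <- norm(names(y))
    tips <- norm(tree$tip.label)
    keep <- intersect(tips, intersect(names(x), names(y)))
    if (length(keep) < 3L) {
      stop("fewer than 3 species shared between tree and data", call. = FALSE)
    }
    if (length(keep) < ape::Ntip(tree)) {
      message("pruning ", ape::Ntip(tree) - length(keep),
              " tree tip(s) without trait data")
      tree <- ape::keep.tip(tree, tree$tip.label[tips %in% keep])
    }
    ord <- norm(tree$tip.label)
    x <- x[ord]; y <- y[ord]
  } else if (length(x) != ape::Ntip(tree) || length(y) != ape::Ntip(tree)) {
    stop("unnamed x/y must match the number of tree tips", call. = FALSE)
  }
  V0 <- phylo_vcv(tree)
  fit_at <- function(lam) {
    gls_fit(x, y, lambda_transform(V0, lam),
            through_origin = through_origin, reml = reml)
  }
  profile_grid <- seq(0, 1, by = 0.1)
  if (is.null(lambda)) {
    obj <- function(lam) fit_at(lam)$logLik
    opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE,
                           tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    ll <- vapply(cand, obj, 0)
    lambda_hat <- cand[which.max(ll)]
  } else {
    if (lambda < 0 || lambda > 1) {
      stop("lambda must be in [0, 1]", call. = FALSE)
    }
    lambda_hat <- lambda
  }
  fit <- fit_at(lambda_hat)
  fit$lambda <- lambda_hat
  fit$lambda_fixed <- !is.null(lambda)
  fit$k <- if (is.null(k)) fit$p + 2L else k
  fit$aicc <- aicc(fit$logLik, fit$k, fit$n)
  fit$lambda_profile <- data.frame(
    lambda = profile_grid,
    logLik = vapply(profile_grid, function(l) fit_at(l)$logLik, 0)
  )
  fit$tree_tips_used <- tree$tip.label
  fit
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("<pgls_fit>", if (x$through_origin) "through-origin", "n =", x$n,
      if (!is.null(x$lambda)) paste0("lambda = ", signif(x$lambda, 4)), "\n")
  co <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(signif(co, 5))
  cat("r2 =", signif(x$r2, 4), " logLik =", signif(x$logLik, 6),
      if (!is.null(x$aicc)) paste(" AICc =", signif(x$aicc, 6)), "\n")
  invisible(x)
}
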