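# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of closed forms,
# pracma::polyarea instead of polygon_area(), explicit normal equations
# instead of the Cholesky GLS.

# Midpoint-quadrature area of a half-ellipse with semi-axes a (along x)
# and b (height), i.e. height b*sqrt(1 - (x/a)^2) over [-a, a].
half_ellipse_area_quadrature <- function(a, b, n = 4e5) {
  h <- 2 * a / n
  x <- -a + (seq_len(n) - 0.5) * h
  sum(b * sqrt(pmax(0, 1 - (x / a)^2))) * h
}

# Shoelace oracle from pracma (independent of wingplan::polygon_area).
shoelace <- function(x, y) abs(pracma::polyarea(x, y))

# Densely sampled composite planform boundary built here, not with
# make_planform(): straight leading edge plus a trailing edge that stacks
# a quarter-ellipse (fraction f of S1) on a right triangle.
reference_planform_polygon <- function(WL, S1, WS, f, n = 1e4) {
  x0 <- WS / 2 - WL
  trailing <- function(xa) {
    u <- pmin(1, pmax(0, (abs(xa) - x0) / WL))
    ifelse(abs(xa) <= x0, S1,
           S1 * (f * sqrt(pmax(0, 1 - u^2)) + (1 - f) * (1 - u)))
  }
  # parameterize the hand arcs by angle so the chords converge fast
  th <- seq(0, pi / 2, length.out = floor(n / 2))
  xr <- x0 + WL * cos(th)
  xl <- -rev(xr)
  xs <- c(-WS / 2, WS / 2, xr, xl)
  ys <- c(0, 0, trailing(xr), trailing(xl))
  list(x = xs, y = ys)
}

# Ordinary least squares through explicit normal equations.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  r <- y - X %*% beta
  s2 <- sum(r^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(XtX))))
}

# Small fixed trees with hand-checkable covariances.
tree_star2 <- function() wingplan::read_newick(text = "(A:1,B:1);")
tree_abc <- function() wingplan::read_newick(text = "((A:1,B:1):1,C:2);")

# A reproducible 50-tip ultrametric tree for the recovery simulations.
tree50 <- function(seed = 20260101) {
  set.seed(seed)
  ape::rcoal(50)
}

make_mask <- function(m, scale = 1) wingplan::binary_mask(m > 0, scale)
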