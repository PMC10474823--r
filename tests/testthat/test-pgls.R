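test_that("phylogenetic covariances are shared root-to-ancestor path lengths", {
  V2 <- phylo_vcv(tree_star2())
  expect_equal(unname(V2), diag(2))
  V3 <- phylo_vcv(tree_abc())
  expect_equal(V3["A", "A"], 2)
  expect_equal(V3["B", "B"], 2)
  expect_equal(V3["C", "C"], 2)
  expect_equal(V3["A", "B"], 1)
  expect_equal(V3["A", "C"], 0)
  expect_equal(V3, t(V3))
  # ultrametric tree: constant diagonal; off-diagonals bounded by diagonal
  set.seed(31)
  tr <- ape::rcoal(12)
  V <- phylo_vcv(tr)
  expect_equal(max(diag(V)) - min(diag(V)), 0, tolerance = 1e-10)
  expect_true(all(V <= min(diag(V)) + 1e-12))
  bad <- tr; bad$edge.length[1] <- -0.1
  expect_error(phylo_vcv(bad), "negative branch")
})

test_that("lambda transform scales off-diagonals only", {
  V <- phylo_vcv(tree_abc())
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(diag(V)),
               ignore_attr = TRUE)
  expect_equal(lambda_transform(V, 0.5)["A", "B"], 0.5)
  expect_equal(diag(lambda_transform(V, 0.5)), diag(V))
  expect_error(lambda_transform(V, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(V, -0.1), "\\[0, 1\\]")
})

test_that("gls_fit with identity covariance reproduces OLS exactly", {
  # noiseless proportional data: exact through-origin fit
  f0 <- gls_fit(c(1, 2, 3), c(2, 4, 6), diag(3))
  expect_equal(unname(f0$coefficients), 2)
  expect_equal(f0$rss, 0, tolerance = 1e-20)
  # random data versus explicit normal equations, both designs
  set.seed(32)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 1.5 * x + rnorm(n)
    for (origin in c(TRUE, FALSE)) {
      X <- if (origin) cbind(x) else cbind(1, x)
      ref <- ols_oracle(X, y)
      fit <- gls_fit(x, y, diag(n), through_origin = origin)
      expect_equal(unname(fit$coefficients), unname(ref$beta),
                   tolerance = 1e-10)
      expect_equal(unname(fit$se), unname(ref$se), tolerance = 1e-10)
    }
    # V = sigma2 * I leaves the estimates unchanged
    fit2 <- gls_fit(x, y, 3.7 * diag(n))
    expect_equal(fit2$coefficients, gls_fit(x, y, diag(n))$coefficients,
                 tolerance = 1e-10)
  }
  expect_error(gls_fit(rep(1, 4), rnorm(4), diag(4),
                       through_origin = FALSE), "collinear")
})

test_that("fixed-lambda PGLS matches the nlme/corPagel reference", {
  skip_if_not_installed("nlme")
  set.seed(33)
  tr <- ape::rcoal(25)
  x <- simulate_lambda_brownian(tr, 1, 1, seed = 34)
  y <- 1.2 * x + simulate_lambda_brownian(tr, 1, 0.3, seed = 35)
  d <- data.frame(x = x, y = y, sp = factor(names(x), levels = tr$tip.label))
  for (lam in c(0.3, 0.9)) {
    mine <- gls_fit(x, y, lambda_transform(phylo_vcv(tr), lam),
                    through_origin = FALSE)
    ref <- nlme::gls(y ~ x, data = d, method = "ML",
                     correlation = ape::corPagel(lam, phy = tr, form = ~sp,
                                                 fixed = TRUE))
    expect_equal(unname(mine$coefficients["x"]), unname(coef(ref)["x"]),
                 tolerance = 1e-8)
    expect_equal(unname(mine$se["x"]), sqrt(diag(vcov(ref))[["x"]]),
                 tolerance = 1e-8)
    expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
  }
})

test_that("AICc follows the small-sample penalty arithmetic", {
  expect_equal(aicc(-50.1, k = 2, n = 41), 100.2 + 4 + 12 / 38)
  # one extra parameter: ordering governed by -2 logLik + penalty
  ll <- -30
  expect_equal(aicc(ll, 3, 20) - aicc(ll, 2, 20),
               (2 * 3 + 24 / 16) - (2 * 2 + 12 / 17))
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("ML lambda fit is optimal on the grid and permutation-invariant", {
  set.seed(36)
  tr <- ape::rcoal(30)
  x <- simulate_lambda_brownian(tr, 0.6, 1, seed = 37)
  y <- 1.1 * x + simulate_lambda_brownian(tr, 0.6, 0.4, seed = 38)
  fit <- fit_pgls_ml(x, y, tr)
  expect_true(all(fit$logLik >= fit$lambda_profile$logLik - 1e-8))
  expect_equal(fit$aicc, aicc(fit$logLik, fit$k, fit$n))
  expect_equal(fit$k, 3L)  # slope + sigma2 + lambda
  expect_equal(fit_pgls_ml(x, y, tr, k = 2L)$k, 2L)
  # permuting species order changes nothing
  perm <- sample(length(x))
  fit_p <- fit_pgls_ml(x[perm], y[perm], tr)
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_equal(fit_p$se, fit$se, tolerance = 1e-10)
  expect_equal(fit_p$lambda, fit$lambda, tolerance = 1e-6)
  expect_equal(fit_p$logLik, fit$logLik, tolerance = 1e-10)
  # fixing lambda skips estimation
  expect_equal(fit_pgls_ml(x, y, tr, lambda = 0.25)$lambda, 0.25)
})

test_that("unmatched tips are pruned by normalized species names", {
  tr <- read_newick(text = paste0(
    "(((Aus_bus:1,Cus_dus:1):1,(Eus_fus:1.5,Gus_hus:1.5):0.5):1,",
    "(Ius_jus:2,Kus_lus:2):1);"))
  set.seed(61)
  x <- c("Aus bus" = 1, "Cus dus" = 2, "Eus fus" = 3, "Gus hus" = 4,
         "Ius jus" = 5, "Kus lus" = 6, "Mus nus" = 7)
  y <- 2 * x + rnorm(7, 0, 0.3)
  names(y) <- names(x)
  # extra data species is ignored; all 6 tree tips keep their data
  expect_message(fit <- fit_pgls_ml(x, y, tr), regexp = NA)
  expect_equal(fit$n, 6)
  # a tree tip with no data is pruned with a message
  x2 <- x[1:5]; y2 <- y[1:5]
  expect_message(fit2 <- fit_pgls_ml(x2, y2, tr), "pruning 1")
  expect_equal(fit2$n, 5)
  expect_error(fit_pgls_ml(x[1:2], y[1:2], tr), "fewer than 3")
})

test_that("lambda and slope are recovered from simulated regimes", {
  tr <- tree50()
  # lambda = 1 regime: high signal detected, slope near truth
  lam1 <- vapply(1:40, function(i) {
    x <- simulate_lambda_brownian(tr, 1, 1, seed = 400 + i)
    y <- 1.1 * x + simulate_lambda_brownian(tr, 1, 0.3, seed = 7000 + i)
    fit_pgls_ml(x, y, tr)$lambda
  }, 0)
  expect_gt(mean(lam1 > 0.9), 0.5)
  # lambda = 0 regime: star-like residuals detected
  lam0 <- vapply(1:40, function(i) {
    x <- simulate_lambda_brownian(tr, 0, 1, seed = 500 + i)
    y <- 1.1 * x + simulate_lambda_brownian(tr, 0, 0.3, seed = 8000 + i)
    fit_pgls_ml(x, y, tr)$lambda
  }, 0)
  expect_gt(mean(lam0 < 0.1), 0.5)
})
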