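test_that("design matrices encode the LQ and MLQ linear predictors", {
  tab <- data.frame(NC = c(3L, 2L, 1L), D = c(5, 0, 5), d = c(0.2, 0, 0),
                    included = TRUE)
  des <- build_design(tab, "MLQ")
  expect_equal(unname(des$X[1, ]), c(1, 5, 25, 1.0))
  expect_equal(unname(des$X[2, ]), c(1, 0, 0, 0))    # control quadrat
  expect_equal(unname(des$X[3, 1:3]), unname(build_design(tab, "LQ")$X[3, ]))
  expect_equal(des$X[3, 4], c(Dd = 0))               # open-field quadrat
  expect_equal(des$y, c(3L, 2L, 1L))
})

test_that("intercept-only Poisson MLE is the log of the sample mean", {
  fit <- fit_poisson_glm(matrix(1, 3), c(2L, 3L, 4L))
  expect_equal(unname(fit$coefficients), log(3), tolerance = 1e-10)
  expect_equal(unname(fit$params["nc0"]), 3, tolerance = 1e-10)
})

test_that("a saturated three-dose fit reproduces group means and the 2x2 solution", {
  set.seed(8)
  doses <- rep(c(0, 2, 5), each = 200)
  y <- rpois(600, exp(1 - 0.2 * doses - 0.02 * doses^2))
  tab <- data.frame(NC = y, D = doses, d = 0, included = TRUE)
  fit <- fit_survival_model(tab, "LQ")
  m <- tapply(y, doses, mean)
  expect_equal(unname(tapply(fit$fitted, doses, mean)), unname(m),
               tolerance = 1e-8)
  # oracle: solve ln(m1/m0) = -2a - 4b, ln(m2/m0) = -5a - 25b
  sol <- solve(matrix(c(-2, -5, -4, -25), 2), log(c(m[2] / m[1], m[3] / m[1])))
  expect_equal(unname(fit$params["alpha"]), sol[1], tolerance = 1e-8)
  expect_equal(unname(fit$params["beta"]), sol[2], tolerance = 1e-8)
  # predictions on the same quadrats equal the observed group means
  expect_equal(unname(tapply(predict_counts(fit, tab), doses, mean)),
               unname(m), tolerance = 1e-8)
})

test_that("IRLS matches direct likelihood maximisation and glm()", {
  tab <- synthetic_quadrat_table(n = 800, seed = 13)
  des <- build_design(tab, "MLQ")
  fit <- fit_poisson_glm(des$X, des$y, model = "MLQ")
  # independent route 1: direct numerical maximisation of the log-likelihood
  nll <- function(b) {
    eta <- drop(des$X %*% b)
    -sum(des$y * eta - exp(eta))
  }
  ngr <- function(b) -drop(crossprod(des$X, des$y - exp(drop(des$X %*% b))))
  opt <- optim(c(log(mean(des$y)), 0, 0, 0), nll, ngr, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  expect_lt(max(abs(opt$par - fit$coefficients)), 1e-6)
  # independent route 2: stats::glm IRLS
  gl <- glm(des$y ~ des$X - 1, family = poisson())
  expect_equal(unname(coef(gl)), unname(fit$coefficients), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(gl)))), unname(fit$se), tolerance = 1e-4)
  # score equations hold at the optimum
  expect_lt(fit$score_norm, 1e-8)
  # information criteria follow their definitions
  expect_equal(fit$aic, 2 * 4 - 2 * fit$loglik)
  expect_equal(fit$bic, 4 * log(fit$n_obs) - 2 * fit$loglik)
})

test_that("model fitting validates its inputs", {
  X <- cbind(1, c(1, 2, 3))
  expect_error(fit_poisson_glm(X, c(1.5, 2, 1)), "integer")
  expect_error(fit_poisson_glm(X, c(-1L, 2L, 1L)), "integer|non-negative")
  expect_error(fit_poisson_glm(X, c(0L, 0L, 0L)), "all-zero")
  expect_error(fit_poisson_glm(cbind(1, c(2, 2, 2)), c(1L, 2L, 3L)),
               "collinear")
})

test_that("MLQ never fits worse than LQ and reduces exactly on open-field data", {
  tab <- synthetic_quadrat_table(n = 1000, seed = 17)
  lq <- fit_survival_model(tab, "LQ")
  mlq <- fit_survival_model(tab, "MLQ")
  expect_gte(mlq$loglik, lq$loglik)  # LQ is MLQ with delta = 0

  open <- tab
  open$d <- 0
  red <- fit_survival_model(open, "MLQ")
  lq_open <- fit_survival_model(open, "LQ")
  expect_true(red$reduced)
  expect_true(is.na(red$params["delta"]))
  expect_equal(red$coefficients, lq_open$coefficients)
  expect_equal(red$loglik, lq_open$loglik)
})

test_that("predictions are positive, NC0 at zero dose, increasing in d for delta < 0", {
  tab <- synthetic_quadrat_table(n = 2000, seed = 19)
  fit <- fit_survival_model(tab, "MLQ")
  expect_lt(unname(fit$params["delta"]), 0)
  grid <- data.frame(NC = 0L, D = 5, d = seq(0, 1, 0.1), included = TRUE)
  pred <- predict_counts(fit, grid)
  expect_true(all(pred > 0))
  expect_true(all(diff(pred) > 0))
  at0 <- predict_counts(fit, data.frame(NC = 0L, D = 0, d = 0,
                                        included = TRUE))
  expect_equal(at0, unname(fit$params["nc0"]))
})

test_that("Wald inference reports significant generating effects", {
  tab <- synthetic_quadrat_table(n = 3000, seed = 23)
  fit <- fit_survival_model(tab, "LQ")
  wi <- wald_inference(fit)
  expect_true(all(wi$p[wi$term %in% c("D", "D2")] < 0.001))
  a <- wi[wi$term == "alpha", ]
  expect_true(a$lower < 0.25 && 0.25 < a$upper)  # covers generating alpha
  expect_equal(wi$z[wi$term == "D"], -wi$z[wi$term == "alpha"])
})

test_that("a null distance covariate gives nominal type-I error for delta", {
  params0 <- list(nc0 = 2.5, alpha = 0.25, beta = 0.035, delta = 0)
  pvals <- vapply(1:120, function(s) {
    tab <- synthetic_quadrat_table(n = 400, params = params0, seed = 500 + s)
    fit <- fit_survival_model(tab, "MLQ")
    wald_inference(fit)$p[4]
  }, numeric(1))
  # rejection rate at 5% within binomial noise of the nominal level
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.06)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the dispersion test is calibrated and detects overdispersion", {
  expect_equal(poisson_dispersion_test(rep(3L, 50))$statistic, 0)

  set.seed(29)
  p_pois <- vapply(1:300, function(i) {
    poisson_dispersion_test(rpois(1000, 2.4))$p
  }, numeric(1))
  expect_lt(abs(mean(p_pois < 0.05) - 0.05), 0.035)

  p_nb <- vapply(1:50, function(i) {
    poisson_dispersion_test(rnbinom(1000, mu = 2.4, size = 2.4))$p
  }, numeric(1))
  expect_gt(mean(p_nb < 0.05), 0.9)

  expect_warning(poisson_dispersion_test(rep(0L, 30)), "zero mean")
  expect_warning(poisson_dispersion_test(1:5), "fewer")
})
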