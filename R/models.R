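#' Build the regression design for an LQ or MLQ survival model
#'
#' The expected colony count per quadrat is modelled on the log scale as
#' a linear predictor: LQ rows are `[1, D, D^2]` and MLQ rows are
#' `[1, D, D^2, D*d]`, with response `y = NC`. The fitted coefficients
#' are `(lambda0, -alpha, -beta[, -delta])`.
#'
#' @param table a quadrat table with columns `NC`, `D` and (for MLQ)
#'   `d`; only included quadrats should be passed.
#' @param model `"LQ"` or `"MLQ"`.
#' @return list with `X` (design matrix), `y` (counts) and `model`.
#' @export
build_design <- function(table, model = c("LQ", "MLQ")) {
  model <- match.arg(model)
  if ("included" %in% names(table)) table <- table[table$included, ]
  D <- table$D
  if (any(!is.finite(D))) stop("non-finite dose covariate", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, D = D, D2 = D^2)
  if (model == "MLQ") {
    d <- table$d
    if (is.null(d) || any(!is.finite(d))) {
      stop("MLQ model requires a finite distance covariate d", call. = FALSE)
    }
    X <- cbind(X, Dd = D * d)
  }
  list(X = X, y = table$NC, model = model)
}

#' Fit a Poisson generalized linear model by IRLS
#'
#' Maximum-likelihood estimation of `y ~ Poisson(exp(X xi))` by
#' iteratively reweighted least squares, initialised from the working
#' response `log(pmax(y, 0.5))` and iterated until the relative change
#' in log-likelihood falls below `tol`. At convergence the score
#' equations `X'(y - mu) = 0` hold to numerical tolerance; the
#' coefficient covariance is the inverse Fisher information
#' `(X' W X)^-1` with `W = diag(mu)`.
#'
#' @param X design matrix (full column rank).
#' @param y non-negative integer counts, `length(y) == nrow(X)`.
#' @param model label stored in the result (`"LQ"`, `"MLQ"`, ...).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return an object of class `grid_fit`: coefficients, `vcov`, `se`,
#'   survival-scale `params` (`nc0`, `alpha`, `beta`, `delta`),
#'   `loglik`, `aic`, `bic`, `n_obs`, `n_params`, `score_norm`,
#'   `converged`, `iterations`, `fitted`.
#' @export
fit_poisson_glm <- function(X, y, model = "custom", tol = 1e-10,
                            max_iter = 100) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (any(y < 0) || any(y != round(y))) {
    stop("y must be non-negative integer counts", call. = FALSE)
  }
  if (all(y == 0)) stop("all-zero response: model is unidentifiable",
                        call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("collinear design: rank-deficient regression matrix", call. = FALSE)
  }
  eta <- log(pmax(y, 0.5))
  lfact <- sum(lgamma(y + 1))
  mu <- exp(eta)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    z <- eta + (y - mu) / mu
    XtWX <- crossprod(X, X * mu)
    beta <- solve(XtWX, crossprod(X, mu * z))
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    ll <- sum(y * eta - mu) - lfact
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      # one polishing Newton step: quadratic convergence drives the
      # score equations to numerical zero
      z <- eta + (y - mu) / mu
      beta <- solve(crossprod(X, X * mu), crossprod(X, mu * z))
      eta <- drop(X %*% beta)
      mu <- exp(eta)
      ll <- sum(y * eta - mu) - lfact
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    stop(sprintf(
      "IRLS did not converge in %d iterations (last logLik %.6g, change %.3g)",
      max_iter, ll, ll - ll_old), call. = FALSE)
  }
  beta <- drop(beta)
  names(beta) <- colnames(X)
  XtWX <- crossprod(X, X * mu)
  vcov <- solve(XtWX)
  dimnames(vcov) <- list(names(beta), names(beta))
  k <- ncol(X)
  n <- length(y)
  params <- c(nc0 = unname(exp(beta[1])),
              alpha = if (k >= 2) -unname(beta[2]) else NA_real_,
              beta = if (k >= 3) -unname(beta[3]) else NA_real_,
              delta = if (k >= 4) -unname(beta[4]) else NA_real_)
  structure(
    list(model = model, coefficients = beta, vcov = vcov,
         se = sqrt(diag(vcov)), params = params,
         loglik = ll, aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
         n_obs = n, n_params = k,
         score_norm = max(abs(crossprod(X, y - mu))),
         converged = converged, iterations = iter, fitted = mu,
         reduced = FALSE),
    class = "grid_fit"
  )
}

#' Fit the LQ or MLQ survival model to a quadrat table
#'
#' Builds the design with [build_design()] on included quadrats and
#' fits by [fit_poisson_glm()]. The survival-scale parameters are
#' exposed with their conventional signs: `nc0 = exp(lambda0)`,
#' `alpha = -c_D` (1/Gy), `beta = -c_D2` (1/Gy^2),
#' `delta = -c_Dd` (1/(Gy cm)).
#'
#' If an MLQ fit is requested on data whose `D*d` column is identically
#' zero (open fields and controls only), the column carries no
#' information: the model is reduced to LQ, `delta` is `NA`, and the
#' result is flagged `reduced = TRUE`.
#'
#' @param table a quadrat table.
#' @param model `"LQ"` or `"MLQ"`.
#' @param ... passed to [fit_poisson_glm()].
#' @return a `grid_fit`.
#' @export
fit_survival_model <- function(table, model = c("LQ", "MLQ"), ...) {
  model <- match.arg(model)
  des <- build_design(table, model)
  reduced <- FALSE
  if (model == "MLQ" && all(des$X[, "Dd"] == 0)) {
    des$X <- des$X[, colnames(des$X) != "Dd", drop = FALSE]
    reduced <- TRUE
  }
  fit <- fit_poisson_glm(des$X, des$y, model = model, ...)
  fit$reduced <- reduced
  if (reduced) fit$params["delta"] <- NA_real_
  fit
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf("Poisson GLM survival fit: %s model%s\n", x$model,
              if (x$reduced) " (reduced: D*d column was all zero)" else ""))
  p <- x$params
  cat(sprintf("  NC0 = %.4f, alpha = %.4f /Gy, beta = %.4f /Gy^2", p["nc0"],
              p["alpha"], p["beta"]))
  if (!is.na(p["delta"])) cat(sprintf(", delta = %.4f /(Gy cm)", p["delta"]))
  cat("\n")
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f, BIC = %.2f (%d iterations)\n",
              x$n_obs, x$loglik, x$aic, x$bic, x$iterations))
  invisible(x)
}

#' @export
logLik.grid_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.grid_fit <- function(object, ...) object$coefficients

#' @export
vcov.grid_fit <- function(object, ...) object$vcov

#' Predict expected colony counts per quadrat
#'
#' Evaluates `lambda = exp(X xi_hat)` for the quadrats of `table` under
#' a fitted model; predictions are strictly positive.
#'
#' @param fit a `grid_fit`.
#' @param table a quadrat table with the covariates the fit requires.
#' @return numeric vector of expected counts, one per (included)
#'   quadrat.
#' @export
predict_counts <- function(fit, table) {
  stopifnot(inherits(fit, "grid_fit"))
  model <- if (fit$model %in% c("LQ", "MLQ")) fit$model else "LQ"
  des <- build_design(table, model)
  X <- des$X[, names(fit$coefficients), drop = FALSE]
  drop(exp(X %*% fit$coefficients))
}

#' Wald inference for a fitted survival model
#'
#' Per-coefficient z statistics, two-sided normal p-values and 95%
#' confidence intervals, on both the regression scale and the
#' survival-parameter scale (`nc0` by the delta method, `alpha`, `beta`,
#' `delta` by sign flip).
#'
#' @param fit a `grid_fit`.
#' @param level confidence level, default 0.95.
#' @return data.frame with `term`, `estimate`, `se`, `z`, `p`, `lower`,
#'   `upper`.
#' @export
wald_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "grid_fit"))
  if (any(!is.finite(fit$se))) {
    stop("inference unavailable: singular covariance", call. = FALSE)
  }
  q <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients
  se <- fit$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  reg <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), z = unname(z), p = unname(p),
                    lower = unname(est - q * se),
                    upper = unname(est + q * se))
  # survival scale: nc0 = exp(lambda0); alpha/beta/delta = -coef
  surv_names <- c("nc0", "alpha", "beta", "delta")[seq_along(est)]
  s_est <- c(exp(est[1]), -est[-1])
  s_se <- c(exp(est[1]) * se[1], se[-1])
  s_low <- c(exp(est[1] - q * se[1]), -(est[-1] + q * se[-1]))
  s_up <- c(exp(est[1] + q * se[1]), -(est[-1] - q * se[-1]))
  surv <- data.frame(term = surv_names, estimate = unname(s_est),
                     se = unname(s_se), z = unname(c(z[1], -z[-1])),
                     p = unname(p), lower = unname(s_low),
                     upper = unname(s_up))
  rbind(reg, surv)
}

#' Chi-square dispersion test for Poisson counts
#'
#' Tests whether counts are consistent with a Poisson distribution via
#' the index-of-dispersion statistic `sum((y - ybar)^2) / ybar`, which
#' is approximately chi-square with `n - 1` degrees of freedom under the
#' Poisson null. The two-sided p-value flags both overdispersion and
#' underdispersion. With `group` given, the test is run per group
#' (groups with zero mean are skipped with a warning).
#'
#' @param counts non-negative integer counts.
#' @param group optional grouping factor (e.g. condition or dose bin).
#' @param min_n minimum group size, default 20.
#' @return data.frame with `group`, `n`, `mean`, `dispersion`
#'   (statistic / df), `statistic`, `df`, `p`.
#' @export
poisson_dispersion_test <- function(counts, group = NULL, min_n = 20) {
  if (is.null(group)) group <- rep("all", length(counts))
  groups <- split(counts, group)
  out <- lapply(names(groups), function(g) {
    y <- groups[[g]]
    if (length(y) < min_n) {
      warning("group '", g, "' has fewer than ", min_n, " quadrats; skipped")
      return(NULL)
    }
    m <- mean(y)
    if (m == 0) {
      warning("group '", g, "' has zero mean count; dispersion undefined")
      return(NULL)
    }
    stat <- sum((y - m)^2) / m
    df <- length(y) - 1
    p_hi <- stats::pchisq(stat, df, lower.tail = FALSE)
    data.frame(group = g, n = length(y), mean = m,
               dispersion = stat / df, statistic = stat, df = df,
               p = 2 * min(p_hi, 1 - p_hi))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
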