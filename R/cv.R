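#' Assign cross-validation folds to flasks
#'
#' Partitions flasks into `k` folds. The default replicate-stratified
#' strategy permutes the replicates of every condition (pattern x
#' nominal dose, controls included) and deals them round-robin across
#' folds, so with 4 replicates and `k = 4` each fold holds exactly one
#' replicate of every condition (75% training / 25% testing). The
#' `"random"` strategy permutes flasks freely.
#'
#' @param manifest data.frame with `flask_id`, `pattern`,
#'   `nominal_dose` (as from [simulate_experiment()]).
#' @param k number of folds (>= 2).
#' @param seed optional integer seed.
#' @param strategy `"replicate"` (stratified) or `"random"`.
#' @return named integer vector: fold label (1..k) per flask id.
#' @export
assign_folds <- function(manifest, k = 4, seed = NULL,
                         strategy = c("replicate", "random")) {
  strategy <- match.arg(strategy)
  if (k < 2) stop("k must be >= 2: k = 1 leaves no held-out data",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- manifest$flask_id
  if (anyDuplicated(ids)) stop("duplicate flask ids in manifest", call. = FALSE)
  folds <- integer(length(ids))
  names(folds) <- ids
  if (strategy == "random") {
    folds[sample(ids)] <- rep_len(seq_len(k), length(ids))
    return(folds)
  }
  cond <- interaction(manifest$pattern, manifest$nominal_dose, drop = TRUE)
  for (members in split(ids, cond)) {
    if (length(members) < k) {
      stop("condition with ", length(members),
           " replicates cannot be stratified over ", k, " folds",
           call. = FALSE)
    }
    perm <- sample(members)
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  folds
}

#' Cross-validate a survival model over flask folds
#'
#' For each fold, fits the model to the training quadrats, predicts the
#' held-out quadrat counts, and records the test root-mean-square error
#' and mean absolute error on the count scale.
#'
#' @param table a pooled quadrat table (included quadrats).
#' @param model `"LQ"` or `"MLQ"`.
#' @param folds fold assignment from [assign_folds()].
#' @param ... passed to [fit_survival_model()].
#' @return data.frame with one row per fold: `fold`, `nc0`, `alpha`,
#'   `beta`, `delta`, `aic`, `bic`, `rmse`, `mae`, `n_train`, `n_test`;
#'   the per-fold `grid_fit`s are attached as attribute `fits`.
#' @export
cross_validate <- function(table, model = c("LQ", "MLQ"), folds, ...) {
  model <- match.arg(model)
  if ("included" %in% names(table)) table <- table[table$included, ]
  fold_of_row <- folds[as.character(table$flask_id)]
  if (any(is.na(fold_of_row))) {
    stop("table contains flasks without a fold assignment", call. = FALSE)
  }
  # design built once; folds subset matrix rows
  des <- build_design(table, model)
  ks <- sort(unique(folds))
  rows <- vector("list", length(ks))
  fits <- vector("list", length(ks))
  for (f in seq_along(ks)) {
    test <- fold_of_row == ks[f]
    if (!any(test)) {
      warning("fold ", ks[f], " has no test quadrats; skipped")
      next
    }
    X_train <- des$X[!test, , drop = FALSE]
    reduced <- FALSE
    if (model == "MLQ" && all(X_train[, "Dd"] == 0)) {
      X_train <- X_train[, colnames(X_train) != "Dd", drop = FALSE]
      reduced <- TRUE
    }
    fit <- fit_poisson_glm(X_train, des$y[!test], model = model, ...)
    fit$reduced <- reduced
    if (reduced) fit$params["delta"] <- NA_real_
    X_test <- des$X[test, names(fit$coefficients), drop = FALSE]
    pred <- drop(exp(X_test %*% fit$coefficients))
    err <- des$y[test] - pred
    fits[[f]] <- fit
    rows[[f]] <- data.frame(
      fold = ks[f], nc0 = fit$params[["nc0"]], alpha = fit$params[["alpha"]],
      beta = fit$params[["beta"]], delta = fit$params[["delta"]],
      aic = fit$aic, bic = fit$bic,
      rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
      n_train = sum(!test), n_test = sum(test)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "model") <- model
  out
}

#' Repeated k-fold cross-validation of the LQ and MLQ models
#'
#' Repeats stratified k-fold cross-validation with independent fold
#' assignments drawn from a seeded stream, and summarises every model
#' parameter and error metric by its mean and percentile (2.5%, 97.5%)
#' confidence interval over the pooled repeat x fold values.
#'
#' @param table pooled quadrat table.
#' @param models models to compare.
#' @param n_repeats number of CV repetitions.
#' @param k folds per repetition.
#' @param seed master integer seed.
#' @param strategy fold assignment strategy, see [assign_folds()].
#' @param level confidence level for the percentile intervals.
#' @return an object of class `grid_cv`: list with `folds_values` (per
#'   model, data.frame of all repeat x fold results), `summary` (per
#'   model, data.frame quantity/mean/lower/upper), `n_repeats`, `k`,
#'   `seed`.
#' @export
repeat_cv <- function(table, models = c("LQ", "MLQ"), n_repeats = 100,
                      k = 4, seed = 1, strategy = "replicate",
                      level = 0.95) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  if ("included" %in% names(table)) table <- table[table$included, ]
  manifest <- unique(data.frame(flask_id = table$flask_id,
                                pattern = table$pattern,
                                nominal_dose = table$nominal_dose))
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  per_model <- stats::setNames(vector("list", length(models)), models)
  for (r in seq_len(n_repeats)) {
    folds <- assign_folds(manifest, k = k, seed = repeat_seeds[r],
                          strategy = strategy)
    for (m in models) {
      res <- cross_validate(table, m, folds)
      res$repeat_id <- r
      attr(res, "fits") <- NULL
      per_model[[m]][[r]] <- res
    }
  }
  folds_values <- lapply(per_model, function(x) {
    out <- do.call(rbind, x)
    rownames(out) <- NULL
    out
  })
  a <- (1 - level) / 2
  summaries <- lapply(folds_values, function(df) {
    qty <- c("nc0", "alpha", "beta", "delta", "aic", "bic", "rmse", "mae")
    do.call(rbind, lapply(qty, function(q) {
      v <- df[[q]]
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NULL)
      data.frame(quantity = q, mean = mean(v),
                 lower = stats::quantile(v, a, names = FALSE),
                 upper = stats::quantile(v, 1 - a, names = FALSE))
    }))
  })
  structure(list(folds_values = folds_values, summary = summaries,
                 n_repeats = n_repeats, k = k, seed = seed, level = level),
            class = "grid_cv")
}

#' @export
print.grid_cv <- function(x, ...) {
  cat(sprintf("Repeated %d-fold cross-validation, %d repeats (seed %d)\n",
              x$k, x$n_repeats, x$seed))
  for (m in names(x$summary)) {
    cat(" ", m, "model:\n")
    s <- x$summary[[m]]
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-6s %10.4f (%.4f, %.4f)\n", s$quantity[i],
                  s$mean[i], s$lower[i], s$upper[i]))
    }
  }
  invisible(x)
}

#' Compare LQ and MLQ predictions by paired t-tests per dose group
#'
#' Two-tailed paired Student's t-test on the per-quadrat predicted
#' counts of the two models, within each nominal-dose group. A
#' zero-variance difference vector (identical predictions) is reported
#' with `t = 0`, `p = 1` and `degenerate = TRUE`.
#'
#' @param pred_lq,pred_mlq aligned prediction vectors.
#' @param group grouping vector (e.g. nominal dose), same length.
#' @param paired use a paired test (default); otherwise Welch.
#' @return data.frame with `group`, `n`, `mean_diff`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
compare_models_ttest <- function(pred_lq, pred_mlq, group, paired = TRUE) {
  if (length(pred_lq) != length(pred_mlq) ||
      length(pred_lq) != length(group)) {
    stop("prediction vectors and group must be aligned", call. = FALSE)
  }
  idx <- split(seq_along(group), group)
  out <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    diff <- pred_lq[i] - pred_mlq[i]
    degenerate <- length(i) < 2 ||
      stats::sd(diff) <= 1e-9 * (abs(mean(diff)) + 1e-12)
    if (degenerate) {
      return(data.frame(group = g, n = length(i), mean_diff = mean(diff),
                        t = 0, df = length(i) - 1, p = 1, degenerate = TRUE))
    }
    tt <- if (paired) {
      stats::t.test(pred_lq[i], pred_mlq[i], paired = TRUE)
    } else {
      stats::t.test(pred_lq[i], pred_mlq[i])
    }
    data.frame(group = g, n = length(i), mean_diff = mean(diff),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Model-selection report for LQ versus MLQ
#'
#' Tabulates AIC/BIC of full-data fits and, when available, the
#' cross-validated RMSE/MAE, with deltas computed as LQ minus MLQ
#' (positive deltas favour MLQ). The preferred model is the one with
#' the lower AIC; exact ties are reported as `"tie"`.
#'
#' @param fit_lq,fit_mlq `grid_fit`s on the same data.
#' @param cv optional `grid_cv` with both models.
#' @return list with `table` (data.frame metric/LQ/MLQ/delta) and
#'   `preferred`.
#' @export
model_selection_report <- function(fit_lq, fit_mlq, cv = NULL) {
  stopifnot(inherits(fit_lq, "grid_fit"), inherits(fit_mlq, "grid_fit"))
  if (fit_lq$n_obs != fit_mlq$n_obs) {
    stop("fits are not comparable: different n_obs", call. = FALSE)
  }
  tab <- data.frame(
    metric = c("logLik", "AIC", "BIC"),
    LQ = c(fit_lq$loglik, fit_lq$aic, fit_lq$bic),
    MLQ = c(fit_mlq$loglik, fit_mlq$aic, fit_mlq$bic)
  )
  if (!is.null(cv)) {
    for (metric in c("rmse", "mae")) {
      m_lq <- mean(cv$folds_values$LQ[[metric]])
      m_mlq <- mean(cv$folds_values$MLQ[[metric]])
      tab <- rbind(tab, data.frame(metric = toupper(metric), LQ = m_lq,
                                   MLQ = m_mlq))
    }
  }
  tab$delta <- tab$LQ - tab$MLQ
  d_aic <- fit_lq$aic - fit_mlq$aic
  preferred <- if (d_aic > 0) "MLQ" else if (d_aic < 0) "LQ" else "tie"
  list(table = tab, preferred = preferred)
}
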