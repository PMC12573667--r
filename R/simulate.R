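#' Configure a synthetic GRID survival experiment
#'
#' Bundles the study design: field patterns, nominal doses, replicates,
#' flask geometry, quadrat size, and the cell-survival parameters of the
#' generating model. Defaults reproduce the in vitro A549 design this
#' package targets: 3 patterns (open, striped, dotted) x 3 nominal doses
#' (2, 5, 10 Gy) x 4 replicates plus 4 unirradiated controls, a 64 x 47
#' mm analysable flask area tiled by 1 mm^2 quadrats.
#'
#' @param patterns field patterns to simulate.
#' @param nominal_doses nominal doses, Gy.
#' @param replicates replicates per pattern x dose condition.
#' @param controls number of unirradiated control flasks.
#' @param region flask analysis region `c(width, height)`, mm.
#' @param quadrat_size quadrat side length, mm.
#' @param spacing pixel spacing of the rendered maps, mm/px.
#' @param params generating survival parameters: list with `nc0`
#'   (expected colonies per quadrat at zero dose), `alpha` (1/Gy), `beta`
#'   (1/Gy^2), `delta` (1/(Gy cm)).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(patterns = c("open", "striped", "dotted"),
                              nominal_doses = c(2, 5, 10),
                              replicates = 4,
                              controls = 4,
                              region = c(64, 47),
                              quadrat_size = 1,
                              spacing = 0.2,
                              params = list(nc0 = 2.448, alpha = 0.2539,
                                            beta = 0.0388, delta = 0)) {
  patterns <- match.arg(patterns, c("open", "striped", "dotted"),
                        several.ok = TRUE)
  if (any(nominal_doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (quadrat_size <= 0) stop("quadrat_size must be positive", call. = FALSE)
  params <- .check_params(params)
  structure(
    list(patterns = patterns, nominal_doses = nominal_doses,
         replicates = replicates, controls = controls, region = region,
         quadrat_size = quadrat_size, spacing = spacing, params = params),
    class = "experiment_config"
  )
}

.check_params <- function(params) {
  for (nm in c("nc0", "alpha", "beta")) {
    if (is.null(params[[nm]])) stop("params$", nm, " is required", call. = FALSE)
  }
  if (is.null(params$delta)) params$delta <- 0
  if (params$nc0 <= 0) stop("nc0 must be positive", call. = FALSE)
  params
}

#' @export
print.experiment_config <- function(x, ...) {
  n_irr <- length(x$patterns) * length(x$nominal_doses) * x$replicates
  cat(sprintf("Experiment config: %d irradiated flasks + %d controls\n",
              n_irr, x$controls))
  cat(sprintf("  patterns: %s; doses: %s Gy; %d replicates\n",
              paste(x$patterns, collapse = ", "),
              paste(x$nominal_doses, collapse = ", "), x$replicates))
  cat(sprintf("  region %g x %g mm, %g mm quadrats, %g mm/px maps\n",
              x$region[1], x$region[2], x$quadrat_size, x$spacing))
  cat(sprintf("  params: NC0 %g, alpha %g /Gy, beta %g /Gy^2, delta %g /(Gy cm)\n",
              x$params$nc0, x$params$alpha, x$params$beta, x$params$delta))
  invisible(x)
}

# Per-pixel expected colonies per mm^2 under the (M)LQ model.
.intensity_per_mm2 <- function(dose_values, dist_values, params, quadrat_area) {
  (params$nc0 / quadrat_area) *
    exp(-params$alpha * dose_values - params$beta * dose_values^2 -
          params$delta * dose_values * dist_values)
}

#' Simulate surviving-colony centroids on a flask
#'
#' Colonies are placed as an inhomogeneous Poisson point process whose
#' local intensity per unit area follows the modified linear-quadratic
#' survival model,
#' `lambda(x, y) = (NC0 / A) * exp(-alpha D - beta D^2 - delta D d)`,
#' with `D` the local dose (Gy), `d` the local distance to the nearest
#' peak rim (cm) and `A` the quadrat area the zero-dose rate `NC0` refers
#' to. Sampling uses thinning of a homogeneous process at the maximum
#' intensity, which is exact for inhomogeneous intensities. Colonies fall
#' only inside the map region.
#'
#' @param dose a [dose_map()].
#' @param dist a [distance_map()] co-registered with `dose`, or `NULL`
#'   for `d = 0` everywhere (open fields and controls).
#' @param params survival parameters (`nc0`, `alpha`, `beta`, `delta`);
#'   `nc0` is the expected count per quadrat of area `quadrat_area`.
#' @param quadrat_area quadrat area `nc0` refers to, mm^2 (default 1).
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `colony_set`: data.frame with `x_mm`,
#'   `y_mm` and attributes `flask_id`, `pattern`, `nominal_dose`,
#'   `region`.
#' @export
simulate_colonies <- function(dose, dist = NULL, params, quadrat_area = 1,
                              seed = NULL) {
  stopifnot(inherits(dose, "dose_map"))
  params <- .check_params(params)
  if (is.null(dist)) {
    dist_values <- 0 * dose$values
  } else {
    if (!identical(dim(dist$values), dim(dose$values))) {
      stop("dose and distance maps are not co-registered", call. = FALSE)
    }
    dist_values <- dist$values
  }
  if (!is.null(seed)) set.seed(seed)
  lam <- .intensity_per_mm2(dose$values, dist_values, params, quadrat_area)
  lam_max <- max(lam)
  width <- ncol(dose$values) * dose$spacing
  height <- nrow(dose$values) * dose$spacing
  n <- stats::rpois(1, lam_max * width * height)
  x <- stats::runif(n, 0, width)
  y <- stats::runif(n, 0, height)
  col_idx <- pmin(ncol(dose$values), pmax(1L, ceiling(x / dose$spacing)))
  row_idx <- pmin(nrow(dose$values), pmax(1L, ceiling(y / dose$spacing)))
  keep <- stats::runif(n) * lam_max <= lam[cbind(row_idx, col_idx)]
  structure(
    data.frame(x_mm = x[keep], y_mm = y[keep]),
    flask_id = dose$flask_id, pattern = dose$pattern,
    nominal_dose = dose$nominal_dose, region = c(width, height),
    class = c("colony_set", "data.frame")
  )
}

# Render a pattern's 5 Gy reference dose map and its distance map once;
# other nominal doses are obtained by exact relative rescaling.
.pattern_reference <- function(pattern, config, reference_dose = 5) {
  spec <- grid_pattern_spec(pattern)
  mask <- make_pattern_mask(spec, region = config$region,
                            spacing = config$spacing)
  dmap <- render_dose_map(mask, reference_dose, spec, spacing = config$spacing)
  if (pattern == "open") {
    dist <- distance_map(0 * dmap$values, config$spacing)
  } else {
    peaks <- segment_peaks(dmap)
    dist <- distance_to_peak_rim(peaks)
  }
  list(spec = spec, dose = dmap, dist = dist)
}

#' Simulate a full GRID survival experiment
#'
#' Generates, for every flask in the design, a dose map, a distance map
#' and a simulated colony set, together with a manifest table. Controls
#' receive an all-zero dose map; open fields (and controls) have all-zero
#' distance maps. A single master seed is split into independent
#' per-flask seeds so each flask is reproducible in isolation.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @return list with `flasks` (list of `list(dose, dist, colonies, ...)`)
#'   and `manifest` (data.frame: `flask_id`, `pattern`, `nominal_dose`,
#'   `replicate`).
#' @export
simulate_experiment <- function(config, seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  manifest <- .build_manifest(config)
  set.seed(seed)
  flask_seeds <- sample.int(.Machine$integer.max - 1L, nrow(manifest))
  refs <- lapply(stats::setNames(config$patterns, config$patterns),
                 .pattern_reference, config = config)
  flasks <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pat <- manifest$pattern[i]
    dose_i <- manifest$nominal_dose[i]
    if (pat == "control") {
      ref <- refs[[config$patterns[1]]]
      dmap <- dose_map(0 * ref$dose$values, config$spacing,
                       pattern = "control", nominal_dose = 0,
                       flask_id = manifest$flask_id[i])
      dist <- distance_map(0 * ref$dose$values, config$spacing)
    } else {
      ref <- refs[[pat]]
      dmap <- rescale_dose_map(ref$dose, dose_i)
      dmap$flask_id <- manifest$flask_id[i]
      dist <- ref$dist
    }
    colonies <- simulate_colonies(dmap, dist, config$params,
                                  quadrat_area = config$quadrat_size^2,
                                  seed = flask_seeds[i])
    flasks[[i]] <- list(dose = dmap, dist = dist, colonies = colonies,
                        flask_id = manifest$flask_id[i], pattern = pat,
                        nominal_dose = dose_i,
                        replicate = manifest$replicate[i])
  }
  list(flasks = flasks, manifest = manifest)
}

.build_manifest <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      nominal_dose = config$nominal_doses,
                      pattern = config$patterns,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("pattern", "nominal_dose", "replicate")]
  if (config$controls > 0) {
    grid <- rbind(grid,
                  data.frame(pattern = "control", nominal_dose = 0,
                             replicate = seq_len(config$controls)))
  }
  grid$flask_id <- sprintf("%s_%gGy_r%d", grid$pattern, grid$nominal_dose,
                           grid$replicate)
  grid[, c("flask_id", "pattern", "nominal_dose", "replicate")]
}

#' Draw Poisson quadrat counts under the (M)LQ model
#'
#' Given a quadrat table carrying mean dose `D` and mean distance `d`,
#' replaces (or fills) the colony count `NC` with a Poisson draw whose
#' mean is `nc0 * exp(-alpha D - beta D^2 - delta D d)` per quadrat. This
#' is the quadrat-level counterpart of [simulate_colonies()]: counts are
#' generated directly at the aggregated covariates, so a model fitted to
#' the same table estimates the generating parameters without
#' within-quadrat aggregation bias.
#'
#' @param table a quadrat table (see [partition_and_aggregate()]) with
#'   columns `D` and `d`.
#' @param params survival parameters (`nc0`, `alpha`, `beta`, `delta`).
#' @param seed optional integer seed.
#' @return the table with a fresh integer `NC` column.
#' @export
simulate_quadrat_counts <- function(table, params, seed = NULL) {
  params <- .check_params(params)
  if (!all(c("D", "d") %in% names(table))) {
    stop("table must have D and d columns", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- params$nc0 * exp(-params$alpha * table$D - params$beta * table$D^2 -
                           params$delta * table$D * table$d)
  table$NC <- stats::rpois(nrow(table), mu)
  table
}

#' Simulate study-scale quadrat data directly
#'
#' Builds the pooled quadrat analysis table for a whole experiment
#' design: per pattern, a dose map is rendered once at a 5 Gy reference,
#' peaks are segmented at 95% of the maximum, the distance-to-peak-rim
#' map is computed, and both are aggregated to quadrat means; other
#' nominal doses reuse the same geometry by exact relative scaling.
#' Counts are then drawn per quadrat with [simulate_quadrat_counts()].
#' This is the generator used for parameter-recovery studies; use
#' [simulate_experiment()] when individual colony centroids are needed.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @return a pooled quadrat table (data.frame) with columns `flask_id`,
#'   `pattern`, `nominal_dose`, `replicate`, `ix`, `iy`, `NC`, `D`, `d`,
#'   `included`.
#' @export
simulate_study_quadrats <- function(config, seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  manifest <- .build_manifest(config)
  refs <- lapply(stats::setNames(config$patterns, config$patterns),
                 function(p) {
                   ref <- .pattern_reference(p, config)
                   .aggregate_maps(ref$dose, ref$dist,
                                   quadrat_size = config$quadrat_size)
                 })
  set.seed(seed)
  flask_seeds <- sample.int(.Machine$integer.max - 1L, nrow(manifest))
  pieces <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pat <- manifest$pattern[i]
    base <- if (pat == "control") refs[[config$patterns[1]]] else refs[[pat]]
    tab <- base
    if (pat == "control") {
      tab$D <- 0
      tab$d <- 0
    } else {
      tab$D <- tab$D * manifest$nominal_dose[i] / 5
    }
    tab$flask_id <- manifest$flask_id[i]
    tab$pattern <- pat
    tab$nominal_dose <- manifest$nominal_dose[i]
    tab$replicate <- manifest$replicate[i]
    pieces[[i]] <- simulate_quadrat_counts(tab, config$params,
                                           seed = flask_seeds[i])
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "quadrat_size") <- config$quadrat_size
  attr(out, "grid_shape") <- attr(refs[[1]], "grid_shape")
  class(out) <- c("quadrat_table", "data.frame")
  out
}

#' Simulate radiochromic film calibration scans
#'
#' Generates per-replicate scanner intensities for film pieces exposed to
#' a series of calibration doses, in three colour channels. The
#' generating response is the netOD model `D = b netOD + c netOD^n`
#' (inverted numerically), with Gaussian noise of standard deviation
#' `noise_sd` added on the netOD scale, and intensities formed as
#' `I = (I_unexposed - I_background) * 10^-netOD + I_background` so the
#' film darkens with dose. At zero dose and zero noise the intensity
#' equals the unexposed reference.
#'
#' @param doses calibration doses, Gy (default the 0-10 Gy series used
#'   for EBT3 calibration).
#' @param response_params named list of per-channel `(b, c, n)` response
#'   coefficients (Gy); defaults give the red channel the strongest
#'   response, as observed for EBT3.
#' @param noise_sd netOD noise standard deviation (>= 0).
#' @param replicates film pieces per dose (default 8).
#' @param unexposed,background unexposed and opaque-background scanner
#'   intensities (16-bit scale).
#' @param seed optional integer seed.
#' @return data.frame `channel`, `dose`, `replicate`, `intensity`,
#'   `netod_true`, with attributes `unexposed`, `background`,
#'   `response_params`.
#' @export
simulate_calibration_films <- function(doses = c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10),
                                       response_params = list(
                                         red = c(b = 10, c = 50, n = 2.5),
                                         green = c(b = 30, c = 180, n = 2.8),
                                         blue = c(b = 90, c = 600, n = 3.2)),
                                       noise_sd = 0.002,
                                       replicates = 8,
                                       unexposed = 40000,
                                       background = 1000,
                                       seed = NULL) {
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ch in names(response_params)) {
    p <- response_params[[ch]]
    netod_true <- vapply(doses, .invert_netod_model, numeric(1),
                         b = p[["b"]], c = p[["c"]], n = p[["n"]])
    for (r in seq_len(replicates)) {
      netod_obs <- netod_true + stats::rnorm(length(doses), sd = noise_sd)
      out[[length(out) + 1]] <- data.frame(
        channel = ch, dose = doses, replicate = r,
        intensity = (unexposed - background) * 10^(-netod_obs) + background,
        netod_true = netod_true
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "unexposed") <- unexposed
  attr(out, "background") <- background
  attr(out, "response_params") <- response_params
  out
}

# netOD solving D = b x + c x^n for a given dose (monotone in x >= 0)
.invert_netod_model <- function(dose, b, c, n) {
  if (dose <= 0) return(0)
  f <- function(x) b * x + c * x^n - dose
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}
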