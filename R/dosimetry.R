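#' Net optical density of an exposed film
#'
#' The film's dose-responsive signal:
#' `netOD = log10((I_unexposed - I_background) / (I_exposed - I_background))`,
#' where the background intensity is the opaque-film reading of the
#' scanner. Works element-wise on scalars, vectors or matrices.
#'
#' @param exposed intensity of the exposed film.
#' @param unexposed intensity of the matched unexposed film.
#' @param background scanner background (opaque) intensity, default 0.
#' @return netOD, same shape as `exposed`.
#' @export
compute_netod <- function(exposed, unexposed, background = 0) {
  if (any(unexposed <= background)) {
    stop("unexposed intensity must exceed background", call. = FALSE)
  }
  if (any(exposed <= background)) {
    stop("exposed intensity at or below background: saturated or invalid scan",
         call. = FALSE)
  }
  log10((unexposed - background) / (exposed - background))
}

#' Mean intensity in a square region of interest
#'
#' Arithmetic mean of the pixel intensities inside a square ROI centred
#' at a physical position, e.g. the central 4 x 4 mm^2 patch of a
#' calibration film piece.
#'
#' @param image intensity matrix (rows index y, columns x).
#' @param center ROI centre `c(x, y)` in mm; defaults to the image
#'   centre.
#' @param roi_size ROI side length, mm (default 4).
#' @param spacing pixel spacing, mm/px.
#' @return mean pixel intensity.
#' @export
extract_roi_mean <- function(image, center = NULL, roi_size = 4,
                             spacing = 25.4 / 300) {
  image <- as.matrix(image)
  w <- ncol(image) * spacing
  h <- nrow(image) * spacing
  if (is.null(center)) center <- c(w / 2, h / 2)
  half <- roi_size / 2
  if (center[1] - half < 0 || center[1] + half > w ||
      center[2] - half < 0 || center[2] + half > h) {
    stop("ROI extends outside the image", call. = FALSE)
  }
  cols <- which((seq_len(ncol(image)) - 0.5) * spacing >= center[1] - half &
                  (seq_len(ncol(image)) - 0.5) * spacing < center[1] + half)
  rows <- which((seq_len(nrow(image)) - 0.5) * spacing >= center[2] - half &
                  (seq_len(nrow(image)) - 0.5) * spacing < center[2] + half)
  mean(image[rows, cols])
}

#' Fit a dose-versus-netOD calibration curve
#'
#' Least-squares fit of the standard radiochromic-film response
#' `D(netOD) = b * netOD + c * netOD^n` with `n > 1`, which passes
#' through the origin (zero dose at zero netOD) and is strictly
#' increasing for positive coefficients. For a fixed exponent `n` the
#' model is linear in `(b, c)`, so the fit profiles the linear
#' coefficients and optimises the residual sum of squares over `n`
#' alone, which is robust and accurate to numerical tolerance on
#' noiseless data.
#'
#' @param netod netOD values (one per calibration measurement).
#' @param dose corresponding doses, Gy; at least 4 distinct values
#'   including 0.
#' @param channel colour channel label.
#' @param n_range search interval for the exponent.
#' @return an object of class `calibration_curve`: coefficients `b`,
#'   `c`, `n`, plus `r2`, `rmse` (Gy), `netod_range` and `channel`.
#' @export
fit_calibration <- function(netod, dose, channel = "red",
                            n_range = c(1.05, 8)) {
  if (length(netod) != length(dose)) {
    stop("netod and dose lengths differ", call. = FALSE)
  }
  if (length(unique(dose)) < 4 || !any(dose == 0)) {
    stop("need >= 4 distinct doses including 0", call. = FALSE)
  }
  if (all(netod[dose > 0] == 0)) {
    stop("degenerate input: netOD is zero at positive doses", call. = FALSE)
  }
  # noise can push zero-dose netOD slightly negative; the power term is
  # evaluated on the non-negative part so fractional exponents stay real
  pw <- pmax(netod, 0)
  rss_for_n <- function(n) {
    X <- cbind(netod, pw^n)
    fit <- stats::lm.fit(X, dose)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(rss_for_n, n_range, tol = 1e-10)
  n <- opt$minimum
  co <- stats::lm.fit(cbind(netod, pw^n), dose)$coefficients
  pred <- co[1] * netod + co[2] * pw^n
  rss <- sum((dose - pred)^2)
  tss <- sum((dose - mean(dose))^2)
  structure(
    list(channel = channel, b = unname(co[1]), c = unname(co[2]), n = n,
         r2 = 1 - rss / tss, rmse = sqrt(rss / length(dose)),
         netod_range = range(netod)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [%s]: D = %.4g netOD + %.4g netOD^%.4g\n",
              x$channel, x$b, x$c, x$n))
  cat(sprintf("  R^2 = %.5f, RMSE = %.4g Gy, netOD range [%.4g, %.4g]\n",
              x$r2, x$rmse, x$netod_range[1], x$netod_range[2]))
  invisible(x)
}

#' Calibrate every colour channel and select the best
#'
#' Fits a [fit_calibration()] curve per channel from replicate film
#' measurements and flags the channel with the highest R^2 (ties broken
#' by lowest RMSE) as selected; for EBT3 film this is typically the red
#' channel.
#'
#' @param films calibration data.frame with columns `channel`, `dose`,
#'   `intensity` (e.g. from [simulate_calibration_films()]).
#' @param unexposed,background reference intensities; defaults taken
#'   from the data attributes when present.
#' @return list with `curves` (per channel), `selected` (channel name)
#'   and `summary` (data.frame of channel, r2, rmse, selected).
#' @export
fit_calibration_channels <- function(films,
                                     unexposed = attr(films, "unexposed"),
                                     background = attr(films, "background")) {
  if (is.null(unexposed)) stop("unexposed reference intensity required",
                               call. = FALSE)
  if (is.null(background)) background <- 0
  channels <- unique(films$channel)
  curves <- lapply(channels, function(ch) {
    sub <- films[films$channel == ch, ]
    netod <- compute_netod(sub$intensity, unexposed, background)
    fit_calibration(netod, sub$dose, channel = ch)
  })
  names(curves) <- channels
  r2 <- vapply(curves, `[[`, numeric(1), "r2")
  rmse <- vapply(curves, `[[`, numeric(1), "rmse")
  selected <- channels[order(-r2, rmse)][1]
  list(curves = curves, selected = selected,
       summary = data.frame(channel = channels, r2 = r2, rmse = rmse,
                            selected = channels == selected,
                            row.names = NULL))
}

#' Convert a netOD map to an absorbed-dose map
#'
#' Applies the calibration function element-wise. netOD values outside
#' the calibration range are clipped to it (with a warning) rather than
#' extrapolated; negative dose predictions are clipped to zero.
#'
#' @param netod netOD matrix (or vector/scalar).
#' @param curve a [fit_calibration()] curve.
#' @param spacing pixel spacing mm/px for the returned map.
#' @param channel channel of the netOD data; must match the curve if
#'   given.
#' @param ... labels passed to [dose_map()] (`pattern`, `nominal_dose`,
#'   `flask_id`).
#' @return a [dose_map()] when `netod` is a matrix, else a numeric
#'   vector of doses (Gy).
#' @export
netod_to_dose <- function(netod, curve, spacing = 25.4 / 300,
                          channel = NULL, ...) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.null(channel) && !identical(channel, curve$channel)) {
    stop("channel mismatch: data are ", channel, " but curve is ",
         curve$channel, call. = FALSE)
  }
  x <- netod
  rng <- curve$netod_range
  if (any(x < rng[1] - 1e-12) || any(x > rng[2] + 1e-12)) {
    warning("netOD values outside calibration range were clipped")
  }
  x <- pmin(pmax(x, rng[1]), rng[2])
  d <- pmax(0, curve$b * x + curve$c * pmax(x, 0)^curve$n)
  if (is.matrix(netod)) {
    dose_map(matrix(d, nrow(netod)), spacing, ...)
  } else {
    d
  }
}

#' Rescale a dose map to another nominal dose
#'
#' GRID dose maps are measured at one nominal dose (5 Gy here) and maps
#' for other nominal doses are derived by exact relative scaling, which
#' preserves the PVDR and all dose ratios.
#'
#' @param map a [dose_map()] with positive `nominal_dose`.
#' @param target_nominal target nominal dose, Gy (> 0).
#' @return the rescaled [dose_map()].
#' @export
rescale_dose_map <- function(map, target_nominal) {
  stopifnot(inherits(map, "dose_map"))
  if (!is.numeric(target_nominal) || target_nominal <= 0) {
    stop("target nominal dose must be positive", call. = FALSE)
  }
  if (is.na(map$nominal_dose) || map$nominal_dose <= 0) {
    stop("map nominal_dose must be positive for relative scaling",
         call. = FALSE)
  }
  map$values <- map$values * (target_nominal / map$nominal_dose)
  map$nominal_dose <- target_nominal
  map
}
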