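#' Segment peak regions of a dose map
#'
#' Peak pixels are those at or above `threshold_fraction` of the reference
#' maximum dose. The reference maximum defaults to the 99.9th percentile
#' of the map (a robust maximum, insensitive to isolated noise spikes on
#' scanned film; equal to the true maximum on noiseless synthetic maps).
#' The threshold comparison is inclusive, so boundary pixels exactly at
#' the cutoff count as peak.
#'
#' @param map a [dose_map()].
#' @param threshold_fraction fraction of the reference maximum defining a
#'   peak, default 0.95.
#' @param reference_max reference maximum dose, Gy. Supply a pooled value
#'   when peaks should be defined per GRID configuration rather than per
#'   flask; `NULL` (default) uses the robust maximum of this map.
#' @return an object of class `peak_mask`: a logical matrix with
#'   attributes `threshold_fraction`, `reference_max` and `spacing`.
#' @export
segment_peaks <- function(map, threshold_fraction = 0.95,
                          reference_max = NULL) {
  stopifnot(inherits(map, "dose_map"))
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("threshold_fraction must be in (0, 1]", call. = FALSE)
  }
  if (is.null(reference_max)) {
    reference_max <- stats::quantile(map$values, 0.999, names = FALSE)
  }
  if (reference_max <= 0) {
    warning("all-zero dose map: peak mask is empty")
    mask <- matrix(FALSE, nrow(map$values), ncol(map$values))
  } else {
    mask <- map$values >= threshold_fraction * reference_max
  }
  structure(mask, threshold_fraction = threshold_fraction,
            reference_max = reference_max, spacing = map$spacing,
            class = c("peak_mask", "matrix", "array"))
}

#' Euclidean distance to the nearest peak-region rim
#'
#' For every non-peak pixel, the shortest Euclidean distance (in cm) to
#' the nearest peak pixel; zero inside peak regions. If the mask covers
#' the whole map (an open field) every distance is zero. Computed with an
#' exact Euclidean distance transform.
#'
#' @param mask a `peak_mask` from [segment_peaks()], or any logical
#'   matrix.
#' @param spacing pixel spacing, mm/px; taken from the mask attribute if
#'   present.
#' @return an object of class `distance_map`: list with `values` (cm
#'   matrix) and `spacing` (mm/px).
#' @export
distance_to_peak_rim <- function(mask, spacing = attr(mask, "spacing")) {
  m <- unclass(mask)
  storage.mode(m) <- "double"
  if (is.null(spacing) || !is.numeric(spacing) || spacing <= 0) {
    stop("a positive pixel spacing (mm/px) is required", call. = FALSE)
  }
  if (!any(m > 0)) {
    stop("empty peak mask: distance to peak is undefined", call. = FALSE)
  }
  # distance of each non-peak pixel to the nearest peak pixel, in pixels
  d_px <- EBImage::imageData(EBImage::distmap(1 - m))
  distance_map(matrix(d_px, nrow(m)) * spacing / 10, spacing)
}

#' Construct a distance-map object
#'
#' @param values matrix of distances to the nearest peak rim, cm.
#' @param spacing pixel spacing, mm/px.
#' @return an object of class `distance_map`.
#' @export
distance_map <- function(values, spacing) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing), class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("Distance map: %d x %d px at %g mm/px, range [0, %.3g] cm\n",
              nrow(x$values), ncol(x$values), x$spacing, max(x$values)))
  invisible(x)
}

#' Peak and valley dose statistics
#'
#' Mean peak dose, mean valley dose and their ratio (PVDR). The valley
#' region is taken as pixels at or below `valley_fraction_max` of the
#' reference maximum and at least `valley_min_distance_mm` from the peak
#' rim, which excludes the penumbra. For an effectively uniform field
#' (empty valley) the PVDR is reported as 1 with `uniform = TRUE`.
#'
#' @param map a [dose_map()].
#' @param mask a `peak_mask`; default segments `map` at 95%.
#' @param valley_fraction_max valley dose cutoff as a fraction of the
#'   reference maximum, default 0.25.
#' @param valley_min_distance_mm minimum distance from the peak rim for a
#'   valley pixel, mm, default 2.
#' @return list with `peak_mean`, `valley_mean` (Gy), `pvdr`, `uniform`.
#' @export
peak_valley_stats <- function(map, mask = segment_peaks(map),
                              valley_fraction_max = 0.25,
                              valley_min_distance_mm = 2) {
  stopifnot(inherits(map, "dose_map"))
  m <- unclass(mask)
  if (!any(m)) stop("empty peak mask", call. = FALSE)
  peak_mean <- mean(map$values[m])
  ref <- attr(mask, "reference_max")
  if (is.null(ref)) ref <- max(map$values)
  if (all(m)) {
    return(list(peak_mean = peak_mean, valley_mean = peak_mean, pvdr = 1,
                uniform = TRUE))
  }
  dist_cm <- distance_to_peak_rim(mask, spacing = map$spacing)$values
  valley <- !m & map$values <= valley_fraction_max * ref &
    dist_cm * 10 >= valley_min_distance_mm
  if (!any(valley)) {
    warning("no valley pixels below the dose cutoff; reporting PVDR = 1")
    return(list(peak_mean = peak_mean, valley_mean = peak_mean, pvdr = 1,
                uniform = TRUE))
  }
  valley_mean <- mean(map$values[valley])
  list(peak_mean = peak_mean, valley_mean = valley_mean,
       pvdr = peak_mean / valley_mean, uniform = FALSE)
}

#' Percent peak-dose loss and valley scatter
#'
#' Collimation both attenuates the peak relative to the open field and
#' scatters dose into the valleys. `loss` is the percentage of the
#' open-field dose lost in the peak, `100 * (1 - peak_mean / open_dose)`;
#' `scatter` is the valley dose as a percentage of the peak dose,
#' `100 * valley_mean / peak_mean`.
#'
#' @param open_dose mean open-field dose, Gy (> 0).
#' @param peak_mean mean peak dose, Gy (> 0).
#' @param valley_mean mean valley dose, Gy.
#' @return list with `loss` and `scatter`, both percentages.
#' @export
percent_peak_loss_and_scatter <- function(open_dose, peak_mean, valley_mean) {
  if (!is.numeric(open_dose) || open_dose <= 0) {
    stop("open_dose must be positive", call. = FALSE)
  }
  if (!is.numeric(peak_mean) || peak_mean <= 0) {
    stop("peak_mean must be positive", call. = FALSE)
  }
  list(loss = 100 * (1 - peak_mean / open_dose),
       scatter = 100 * valley_mean / peak_mean)
}

#' Central dose profile across replicate maps
#'
#' Extracts the dose profile along the central line of each map (along x
#' at the central y by default), optionally normalised to its maximum,
#' and summarises replicates by the per-position mean and a percentile
#' confidence interval.
#'
#' @param maps a list of [dose_map()]s with identical geometry.
#' @param axis `"x"` (profile varies along x) or `"y"`.
#' @param normalize divide each profile by its own maximum.
#' @param level confidence level for the percentile interval.
#' @return data.frame with `position_mm`, `mean`, `lower`, `upper`.
#' @export
central_profile <- function(maps, axis = c("x", "y"), normalize = TRUE,
                            level = 0.95) {
  axis <- match.arg(axis)
  if (inherits(maps, "dose_map")) maps <- list(maps)
  if (length(maps) < 1) stop("at least one map required", call. = FALSE)
  dims <- vapply(maps, function(m) dim(m$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("maps have mismatched geometry", call. = FALSE)
  }
  spacing <- maps[[1]]$spacing
  profs <- vapply(maps, function(m) {
    v <- m$values
    p <- if (axis == "x") v[ceiling(nrow(v) / 2), ] else v[, ceiling(ncol(v) / 2)]
    if (normalize) p <- p / max(p)
    p
  }, numeric(if (axis == "x") dims[2, 1] else dims[1, 1]))
  profs <- matrix(profs, ncol = length(maps))
  a <- (1 - level) / 2
  data.frame(
    position_mm = (seq_len(nrow(profs)) - 0.5) * spacing,
    mean = rowMeans(profs),
    lower = apply(profs, 1, stats::quantile, probs = a, names = FALSE),
    upper = apply(profs, 1, stats::quantile, probs = 1 - a, names = FALSE)
  )
}
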