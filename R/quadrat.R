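#' Bring colony centroids into the dose-map millimetre frame
#'
#' Colony scans and film scans share a fixed scanner position, so
#' registration is translation-only. Pixel coordinates are converted to
#' mm with `25.4 / dpi` mm per pixel (the resolution difference between
#' e.g. 1200 dpi colony scans and 300 dpi film scans is absorbed by the
#' conversion) and then shifted by `offset`.
#'
#' @param colonies data.frame with `x_mm`/`y_mm` columns (already in mm)
#'   or `x_px`/`y_px` columns (pixels).
#' @param dpi scan resolution, dots per inch; required for pixel input.
#' @param offset translation `c(dx, dy)` in mm applied after conversion.
#' @return the colonies with `x_mm`, `y_mm` in the common frame.
#' @export
register_to_common_frame <- function(colonies, dpi = NULL, offset = c(0, 0)) {
  if (all(c("x_px", "y_px") %in% names(colonies))) {
    if (is.null(dpi)) {
      dpi <- attr(colonies, "source_resolution")
    }
    if (is.null(dpi) || !is.numeric(dpi) || dpi <= 0) {
      stop("pixel-coordinate input requires a positive dpi", call. = FALSE)
    }
    colonies$x_mm <- colonies$x_px * 25.4 / dpi
    colonies$y_mm <- colonies$y_px * 25.4 / dpi
  } else if (!all(c("x_mm", "y_mm") %in% names(colonies))) {
    stop("colonies must have x_mm/y_mm or x_px/y_px columns", call. = FALSE)
  }
  colonies$x_mm <- colonies$x_mm + offset[1]
  colonies$y_mm <- colonies$y_mm + offset[2]
  colonies
}

# Quadrat means of a dose map and distance map: data.frame(ix, iy, D, d)
# with a grid_shape attribute (n_x, n_y). Means are over the dose/distance
# pixels whose centres fall inside each quadrat cell.
.aggregate_maps <- function(dose, dist = NULL, quadrat_size = 1) {
  s <- dose$spacing
  v <- dose$values
  n_qx <- as.integer(floor(ncol(v) * s / quadrat_size + 1e-9))
  n_qy <- as.integer(floor(nrow(v) * s / quadrat_size + 1e-9))
  if (n_qx < 1 || n_qy < 1) stop("quadrat grid is empty", call. = FALSE)
  px_x <- (seq_len(ncol(v)) - 0.5) * s
  px_y <- (seq_len(nrow(v)) - 0.5) * s
  qx <- as.integer(floor(px_x / quadrat_size)) + 1L
  qy <- as.integer(floor(px_y / quadrat_size)) + 1L
  keep_x <- qx <= n_qx
  keep_y <- qy <= n_qy
  v <- v[keep_y, keep_x, drop = FALSE]
  qx <- qx[keep_x]
  qy <- qy[keep_y]
  idx <- as.vector(outer(qy, (qx - 1L) * n_qy, `+`))  # column-major linear id
  npx <- as.vector(rowsum(rep(1, length(idx)), idx))
  full <- data.frame(
    ix = rep(seq_len(n_qx), each = n_qy),
    iy = rep(seq_len(n_qy), times = n_qx),
    D = as.vector(rowsum(as.vector(v), idx)) / npx
  )
  if (!is.null(dist)) {
    dv <- dist$values[keep_y, keep_x, drop = FALSE]
    full$d <- as.vector(rowsum(as.vector(dv), idx)) / npx
  } else {
    full$d <- 0
  }
  attr(full, "grid_shape") <- c(n_qx, n_qy)
  attr(full, "quadrat_size") <- quadrat_size
  full
}

#' Partition a flask into quadrats and aggregate counts and covariates
#'
#' Tiles the common mm frame with square quadrats (`[x, x+s) x [y, y+s)`
#' half-open cells, so every centroid maps to exactly one quadrat),
#' counts colony centroids per quadrat, and averages the dose and
#' distance pixels whose centres fall inside each quadrat. A quadrat is
#' `included` only if its cell lies entirely inside `overlap`, the
#' common region of the cell flask and the dose film.
#'
#' @param colonies a `colony_set` (or data.frame with `x_mm`, `y_mm`) in
#'   the map frame.
#' @param dose a [dose_map()].
#' @param dist a [distance_map()] co-registered with `dose`, or `NULL`
#'   for `d = 0`.
#' @param quadrat_size quadrat side, mm (default 1).
#' @param overlap overlap region `c(xmin, xmax, ymin, ymax)` in mm, or
#'   `NULL` for the full frame.
#' @return a `quadrat_table`: data.frame with `flask_id`, `pattern`,
#'   `nominal_dose`, `ix`, `iy`, `NC`, `D`, `d`, `included` and
#'   attributes `grid_shape`, `quadrat_size`.
#' @export
partition_and_aggregate <- function(colonies, dose, dist = NULL,
                                    quadrat_size = 1, overlap = NULL) {
  stopifnot(inherits(dose, "dose_map"))
  if (!is.numeric(quadrat_size) || quadrat_size <= 0) {
    stop("quadrat_size must be positive", call. = FALSE)
  }
  if (!is.null(dist) && !identical(dim(dist$values), dim(dose$values))) {
    stop("dose and distance maps are not co-registered", call. = FALSE)
  }
  tab <- .aggregate_maps(dose, dist, quadrat_size)
  shape <- attr(tab, "grid_shape")
  n_qx <- shape[1]; n_qy <- shape[2]
  cix <- as.integer(floor(colonies$x_mm / quadrat_size)) + 1L
  ciy <- as.integer(floor(colonies$y_mm / quadrat_size)) + 1L
  inside <- cix >= 1L & cix <= n_qx & ciy >= 1L & ciy <= n_qy
  lin <- (cix[inside] - 1L) * n_qy + ciy[inside]
  tab$NC <- tabulate(lin, nbins = n_qx * n_qy)
  if (is.null(overlap)) {
    tab$included <- TRUE
  } else {
    x0 <- (tab$ix - 1L) * quadrat_size
    y0 <- (tab$iy - 1L) * quadrat_size
    tab$included <- x0 >= overlap[1] & (x0 + quadrat_size) <= overlap[2] &
      y0 >= overlap[3] & (y0 + quadrat_size) <= overlap[4]
    if (!any(tab$included)) warning("empty overlap region: no included quadrats")
  }
  tab$flask_id <- dose$flask_id
  tab$pattern <- dose$pattern
  tab$nominal_dose <- dose$nominal_dose
  tab <- tab[, c("flask_id", "pattern", "nominal_dose", "ix", "iy",
                 "NC", "D", "d", "included")]
  attr(tab, "grid_shape") <- shape
  attr(tab, "quadrat_size") <- quadrat_size
  class(tab) <- c("quadrat_table", "data.frame")
  tab
}

#' Pool quadrat tables across flasks and conditions
#'
#' Concatenates per-flask quadrat tables for joint analysis, keeping
#' only included quadrats. All tables must share the quadrat size.
#'
#' @param tables list of `quadrat_table`s.
#' @return a pooled `quadrat_table` (possibly empty).
#' @export
join_conditions <- function(tables) {
  if (length(tables) == 0) {
    out <- data.frame(flask_id = character(), pattern = character(),
                      nominal_dose = numeric(), ix = integer(),
                      iy = integer(), NC = integer(), D = numeric(),
                      d = numeric(), included = logical())
    class(out) <- c("quadrat_table", "data.frame")
    return(out)
  }
  sizes <- vapply(tables, function(t) attr(t, "quadrat_size") %||% NA_real_,
                  numeric(1))
  if (length(unique(sizes[!is.na(sizes)])) > 1) {
    stop("incompatible tables: quadrat sizes differ", call. = FALSE)
  }
  out <- do.call(rbind, lapply(tables, function(t) {
    as.data.frame(t)[t$included, , drop = FALSE]
  }))
  rownames(out) <- NULL
  attr(out, "quadrat_size") <- sizes[!is.na(sizes)][1]
  class(out) <- c("quadrat_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
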