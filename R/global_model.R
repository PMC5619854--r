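#' Per-pixel statistics over an image stack
#'
#' Computes the mean, unbiased sample variance and index of dispersion
#' (variance/mean) of the counts at each pixel across all images in a
#' rotation series, using only pixels whose per-image mask is `TRUE`
#' (i.e. pixels not predicted to contain reflection intensity).  A second
#' mask marks pixels usable for the global background model: those to which
#' strictly more than `min_images` images contributed.  When the stack has
#' fewer images than that threshold allows, the requirement is relaxed to
#' `max(1, n_images - 1)` so that short scans still produce a model.
#'
#' @param stack An image stack: a list with `images` (list of equal-shape
#'   non-negative integer matrices) and optionally `masks` (list of logical
#'   matrices, `TRUE` = background-usable pixel; default all `TRUE`).
#' @param min_images Minimum number of contributing images a pixel must
#'   exceed to be usable (default 10).
#' @return An object of class `pixel_statistics`: matrices `mean`,
#'   `variance`, `dispersion`, integer matrix `n_contrib`, logical matrix
#'   `usable`, and the effective threshold `min_images_used`.
#' @export
accumulate_mean <- function(stack, min_images = 10L) {
  stack <- as_image_stack(stack)
  n_img <- length(stack$images)
  dm <- dim(stack$images[[1]])
  s1 <- matrix(0, dm[1], dm[2])
  s2 <- matrix(0, dm[1], dm[2])
  n <- matrix(0L, dm[1], dm[2])
  for (k in seq_len(n_img)) {
    img <- stack$images[[k]]
    m <- stack$masks[[k]]
    s1 <- s1 + ifelse(m, img, 0)
    s2 <- s2 + ifelse(m, img * img, 0)
    n <- n + m
  }
  mean_img <- ifelse(n > 0, s1 / pmax(n, 1L), NA_real_)
  # unbiased sample variance (n - 1 denominator); needs n >= 2
  var_img <- ifelse(n >= 2, pmax(s2 - n * mean_img^2, 0) / pmax(n - 1L, 1L),
                    NA_real_)
  disp <- ifelse(n >= 2 & !is.na(mean_img) & mean_img > 0,
                 var_img / mean_img, NA_real_)
  eff <- if (n_img <= min_images) max(1L, n_img - 1L) else as.integer(min_images)
  structure(list(mean = mean_img, variance = var_img, dispersion = disp,
                 n_contrib = n, usable = n > eff, n_images = n_img,
                 min_images_used = eff),
            class = "pixel_statistics")
}

#' @export
print.pixel_statistics <- function(x, ...) {
  cat(sprintf("Pixel statistics over %d images (%d x %d)\n", x$n_images,
              nrow(x$mean), ncol(x$mean)))
  cat(sprintf("  usable pixels: %d (n_contrib > %d)\n", sum(x$usable),
              x$min_images_used))
  md <- stats::median(x$dispersion, na.rm = TRUE)
  if (is.finite(md)) cat(sprintf("  median index of dispersion: %.3f\n", md))
  invisible(x)
}

# validate / normalise a stack argument
as_image_stack <- function(stack) {
  if (!is.list(stack) || is.null(stack$images) || length(stack$images) == 0)
    stop("stack must be a list with at least one image in $images")
  dm <- dim(stack$images[[1]])
  for (img in stack$images) {
    if (!identical(dim(img), dm)) stop("all images must have the same shape")
    if (any(img < 0)) stop("counts must be non-negative")
  }
  if (is.null(stack$masks)) {
    stack$masks <- rep(list(matrix(TRUE, dm[1], dm[2])), length(stack$images))
  } else {
    if (length(stack$masks) != length(stack$images))
      stop("masks must match images one-to-one")
    for (m in stack$masks)
      if (!identical(dim(m), dm)) stop("mask shape mismatch")
  }
  stack
}

#' Forward polar transform
#'
#' Redistributes the counts of a detector image onto the polar grid using
#' precomputed overlap fractions.  Masked pixels contribute nothing.  Each
#' cell records the accumulated counts (`values`) and the accumulated
#' fractional pixel area (`weight`); `values / weight` is the
#' area-normalised cell value, so partially covered cells are not biased
#' low.  The transform conserves counts: the total over all cells equals
#' the total over unmasked pixels.
#'
#' A cell is `valid` when its weight reaches `valid_frac` of the weight it
#' would receive with nothing masked (stored in the fractions object), so
#' cells that are mostly shadowed by masks or off the detector edge are
#' flagged for the later fill stage.
#'
#' @param image Numeric detector matrix.
#' @param mask Logical matrix, `TRUE` = use pixel; `NULL` for all.
#' @param fractions An [pixel_overlap_fractions()] object for this geometry.
#' @param valid_frac Minimum fraction of full-coverage weight for a cell to
#'   count as observed (default 0.5).
#' @return An object of class `polar_image` with matrices `values`,
#'   `weight`, `norm` (values/weight, `NA` where empty), logical `valid`,
#'   and the originating `grid`.
#' @export
polar_transform <- function(image, mask = NULL, fractions, valid_frac = 0.5) {
  stopifnot(inherits(fractions, "overlap_fractions"))
  geom <- fractions$geom
  if (!identical(dim(image), c(geom$n_slow, geom$n_fast)))
    stop("image shape does not match the geometry of the overlap fractions")
  if (is.null(mask)) mask <- matrix(TRUE, geom$n_slow, geom$n_fast)
  if (!identical(dim(mask), dim(image))) stop("mask shape mismatch")
  grid <- fractions$grid
  ncell <- grid$n_res * grid$n_az
  acc <- cpp_accumulate_polar(fractions$pixel, fractions$cell, fractions$frac,
                              as.numeric(image), as.logical(mask), ncell)
  values <- matrix(acc$values, grid$n_res, grid$n_az)
  weight <- matrix(acc$weight, grid$n_res, grid$n_az)
  wfull <- matrix(fractions$wfull, grid$n_res, grid$n_az)
  valid <- weight >= valid_frac * wfull & wfull > 0 & weight > 0
  norm <- ifelse(weight > 0, values / weight, NA_real_)
  structure(list(values = values, weight = weight, wfull = wfull,
                 norm = norm, valid = valid, grid = grid),
            class = "polar_image")
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("Polar image: %d x %d (radius x azimuth), %d valid cells, total %.6g counts\n",
              x$grid$n_res, x$grid$n_az, sum(x$valid), sum(x$values)))
  invisible(x)
}

#' Wrapped azimuthal median filter
#'
#' Replaces each valid polar cell's area-normalised value by the median over
#' itself and its `window` nearest valid neighbours along the same
#' constant-resolution row, with circular wrapping at the row ends.  This
#' removes high-valued pixel outliers (zingers, badly predicted reflection
#' tails) while leaving the azimuthally smooth ice-ring signal intact.
#' Invalid cells are excluded from neighbour sets and remain invalid.  Rows
#' with fewer than `window + 1` valid cells are left unchanged.
#'
#' @param p A [polar_transform()] result.
#' @param window Number of neighbours N in the median window (default 10;
#'   the window is the cell itself plus its N nearest wrapped valid
#'   neighbours).
#' @return A `polar_image` with filtered `norm` (and `values` rescaled to
#'   `norm * weight`).
#' @export
median_filter_columns <- function(p, window = 10L) {
  stopifnot(inherits(p, "polar_image"), window >= 1)
  norm <- p$norm
  norm[!p$valid | is.na(norm)] <- 0  # ignored by the filter: invalid cells skipped
  filtered <- cpp_median_filter_az(norm, p$valid, as.integer(window))
  out <- p
  out$norm <- ifelse(p$valid, filtered, p$norm)
  out$values <- ifelse(p$valid, filtered * p$weight, p$values)
  out
}

#' Diffusion fill of missing polar cells
#'
#' Completes the polar image over its invalid cells by solving Laplace's
#' equation with the valid cells as Dirichlet boundary data, via Jacobi
#' iteration: every missing cell is repeatedly replaced by the mean of its
#' 4-neighbours (azimuth wraps circularly, radius does not) until the
#' largest update falls below `tol` times the value range of the valid
#' cells.  Valid cells are never altered.  The discrete maximum principle
#' guarantees filled values stay within the range of the boundary data.
#'
#' Unknown cells start from the mean of the valid cells in their own
#' constant-resolution row (falling back to the overall valid mean for rows
#' with no data), which is an accurate guess for radially structured
#' backgrounds and shortens the iteration considerably; the converged
#' solution does not depend on it.  The Laplace domain is restricted to
#' cells that overlap the detector at all: polar cells wholly off the
#' panel (e.g. the full-circle completion of an off-centre beam geometry)
#' are given the row-mean value directly, since no detector pixel ever
#' reads them back.
#'
#' @param p A `polar_image`.
#' @param tol Convergence tolerance, relative to the valid-cell value range
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 10000); hitting it raises a
#'   warning and sets `converged = FALSE`.
#' @return A fully valid `polar_image` with attributes `n_iter` and
#'   `converged`.
#' @export
fill_missing_diffusion <- function(p, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(p, "polar_image"))
  if (!any(p$valid)) stop("cannot fill: no valid cells")
  norm <- p$norm
  vv <- norm[p$valid]
  rng <- diff(range(vv))
  abs_tol <- tol * max(rng, .Machine$double.eps)
  row_init <- vapply(seq_len(nrow(norm)), function(r) {
    v <- norm[r, p$valid[r, ]]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  row_init[is.na(row_init)] <- mean(vv)
  init <- matrix(row_init, nrow(norm), ncol(norm))
  norm[!p$valid | is.na(norm)] <- init[!p$valid | is.na(norm)]
  domain <- if (is.null(p$wfull)) matrix(TRUE, nrow(norm), ncol(norm))
            else p$wfull > 0
  domain <- domain | p$valid
  res <- cpp_diffusion_fill(norm, p$valid, domain, abs_tol,
                            as.integer(max_iter))
  if (!res$converged)
    warning("diffusion fill did not converge within ", max_iter, " iterations")
  out <- p
  out$norm <- res$values
  wfull <- ifelse(p$weight > 0, p$weight, NA)
  out$values <- res$values * ifelse(is.na(wfull), 0, wfull)
  out$valid <- matrix(TRUE, p$grid$n_res, p$grid$n_az)
  attr(out, "n_iter") <- res$n_iter
  attr(out, "converged") <- res$converged
  out
}

#' Inverse polar transform
#'
#' Maps a (fully valid) polar image back to the detector: every pixel
#' receives the overlap-weighted mean of the area-normalised values of the
#' cells it intersects.  Because overlap fractions per pixel sum to one, a
#' constant polar field maps back to the same constant, and a forward/
#' inverse round trip conserves total counts (up to the extra azimuthal
#' smoothing inherent in regridding).  Pixels with no overlap (inside the
#' beam-centre exclusion disc) get value 0 and are flagged in the model
#' mask.
#'
#' @param p A `polar_image`, normally after [fill_missing_diffusion()].
#' @param fractions The same [pixel_overlap_fractions()] used forward.
#' @return An object of class `background_model` with matrix `b` (>= 0),
#'   logical `valid` (pixels covered by the grid) and provenance fields.
#' @export
inverse_polar_transform <- function(p, fractions) {
  stopifnot(inherits(p, "polar_image"), inherits(fractions, "overlap_fractions"))
  geom <- fractions$geom
  npix <- geom$n_slow * geom$n_fast
  sc <- cpp_scatter_detector(fractions$pixel, fractions$cell, fractions$frac,
                             as.numeric(p$norm), npix)
  w <- matrix(sc$wsum, geom$n_slow, geom$n_fast)
  b <- matrix(sc$values, geom$n_slow, geom$n_fast)
  b <- ifelse(w > 0, b / w, 0)
  b <- pmax(b, 0)
  structure(list(b = b, valid = w > 0, geom = geom, grid = p$grid,
                 provenance = list()),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Global background model: %d x %d px, range [%.4g, %.4g] counts/px\n",
              nrow(x$b), ncol(x$b), min(x$b[x$valid]), max(x$b[x$valid])))
  if (length(x$provenance))
    cat(sprintf("  built from %s images, min_images %s, median window %s\n",
                x$provenance$n_images, x$provenance$min_images,
                x$provenance$median_window))
  invisible(x)
}

#' @export
plot.background_model <- function(x, ...) {
  graphics::image(x$b, useRaster = TRUE, asp = ncol(x$b) / nrow(x$b),
                  xlab = "slow", ylab = "fast",
                  main = "Global background model", ...)
  invisible(x)
}

#' Build the global background model
#'
#' Composes the full static background pipeline: masked per-pixel mean over
#' the stack ([accumulate_mean()]), forward polar regrid
#' ([polar_transform()]), wrapped azimuthal median filter
#' ([median_filter_columns()]), Laplace diffusion fill
#' ([fill_missing_diffusion()]) and inverse regrid
#' ([inverse_polar_transform()]).  The result is a smoothly varying
#' per-pixel background shape `b` which is later scaled per reflection.
#' The whole pipeline is deterministic given its inputs.
#'
#' @param stack Image stack (see [accumulate_mean()]); per-image masks
#'   should be `FALSE` on predicted reflection foreground pixels.
#' @param geom A [detector_geometry()].
#' @param min_images Usability threshold for [accumulate_mean()].
#' @param median_window Azimuthal median window N (default 10).
#' @param diffusion_tol,diffusion_max_iter Fill convergence controls.
#' @param grid Optional [polar_grid()]; default built from `geom`.
#' @param fractions Optional precomputed [pixel_overlap_fractions()]
#'   (reused across calls for speed).
#' @param valid_frac Polar-cell coverage threshold (see
#'   [polar_transform()]).
#' @return A `background_model`; `$statistics` holds the
#'   [accumulate_mean()] result, `$provenance` the parameters used.
#' @export
build_global_model <- function(stack, geom, min_images = 10L,
                               median_window = 10L, diffusion_tol = 1e-6,
                               diffusion_max_iter = 10000L, grid = NULL,
                               fractions = NULL, valid_frac = 0.5) {
  stopifnot(inherits(geom, "detector_geometry"))
  stats <- accumulate_mean(stack, min_images = min_images)
  if (is.null(fractions)) {
    if (is.null(grid)) grid <- polar_grid(geom)
    fractions <- pixel_overlap_fractions(geom, grid)
  }
  mean_img <- stats$mean
  mean_img[is.na(mean_img)] <- 0
  usable <- stats$usable & !is.na(stats$mean)
  p <- polar_transform(mean_img, usable, fractions, valid_frac = valid_frac)
  p <- median_filter_columns(p, window = median_window)
  p <- fill_missing_diffusion(p, tol = diffusion_tol,
                              max_iter = diffusion_max_iter)
  model <- inverse_polar_transform(p, fractions)
  model$statistics <- stats
  model$provenance <- list(n_images = length(stack$images),
                           min_images = min_images,
                           median_window = median_window,
                           diffusion_tol = diffusion_tol,
                           valid_frac = valid_frac,
                           n_res = fractions$grid$n_res,
                           n_az = fractions$grid$n_az)
  model
}
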