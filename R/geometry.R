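#' Detector geometry
#'
#' Describes a flat single-panel photon-counting detector placed
#' perpendicular to the beam.  The geometry maps every pixel to a scattering
#' angle and hence a resolution (d-spacing) via Bragg's law
#' \eqn{d = \lambda / (2 \sin\theta)} with \eqn{2\theta = \arctan(r / D)},
#' where \eqn{r} is the radial distance of the pixel from the beam centre in
#' mm and \eqn{D} the sample-to-detector distance.
#'
#' Pixel coordinates are 0-based: pixel \eqn{(i, j)} occupies the half-open
#' square \eqn{[i, i+1) \times [j, j+1)} in slow/fast units, with its centre
#' at \eqn{(i + 0.5, j + 0.5)}.  The beam centre may lie off the panel.
#'
#' @param n_slow,n_fast Number of pixels along the slow and fast axes.
#' @param pixel_size Pixel edge length in mm (square pixels).
#' @param distance Sample-to-detector distance along the beam, mm.
#' @param beam_centre Length-2 numeric, beam centre in (slow, fast) pixel
#'   units.
#' @param wavelength X-ray wavelength in Angstrom.
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry(256, 256, pixel_size = 0.2, distance = 80,
#'                           beam_centre = c(128, 128), wavelength = 1.0)
#' d <- resolution_map(geom)
#' @export
detector_geometry <- function(n_slow, n_fast, pixel_size, distance,
                              beam_centre, wavelength) {
  if (length(beam_centre) != 2L || !is.numeric(beam_centre))
    stop("beam_centre must be a numeric vector of length 2 (slow, fast)")
  vals <- c(n_slow = n_slow, n_fast = n_fast, pixel_size = pixel_size,
            distance = distance, wavelength = wavelength)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid geometry: n_slow, n_fast, pixel_size, distance and ",
         "wavelength must all be positive and finite")
  structure(list(n_slow = as.integer(n_slow), n_fast = as.integer(n_fast),
                 pixel_size = pixel_size, distance = distance,
                 beam_centre = as.numeric(beam_centre),
                 wavelength = wavelength),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("Detector geometry: %d x %d px, %.4g mm/px\n",
              x$n_slow, x$n_fast, x$pixel_size))
  cat(sprintf("  distance %.4g mm, wavelength %.4g A, beam centre (%.2f, %.2f) px\n",
              x$distance, x$wavelength, x$beam_centre[1], x$beam_centre[2]))
  invisible(x)
}

# radial distance of each pixel centre from the beam centre, in pixel units
pixel_radius <- function(geom) {
  ds <- (seq_len(geom$n_slow) - 0.5) - geom$beam_centre[1]
  df <- (seq_len(geom$n_fast) - 0.5) - geom$beam_centre[2]
  sqrt(outer(ds^2, df^2, `+`))
}

# azimuth of each pixel centre about the beam centre, radians in (-pi, pi]
pixel_azimuth <- function(geom) {
  ds <- (seq_len(geom$n_slow) - 0.5) - geom$beam_centre[1]
  df <- (seq_len(geom$n_fast) - 0.5) - geom$beam_centre[2]
  atan2(outer(rep(1, geom$n_slow), df), outer(ds, rep(1, geom$n_fast)))
}

# d-spacing for a radius given in pixel units (vectorised)
radius_to_d <- function(r_px, geom) {
  theta <- atan(r_px * geom$pixel_size / geom$distance) / 2
  geom$wavelength / (2 * sin(theta))
}

# pixel radius (in pixels) at which resolution d is observed
d_to_radius <- function(d, geom) {
  stheta <- geom$wavelength / (2 * d)
  tan(2 * asin(stheta)) * geom$distance / geom$pixel_size
}

#' Per-pixel resolution map
#'
#' Resolution (d-spacing, Angstrom) at every pixel centre.  The pixel
#' containing the beam centre has \eqn{2\theta = 0} and is returned as
#' `Inf`; downstream stages mask a small disc around the beam centre rather
#' than use such values.
#'
#' @param geom A [detector_geometry()].
#' @return An `n_slow` x `n_fast` numeric matrix of d-spacings.
#' @export
resolution_map <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  radius_to_d(pixel_radius(geom), geom)
}

#' Polar resampling grid
#'
#' A (radius x azimuth) grid over the detector.  Columns of constant radius
#' are lines of constant resolution, which is what makes azimuthal filtering
#' effective against ice rings.  The radial coordinate is the distance from
#' the beam centre in pixel units with uniform 1-px-wide bins by default, so
#' high-resolution pixels (large circumference per cell) are sampled more
#' coarsely along the ring than low-resolution ones.  Azimuth bins are
#' uniform over a full circle, starting at `az_offset - pi`.
#'
#' @param geom A [detector_geometry()].
#' @param n_res Number of radial bins; default two per pixel of maximal
#'   radius (detector corner furthest from the beam centre).  Half-pixel
#'   radial bins roughly halve the radial profile distortion of sharp
#'   rings compared with one-pixel bins, at modest cost.
#' @param n_az Number of azimuth bins (default 360).
#' @param az_offset Rotation of the azimuthal bin edges, radians.  The
#'   regridded image is equivariant under this rotation; it exists mainly to
#'   exercise the +/- pi seam handling.
#' @return An object of class `polar_grid` with elements `res_edges`
#'   (length `n_res + 1`, pixel units), `n_res`, `n_az`, `az0`.
#' @export
polar_grid <- function(geom, n_res = NULL, n_az = 360L, az_offset = 0) {
  stopifnot(inherits(geom, "detector_geometry"))
  corners_s <- c(0, geom$n_slow, 0, geom$n_slow) - geom$beam_centre[1]
  corners_f <- c(0, 0, geom$n_fast, geom$n_fast) - geom$beam_centre[2]
  rmax <- max(sqrt(corners_s^2 + corners_f^2))
  if (is.null(n_res)) n_res <- ceiling(2 * rmax)
  structure(list(n_res = as.integer(n_res), n_az = as.integer(n_az),
                 res_edges = seq(0, rmax, length.out = n_res + 1),
                 az0 = as.numeric(az_offset) - pi),
            class = "polar_grid")
}

#' Intersection of two convex polygons
#'
#' Sutherland-Hodgman clipping of one convex polygon by another.  Vertex
#' order of either argument may be clockwise or counter-clockwise; the
#' result is returned in counter-clockwise order.  Disjoint or degenerate
#' (zero-area) inputs give an empty polygon, never an error.
#'
#' @param subject,clip Numeric matrices with two columns (x, y), one vertex
#'   per row, describing convex polygons.
#' @return A two-column matrix of vertices of the intersection (0 rows if
#'   empty).
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(clip_polygon(sq, sq + 0.5))  # 0.25
#' @export
clip_polygon <- function(subject, clip) {
  subject <- as.matrix(subject)
  clip <- as.matrix(clip)
  stopifnot(ncol(subject) == 2, ncol(clip) == 2)
  if (nrow(subject) < 3 || nrow(clip) < 3)
    return(matrix(numeric(0), 0, 2))
  out <- cpp_clip_polygon(subject, clip)
  if (nrow(out) >= 3 && cpp_polygon_area(out) > 0) {
    # normalise to counter-clockwise
    xs <- out[, 1]; ys <- out[, 2]
    a <- sum(xs * ys[c(2:length(ys), 1)] - xs[c(2:length(xs), 1)] * ys)
    if (a < 0) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
    out
  } else {
    matrix(numeric(0), 0, 2)
  }
}

#' Polygon area
#'
#' Unsigned shoelace area of a simple polygon given as a two-column vertex
#' matrix.  Polygons with fewer than three vertices have area 0.
#'
#' @param poly Two-column numeric matrix of vertices.
#' @return Non-negative scalar area.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) return(0)
  cpp_polygon_area(poly)
}

#' Pixel / polar-cell overlap fractions
#'
#' For every detector pixel, the fraction of its (transformed) area falling
#' in each polar-grid cell.  Pixel corners are mapped to (azimuth, radius)
#' about the beam centre and the resulting straight-edged quadrilateral is
#' clipped against the cell rectangles; quadrilaterals spanning the
#' \eqn{\pm\pi} azimuth seam are unwrapped and clipped against periodic
#' copies of the cells, so no pixel is dropped at the seam.  Fractions for
#' each kept pixel sum to 1, which is what makes the forward and inverse
#' transforms count-conserving.
#'
#' Pixels with any corner within `min_radius` pixels of the beam centre are
#' excluded: the straight-edge approximation of the transformed
#' quadrilateral has error O(pixel/radius) and degenerates at the centre.
#'
#' @param geom A [detector_geometry()].
#' @param grid A [polar_grid()] for the same geometry.
#' @param min_radius Exclusion radius around the beam centre, pixels
#'   (default 2).
#' @return An object of class `overlap_fractions`: a list with integer
#'   vectors `pixel`, `cell` (1-based linear indices into the detector and
#'   polar matrices), numeric `frac`, the full-coverage cell weight `wfull`
#'   (sum of fractions per cell with no mask), and the grid/geometry used.
#' @export
pixel_overlap_fractions <- function(geom, grid, min_radius = 2) {
  stopifnot(inherits(geom, "detector_geometry"), inherits(grid, "polar_grid"))
  tr <- cpp_overlap_fractions(geom$n_slow, geom$n_fast,
                              geom$beam_centre[1], geom$beam_centre[2],
                              grid$res_edges, grid$n_az, grid$az0,
                              min_radius)
  ncell <- grid$n_res * grid$n_az
  wfull <- cpp_accumulate_polar(tr$pixel, tr$cell, tr$frac,
                                rep(0, geom$n_slow * geom$n_fast),
                                rep(TRUE, geom$n_slow * geom$n_fast),
                                ncell)$weight
  structure(list(pixel = tr$pixel, cell = tr$cell, frac = tr$frac,
                 wfull = wfull, geom = geom, grid = grid,
                 min_radius = min_radius),
            class = "overlap_fractions")
}

#' @export
print.overlap_fractions <- function(x, ...) {
  cat(sprintf("Overlap fractions: %d entries, %d x %d detector -> %d x %d polar grid\n",
              length(x$frac), x$geom$n_slow, x$geom$n_fast,
              x$grid$n_res, x$grid$n_az))
  invisible(x)
}
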