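# shared fixtures and independent oracles for the test suite

# small centred-beam geometry for fast regridding tests
small_geometry <- function(n = 64L) {
  detector_geometry(n, n, pixel_size = 0.2, distance = 80,
                    beam_centre = c(n / 2, n / 2), wavelength = 1.0)
}

# random convex polygon: convex hull of random points (>= 3 vertices)
random_convex_polygon <- function(n_pts = 8, scale = 1, centre = c(0, 0)) {
  repeat {
    pts <- cbind(stats::runif(n_pts, -scale, scale) + centre[1],
                 stats::runif(n_pts, -scale, scale) + centre[2])
    h <- grDevices::chull(pts)
    if (length(h) >= 3) return(pts[rev(h), , drop = FALSE])  # chull is clockwise
  }
}

# Independent convex-intersection area oracle: the intersection's vertices
# are the vertices of each polygon inside the other plus all pairwise edge
# intersections; their convex hull's shoelace area is the intersection
# area.  Shares no code path with the Sutherland-Hodgman clipper.
oracle_intersection_area <- function(a, b) {
  inside <- function(p, poly) {
    n <- nrow(poly)
    s <- 0
    for (i in seq_len(n)) {
      j <- i %% n + 1
      cr <- (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) -
            (poly[j, 2] - poly[i, 2]) * (p[1] - poly[i, 1])
      if (i == 1) s <- sign(cr)
      else if (cr * s < -1e-12) return(FALSE)
    }
    TRUE
  }
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(NULL)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12) return(NULL)
    p1 + t * d1
  }
  pts <- list()
  for (i in seq_len(nrow(a)))
    if (inside(a[i, ], b)) pts[[length(pts) + 1]] <- a[i, ]
  for (i in seq_len(nrow(b)))
    if (inside(b[i, ], a)) pts[[length(pts) + 1]] <- b[i, ]
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    p <- seg_int(a[i, ], a[i %% na + 1, ], b[j, ], b[j %% nb + 1, ])
    if (!is.null(p)) pts[[length(pts) + 1]] <- p
  }
  if (length(pts) < 3) return(0)
  m <- do.call(rbind, pts)
  h <- grDevices::chull(m)
  if (length(h) < 3) return(0)
  m <- m[h, , drop = FALSE]
  x <- m[, 1]; y <- m[, 2]
  abs(sum(x * y[c(2:length(y), 1)] - x[c(2:length(x), 1)] * y)) / 2
}

# hand-built polar image (for filter/fill unit tests)
fake_polar_image <- function(norm, valid = NULL, weight = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(norm), ncol(norm))
  if (is.null(weight)) weight <- matrix(1, nrow(norm), ncol(norm))
  grid <- structure(list(n_res = nrow(norm), n_az = ncol(norm),
                         res_edges = seq(0, nrow(norm)), az0 = -pi),
                    class = "polar_grid")
  structure(list(values = norm * weight, weight = weight,
                 wfull = matrix(1, nrow(norm), ncol(norm)),
                 norm = norm, valid = valid, grid = grid),
            class = "polar_image")
}

# a flat-background Poisson stack on a small geometry
flat_stack <- function(n = 32L, lambda = 20, n_images = 20L, seed = 1) {
  set.seed(seed)
  list(images = replicate(n_images, matrix(rpois(n * n, lambda), n, n),
                          simplify = FALSE))
}

# zero-intensity reflection design used by the bias experiments: spots in
# the resolution band containing the hexagonal rings of the presets
ring_band_spots <- function(n_images, n_per, seed) {
  set.seed(seed)
  n <- n_images * n_per
  radii <- runif(n, 455, 585)
  az <- runif(n, 58, 122) * pi / 180
  data.frame(image = rep(seq_len(n_images), each = n_per),
             slow = 320 + radii * cos(az), fast = 20 + radii * sin(az),
             intensity = 0, sigma = 1.5)
}

# resolution bins aligned so the hexagonal ring d-spacings sit mid-bin
# (ring spacing 0.228 A = 4 bins of 0.057 A)
ring_centred_edges <- function(w = 0.057) {
  seq(3.441 - w / 2 - 2 * w, 3.897 + w / 2 + 3 * w, by = w)
}
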