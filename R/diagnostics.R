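#' Intensity versus resolution
#'
#' Bins integrated intensities by resolution and reports the per-bin mean
#' with its standard error, flagging bins that overlap configured ice-ring
#' d-spacings.  On data integrated with a flat background model this plot
#' shows the characteristic ice-ring signature: a spike in mean intensity
#' at the ring resolution (background under the peak underestimated) with
#' dips either side (background overestimated as the ring intrudes into the
#' background frame).  An unbiased model shows a flat trend.
#'
#' @param d Per-reflection resolution (Angstrom).
#' @param intensity Per-reflection integrated intensity.
#' @param variance Optional per-reflection variance (carried into the
#'   output).
#' @param n_bins Number of resolution bins (default 20).
#' @param edges Optional explicit bin edges (overrides `n_bins`); useful
#'   for centring bins on known ice-ring d-spacings.
#' @param ring_d Numeric vector of ice-ring d-spacings to flag (default the
#'   inner hexagonal rings).  A bin is flagged when it contains a ring
#'   centre or lies within `ring_halfwidth` of one.
#' @param ring_halfwidth Half-width (Angstrom) of the flagged band around
#'   each ring (default 0.03).
#' @return An object of class `resolution_series`: a data frame with one
#'   row per non-empty bin (`d_mid`, `d_lo`, `d_hi`, `n`, `mean_I`, `se_I`,
#'   `ring`), with the raw points attached as attribute `"points"`.
#' @export
intensity_vs_resolution <- function(d, intensity, variance = NULL,
                                    n_bins = 20L, edges = NULL,
                                    ring_d = ice_ring_d_spacings$hexagonal[1:3],
                                    ring_halfwidth = 0.03) {
  keep <- is.finite(d) & is.finite(intensity)
  if (!any(keep)) stop("no finite (d, intensity) pairs to bin")
  d <- d[keep]
  intensity <- intensity[keep]
  if (is.null(edges)) {
    edges <- seq(min(d), max(d), length.out = n_bins + 1)
    edges[length(edges)] <- edges[length(edges)] + 1e-9
  } else {
    stopifnot(length(edges) >= 2, !is.unsorted(edges))
    n_bins <- length(edges) - 1L
  }
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(n_bins), function(k) {
    sel <- bin == k
    n <- sum(sel)
    if (n == 0) return(NULL)
    mi <- mean(intensity[sel])
    se <- if (n > 1) stats::sd(intensity[sel]) / sqrt(n) else NA_real_
    lo <- edges[k]; hi <- edges[k + 1]
    ring <- any(ring_d + ring_halfwidth >= lo & ring_d - ring_halfwidth <= hi)
    data.frame(d_mid = (lo + hi) / 2, d_lo = lo, d_hi = hi, n = n,
               mean_I = mi, se_I = se, ring = ring)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("resolution_series", "data.frame")
  attr(out, "points") <- data.frame(d = d, intensity = intensity)
  out
}

#' @export
plot.resolution_series <- function(x, ...) {
  pts <- attr(x, "points")
  graphics::plot(pts$d, pts$intensity, pch = ".", col = "grey60",
                 xlim = rev(range(pts$d)), xlab = "resolution d (A)",
                 ylab = "intensity", ...)
  graphics::lines(x$d_mid, x$mean_I, lwd = 2)
  graphics::abline(v = x$d_mid[x$ring], col = "red", lty = 3)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Fourth moment of the normalised structure-factor amplitude E
#'
#' For acentric reflections obeying Wilson statistics the intensity is
#' exponentially distributed and the fourth moment of
#' \eqn{E = \sqrt{I / \langle I \rangle}} equals 2; for a perfect twin
#' (intensities averaged over two independent lattices) it is 1.5.
#' Measurement errors inflate the observed moment by
#' \eqn{\sigma(I)^2 / \langle I \rangle^2}, so the expectation reported for
#' comparison is \eqn{2 + \sigma(I)^2/\langle I\rangle^2} per bin.
#' Normalisation is per resolution bin (binned Wilson normalisation);
#' negative intensities contribute to \eqn{\langle I \rangle} but are
#' clipped at zero in the moment numerator.
#'
#' @param intensity Acentric reflection intensities.
#' @param variance Optional intensity variances (for the inflated
#'   expectation; default 0).
#' @param d Optional resolutions; when `NULL` (default) a single bin is
#'   used.
#' @param n_bins Number of resolution bins when `d` is given (default 20).
#' @return An object of class `moment_series`: data frame with per-bin
#'   `n`, `mean_I`, `m4` (the observed fourth moment of E) and
#'   `m4_expected` (error-inflated untwinned expectation).  Bins with
#'   non-positive mean intensity are dropped with a flag attribute.
#' @export
fourth_moment_E <- function(intensity, variance = NULL, d = NULL,
                            n_bins = 20L) {
  if (is.null(variance)) variance <- rep(0, length(intensity))
  stopifnot(length(variance) == length(intensity))
  if (is.null(d)) {
    bin <- rep(1L, length(intensity))
    n_bins <- 1L
    mids <- NA_real_
  } else {
    stopifnot(length(d) == length(intensity))
    edges <- seq(min(d), max(d), length.out = n_bins + 1)
    edges[length(edges)] <- edges[length(edges)] + 1e-9
    bin <- findInterval(d, edges, rightmost.closed = TRUE)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
  }
  dropped <- 0L
  rows <- lapply(seq_len(n_bins), function(k) {
    sel <- bin == k
    n <- sum(sel)
    if (n == 0) return(NULL)
    mi <- mean(intensity[sel])
    if (mi <= 0) return(structure(list(), flagged = TRUE))
    e2 <- pmax(intensity[sel], 0) / mi
    m4 <- mean(e2^2)
    infl <- mean(variance[sel]) / mi^2
    data.frame(d_mid = mids[k], n = n, mean_I = mi, m4 = m4,
               m4_expected = 2 + infl)
  })
  flagged <- sum(vapply(rows, function(r) isTRUE(attr(r, "flagged")), TRUE))
  rows <- Filter(function(r) is.data.frame(r), rows)
  if (!length(rows)) stop("no bins with positive mean intensity")
  out <- do.call(rbind, rows)
  class(out) <- c("moment_series", "data.frame")
  attr(out, "n_flagged") <- flagged
  out
}

#' Index-of-dispersion report
#'
#' Summarises the per-pixel index of dispersion (variance / mean across
#' images) from [accumulate_mean()]: the overall median, the median per
#' resolution bin, and a ring/non-ring contrast (median dispersion in bins
#' overlapping configured ice-ring d-spacings against the median
#' elsewhere).  Static Poisson background has dispersion 1; pixels whose
#' rate drifts over the scan (e.g. growing ice rings) are over-dispersed,
#' exceeding 2 in severe cases.
#'
#' Bins are uniform in \eqn{1/d^2} (the usual crystallographic binning),
#' which keeps bin populations comparable where d diverges towards the
#' beam centre.
#'
#' @param stats A `pixel_statistics` object from [accumulate_mean()].
#' @param geom The [detector_geometry()].
#' @param n_bins Number of resolution bins (default 30).
#' @param ring_d Ice-ring d-spacings to contrast (default inner hexagonal).
#' @param ring_halfwidth Band half-width in Angstrom (default 0.03).
#' @return A list of class `dispersion_report`: `median_dispersion`,
#'   per-bin data frame `by_resolution` (`d_mid`, `n`, `median_dispersion`,
#'   `ring`), `ring_median`, `nonring_median`, `contrast`
#'   (ring - non-ring).
#' @export
dispersion_report <- function(stats, geom, n_bins = 30L,
                              ring_d = ice_ring_d_spacings$hexagonal[1:3],
                              ring_halfwidth = 0.03) {
  stopifnot(inherits(stats, "pixel_statistics"),
            inherits(geom, "detector_geometry"))
  disp <- stats$dispersion
  d_map <- resolution_map(geom)
  keep <- is.finite(disp) & is.finite(d_map)
  s2 <- 1 / d_map[keep]^2
  dv <- disp[keep]
  edges <- seq(min(s2), max(s2), length.out = n_bins + 1)
  edges[length(edges)] <- edges[length(edges)] + 1e-12
  bin <- findInterval(s2, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(n_bins), function(k) {
    sel <- bin == k
    if (!any(sel)) return(NULL)
    d_hi <- 1 / sqrt(edges[k]); d_lo <- 1 / sqrt(edges[k + 1])
    ring <- any(ring_d + ring_halfwidth >= d_lo &
                ring_d - ring_halfwidth <= d_hi)
    data.frame(d_mid = (d_lo + d_hi) / 2, n = sum(sel),
               median_dispersion = stats::median(dv[sel]), ring = ring)
  })
  by_res <- do.call(rbind, rows)
  ring_med <- stats::median(by_res$median_dispersion[by_res$ring])
  non_med <- stats::median(by_res$median_dispersion[!by_res$ring])
  structure(list(median_dispersion = stats::median(dv),
                 by_resolution = by_res,
                 ring_median = ring_med, nonring_median = non_med,
                 contrast = ring_med - non_med),
            class = "dispersion_report")
}

#' @export
print.dispersion_report <- function(x, ...) {
  cat(sprintf("Index of dispersion: overall median %.3f\n",
              x$median_dispersion))
  if (is.finite(x$contrast))
    cat(sprintf("  ring bins %.3f vs non-ring %.3f (contrast %+.3f)\n",
                x$ring_median, x$nonring_median, x$contrast))
  invisible(x)
}
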