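test_that("pixel statistics: means, masking rule and image-count threshold", {
  img <- matrix(7, 8, 8)
  st <- accumulate_mean(list(images = rep(list(img), 20)))
  expect_equal(st$mean, img)
  expect_equal(st$variance, matrix(0, 8, 8))
  expect_true(all(st$usable))

  # pixel masked in all but 5 of 50 images is excluded at min_images = 10
  set.seed(3)
  imgs <- replicate(50, matrix(rpois(16, 10), 4, 4), simplify = FALSE)
  masks <- replicate(50, matrix(TRUE, 4, 4), simplify = FALSE)
  for (k in 6:50) masks[[k]][2, 3] <- FALSE
  st <- accumulate_mean(list(images = imgs, masks = masks), min_images = 10)
  expect_false(st$usable[2, 3])
  expect_equal(st$n_contrib[2, 3], 5)
  expect_true(all(st$usable[-10]))

  # short stacks: threshold drops to n_images - 1
  st3 <- accumulate_mean(list(images = imgs[1:4]), min_images = 10)
  expect_equal(st3$min_images_used, 3L)
  expect_true(all(st3$usable))

  expect_error(accumulate_mean(list(images = list())), "at least one")
})

test_that("per-pixel dispersion of a Poisson stack centres on 1", {
  set.seed(5)
  stack <- list(images = replicate(200, matrix(rpois(1024, 10), 32, 32),
                                   simplify = FALSE))
  st <- accumulate_mean(stack)
  expect_equal(median(st$dispersion), 1, tolerance = 0.05)
  expect_equal(mean(st$dispersion), 1, tolerance = 0.02)
})

test_that("polar transform conserves counts and constant fields", {
  geom <- small_geometry(64)
  fr <- pixel_overlap_fractions(geom, polar_grid(geom))

  # all-masked image: nothing arrives
  p0 <- polar_transform(matrix(5, 64, 64), matrix(FALSE, 64, 64), fr)
  expect_equal(sum(p0$values), 0)
  expect_false(any(p0$valid))

  # uniform field: every valid cell's normalised value is the constant
  pu <- polar_transform(matrix(3.5, 64, 64), NULL, fr)
  expect_lt(max(abs(pu$norm[pu$valid] - 3.5)), 1e-6)

  # count conservation on random masked images
  set.seed(21)
  for (k in 1:5) {
    img <- matrix(rpois(64 * 64, 50), 64, 64)
    mask <- matrix(runif(64 * 64) > 0.3, 64, 64)
    kept <- mask & matrix(seq_len(64 * 64) %in% fr$pixel, 64, 64)
    p <- polar_transform(img, mask, fr)
    expect_equal(sum(p$values), sum(img[kept]), tolerance = 1e-6)
  }
  expect_error(polar_transform(matrix(1, 10, 10), NULL, fr), "shape")
})

test_that("azimuthal median filter is wrapped, robust and skips invalid cells", {
  # constant rows unchanged
  p <- fake_polar_image(matrix(10, 4, 30))
  expect_equal(median_filter_columns(p, 10)$norm, p$norm)

  # a single spike is removed entirely (stated purpose of the filter)
  norm <- matrix(10, 4, 30)
  norm[2, 17] <- 1000
  pf <- median_filter_columns(fake_polar_image(norm), 10)
  expect_equal(pf$norm[2, ], rep(10, 30))

  # wrapped-window brute-force oracle on random rows with invalid gaps
  set.seed(9)
  for (rep in 1:20) {
    n_az <- 40
    v <- matrix(rpois(n_az, 30), 1, n_az)
    valid <- matrix(runif(n_az) > 0.2, 1, n_az)
    w <- sample(c(2, 4, 10), 1)
    got <- median_filter_columns(fake_polar_image(v, valid), w)$norm
    idx <- which(valid[1, ])
    m <- length(idx)
    if (m >= w + 1) {
      lo <- w %/% 2
      for (t in seq_len(m)) {
        offs <- (t - lo):(t - lo + w)
        nb <- v[1, idx[(offs - 1) %% m + 1]]
        expect_equal(got[1, idx[t]], median(nb))
      }
    } else {
      expect_equal(got, v)  # too few valid cells: row left unchanged
    }
    expect_equal(got[1, !valid[1, ]], v[1, !valid[1, ]])  # invalid untouched
  }

  # idempotence on an already-filtered constant row
  pc <- median_filter_columns(p, 10)
  expect_equal(median_filter_columns(pc, 10)$norm, pc$norm)
})

test_that("diffusion fill solves Laplace with Dirichlet boundaries", {
  # one missing cell surrounded by v -> v
  norm <- matrix(4, 5, 8)
  valid <- matrix(TRUE, 5, 8)
  valid[3, 4] <- FALSE
  pf <- fill_missing_diffusion(fake_polar_image(norm, valid))
  expect_equal(pf$norm[3, 4], 4, tolerance = 1e-5)
  expect_true(all(pf$valid))

  # missing radial band between values a and b -> linear interpolation
  norm <- matrix(0, 12, 6)
  norm[1, ] <- 2; norm[12, ] <- 7
  valid <- matrix(FALSE, 12, 6)
  valid[c(1, 12), ] <- TRUE
  pf <- fill_missing_diffusion(fake_polar_image(norm, valid), tol = 1e-9)
  expect_equal(pf$norm[, 3], seq(2, 7, length.out = 12), tolerance = 1e-4)

  # discrete maximum principle on random validity patterns
  set.seed(13)
  for (rep in 1:5) {
    norm <- matrix(runif(15 * 20, 5, 9), 15, 20)
    valid <- matrix(runif(15 * 20) > 0.4, 15, 20)
    if (!any(valid)) next
    pf <- fill_missing_diffusion(fake_polar_image(norm, valid))
    expect_gte(min(pf$norm), min(norm[valid]) - 1e-9)
    expect_lte(max(pf$norm), max(norm[valid]) + 1e-9)
    expect_equal(pf$norm[valid], norm[valid])  # Dirichlet data untouched
  }

  expect_error(
    fill_missing_diffusion(fake_polar_image(matrix(1, 3, 3),
                                            matrix(FALSE, 3, 3))),
    "no valid cells")
})

test_that("inverse transform round-trips constants, counts and sharp rings", {
  geom <- small_geometry(64)
  fr <- pixel_overlap_fractions(geom, polar_grid(geom))
  on_grid <- matrix(seq_len(64 * 64) %in% fr$pixel, 64, 64)

  # constant round trip
  p <- polar_transform(matrix(6, 64, 64), NULL, fr)
  p <- fill_missing_diffusion(p)
  m <- inverse_polar_transform(p, fr)
  expect_lt(max(abs(m$b[on_grid] - 6)), 1e-6)
  expect_true(all(m$b[!on_grid] == 0))  # off-grid pixels flagged zero
  expect_false(any(m$valid[!on_grid]))

  # total counts conserved through the round trip
  set.seed(31)
  img <- matrix(rpois(64 * 64, 40), 64, 64)
  p <- fill_missing_diffusion(polar_transform(img, NULL, fr))
  m <- inverse_polar_transform(p, fr)
  expect_equal(sum(m$b[on_grid]), sum(img[on_grid]), tolerance = 1e-6)

  # a sharp ring keeps its peak radius (within 1 px) and is azimuthally
  # smoothed, not shifted
  r <- icebg:::pixel_radius(geom)
  ring <- 100 * exp(-(r - 20)^2 / (2 * 1.5^2))
  p <- fill_missing_diffusion(polar_transform(ring, NULL, fr))
  m <- inverse_polar_transform(p, fr)
  prof <- tapply(m$b[on_grid], round(r[on_grid]), mean)
  peak_r <- as.numeric(names(prof))[which.max(prof)]
  expect_lte(abs(peak_r - 20), 1)
})

test_that("build_global_model recovers flat, radial and ringed backgrounds", {
  geom <- small_geometry(64)

  # flat Poisson background: model ~ lambda with averaging-limited error
  n_img <- 25
  set.seed(41)
  stack <- list(images = replicate(n_img, matrix(rpois(64 * 64, 20), 64, 64),
                                   simplify = FALSE))
  model <- build_global_model(stack, geom)
  sel <- model$valid
  rms <- sqrt(mean((model$b[sel] - 20)^2))
  expect_lt(rms, 3 * sqrt(20) / sqrt(n_img))

  # noiseless radial background: < 5% relative error away from the centre
  r <- icebg:::pixel_radius(geom)
  lam <- 20 + 0.5 * r
  noiseless <- list(images = rep(list(lam), 12))
  model <- build_global_model(noiseless, geom)
  sel <- model$valid & r > 4
  expect_lt(max(abs(model$b[sel] - lam[sel]) / lam[sel]), 0.05)

  # image order must not matter (mean is order-invariant)
  m1 <- build_global_model(stack, geom)
  m2 <- build_global_model(list(images = rev(stack$images)), geom)
  expect_identical(m1$b, m2$b)
})

test_that("azimuthal model profile peaks at the simulated ring resolutions", {
  cfg <- default_presets("diffuse", n_images = 12, seed = 4)
  geom <- cfg$geometry
  sim <- simulate_stack(cfg)
  model <- build_global_model(sim$stack, geom)
  r <- icebg:::pixel_radius(geom)
  sel <- model$valid
  prof <- tapply(model$b[sel], round(r[sel] / 4) * 4, mean)
  rr <- as.numeric(names(prof))
  r_ring <- icebg:::d_to_radius(3.669, geom)
  in_ring <- abs(rr - r_ring) < 40
  baseline <- approx(rr[!in_ring], prof[!in_ring], xout = rr[in_ring])$y
  expect_gt(max(prof[in_ring] - baseline), 10)
})
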