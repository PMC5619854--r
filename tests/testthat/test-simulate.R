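test_that("simulation is deterministic and obeys Poisson statistics", {
  g <- detector_geometry(48, 48, 0.1, 100, c(24, 24), 1.0)
  cfg <- simulation_config(g, n_images = 100, seed = 42, base_background = 15)
  s1 <- simulate_stack(cfg)
  s2 <- simulate_stack(cfg)
  expect_identical(s1$stack$images, s2$stack$images)
  s3 <- simulate_stack(simulation_config(g, n_images = 100, seed = 43,
                                         base_background = 15))
  expect_false(identical(s1$stack$images, s3$stack$images))

  # flat base, no rings or spots: mean -> lambda, dispersion -> 1
  st <- accumulate_mean(s1$stack)
  expect_equal(mean(st$mean), 15, tolerance = 0.01)
  expect_equal(median(st$dispersion), 1, tolerance = 0.06)
  expect_equal(s1$truth$lambda_base, matrix(15, 48, 48))
  expect_equal(s1$truth$lambda_ring, matrix(0, 48, 48))
})

test_that("rings are placed at their configured d-spacings", {
  g <- detector_geometry(128, 128, 0.2, 40, c(64, 64), 1.0)
  cfg <- simulation_config(g, n_images = 1, seed = 1, base_background = 5,
                           rings = data.frame(d = 3.669, amplitude = 50,
                                              width = 0.05))
  sim <- simulate_stack(cfg)
  lam <- sim$truth$lambda_ring
  r <- icebg:::pixel_radius(g)
  peak_r <- mean(r[lam > 0.9 * max(lam)])
  expect_equal(peak_r, icebg:::d_to_radius(3.669, g), tolerance = 0.02)
  expect_true(all(sim$truth$lambda_base + lam >= 0))
})

test_that("azimuthal modulation and drift shape the ring as configured", {
  g <- detector_geometry(128, 128, 0.2, 40, c(64, 64), 1.0)
  cfg <- simulation_config(g, n_images = 4, seed = 1, base_background = 0.001,
                           rings = data.frame(d = 3.669, amplitude = 50,
                                              width = 0.05, modulation = 0.5,
                                              phase = 0),
                           ring_drift = c(0.5, 1, 1.5, 2))
  sim <- simulate_stack(cfg)
  az <- icebg:::pixel_azimuth(g)
  r <- icebg:::pixel_radius(g)
  ring <- sim$truth$lambda_ring
  peak <- abs(r - icebg:::d_to_radius(3.669, g)) < 1
  # modulation: brightest azimuths ~ (1+m)/(1-m) times the dimmest
  hi <- mean(ring[peak & cos(az) > 0.95])
  lo <- mean(ring[peak & cos(az) < -0.95])
  expect_equal(hi / lo, 1.5 / 0.5, tolerance = 0.1)
  # drift scales the ring part image by image
  expect_equal(sim$truth$drift, c(0.5, 1, 1.5, 2))
})

test_that("spots make shoeboxes with foreground masked out of the stack", {
  g <- detector_geometry(64, 64, 0.1, 100, c(32, 32), 1.0)
  spots <- data.frame(image = c(1, 2, 1), slow = c(20.3, 40.0, 100),
                      fast = c(30.6, 22.2, 10), intensity = c(500, 300, 100),
                      sigma = 1.2)
  cfg <- simulation_config(g, n_images = 2, seed = 5, base_background = 10,
                           spots = spots)
  expect_warning(sim <- simulate_stack(cfg), "off detector")
  expect_length(sim$shoeboxes, 2)  # third spot skipped
  expect_equal(nrow(sim$shoebox_table), 2)
  expect_equal(sim$shoebox_table$intensity_true, c(500, 300))

  sb <- sim$shoeboxes[[1]]
  # foreground pixels are masked out of that image's background mask
  msk <- sim$stack$masks[[1]][(sb$bbox[1] + 1):sb$bbox[2],
                              (sb$bbox[3] + 1):sb$bbox[4]]
  expect_true(all(!msk[sb$fg_mask]))
  expect_true(all(msk[!sb$fg_mask]))
  # the other image is unmasked there
  expect_true(all(sim$stack$masks[[2]][(sb$bbox[1] + 1):sb$bbox[2],
                                       (sb$bbox[3] + 1):sb$bbox[4]]))
  # counts in the shoebox equal the image block
  expect_identical(sb$counts,
                   sim$stack$images[[1]][(sb$bbox[1] + 1):sb$bbox[2],
                                         (sb$bbox[3] + 1):sb$bbox[4]])
  # the spot deposits roughly its intensity above background in the fg disc
  excess <- sum(sb$counts[sb$fg_mask]) - 10 * sum(sb$fg_mask)
  expect_lt(abs(excess - 500), 5 * sqrt(500 + 10 * sum(sb$fg_mask)))
})

test_that("detector gaps are masked everywhere", {
  g <- detector_geometry(32, 32, 0.1, 100, c(16, 16), 1.0)
  cfg <- simulation_config(g, n_images = 3, seed = 2, base_background = 8,
                           gaps = data.frame(slow0 = 10, slow1 = 12,
                                             fast0 = 0, fast1 = 32))
  sim <- simulate_stack(cfg)
  for (m in sim$stack$masks) {
    expect_true(all(!m[11:12, ]))
    expect_true(all(m[-(11:12), ]))
  }
})

test_that("presets encode the sharp/diffuse/faint/clean regimes", {
  sharp <- default_presets("sharp", n_images = 5)
  diffuse <- default_presets("diffuse", n_images = 5)
  faint <- default_presets("faint", n_images = 5)
  clean <- default_presets("clean", n_images = 5)

  expect_true(all(sharp$rings$width <= 0.02))
  expect_true(all(diffuse$rings$width >= 0.08))
  expect_true(all(faint$rings$width >= 0.08))
  expect_setequal(round(sharp$rings$d, 2), c(3.90, 3.67, 3.44))
  # only the sharp (irregular, drifting) preset is azimuthally modulated
  expect_true(all(sharp$rings$modulation > 0))
  expect_true(all(diffuse$rings$modulation == 0))
  expect_true(all(faint$rings$modulation == 0))
  expect_null(clean$rings)
  expect_true(any(sharp$ring_drift != 1))
  expect_true(all(diffuse$ring_drift == 1))
  # faint really is faint
  expect_lt(max(faint$rings$amplitude), min(diffuse$rings$amplitude))
})

test_that("drifting rings are over-dispersed, static background is not", {
  cfg <- default_presets("sharp", n_images = 30, seed = 9)
  sim <- simulate_stack(cfg)
  st <- accumulate_mean(sim$stack)
  rep <- dispersion_report(st, cfg$geometry)
  expect_gt(rep$ring_median, rep$nonring_median)
  expect_equal(rep$nonring_median, 1, tolerance = 0.05)
})
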