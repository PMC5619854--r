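test_that("Anscombe transform matches its closed form and stabilises variance", {
  expect_equal(anscombe(0), 2 * sqrt(0.375))
  expect_equal(anscombe(1), 2 * sqrt(1.375))
  expect_error(anscombe(-1), "non-negative")
  x <- 0:100
  expect_true(all(diff(anscombe(x)) > 0))
  set.seed(2)
  expect_equal(var(anscombe(rpois(2e5, 10))), 1, tolerance = 0.03)
})

test_that("Huber weights damp beyond the tuning constant, continuously", {
  expect_equal(huber_weight(0), 1)
  expect_equal(huber_weight(6, c_tune = 3), 0.5)
  expect_equal(huber_weight(c(-3, 3), c_tune = 3), c(1, 1))
  eps <- 1e-8
  expect_equal(huber_weight(3 + eps), huber_weight(3 - eps), tolerance = 1e-7)
  r <- seq(-10, 10, by = 0.1)
  w <- huber_weight(r)
  expect_true(all(w > 0 & w <= 1))
})

test_that("ML scale fit has the closed form sum(c)/sum(b)", {
  b <- c(4, 9, 2.5)
  expect_equal(fit_scale_ml(b, b)$B, 1)
  f <- fit_scale_ml(c(2, 4, 6), c(1, 2, 3))
  expect_equal(f$B, 2)
  expect_equal(f$var_B, 2 / 6)
  expect_true(all(f$weights == 1))

  z <- fit_scale_ml(c(1, 2), c(0, 0))
  expect_true(is.na(z$B))
  expect_true("zero_model" %in% z$flags)
  expect_error(fit_scale_ml(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(fit_scale_ml(c(1, 2), c(1, 2, 3)), "length")
})

test_that("ML closed form maximises the Poisson likelihood (grid oracle)", {
  set.seed(17)
  loglik <- function(B, c, b) sum(dpois(c, pmax(B * b, 1e-12), log = TRUE))
  for (k in 1:30) {
    n <- sample(5:30, 1)
    b <- runif(n, 0.2, 3)
    c <- rpois(n, runif(1, 1, 30) * b)
    Bhat <- fit_scale_ml(c, b)$B
    grid <- seq(max(Bhat - 2, 0.01), Bhat + 2, length.out = 4001)
    expect_equal(grid[which.max(vapply(grid, loglik, 0, c = c, b = b))],
                 Bhat, tolerance = 1e-3)
  }
})

test_that("robust fit agrees with ML on clean data and at exact fits", {
  # exact data: residuals are all zero, so the ML solution is a fixed point
  b <- c(5, 10, 20, 40)
  f <- fit_scale_robust(3 * b, b)
  expect_equal(f$B, 3, tolerance = 1e-10)
  expect_true(f$converged)
  expect_true(all(f$weights == 1))

  # outlier-free Poisson data at healthy counts: within 2% of sum(c)/sum(b)
  set.seed(23)
  for (k in 1:10) {
    b <- runif(80, 0.5, 2)
    c <- rpois(80, 50 * b)
    fr <- fit_scale_robust(c, b)
    fm <- fit_scale_ml(c, b)
    expect_true(fr$converged)
    expect_equal(fr$B, fm$B, tolerance = 0.02)
  }

  # scale equivariance: scaling all counts by k scales B by ~k
  set.seed(29)
  b <- runif(100, 0.5, 2)
  c <- rpois(100, 60 * b)
  f1 <- fit_scale_robust(c, b)
  f3 <- fit_scale_robust(3 * c, b)
  expect_equal(f3$B / f1$B, 3, tolerance = 0.02)
  expect_equal(fit_scale_ml(3 * c, b)$B, 3 * fit_scale_ml(c, b)$B)

  # degenerate cases
  expect_true(is.na(fit_scale_robust(c(1, 2), c(0, 0))$B))
  f0 <- fit_scale_robust(c(0, 0, 0), c(1, 2, 3))
  expect_equal(f0$B, 0)
  expect_true("all_zero_counts" %in% f0$flags)
  expect_true("low_counts" %in% fit_scale_robust(c(1, 2, 1), c(1, 1, 1))$flags)
})

test_that("a single gross outlier barely moves the robust fit", {
  set.seed(37)
  shifts_r <- shifts_m <- numeric(20)
  for (k in 1:20) {
    b <- runif(100, 0.8, 1.2)
    c <- rpois(100, 30 * b)
    clean <- fit_scale_robust(c, b)
    cc <- c
    cc[1] <- round(100 * 30 * b[1])  # 100x its expectation
    dirty <- fit_scale_robust(cc, b)
    ml <- fit_scale_ml(cc, b)
    shifts_r[k] <- abs(dirty$B - clean$B) / clean$B
    # plain ML shifts by the outlier's share of the counts
    expect_equal(ml$B - fit_scale_ml(c, b)$B, (cc[1] - c[1]) / sum(b))
    shifts_m[k] <- abs(ml$B - clean$B) / clean$B
    expect_lt(min(dirty$weights), 0.05)  # the outlier is heavily damped
  }
  expect_lt(max(shifts_r), 0.05)
  expect_gt(min(shifts_m), 0.5)

  # breakdown: making the outlier arbitrarily large keeps robust B bounded
  b <- rep(1, 50)
  set.seed(41)
  c <- rpois(50, 20)
  base <- fit_scale_robust(c, b)$B
  for (out in c(1e4, 1e6, 1e8)) {
    cc <- c; cc[7] <- out
    expect_lt(abs(fit_scale_robust(cc, b)$B - base) / base, 0.1)
  }
})

test_that("shoeboxes validate their masks and fit both background models", {
  counts <- matrix(rpois(49, 10), 7, 7)
  fg <- matrix(FALSE, 7, 7); fg[3:5, 3:5] <- TRUE
  sb <- shoebox(c(10, 17, 20, 27), counts, fg)
  expect_s3_class(sb, "shoebox")
  expect_error(shoebox(c(10, 16, 20, 27), counts, fg), "shape")
  expect_error(shoebox(c(10, 17, 20, 27), counts - 20, fg), "non-negative")

  # flat baseline is the mean background count, bit-equal to ML with b = 1
  counts[!fg] <- 5
  counts[fg] <- 99
  sb <- shoebox(c(0, 7, 0, 7), counts, fg)
  ff <- fit_shoebox(sb, method = "flat")
  expect_identical(ff$B, 5)
  cc <- counts[!fg]
  expect_identical(ff$B, fit_scale_ml(cc, rep(1, length(cc)))$B)
  expect_identical(fit_flat_baseline(c(3, 5, 7))$B, 5)
})

test_that("summation integration subtracts the scaled model under the peak", {
  fg <- matrix(FALSE, 5, 5); fg[2:4, 2:4] <- TRUE
  bmat <- matrix(10, 5, 5)
  model <- structure(list(b = matrix(10, 30, 30),
                          valid = matrix(TRUE, 30, 30)),
                     class = "background_model")
  # foreground counts exactly B * b -> I = 0
  counts <- matrix(20L, 5, 5)
  sb <- shoebox(c(4, 9, 4, 9), counts, fg)
  fit <- fit_shoebox(sb, model, method = "ml")
  expect_equal(fit$B, 2)
  res <- integrate_summation(sb, model, fit)
  expect_equal(res$intensity, 0)
  expect_gt(res$variance, 0)

  # flat-model route reduces to counts minus mean background * n_fg
  resf <- integrate_summation(sb, NULL, fit_shoebox(sb, method = "flat"))
  expect_equal(resf$intensity, sum(counts[fg]) - mean(counts[!fg]) * sum(fg))

  # empty foreground is flagged
  sb2 <- shoebox(c(4, 9, 4, 9), counts, matrix(FALSE, 5, 5))
  r2 <- integrate_summation(sb2, model, fit_shoebox(sb2, model, "ml"))
  expect_true("no_foreground" %in% r2$flags)
  expect_true(is.na(r2$intensity))
})

test_that("known spot intensities are recovered without bias", {
  # 500 replicates of a Gaussian spot of strength S on a known background
  set.seed(47)
  S <- 300
  n_rep <- 500
  fg <- matrix(FALSE, 11, 11)
  ctr <- 6
  xy <- expand.grid(1:11, 1:11)
  d2 <- (xy[[1]] - ctr)^2 + (xy[[2]] - ctr)^2
  fg[d2 <= 3.5^2] <- TRUE
  prof <- matrix(exp(-d2 / (2 * 1.0^2)), 11, 11)
  prof <- S * prof / sum(prof)
  bmat <- matrix(12, 11, 11)
  got <- numeric(n_rep)
  model <- structure(list(b = matrix(12, 40, 40),
                          valid = matrix(TRUE, 40, 40)),
                     class = "background_model")
  for (k in seq_len(n_rep)) {
    counts <- matrix(rpois(121, bmat + prof), 11, 11)
    sb <- shoebox(c(10, 21, 10, 21), counts, fg)
    fit <- fit_shoebox(sb, model, method = "ml")
    got[k] <- integrate_summation(sb, model, fit)$intensity
  }
  se <- sd(got) / sqrt(n_rep)
  expect_lt(abs(mean(got) - sum(prof[fg])), 2 * se)
  # intensity outside the foreground disc is not part of the target
  expect_gt(sum(prof[fg]) / S, 0.99)
})
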