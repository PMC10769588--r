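# Brute-force numerical convolution of an object profile with the Gaussian
# PRF, used as the oracle for the analytic imaging formulas.
quadrature_prf_image <- function(obj_fun, prf, detectors, pad = 40,
                                 step = 0.5) {
  xs <- seq(-pad, 64 + pad, by = step)
  pts <- as.matrix(expand.grid(x = xs, y = xs))
  ov <- obj_fun(pts)
  vapply(seq_len(nrow(detectors)), function(i) {
    d2 <- (pts[, 1] - detectors[i, 1])^2 + (pts[, 2] - detectors[i, 2])^2
    prf_v <- prf$height / (2 * pi * prf$width^2) *
      exp(-d2 / (2 * prf$width^2))
    sum(ov * prf_v) * step^2
  }, numeric(1))
}

test_that("analytic lumpy imaging equals brute-force convolution", {
  model <- lumpy_model(mean_lumps = 6, amplitude = 1, width = 8, fov = 64)
  prf <- gaussian_prf(height = 35, width = 2, grid = fov_grid(64))
  p <- lumpy_params(matrix(c(20, 20), 1))
  b <- image_lumpy_background(p, model, prf)

  # peak value: a * h * wb^2 / (wh^2 + wb^2) at the lump center
  expect_equal(b[20 + 20 * 64 + 1], 35 * 64 / 68, tolerance = 1e-10)

  dets <- rbind(c(20, 20), c(25, 20), c(30, 35), c(10, 50), c(0, 0))
  oracle <- quadrature_prf_image(
    function(pts) evaluate_lumpy_object(p, model, pts), prf, dets)
  analytic <- image_lumpy_background(
    p, model, gaussian_prf(35, 2, grid = dets))
  expect_lt(max(abs(analytic - oracle) / abs(oracle)), 1e-3)

  # zero lumps image to zero; imaging is additive over lumps
  expect_equal(
    image_lumpy_background(lumpy_params(matrix(numeric(0), 0, 2)),
                           model, prf),
    rep(0, 4096))
  p2 <- lumpy_params(rbind(c(20, 20), c(40, 30)))
  expect_equal(
    image_lumpy_background(p2, model, prf),
    b + image_lumpy_background(lumpy_params(matrix(c(40, 30), 1)),
                               model, prf))
})

test_that("analytic signal imaging equals brute-force convolution", {
  prf <- gaussian_prf(height = 35, width = 2, grid = fov_grid(64))
  sig <- gaussian_signal(amplitude = 0.3, width = 2.5, center = c(32, 32))
  s <- image_gaussian_signal(sig, prf)

  expect_equal(s[32 + 32 * 64 + 1], 0.3 * 35 * 6.25 / 10.25,
               tolerance = 1e-10)

  dets <- rbind(c(32, 32), c(34, 32), c(28, 36))
  oracle <- quadrature_prf_image(
    function(pts) evaluate_gaussian_signal(sig, pts), prf, dets)
  analytic <- image_gaussian_signal(sig, gaussian_prf(35, 2, grid = dets))
  expect_lt(max(abs(analytic - oracle) / abs(oracle)), 1e-3)

  zero <- gaussian_signal(amplitude = 0, width = 2.5, center = c(32, 32))
  expect_equal(image_gaussian_signal(zero, prf), rep(0, 4096))

  # radial symmetry about the signal center on a symmetric grid
  m <- matrix(s, 64, 64)
  expect_equal(m[33 + 3, 33], m[33 - 3, 33])
  expect_equal(m[33, 33 + 5], m[33, 33 - 5])
})

test_that("narrow lumps image to the PRF shape", {
  # wb -> 0 with a * wb^2 fixed: the image tends to h * c * exp(-d^2/(2 wh^2))
  wb <- 0.01
  model <- lumpy_model(mean_lumps = 1, amplitude = 1 / wb^2, width = wb,
                       fov = 64)
  prf <- gaussian_prf(height = 35, width = 2, grid = fov_grid(64))
  b <- image_lumpy_background(lumpy_params(matrix(c(32, 32), 1)), model, prf)
  d2 <- rowSums(sweep(fov_grid(64), 2, c(32, 32))^2)
  # limit amplitude: a * wb^2 * h / wh^2 with a * wb^2 held at 1
  prf_shape <- 35 / 4 * exp(-d2 / (2 * 4))
  expect_lt(max(abs(b - prf_shape)) / max(prf_shape), 1e-3)
})

test_that("noise model adds calibrated i.i.d. Gaussian noise", {
  nz <- noise_model(2, "real")
  set.seed(4)
  x <- rep(5, 1e5)
  g <- add_noise(x, nz)
  expect_lt(abs(var(g - x) - 4), 3 * 4 * sqrt(2 / 1e5))
  expect_lt(abs(mean(g - x)), 3 * 2 / sqrt(1e5))

  # complex kind: independent components, each with variance sigma^2
  nzc <- noise_model(2, "complex")
  gc <- add_noise(complex(real = rep(1, 1e5), imaginary = rep(0, 1e5)), nzc)
  expect_lt(abs(var(Re(gc)) - 4), 3 * 4 * sqrt(2 / 1e5))
  expect_lt(abs(var(Im(gc)) - 4), 3 * 4 * sqrt(2 / 1e5))
  expect_lt(abs(cor(Re(gc), Im(gc))), 3 / sqrt(1e5))

  # determinism under a fixed seed; near-identity for tiny sigma
  set.seed(9); a <- add_noise(x[1:10], nz)
  set.seed(9); b <- add_noise(x[1:10], nz)
  expect_identical(a, b)
  tiny <- add_noise(x[1:10], noise_model(1e-14, "real"))
  expect_equal(tiny, x[1:10], tolerance = 1e-10)

  expect_error(add_noise(complex(real = 1, imaginary = 1), nz),
               "complex")
})

test_that("psnr inverts its defining formula", {
  expect_equal(psnr(c(2, -2), 2), 0)
  expect_equal(psnr(c(3, 20), 2), 20)
  expect_equal(psnr(55.59, 1), 34.9, tolerance = 1e-3)
  expect_equal(psnr(complex(real = 3, imaginary = 4), 5), 0)
  expect_error(psnr(numeric(0), 1), "empty")
})

test_that("poisson-disc mask meets its sampling-fraction and distance contract", {
  set.seed(11)
  mk <- poisson_disc_mask(64, acceleration = 8, calibration_radius = 3)
  expect_lt(abs(mk$sampled_fraction * 8 - 1), 0.1)

  # calibration disc fully sampled
  expect_true(all(mk$mask[mk$calibration]))

  # exhaustive pair check outside the calibration region
  idx <- which(mk$mask & !mk$calibration, arr.ind = TRUE)
  kx <- mk$kx[idx[, 1]]; ky <- mk$ky[idx[, 2]]
  r <- mk$radius[idx]
  d2 <- outer(kx, kx, "-")^2 + outer(ky, ky, "-")^2
  diag(d2) <- Inf
  rmin <- outer(r, r, pmin)
  expect_equal(sum(d2 < rmin^2), 0)

  # no undersampling: every location sampled
  full <- poisson_disc_mask(16, acceleration = 1)
  expect_true(all(full$mask))
})

test_that("mri forward operator is a masked unitary DFT", {
  set.seed(2)
  mk <- poisson_disc_mask(16, acceleration = 4, calibration_radius = 2)
  const <- matrix(3, 16, 16)
  g <- mri_forward(const, mk)
  # DC (position [1,1], always inside the calibration disc) equals c * L
  dc_index <- which(which(mk$mask) == 1L)
  expect_equal(g[dc_index], 3 * 16 + 0i)
  expect_true(all(Mod(g[-dc_index]) < 1e-10))

  # Parseval before masking
  f <- matrix(rnorm(256), 16, 16)
  F <- fft(f) / 16
  expect_equal(sum(Mod(F)^2), sum(f^2))

  expect_error(mri_forward(matrix(0, 8, 8), mk), "dimensions")
})
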