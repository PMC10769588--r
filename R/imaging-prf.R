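#' Gaussian point-response-function imaging operator
#'
#' An idealized parallel-hole collimator system described by a
#' continuous-to-discrete linear map: the m-th measurement is the integral
#' of the object against a Gaussian point response function
#' `h / (2 pi wh^2) * exp(-||r - rm||^2 / (2 wh^2))` centered at detector
#' location `rm`.
#'
#' @param height Sensitivity height `h` of the PRF.
#' @param width PRF width `wh` in pixels.
#' @param grid M x 2 matrix of detector locations `rm`; defaults are set by
#'   the task that uses the operator.
#' @return An object of class `gaussian_prf`.
#' @export
gaussian_prf <- function(height = 35, width = 2, grid = fov_grid(64)) {
  stopifnot(height > 0, width > 0)
  structure(list(height = height, width = width, grid = as.matrix(grid)),
            class = "gaussian_prf")
}

#' @export
print.gaussian_prf <- function(x, ...) {
  cat("Gaussian-PRF imaging operator: h =", x$height, ", wh =", x$width,
      ",", nrow(x$grid), "detector elements\n")
  invisible(x)
}

#' Image a lumpy object through the Gaussian-PRF operator
#'
#' Uses the exact Gaussian-Gaussian convolution: each lump of amplitude `a`
#' and width `wb` contributes
#' `a * h * wb^2 / (wh^2 + wb^2) * exp(-||rm - rn||^2 / (2 (wh^2 + wb^2)))`
#' to measurement m.  The background terms use the lump width throughout
#' (prefactor and exponent), which is the analytic convolution of the lump
#' profile with the PRF.
#'
#' @param params A [lumpy_params()] realization.
#' @param model The [lumpy_model()].
#' @param prf The [gaussian_prf()] operator.
#' @return Numeric M-vector of noiseless background image data `b`.
#' @export
image_lumpy_background <- function(params, model, prf) {
  stopifnot(inherits(params, "lumpy_params"), inherits(model, "lumpy_model"),
            inherits(prf, "gaussian_prf"))
  w2 <- prf$width^2 + model$width^2
  amp <- model$amplitude * prf$height * model$width^2 / w2
  gaussian_sum_field(params$centers, prf$grid, amp, w2)
}

#' Image a Gaussian signal through the Gaussian-PRF operator
#'
#' Exact convolution of the signal profile with the PRF:
#' `sm = as * h * ws^2 / (wh^2 + ws^2) * exp(-||rm - rs||^2 / (2 (wh^2 + ws^2)))`,
#' with the signal width used consistently in prefactor and exponent.
#'
#' @param signal A [gaussian_signal()].
#' @param prf The [gaussian_prf()] operator.
#' @return Numeric M-vector of noiseless signal image data `s`.
#' @export
image_gaussian_signal <- function(signal, prf) {
  stopifnot(inherits(signal, "gaussian_signal"), inherits(prf, "gaussian_prf"))
  w2 <- prf$width^2 + signal$width^2
  amp <- signal$amplitude * prf$height * signal$width^2 / w2
  gaussian_sum_field(matrix(signal$center, ncol = 2), prf$grid, amp, w2)
}

#' Measurement-noise model
#'
#' Describes i.i.d. Gaussian measurement noise: either real-valued noise on
#' each measurement, or complex noise with independent N(0, sigma^2) real
#' and imaginary components at each sampled k-space location.
#'
#' @param sigma Noise standard deviation per (real) component.
#' @param kind `"real"` or `"complex"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma, kind = c("real", "complex")) {
  stopifnot(sigma > 0)
  kind <- match.arg(kind)
  structure(list(kind = kind, sigma = sigma), class = "noise_model")
}

#' Add i.i.d. Gaussian noise to a noiseless measurement
#'
#' @param noiseless Numeric (real kind) or complex (complex kind) vector.
#' @param noise A [noise_model()].
#' @return Noisy measurement vector of the same type and length.
#' @export
add_noise <- function(noiseless, noise) {
  stopifnot(inherits(noise, "noise_model"))
  m <- length(noiseless)
  if (noise$kind == "real") {
    if (is.complex(noiseless))
      stop("real noise model applied to complex data")
    noiseless + stats::rnorm(m, sd = noise$sigma)
  } else {
    if (!is.complex(noiseless))
      noiseless <- as.complex(noiseless)
    noiseless + complex(real = stats::rnorm(m, sd = noise$sigma),
                        imaginary = stats::rnorm(m, sd = noise$sigma))
  }
}

#' Peak signal-to-noise ratio of a measurement ensemble
#'
#' `PSNR = 20 * log10(max |g| / sigma)` with the maximum modulus taken over
#' every element of the supplied evaluation set.
#'
#' @param measurements A vector, matrix, or list of measurement vectors.
#' @param sigma Noise standard deviation.
#' @return PSNR in decibels.
#' @export
psnr <- function(measurements, sigma) {
  if (is.list(measurements)) measurements <- unlist(measurements)
  if (length(measurements) == 0L) stop("empty measurement set")
  20 * log10(max(Mod(measurements)) / sigma)
}
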