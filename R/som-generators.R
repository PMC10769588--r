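#' Latent-generator contract for generative stochastic object models
#'
#' A latent generator is the package's interface to any generative
#' stochastic object model: a deterministic, continuous map from a
#' k-dimensional standard-normal latent vector `z` to an N-dimensional
#' object or image-data vector.  A trained deep generative model (for
#' example a GAN generator) satisfies this contract; the package also ships
#' analytic generators ([linear_gaussian_generator()],
#' [blob_generator()]) whose induced ideal observer admits closed-form or
#' quadrature reference solutions.
#'
#' @param map Function taking a numeric k-vector and returning a numeric
#'   N-vector.  Must be deterministic: identical inputs give identical
#'   outputs.
#' @param latent_dim Latent dimension k (positive integer).
#' @param output_dim Output length N.
#' @param output_domain Either `"image"` (the map emits image data b, no
#'   further imaging operator needed) or `"object"` (the map emits an
#'   object f that must still be passed through a forward operator).
#' @param ... Extra named fields stored on the object (used by analytic
#'   generators to expose their parameters to oracle observers).
#'
#' @return An object of class `latent_generator`; calling it as a function
#'   evaluates the map.
#' @export
latent_generator <- function(map, latent_dim, output_dim,
                             output_domain = c("image", "object"), ...) {
  stopifnot(is.function(map), latent_dim >= 1, output_dim >= 1)
  output_domain <- match.arg(output_domain)
  g <- structure(
    list(map = map, latent_dim = as.integer(latent_dim),
         output_dim = as.integer(output_dim),
         output_domain = output_domain, ...),
    class = "latent_generator"
  )
  g
}

#' Evaluate a latent generator
#'
#' @param generator A [latent_generator()].
#' @param z Numeric latent vector of length `generator$latent_dim`.
#' @return Numeric vector of length `generator$output_dim`.
#' @export
generate_background <- function(generator, z) {
  stopifnot(inherits(generator, "latent_generator"),
            length(z) == generator$latent_dim, all(is.finite(z)))
  out <- generator$map(as.numeric(z))
  stopifnot(length(out) == generator$output_dim)
  out
}

#' Draw a background (and its latent) from a generator's prior
#'
#' Samples `z ~ N(0, I_k)` and evaluates the generator.  The true latent is
#' returned alongside the image so Markov chains can be initialized at the
#' latent vector that actually generated a simulated measurement.
#'
#' @param generator A [latent_generator()].
#' @return List with elements `z` (latent draw) and `b` (generated vector).
#' @export
sample_generator_prior <- function(generator) {
  z <- stats::rnorm(generator$latent_dim)
  list(z = z, b = generate_background(generator, z))
}

#' @export
print.latent_generator <- function(x, ...) {
  cat("Latent generator: k =", x$latent_dim, "->", x$output_dim,
      "values (", x$output_domain, "domain )\n")
  invisible(x)
}

#' Linear-Gaussian latent generator
#'
#' Builds the generator `b(z) = mean_image + mixing %*% z`.  The induced
#' background distribution is Gaussian with mean `mean_image` and
#' covariance `mixing %*% t(mixing)`, for which the ideal observer has a
#' closed form ([analytic_gaussian_io_log_lr()]); this makes the generator
#' the package's primary exact reference fixture for the latent-space
#' sampler.
#'
#' @param mean_image Numeric N-vector, the background mean.
#' @param mixing N x k numeric matrix of full column rank.
#' @return A `latent_generator` carrying `mean_image` and `mixing` fields.
#' @export
linear_gaussian_generator <- function(mean_image, mixing) {
  mixing <- as.matrix(mixing)
  mean_image <- as.numeric(mean_image)
  stopifnot(nrow(mixing) == length(mean_image))
  if (qr(mixing)$rank < ncol(mixing))
    warning("mixing matrix is rank deficient; induced covariance is singular")
  latent_generator(
    map = function(z) mean_image + drop(mixing %*% z),
    latent_dim = ncol(mixing), output_dim = length(mean_image),
    output_domain = "image",
    mean_image = mean_image, mixing = mixing
  )
}

#' Low-dimensional nonlinear blob generator
#'
#' A smooth nonlinear fixture generator with latent dimension 2 or 3: a
#' single Gaussian blob whose center (and, for k = 3, log-width) are
#' bounded smooth (tanh) functions of the latent coordinates.  Its low
#' latent dimension makes deterministic tensor-grid quadrature of the ideal
#' observer integral feasible ([oracle_quadrature_log_lr()]), providing an
#' independent oracle for the Markov-chain estimate with a genuinely
#' nonlinear generator.
#'
#' @param k Latent dimension, 2 or 3.
#' @param fov Field-of-view side length in pixels.
#' @param amplitude Blob amplitude.
#' @param base_width Blob width at z = 0, in pixels.
#' @return A `latent_generator` with `output_dim = fov^2`.
#' @export
blob_generator <- function(k = 2, fov = 16, amplitude = 1,
                           base_width = fov / 6) {
  stopifnot(k %in% c(2L, 3L))
  grid <- fov_grid(fov)
  c0 <- (fov - 1) / 2
  swing <- fov / 4
  latent_generator(
    map = function(z) {
      cx <- c0 + swing * tanh(z[1])
      cy <- c0 + swing * tanh(z[2])
      w <- if (k == 3L) base_width * exp(0.4 * tanh(z[3])) else base_width
      gaussian_sum_field(matrix(c(cx, cy), ncol = 2), grid, amplitude, w^2)
    },
    latent_dim = k, output_dim = fov^2, output_domain = "image",
    fov = fov, amplitude = amplitude, base_width = base_width
  )
}

#' Constant-output generator
#'
#' Maps every latent vector to the same fixed image.  Under this generator
#' the measurement likelihood is constant in z, so a correct latent-space
#' sampler must reproduce the standard-normal prior; used as a sampler
#' sanity fixture.
#'
#' @param image Numeric vector the generator always returns.
#' @param latent_dim Latent dimension k.
#' @return A `latent_generator`.
#' @export
constant_generator <- function(image, latent_dim = 2) {
  image <- as.numeric(image)
  latent_generator(
    map = function(z) image,
    latent_dim = latent_dim, output_dim = length(image),
    output_domain = "image"
  )
}
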