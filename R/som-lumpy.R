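#' Lumpy background object model
#'
#' Specifies a stochastic "lumpy background": a random superposition of
#' Gaussian lumps.  The number of lumps is Poisson distributed and each lump
#' center is uniform over the square field of view.  This is the canonical
#' low-dimensional stochastic object model used in task-based image-quality
#' studies of signal-known-exactly / background-known-statistically
#' detection.
#'
#' @param mean_lumps Expected number of lumps (Poisson mean), dimensionless.
#' @param amplitude Lump amplitude `a` in object units.
#' @param width Lump width `wb` (Gaussian standard deviation) in pixels.
#' @param fov Side length `L` of the square field of view in pixels; pixel
#'   centers sit at integer coordinates `0 .. L - 1` and continuous lump
#'   centers live in `[0, L)^2`.
#'
#' @return An object of class `lumpy_model`.
#' @examples
#' lm <- lumpy_model(mean_lumps = 6, amplitude = 1, width = 8, fov = 64)
#' @export
lumpy_model <- function(mean_lumps = 6, amplitude = 1, width = 8, fov = 64) {
  stopifnot(mean_lumps > 0, width > 0, fov > 0, amplitude >= 0)
  structure(
    list(mean_lumps = mean_lumps, amplitude = amplitude,
         width = width, fov = fov),
    class = "lumpy_model"
  )
}

#' @export
print.lumpy_model <- function(x, ...) {
  cat("Lumpy background model: Poisson(", x$mean_lumps, ") lumps, a = ",
      x$amplitude, ", wb = ", x$width, ", fov ", x$fov, " x ", x$fov,
      "\n", sep = "")
  invisible(x)
}

#' Lumpy object realization (parameter vector)
#'
#' Bundles one realization of the lumpy model parameters: the lump count and
#' the continuous lump-center coordinates.  This is the variable the
#' conventional object-domain Markov chain samples.
#'
#' @param centers Numeric matrix with one row per lump and two columns
#'   (x, y) in pixels; a 0-row matrix encodes an empty (lump-free) object.
#'
#' @return An object of class `lumpy_params` with fields `n_lumps` and
#'   `centers`.
#' @export
lumpy_params <- function(centers) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  stopifnot(all(is.finite(centers)) || nrow(centers) == 0L)
  structure(list(n_lumps = nrow(centers), centers = centers),
            class = "lumpy_params")
}

#' @export
print.lumpy_params <- function(x, ...) {
  cat("Lumpy object realization:", x$n_lumps, "lumps\n")
  invisible(x)
}

#' Draw lumpy model parameters from the prior
#'
#' Samples `n_lumps ~ Poisson(mean_lumps)` and lump centers i.i.d. uniform
#' on `[0, L)^2`.  A draw of zero lumps is valid and yields an empty object.
#'
#' @param model A [lumpy_model()].
#' @return A [lumpy_params()] realization.
#' @export
sample_lumpy_params <- function(model) {
  stopifnot(inherits(model, "lumpy_model"))
  n <- stats::rpois(1L, model$mean_lumps)
  centers <- matrix(stats::runif(2L * n, 0, model$fov), ncol = 2)
  lumpy_params(centers)
}

#' Pixel-center evaluation grid for a square field of view
#'
#' @param fov Side length in pixels.
#' @return An `fov^2 x 2` matrix of (x, y) coordinates, x varying fastest,
#'   matching column-major storage of an `fov x fov` image matrix whose
#'   rows index x.
#' @export
fov_grid <- function(fov) {
  xy <- seq_len(fov) - 1
  cbind(rep(xy, times = fov), rep(xy, each = fov))
}

#' Evaluate a lumpy object on a set of points
#'
#' The object value at location r is the sum over lumps of
#' `a * exp(-||r - rn||^2 / (2 wb^2))`.
#'
#' @param params A [lumpy_params()] realization.
#' @param model The [lumpy_model()] supplying amplitude and width.
#' @param grid Numeric matrix of evaluation points (one row per point, two
#'   columns); defaults to the pixel grid of the model's field of view.
#' @return Numeric vector of object values, one per grid row.
#' @export
evaluate_lumpy_object <- function(params, model, grid = fov_grid(model$fov)) {
  stopifnot(inherits(params, "lumpy_params"), inherits(model, "lumpy_model"))
  grid <- as.matrix(grid)
  gaussian_sum_field(params$centers, grid, model$amplitude, model$width^2)
}

#' Gaussian signal model
#'
#' A deterministic, signal-known-exactly 2D Gaussian signal
#' `as * exp(-||r - rs||^2 / (2 ws^2))`.
#'
#' @param amplitude Signal amplitude `as` in object units.
#' @param width Signal width `ws` in pixels.
#' @param center Length-2 signal location `rs` in pixels.
#' @return An object of class `gaussian_signal`.
#' @export
gaussian_signal <- function(amplitude = 0.3, width = 2.5, center = c(32, 32)) {
  stopifnot(width > 0, length(center) == 2L)
  structure(list(amplitude = amplitude, width = width,
                 center = as.numeric(center)),
            class = "gaussian_signal")
}

#' Evaluate a Gaussian signal on a set of points
#'
#' @param signal A [gaussian_signal()].
#' @param grid Numeric matrix of evaluation points (rows are points).
#' @return Numeric vector of signal values.
#' @export
evaluate_gaussian_signal <- function(signal, grid) {
  stopifnot(inherits(signal, "gaussian_signal"))
  grid <- as.matrix(grid)
  gaussian_sum_field(matrix(signal$center, ncol = 2), grid,
                     signal$amplitude, signal$width^2)
}
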