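#' Variable-density Poisson-disc k-space sampling mask
#'
#' Generates an undersampled Cartesian k-space mask by variable-density
#' dart throwing: a minimum-distance (Poisson-disc) criterion whose
#' exclusion radius grows linearly with distance from the k-space center,
#' plus a fully sampled central calibration disc.  A bisection on a global
#' density scale adjusts the radius profile until the sampled fraction
#' matches the target `1 / acceleration`.
#'
#' The mask is stored in unshifted DFT order (DC at element `[1, 1]`), so
#' it can be applied directly to the output of [mri_forward()]'s Fourier
#' transform.
#'
#' @param shape Integer length-2 grid dimensions (or a scalar for a square
#'   grid).
#' @param acceleration Target acceleration factor (> 1); the sampled
#'   fraction is `1 / acceleration`.
#' @param calibration_radius Radius (k-space pixels) of the fully sampled
#'   central disc.
#' @param r_min,r_max Exclusion radius at the k-space center and edge,
#'   before density scaling.
#' @param tol Relative tolerance on the achieved sampling fraction.
#' @param max_iter Maximum bisection steps before the combination is
#'   declared infeasible.
#' @return An object of class `kspace_mask` with fields `mask` (logical
#'   matrix, DFT order), `acceleration`, `calibration_radius`,
#'   `sampled_fraction`, `kx`, `ky` (integer frequency coordinates) and
#'   `radius` (the scaled exclusion radius at every grid point).
#' @export
poisson_disc_mask <- function(shape, acceleration, calibration_radius = 4,
                              r_min = 1, r_max = 4, tol = 0.02,
                              max_iter = 40L) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  stopifnot(acceleration >= 1, calibration_radius >= 0)
  nx <- shape[1]; ny <- shape[2]
  kx <- ifelse(seq_len(nx) - 1 < nx / 2, seq_len(nx) - 1, seq_len(nx) - 1 - nx)
  ky <- ifelse(seq_len(ny) - 1 < ny / 2, seq_len(ny) - 1, seq_len(ny) - 1 - ny)
  KX <- matrix(kx, nx, ny); KY <- matrix(ky, nx, ny, byrow = TRUE)
  kr <- sqrt(KX^2 + KY^2)
  kmax <- max(kr)
  profile <- r_min + (r_max - r_min) * kr / kmax
  calib <- kr <= calibration_radius
  target <- 1 / acceleration
  if (acceleration == 1) {
    return(structure(
      list(mask = matrix(TRUE, nx, ny), acceleration = 1,
           calibration_radius = calibration_radius, sampled_fraction = 1,
           kx = kx, ky = ky, radius = 0 * profile, calibration = calib),
      class = "kspace_mask"))
  }
  if (mean(calib) > target * (1 + tol))
    stop("calibration disc alone exceeds the target sampling fraction")

  # fixed candidate order shared across bisection steps (reproducibility
  # and near-monotonicity of the accepted count in the density scale)
  cand <- which(!calib)
  ord <- sample(cand) - 1L
  coords <- cbind(as.numeric(KX), as.numeric(KY))

  throw <- function(scale) {
    acc <- cpp_poisson_disc(coords, scale * as.numeric(profile),
                            as.logical(calib), ord)
    matrix(acc, nx, ny)
  }
  frac <- function(m) mean(m)

  lo <- 1e-3; hi <- 1
  m_hi <- throw(hi)
  it <- 0L
  while (frac(m_hi) > target && it < max_iter) { hi <- hi * 2; m_hi <- throw(hi); it <- it + 1L }
  m_lo <- throw(lo)
  if (frac(m_lo) < target)
    stop("infeasible acceleration/radius-profile combination (too dense even at minimal scale)")
  best <- if (abs(frac(m_hi) - target) < abs(frac(m_lo) - target)) list(m = m_hi, s = hi) else list(m = m_lo, s = lo)
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    m_mid <- throw(mid)
    f <- frac(m_mid)
    if (abs(f - target) < abs(frac(best$m) - target)) best <- list(m = m_mid, s = mid)
    if (abs(f / target - 1) <= tol) break
    if (f > target) lo <- mid else hi <- mid
  }
  achieved <- frac(best$m)
  if (abs(achieved / target - 1) > 0.10)
    stop(sprintf(
      "infeasible acceleration/radius-profile combination: achieved fraction %.4f vs target %.4f",
      achieved, target))
  structure(
    list(mask = best$m, acceleration = acceleration,
         calibration_radius = calibration_radius,
         sampled_fraction = achieved, kx = kx, ky = ky,
         radius = best$s * profile, calibration = calib),
    class = "kspace_mask"
  )
}

#' @export
print.kspace_mask <- function(x, ...) {
  cat(sprintf(
    "Poisson-disc k-space mask %d x %d: acceleration %.3g, sampled fraction %.4f, calibration radius %g\n",
    nrow(x$mask), ncol(x$mask), x$acceleration, x$sampled_fraction,
    x$calibration_radius))
  invisible(x)
}

#' Undersampled-k-space MRI forward operator
#'
#' Applies the unitary 2D discrete Fourier transform to a discretized
#' object and restricts the result to the sampled k-space locations.  With
#' the unitary normalization (`1 / sqrt(nx * ny)`), Parseval's identity
#' holds and noise standard deviations are stated in measurement units
#' without extra scaling.
#'
#' @param object Numeric matrix matching the mask grid, or a vector of
#'   length `prod(dim(mask$mask))` reshaped column-major.
#' @param mask A [poisson_disc_mask()] (or any `kspace_mask`).
#' @return Complex vector of sampled k-space values, in column-major mask
#'   order.
#' @export
mri_forward <- function(object, mask) {
  stopifnot(inherits(mask, "kspace_mask"))
  d <- dim(mask$mask)
  if (is.null(dim(object))) {
    if (length(object) != prod(d)) stop("object length does not match mask grid")
    object <- matrix(object, d[1], d[2])
  } else if (!all(dim(object) == d)) {
    stop("object dimensions do not match mask grid")
  }
  F <- stats::fft(object) / sqrt(prod(d))
  F[mask$mask]
}
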