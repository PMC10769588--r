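#' Sample covariance of a background-image ensemble
#'
#' Unbiased sample covariance of noiseless background images, the
#' object-variability term `Kb` in the measurement covariance
#' decomposition `Kg = Kn + Kb` used to build the Hotelling observer.
#'
#' @param samples Matrix with one background image per row (or a list of
#'   image vectors).
#' @return M x M covariance matrix.
#' @export
estimate_background_covariance <- function(samples) {
  if (is.list(samples)) samples <- do.call(rbind, samples)
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("need at least 2 background samples")
  stats::cov(samples)
}

#' Streaming background covariance for the lumpy task
#'
#' Simulates `n` noiseless lumpy background images and accumulates their
#' mean and cross-product chunkwise, so the full `n x M` sample matrix is
#' never held in memory.  Returns the unbiased sample covariance (and the
#' sample mean as attribute `"mean"`).
#'
#' @param model A [lumpy_model()].
#' @param prf A [gaussian_prf()].
#' @param n Number of background samples.
#' @param chunk Samples simulated per accumulation block.
#' @return M x M covariance matrix with attribute `mean`.
#' @export
lumpy_background_covariance <- function(model, prf, n, chunk = 500L) {
  M <- nrow(prf$grid)
  xtx <- matrix(0, M, M)
  xsum <- numeric(M)
  done <- 0L
  while (done < n) {
    nb <- min(chunk, n - done)
    block <- matrix(0, nb, M)
    for (i in seq_len(nb)) {
      block[i, ] <- image_lumpy_background(sample_lumpy_params(model),
                                           model, prf)
    }
    xtx <- xtx + crossprod(block)
    xsum <- xsum + colSums(block)
    done <- done + nb
  }
  mu <- xsum / n
  kb <- (xtx - n * tcrossprod(mu)) / (n - 1)
  attr(kb, "mean") <- mu
  kb
}

#' Hotelling observer template
#'
#' Solves `(Kb + sigma^2 I) w = s` for the optimal linear (Hotelling)
#' template, using a Cholesky solve rather than an explicit inverse.  If
#' the system is ill-conditioned (reciprocal condition estimate below
#' `1e-10`), a ridge of `1e-6 * trace(Kg) / M` is added and reported.
#'
#' @param Kb Background-image covariance (M x M), e.g. from
#'   [estimate_background_covariance()].
#' @param noise A [noise_model()]; contributes `sigma^2 I` to the
#'   measurement covariance.
#' @param s Signal image data (M-vector).
#' @return An object of class `hotelling_template` with fields `w`
#'   (template), `ridge` (0 if none applied) and `residual` (relative
#'   solve residual).
#' @export
hotelling_template <- function(Kb, noise, s) {
  stopifnot(inherits(noise, "noise_model"))
  Kb <- as.matrix(Kb)
  s <- as.numeric(s)
  if (nrow(Kb) != length(s)) stop("covariance and signal dimensions differ")
  Kg <- Kb + diag(noise$sigma^2, nrow(Kb))
  ridge <- 0
  ch <- tryCatch(chol(Kg), error = function(e) NULL)
  bad <- is.null(ch)
  if (!bad) {
    # cheap conditioning estimate from the Cholesky diagonal
    d <- diag(ch)^2
    bad <- min(d) / max(d) < 1e-20 || !all(is.finite(d))
  }
  if (bad) {
    ridge <- 1e-6 * sum(diag(Kg)) / nrow(Kg)
    ch <- chol(Kg + diag(ridge, nrow(Kg)))
  }
  w <- backsolve(ch, forwardsolve(t(ch), s))
  resid <- sqrt(sum(((Kg + diag(ridge, nrow(Kg))) %*% w - s)^2)) /
    sqrt(sum(s^2))
  structure(list(w = w, ridge = ridge, residual = resid),
            class = "hotelling_template")
}

#' @export
print.hotelling_template <- function(x, ...) {
  cat(sprintf(
    "Hotelling template: %d elements, ridge %.3g, relative residual %.2e\n",
    length(x$w), x$ridge, x$residual))
  invisible(x)
}

#' Hotelling observer test statistic
#'
#' The linear decision variable `t = w' g` (real inner product over
#' stacked real/imaginary components for complex data).
#'
#' @param template A [hotelling_template()] or a raw template vector.
#' @param g Measurement vector.
#' @return Scalar score.
#' @export
hotelling_score <- function(template, g) {
  w <- if (inherits(template, "hotelling_template")) template$w else template
  if (is.complex(g)) sum(Re(Conj(w) * g)) else sum(w * g)
}

#' Closed-form ideal-observer log likelihood ratio for Gaussian backgrounds
#'
#' For a linear-Gaussian generator (background `b0 + A z`,
#' `z ~ N(0, I)`) with i.i.d. Gaussian noise, the measurement is Gaussian
#' under both hypotheses with covariance `Kg = A A' + sigma^2 I`, and the
#' exact ideal observer is linear:
#' `log Lambda = (g - b0 - s/2)' Kg^{-1} s`.  With this generator the
#' ideal-observer and Hotelling decision variables are affinely related.
#'
#' @param g Measurement vector.
#' @param mean_image Background mean `b0`.
#' @param mixing N x k mixing matrix `A`.
#' @param s Signal vector.
#' @param noise A [noise_model()].
#' @return Scalar log likelihood ratio.
#' @export
analytic_gaussian_io_log_lr <- function(g, mean_image, mixing, s, noise) {
  stopifnot(inherits(noise, "noise_model"))
  mixing <- as.matrix(mixing)
  Kg <- tcrossprod(mixing) + diag(noise$sigma^2, length(mean_image))
  sum((g - mean_image - s / 2) * solve(Kg, s))
}

#' Prior-sampling Monte-Carlo oracle for the log likelihood ratio
#'
#' Brute-force estimate of the ideal-observer log likelihood ratio via the
#' prior-expectation form
#' `log E_z[p(g | b(z), H1)] - log E_z[p(g | b(z), H0)]`, with `z` drawn
#' from the standard-normal prior and both expectations sharing the same
#' draws.  A jackknife (leave-one-out) standard error of the log ratio is
#' attached.
#'
#' @param g Measurement vector.
#' @param generator A [latent_generator()].
#' @param s Signal vector (measurement domain).
#' @param noise A [noise_model()].
#' @param n_samples Number of prior draws.
#' @param imaging Optional forward operator for object-domain generators.
#' @return Scalar log likelihood ratio with attribute `se`.
#' @export
oracle_prior_mc_log_lr <- function(g, generator, s, noise,
                                   n_samples = 10000L, imaging = NULL) {
  forward <- if (is.null(imaging)) generator$map else
    function(z) imaging(generator$map(z))
  k <- generator$latent_dim
  l0 <- numeric(n_samples)
  l1 <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    b <- forward(stats::rnorm(k))
    l0[i] <- log_gaussian_likelihood(g, b, noise)
    l1[i] <- log_gaussian_likelihood(g, b + s, noise)
  }
  est <- log_mean_exp(l1) - log_mean_exp(l0)
  loo <- log_mean_exp_loo(l1) - log_mean_exp_loo(l0)
  se <- sqrt((n_samples - 1) / n_samples * sum((loo - mean(loo))^2))
  structure(est, se = se)
}

# leave-one-out log-mean-exp, vectorized
log_mean_exp_loo <- function(x) {
  n <- length(x)
  m <- max(x)
  se <- sum(exp(x - m))
  m + log(pmax(se - exp(x - m), .Machine$double.xmin)) - log(n - 1)
}

#' Tensor-grid quadrature oracle for the log likelihood ratio
#'
#' Deterministic evaluation of the ideal-observer likelihood ratio for
#' generators with latent dimension at most 3, by tensor-product
#' quadrature of the prior-expectation ratio over a uniform latent grid
#' weighted by the standard-normal density.  The result of a refinement
#' check (change under doubling the grid density) is attached as attribute
#' `refinement`.
#'
#' @param g Measurement vector.
#' @param generator A [latent_generator()] with `latent_dim <= 3`.
#' @param s Signal vector.
#' @param noise A [noise_model()].
#' @param grid_range Half-width of the latent grid (in prior standard
#'   deviations).
#' @param grid_points Points per latent dimension.
#' @param imaging Optional forward operator for object-domain generators.
#' @param check_refinement Also evaluate at double density and report the
#'   difference?
#' @return Scalar log likelihood ratio with attribute `refinement`.
#' @export
oracle_quadrature_log_lr <- function(g, generator, s, noise,
                                     grid_range = 6, grid_points = 61L,
                                     imaging = NULL,
                                     check_refinement = TRUE) {
  if (generator$latent_dim > 3L)
    stop("quadrature oracle requires latent dimension <= 3")
  forward <- if (is.null(imaging)) generator$map else
    function(z) imaging(generator$map(z))
  eval_at <- function(npts) {
    zs <- seq(-grid_range, grid_range, length.out = npts)
    grids <- rep(list(zs), generator$latent_dim)
    Z <- as.matrix(expand.grid(grids))
    logw <- rowSums(matrix(stats::dnorm(as.numeric(Z), log = TRUE),
                           nrow(Z), ncol(Z)))
    l0 <- numeric(nrow(Z)); l1 <- numeric(nrow(Z))
    for (i in seq_len(nrow(Z))) {
      b <- forward(as.numeric(Z[i, ]))
      l0[i] <- log_gaussian_likelihood(g, b, noise)
      l1[i] <- log_gaussian_likelihood(g, b + s, noise)
    }
    log_sum_exp(logw + l1) - log_sum_exp(logw + l0)
  }
  est <- eval_at(grid_points)
  refinement <- NA_real_
  if (check_refinement) refinement <- abs(eval_at(2L * grid_points - 1L) - est)
  structure(est, refinement = refinement)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
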