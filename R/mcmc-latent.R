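#' Latent-space Markov chain for ideal-observer estimation
#'
#' Runs a Metropolis-Hastings chain with preconditioned Crank-Nicolson
#' proposals over the standard-normal latent space of a generative object
#' model, targeting the posterior `p(z | g, H0)`.  The per-iteration log
#' BKE likelihood ratio is recorded so [estimate_log_lr()] can form the
#' Monte-Carlo approximation of the ideal-observer likelihood ratio.
#'
#' If the generator emits objects (rather than image data), a forward
#' `imaging` function mapping an object vector to a (possibly complex)
#' measurement vector must be supplied; it is composed with the generator
#' at every iteration.
#'
#' @param g Measurement vector (real, or complex for k-space data).
#' @param generator A [latent_generator()].
#' @param s Signal image data in the measurement domain.
#' @param noise A [noise_model()].
#' @param config A [chain_config()].
#' @param imaging Optional function `object -> measurement vector`;
#'   required when `generator$output_domain == "object"`.
#' @param init_latent Ground-truth latent vector; required for
#'   `init = "true-latent"`.
#' @return A `chain_result` with fields `log_lbke`, `accept`, `states`
#'   (thinned latent snapshots, one row per snapshot), `state_iters`,
#'   `config` (with the frozen step size in `$pcn_beta_final`),
#'   `acceptance_rate` and `final_z`.
#' @export
run_latent_chain <- function(g, generator, s, noise, config,
                             imaging = NULL, init_latent = NULL) {
  stopifnot(inherits(generator, "latent_generator"),
            inherits(noise, "noise_model"),
            inherits(config, "chain_config"))
  if (generator$output_domain == "object" && is.null(imaging))
    stop("generator emits objects: an imaging operator must be supplied")
  forward <- if (is.null(imaging)) {
    function(z) generator$map(z)
  } else {
    function(z) imaging(generator$map(z))
  }

  set.seed(config$seed)
  k <- generator$latent_dim
  z <- switch(config$init,
    "true-latent" = {
      if (is.null(init_latent)) stop("init = 'true-latent' requires init_latent")
      as.numeric(init_latent)
    },
    "fit-latent" = fit_latent_h0(g, forward, k),
    "prior-draw" = stats::rnorm(k)
  )

  n_iter <- config$n_iterations
  burn_in <- config$burn_in
  beta <- config$pcn_beta
  adapt <- config$beta_adapt
  lo <- config$target_acceptance[1]; hi <- config$target_acceptance[2]

  # complex measurements are handled as stacked real/imaginary vectors;
  # restack once so the inner loop works purely on reals
  cplx <- is.complex(g) || is.complex(s)
  stack <- function(x) if (is.complex(x)) c(Re(x), Im(x)) else
    c(x, numeric(length(x)))
  if (cplx) {
    g_r <- stack(g); s_r <- stack(s)
    fwd_r <- function(z) stack(forward(z))
  } else {
    g_r <- as.numeric(g); s_r <- as.numeric(s)
    fwd_r <- function(z) as.numeric(forward(z))
  }
  inv2s2 <- 1 / (2 * noise$sigma^2)
  gs <- g_r - s_r / 2

  b <- fwd_r(z)
  ll <- -sum((g_r - b)^2) * inv2s2
  if (!is.finite(ll)) stop("non-finite likelihood at chain initialization")
  lbke <- sum((gs - b) * s_r) * 2 * inv2s2

  log_lbke <- numeric(n_iter)
  accept <- logical(n_iter)
  stride <- config$state_stride
  snap_iters <- seq(stride, n_iter, by = stride)
  states <- matrix(NA_real_, length(snap_iters), k)
  si <- 1L
  window_acc <- 0L; window_n <- 0L
  sq <- sqrt(1 - beta^2)

  for (t in seq_len(n_iter)) {
    zp <- sq * z + beta * stats::rnorm(k)
    bp <- fwd_r(zp)
    d <- -sum((g_r - bp)^2) * inv2s2 - ll
    if (d >= 0 || stats::runif(1) < exp(d)) {
      z <- zp; b <- bp; ll <- ll + d
      lbke <- sum((gs - b) * s_r) * 2 * inv2s2
      accept[t] <- TRUE
      window_acc <- window_acc + 1L
    }
    log_lbke[t] <- lbke
    window_n <- window_n + 1L

    if (adapt && t <= burn_in && window_n >= 50L) {
      rate <- window_acc / window_n
      if (rate < lo) beta <- max(beta * 0.8, 1e-4)
      else if (rate > hi) beta <- min(beta / 0.8, 1)
      sq <- sqrt(1 - beta^2)
      window_acc <- 0L; window_n <- 0L
    }
    if (si <= length(snap_iters) && t == snap_iters[si]) {
      states[si, ] <- z
      si <- si + 1L
    }
  }

  cfg <- config
  cfg$pcn_beta_final <- beta
  new_chain_result(log_lbke, accept, states, snap_iters, cfg,
                   extra = list(final_z = z))
}

# Bounded least-squares latent fit to g under H0 (Nelder-Mead / BFGS with
# an iteration cap); falls back to a prior draw if the fit fails.
fit_latent_h0 <- function(g, forward, k, max_iter = 200L) {
  obj <- function(z) {
    b <- forward(z)
    sum(Mod(g - b)^2)
  }
  fit <- tryCatch(
    stats::optim(numeric(k), obj, method = "BFGS",
                 control = list(maxit = max_iter)),
    error = function(e) NULL
  )
  if (is.null(fit) || !all(is.finite(fit$par))) stats::rnorm(k) else fit$par
}
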