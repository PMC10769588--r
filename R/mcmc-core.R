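# Complex measurements are treated throughout as stacked real/imaginary
# real vectors with i.i.d. N(0, sigma^2) components, so every likelihood
# reduces to a real Gaussian form.

#' Log Gaussian likelihood (unnormalized)
#'
#' Log of the i.i.d. Gaussian likelihood of a measurement given its mean,
#' up to the additive normalization constant (which cancels in every ratio
#' the samplers and observers form): `-||g - mean||^2 / (2 sigma^2)`,
#' summed over all real components (real and imaginary parts for complex
#' data).
#'
#' @param g Measurement vector (real or complex).
#' @param mean Mean vector of the same type and length.
#' @param noise A [noise_model()].
#' @return Scalar log-likelihood (unnormalized).
#' @export
log_gaussian_likelihood <- function(g, mean, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (length(g) != length(mean)) stop("shape mismatch between g and mean")
  d <- g - mean
  -sum(Mod(d)^2) / (2 * noise$sigma^2)
}

#' Log BKE likelihood ratio
#'
#' The background-known-exactly log likelihood ratio for i.i.d. Gaussian
#' noise: `log Lambda_BKE = (g - b - s/2)' s / sigma^2` (real inner product
#' over stacked real/imaginary components for complex data).  Identically
#' equals the H1 minus H0 log-likelihood difference.
#'
#' @param g Measurement vector.
#' @param b Background image data (the known background).
#' @param s Signal image data.
#' @param noise A [noise_model()].
#' @return Scalar log BKE likelihood ratio.
#' @export
log_lr_bke <- function(g, b, s, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (length(g) != length(b) || length(g) != length(s))
    stop("shape mismatch among g, b, s")
  x <- g - b - s / 2
  if (is.complex(x) || is.complex(s)) {
    sum(Re(x * Conj(s))) / noise$sigma^2
  } else {
    sum(x * s) / noise$sigma^2
  }
}

#' Preconditioned Crank-Nicolson proposal
#'
#' Proposes `z_new = sqrt(1 - beta^2) * z + beta * xi` with
#' `xi ~ N(0, I)`.  This proposal leaves the standard-normal latent prior
#' invariant, so the Metropolis-Hastings acceptance ratio reduces to a
#' likelihood ratio alone.
#'
#' @param z Current latent vector.
#' @param beta Step size in (0, 1]; `beta = 1` is a pure prior draw.
#' @return Proposed latent vector.
#' @export
pcn_propose <- function(z, beta) {
  if (!(beta > 0 && beta <= 1)) stop("beta must lie in (0, 1]")
  sqrt(1 - beta^2) * z + beta * stats::rnorm(length(z))
}

#' pCN acceptance probability
#'
#' With the prior-invariant pCN proposal the acceptance probability is
#' `min(1, p(g | b_proposed, H0) / p(g | b_current, H0))`, computed in the
#' log domain.
#'
#' @param g Measurement vector.
#' @param b_current,b_proposed Background image data at the current and
#'   proposed latent states.
#' @param noise A [noise_model()].
#' @return Acceptance probability in \[0, 1\].
#' @export
pcn_accept_prob <- function(g, b_current, b_proposed, noise) {
  d <- log_gaussian_likelihood(g, b_proposed, noise) -
    log_gaussian_likelihood(g, b_current, noise)
  if (d >= 0) 1 else exp(d)
}

#' Markov-chain sampler configuration
#'
#' @param n_iterations Total chain length (default 200000).
#' @param burn_in Iterations discarded before the Monte-Carlo average
#'   (default 10000).
#' @param pcn_beta Initial pCN step size in (0, 1].
#' @param beta_adapt Adapt the step size during burn-in toward the target
#'   acceptance band, then freeze?
#' @param target_acceptance Length-2 acceptance-rate band used when
#'   adapting.
#' @param seed Integer seed recorded with (and applied by) chain runners.
#' @param init Initialization strategy: `"true-latent"` (use the supplied
#'   ground-truth latent/parameters), `"fit-latent"` (bounded least-squares
#'   latent fit to the measurement under H0, falling back to a prior draw),
#'   or `"prior-draw"`.
#' @param state_stride Thinning stride for stored state snapshots.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_iterations = 200000L, burn_in = 10000L,
                         pcn_beta = 0.5, beta_adapt = TRUE,
                         target_acceptance = c(0.2, 0.4), seed = 1L,
                         init = c("true-latent", "fit-latent", "prior-draw"),
                         state_stride = NULL) {
  stopifnot(burn_in > 0, burn_in < n_iterations,
            pcn_beta > 0, pcn_beta <= 1)
  init <- match.arg(init)
  if (is.null(state_stride))
    state_stride <- max(1L, as.integer(n_iterations / 1000))
  structure(
    list(n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in), pcn_beta = pcn_beta,
         beta_adapt = isTRUE(beta_adapt),
         target_acceptance = target_acceptance, seed = as.integer(seed),
         init = init, state_stride = as.integer(state_stride)),
    class = "chain_config"
  )
}

new_chain_result <- function(log_lbke, accept, states, state_iters, config,
                             extra = list()) {
  res <- c(list(log_lbke = log_lbke, accept = accept, states = states,
                state_iters = state_iters, config = config,
                acceptance_rate = mean(accept)),
           extra)
  class(res) <- "chain_result"
  res
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf(
    "Markov chain: %d iterations (burn-in %d), acceptance rate %.3f\n",
    length(x$log_lbke), x$config$burn_in, x$acceptance_rate))
  cat(sprintf("  estimated log likelihood ratio: %.4f\n",
              estimate_log_lr(x)))
  invisible(x)
}

#' Estimate the log likelihood ratio from a chain
#'
#' The ideal-observer likelihood ratio is the posterior mean of the BKE
#' likelihood ratio; the chain estimate is the arithmetic mean of
#' `Lambda_BKE` over all post-burn-in iterations (rejected proposals repeat
#' the current state's value, per the standard Metropolis-Hastings
#' estimator), computed in the log domain as a log-mean-exp.  A Monte-Carlo
#' standard error of the log estimate is attached as attribute `"se"`:
#' the asymptotic variance of the autocorrelated weight series is
#' estimated by Geyer's initial-positive-sequence method and mapped to
#' the log scale by the delta method.
#'
#' @param chain A `chain_result` from [run_latent_chain()] or
#'   [run_lumpy_chain()].
#' @param burn_in Burn-in override; defaults to the chain's configured
#'   value.
#' @return Scalar log likelihood ratio with attributes `se` (standard
#'   error of the log estimate) and `J` (number of averaged iterations).
#' @export
estimate_log_lr <- function(chain, burn_in = NULL) {
  x <- if (inherits(chain, "chain_result")) chain$log_lbke else as.numeric(chain)
  if (is.null(burn_in))
    burn_in <- if (inherits(chain, "chain_result")) chain$config$burn_in else 0L
  if (burn_in >= length(x)) stop("chain not longer than burn-in")
  x <- x[(burn_in + 1L):length(x)]
  if (all(x == -Inf)) stop("all BKE likelihood-ratio values are zero")
  est <- log_mean_exp(x)
  w <- exp(x - max(x))
  mu <- mean(w)
  se <- sqrt(ips_var_of_mean(w)) / mu
  structure(est, se = se, J = length(x))
}

# Geyer initial-positive-sequence estimate of Var(mean) for a stationary
# autocorrelated series: sum adjacent autocovariance pairs while positive
# and decreasing.
ips_var_of_mean <- function(w, max_lag = min(length(w) - 1L, 5000L)) {
  n <- length(w)
  if (stats::var(w) == 0) return(0)
  acv <- drop(stats::acf(w, lag.max = max_lag, type = "covariance",
                         plot = FALSE, demean = TRUE)$acf)
  n_pairs <- floor(length(acv) / 2)
  prev <- Inf
  total <- -acv[1]
  for (k in seq_len(n_pairs) - 1L) {
    gk <- acv[2 * k + 1] + acv[2 * k + 2]
    if (gk <= 0) break
    gk <- min(gk, prev)
    total <- total + 2 * gk
    prev <- gk
  }
  max(total, acv[1]) / n
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}
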