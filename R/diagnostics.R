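#' Potential scale reduction factor across parallel chains
#'
#' Computes the between-/within-sequence variance diagnostic on a scalar
#' chain summary (here, typically the log BKE likelihood-ratio series)
#' from M parallel chains of equal length Nc:
#' `W = 1 / (M (Nc - 1)) * sum_{m,n} (v_{n,m} - vbar_m)^2`,
#' `B = Nc / (M - 1) * sum_m (vbar_m - vbar)^2`, and
#' `PSRF = (Nc - 1) / Nc + B / (Nc W)`.
#'
#' By default the statistic is returned in exactly this form (no square
#' root), which at `B = 0` evaluates to `(Nc - 1)/Nc`, slightly below one;
#' `sqrt = TRUE` returns the square-root (Gelman-Rubin style) variant.
#'
#' @param chains Numeric matrix with one chain per column, or a list of
#'   equal-length numeric vectors.
#' @param threshold Convergence threshold on the PSRF (default 1.01).
#' @param sqrt_form Return the square root of the variance-ratio statistic?
#' @return An object of class `psrf_report` with fields `psrf`, `W`, `B`,
#'   `M`, `Nc`, `threshold` and `converged`.
#' @export
psrf <- function(chains, threshold = 1.01, sqrt_form = FALSE) {
  if (is.list(chains)) {
    len <- lengths(chains)
    if (length(unique(len)) != 1L) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  M <- ncol(chains); Nc <- nrow(chains)
  if (M < 2L) stop("need at least 2 chains")
  if (Nc < 2L) stop("need at least 2 samples per chain")
  means <- colMeans(chains)
  W <- sum(sweep(chains, 2, means)^2) / (M * (Nc - 1))
  B <- Nc * sum((means - mean(means))^2) / (M - 1)
  if (W == 0) stop("degenerate chains: within-sequence variance is zero")
  val <- (Nc - 1) / Nc + B / (Nc * W)
  if (sqrt_form) val <- sqrt(val)
  structure(
    list(psrf = val, W = W, B = B, M = M, Nc = Nc, threshold = threshold,
         converged = val < threshold),
    class = "psrf_report"
  )
}

#' @export
print.psrf_report <- function(x, ...) {
  cat(sprintf(
    "PSRF = %.5f over %d chains of length %d (W = %.4g, B = %.4g): %s (threshold %g)\n",
    x$psrf, x$M, x$Nc, x$W, x$B,
    if (x$converged) "converged" else "not converged", x$threshold))
  invisible(x)
}

#' Chain autocorrelation function
#'
#' Normalized autocovariance of a scalar chain summary up to `max_lag`;
#' lag 0 is 1 by construction.
#'
#' @param series Numeric vector.
#' @param max_lag Largest lag (default `10 * log10(length)` as in
#'   [stats::acf()]).
#' @return Numeric vector of correlations at lags `0 .. max_lag`.
#' @export
autocorrelation <- function(series, max_lag = NULL) {
  series <- as.numeric(series)
  if (is.null(max_lag)) max_lag <- floor(10 * log10(length(series)))
  max_lag <- min(max_lag, length(series) - 1L)
  drop(stats::acf(series, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
}

#' Run parallel chains and report the convergence diagnostic
#'
#' Runs `n_chains` independently seeded chains of the supplied runner on
#' the same measurement and computes the PSRF on their log BKE
#' likelihood-ratio series (post burn-in).
#'
#' @param run_chain Function of a single integer seed returning a
#'   `chain_result` (close over the measurement, generator/model and
#'   config).
#' @param n_chains Number of parallel chains (default 5).
#' @param seeds Integer seeds, one per chain.
#' @param threshold PSRF convergence threshold.
#' @param discard_burn_in Drop each chain's configured burn-in before the
#'   diagnostic?
#' @return List with `psrf` (a `psrf_report`) and `chains` (list of
#'   `chain_result`s).
#' @export
run_parallel_chains <- function(run_chain, n_chains = 5L,
                                seeds = seq_len(n_chains),
                                threshold = 1.01, discard_burn_in = TRUE) {
  stopifnot(length(seeds) == n_chains, !anyDuplicated(seeds))
  chains <- lapply(seeds, run_chain)
  series <- lapply(chains, function(ch) {
    x <- ch$log_lbke
    if (discard_burn_in) x <- x[-seq_len(ch$config$burn_in)]
    x
  })
  list(psrf = psrf(series, threshold = threshold), chains = chains)
}
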