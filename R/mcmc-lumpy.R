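#' Propose a reversible lumpy-parameter move
#'
#' One Metropolis-Hastings proposal over lumpy-background parameters,
#' drawn from a three-move mixture: perturb one uniformly chosen lump
#' center by an isotropic Gaussian step (probability `p_move`), birth of a
#' lump at a uniform position (`p_birth`), or death of a uniformly chosen
#' lump (`p_death = p_birth`).  The returned log proposal and prior ratios
#' make the full Metropolis-Hastings acceptance ratio computable: the
#' prior ratio uses the Poisson count prior and uniform position
#' densities; the proposal ratio accounts for the birth/death kernel (the
#' two cancel to `log(mean_lumps / (n + 1))` plus the move-probability
#' ratio for a birth).
#'
#' @param params Current [lumpy_params()].
#' @param model The [lumpy_model()] (prior).
#' @param p_move,p_birth Move-mixture probabilities
#'   (`p_death = p_birth`; `p_move + 2 p_birth = 1`).
#' @param step_sd Standard deviation of the center-perturbation step, in
#'   pixels; defaults to a quarter of the lump width.
#' @return A list with `proposal` ([lumpy_params()] or `NULL` for an
#'   auto-rejected move), `log_proposal_ratio` (`log q(theta | proposal) -
#'   log q(proposal | theta)`), `log_prior_ratio` and `move`
#'   (`"move"`, `"birth"`, `"death"`).
#' @export
lumpy_propose <- function(params, model, p_move = 0.8, p_birth = 0.1,
                          step_sd = model$width / 4) {
  stopifnot(inherits(params, "lumpy_params"), inherits(model, "lumpy_model"))
  stopifnot(abs(p_move + 2 * p_birth - 1) < 1e-12)
  n <- params$n_lumps
  L <- model$fov
  lambda <- model$mean_lumps
  u <- stats::runif(1)
  if (u < p_move) {
    if (n == 0L)
      return(list(proposal = params, log_proposal_ratio = 0,
                  log_prior_ratio = 0, move = "move"))
    i <- sample.int(n, 1L)
    centers <- params$centers
    centers[i, ] <- centers[i, ] + stats::rnorm(2, sd = step_sd)
    prior <- if (all(centers[i, ] >= 0 & centers[i, ] < L)) 0 else -Inf
    list(proposal = lumpy_params(centers), log_proposal_ratio = 0,
         log_prior_ratio = prior, move = "move")
  } else if (u < p_move + p_birth) {
    new <- stats::runif(2, 0, L)
    # prior: Poisson pmf ratio lambda/(n+1) times uniform density 1/L^2;
    # proposal: death-pick 1/(n+1) over birth density (1/(n+1)) * (1/L^2)
    list(proposal = lumpy_params(rbind(params$centers, new)),
         log_proposal_ratio = 2 * log(L),
         log_prior_ratio = log(lambda / (n + 1)) - 2 * log(L),
         move = "birth")
  } else {
    if (n == 0L)
      return(list(proposal = NULL, log_proposal_ratio = -Inf,
                  log_prior_ratio = 0, move = "death"))
    i <- sample.int(n, 1L)
    list(proposal = lumpy_params(params$centers[-i, , drop = FALSE]),
         log_proposal_ratio = -2 * log(L),
         log_prior_ratio = log(n / lambda) + 2 * log(L),
         move = "death")
  }
}

#' Object-domain Markov chain over lumpy-background parameters
#'
#' The conventional ideal-observer Markov chain for lumpy backgrounds:
#' Metropolis-Hastings over the lump count and continuous lump centers,
#' targeting `p(theta | g, H0)`, with the acceptance ratio combining the
#' H0 likelihood ratio, the Poisson/uniform prior ratio, and the
#' birth/death proposal ratio.  Background images are updated
#' incrementally (only the moved, born or killed lump's field is
#' recomputed), which the inner C++ loop exploits.
#'
#' @param g Real measurement vector on the PRF grid.
#' @param model The [lumpy_model()] prior.
#' @param prf The [gaussian_prf()] imaging operator.
#' @param s Signal image data on the same grid.
#' @param noise A real-kind [noise_model()].
#' @param config A [chain_config()]; `init = "true-latent"` initializes at
#'   `init_params`, otherwise the chain starts from a prior draw
#'   (`"fit-latent"` is treated as a prior draw for this sampler).
#' @param init_params Ground-truth [lumpy_params()] for
#'   `init = "true-latent"`.
#' @param p_move,p_birth Move-mixture probabilities (`p_death = p_birth`).
#' @param step_sd Center-perturbation standard deviation in pixels.
#' @return A `chain_result` with the per-iteration log BKE likelihood
#'   ratio, acceptance flags, lump-count trace (`n_lumps`) and final
#'   centers.
#' @export
run_lumpy_chain <- function(g, model, prf, s, noise, config,
                            init_params = NULL, p_move = 0.8, p_birth = 0.1,
                            step_sd = model$width / 4) {
  stopifnot(inherits(model, "lumpy_model"), inherits(prf, "gaussian_prf"),
            inherits(noise, "noise_model"), inherits(config, "chain_config"),
            noise$kind == "real")
  set.seed(config$seed)
  params0 <- if (config$init == "true-latent") {
    if (is.null(init_params)) stop("init = 'true-latent' requires init_params")
    init_params
  } else {
    sample_lumpy_params(model)
  }
  w2 <- prf$width^2 + model$width^2
  amp <- model$amplitude * prf$height * model$width^2 / w2
  axes <- tensor_grid_axes(prf$grid)
  out <- cpp_run_lumpy_chain(
    as.numeric(g), as.numeric(s), axes$xs, axes$ys, params0$centers,
    model$mean_lumps, model$fov, amp, w2, noise$sigma,
    config$n_iterations, p_move, p_birth, step_sd
  )
  ll0 <- -sum((g - gaussian_sum_field(params0$centers, prf$grid, amp, w2))^2) /
    (2 * noise$sigma^2)
  if (!is.finite(ll0)) stop("non-finite likelihood at chain initialization")
  stride <- config$state_stride
  snap_iters <- seq(stride, config$n_iterations, by = stride)
  new_chain_result(
    out$log_lbke, out$accept,
    states = matrix(out$n_lumps[snap_iters], ncol = 1),
    state_iters = snap_iters, config = config,
    extra = list(n_lumps = out$n_lumps,
                 final_params = lumpy_params(out$final_centers))
  )
}

# Recover the axis vectors of a tensor-product grid (x fastest, as built
# by fov_grid()); the lumpy chain kernel exploits the separable structure.
tensor_grid_axes <- function(grid) {
  xs <- unique(grid[, 1])
  ys <- grid[seq(1, nrow(grid), by = length(xs)), 2]
  rebuilt <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  if (nrow(grid) != length(xs) * length(ys) ||
      !isTRUE(all.equal(unname(as.matrix(grid)), rebuilt)))
    stop("the lumpy chain requires a tensor-product detector grid (see fov_grid)")
  list(xs = as.numeric(xs), ys = as.numeric(ys))
}
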