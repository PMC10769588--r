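# Observer objects for detection studies: each carries its settings and
# implements score_image(), returning the scalar test statistic for one
# measurement.  MCMC observers seed their chain from the per-image derived
# seed passed in by run_detection_study().

#' Score one measurement with an observer
#'
#' @param observer An observer object.
#' @param g Measurement vector.
#' @param task The detection task the measurement came from.
#' @param truth Simulation ground truth (as returned by
#'   [simulate_measurement()]); used by chain observers for true-state
#'   initialization.
#' @param seed Per-image seed for any observer-internal randomness.
#' @return Scalar score.
#' @export
score_image <- function(observer, g, task, truth = NULL, seed = 1L) {
  UseMethod("score_image")
}

#' Hotelling observer for detection studies
#'
#' @param template A [hotelling_template()].
#' @return Observer object.
#' @export
observer_hotelling <- function(template) {
  stopifnot(inherits(template, "hotelling_template"))
  structure(list(template = template), class = "observer_hotelling")
}

#' @export
score_image.observer_hotelling <- function(observer, g, task, truth = NULL,
                                           seed = 1L) {
  hotelling_score(observer$template, g)
}

#' Lumpy-chain ideal-observer for detection studies
#'
#' Scores each measurement with the object-domain Markov-chain estimate of
#' the log likelihood ratio ([run_lumpy_chain()] + [estimate_log_lr()]),
#' initializing each chain at the true lumpy parameters of the simulated
#' measurement.
#'
#' @param config A [chain_config()] template; the per-image seed replaces
#'   its `seed`.
#' @param p_move,p_birth,step_sd Proposal settings, see
#'   [run_lumpy_chain()].
#' @return Observer object.
#' @export
observer_lumpy_mcmc <- function(config, p_move = 0.8, p_birth = 0.1,
                                step_sd = NULL) {
  stopifnot(inherits(config, "chain_config"))
  structure(list(config = config, p_move = p_move, p_birth = p_birth,
                 step_sd = step_sd),
            class = "observer_lumpy_mcmc")
}

#' @export
score_image.observer_lumpy_mcmc <- function(observer, g, task, truth = NULL,
                                            seed = 1L) {
  stopifnot(inherits(task, "lumpy_task"))
  cfg <- observer$config
  cfg$seed <- seed
  step_sd <- if (is.null(observer$step_sd)) task$model$width / 4 else
    observer$step_sd
  ch <- run_lumpy_chain(g, task$model, task$prf, task$s, task$noise, cfg,
                        init_params = truth$params,
                        p_move = observer$p_move,
                        p_birth = observer$p_birth, step_sd = step_sd)
  as.numeric(estimate_log_lr(ch))
}

#' Latent-chain ideal-observer for detection studies
#'
#' Scores each measurement with the latent-space pCN chain estimate of the
#' log likelihood ratio, initializing each chain at the measurement's true
#' latent vector (or the configured fallback).
#'
#' @param config A [chain_config()] template.
#' @return Observer object.
#' @export
observer_latent_mcmc <- function(config) {
  stopifnot(inherits(config, "chain_config"))
  structure(list(config = config), class = "observer_latent_mcmc")
}

#' @export
score_image.observer_latent_mcmc <- function(observer, g, task, truth = NULL,
                                             seed = 1L) {
  stopifnot(inherits(task, "latent_task"))
  cfg <- observer$config
  cfg$seed <- seed
  ch <- run_latent_chain(g, task$generator, task$s, task$noise, cfg,
                         imaging = task$imaging, init_latent = truth$z)
  as.numeric(estimate_log_lr(ch))
}

#' Closed-form Gaussian ideal observer for detection studies
#'
#' Exact observer for tasks whose generator is a
#' [linear_gaussian_generator()] (see [analytic_gaussian_io_log_lr()]).
#'
#' @return Observer object.
#' @export
observer_analytic_io <- function() {
  structure(list(), class = "observer_analytic_io")
}

#' @export
score_image.observer_analytic_io <- function(observer, g, task, truth = NULL,
                                             seed = 1L) {
  gen <- task$generator
  if (is.null(gen$mixing))
    stop("analytic IO requires a linear-Gaussian generator")
  analytic_gaussian_io_log_lr(g, gen$mean_image, gen$mixing, task$s,
                              task$noise)
}

#' Brute-force oracle observers for detection studies
#'
#' Scores measurements with one of the reference likelihood-ratio oracles:
#' deterministic tensor-grid quadrature (`method = "quadrature"`, latent
#' dimension at most 3) or prior-sampling Monte Carlo (`method = "mc"`).
#'
#' @param method `"quadrature"` or `"mc"`.
#' @param ... Passed to [oracle_quadrature_log_lr()] or
#'   [oracle_prior_mc_log_lr()].
#' @return Observer object.
#' @export
observer_oracle <- function(method = c("quadrature", "mc"), ...) {
  method <- match.arg(method)
  structure(list(method = method, args = list(...)),
            class = "observer_oracle")
}

#' @export
score_image.observer_oracle <- function(observer, g, task, truth = NULL,
                                        seed = 1L) {
  if (observer$method == "quadrature") {
    as.numeric(do.call(oracle_quadrature_log_lr, c(
      list(g = g, generator = task$generator, s = task$s, noise = task$noise,
           imaging = task$imaging, check_refinement = FALSE),
      observer$args)))
  } else {
    set.seed(seed)
    as.numeric(do.call(oracle_prior_mc_log_lr, c(
      list(g = g, generator = task$generator, s = task$s, noise = task$noise,
           imaging = task$imaging),
      observer$args)))
  }
}
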