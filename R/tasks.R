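#' Lumpy-background detection task
#'
#' Bundles the components of the signal-known-exactly /
#' background-known-statistically lumpy task: the lumpy object prior, the
#' Gaussian-PRF imaging operator, the Gaussian signal and the i.i.d.
#' Gaussian noise model.  Defaults reproduce the standard study
#' configuration: Poisson mean 6 lumps with `a = 1`, `wb = 8` on a
#' 64 x 64 field of view; PRF `h = 35`, `wh = 2`; signal `as = 0.3`,
#' `ws = 2.5` at the field-of-view center; noise standard deviation 20.
#'
#' @param model A [lumpy_model()].
#' @param prf A [gaussian_prf()]; defaults to the model's pixel grid.
#' @param signal A [gaussian_signal()].
#' @param noise A real-kind [noise_model()].
#' @return An object of class `lumpy_task` carrying the components plus
#'   the precomputed signal image `s`.
#' @export
lumpy_task <- function(model = lumpy_model(),
                       prf = gaussian_prf(grid = fov_grid(model$fov)),
                       signal = gaussian_signal(center = c(model$fov / 2,
                                                           model$fov / 2)),
                       noise = noise_model(20, "real")) {
  stopifnot(noise$kind == "real")
  structure(
    list(model = model, prf = prf, signal = signal, noise = noise,
         s = image_gaussian_signal(signal, prf)),
    class = c("lumpy_task", "detection_task")
  )
}

#' Latent-generator detection task
#'
#' A detection task whose random background comes from a
#' [latent_generator()]: measurement `g = b(z) (+ s) + n` for image-domain
#' generators, or `g = imaging(f(z)) (+ s) + n` for object-domain
#' generators.
#'
#' @param generator A [latent_generator()].
#' @param s Signal image data in the measurement domain.
#' @param noise A [noise_model()].
#' @param imaging Optional forward operator (function `object ->
#'   measurement`), required for object-domain generators.
#' @return An object of class `latent_task`.
#' @export
latent_task <- function(generator, s, noise, imaging = NULL) {
  stopifnot(inherits(generator, "latent_generator"),
            inherits(noise, "noise_model"))
  if (generator$output_domain == "object" && is.null(imaging))
    stop("object-domain generator requires an imaging operator")
  structure(
    list(generator = generator, s = s, noise = noise, imaging = imaging),
    class = c("latent_task", "detection_task")
  )
}

#' Simulate one measurement from a detection task
#'
#' Draws a background from the task's object prior, images it, optionally
#' adds the signal, and adds measurement noise.  The ground truth (lumpy
#' parameters or latent vector, and the noiseless background image) is
#' returned so chains can be initialized at the truth.
#'
#' @param task A `lumpy_task` or `latent_task`.
#' @param signal_present Add the signal?
#' @return List with `g` (noisy measurement), `b` (noiseless background
#'   image) and the ground truth (`params` or `z`).
#' @export
simulate_measurement <- function(task, signal_present = FALSE) {
  UseMethod("simulate_measurement")
}

#' @export
simulate_measurement.lumpy_task <- function(task, signal_present = FALSE) {
  params <- sample_lumpy_params(task$model)
  b <- image_lumpy_background(params, task$model, task$prf)
  mean_g <- if (signal_present) b + task$s else b
  list(g = add_noise(mean_g, task$noise), b = b, params = params)
}

#' @export
simulate_measurement.latent_task <- function(task, signal_present = FALSE) {
  draw <- sample_generator_prior(task$generator)
  b <- if (is.null(task$imaging)) draw$b else task$imaging(draw$b)
  mean_g <- if (signal_present) b + task$s else b
  list(g = add_noise(mean_g, task$noise), b = b, z = draw$z)
}

#' Deterministic per-image seed derivation
#'
#' Derives a per-use seed from a master seed, an image index and a chain
#' id, so independently processed images need no shared random-stream
#' coordination.  The result is always a valid (below 2^31) positive
#' integer.
#'
#' @param master Master integer seed.
#' @param index Image index.
#' @param chain_id Chain identifier (0 for data simulation).
#' @return Integer seed.
#' @export
derive_seed <- function(master, index, chain_id = 0L) {
  v <- (as.double(master) %% 2147483647) * 1048576 +
    as.double(index) * 1031 + as.double(chain_id) * 7919
  as.integer(v %% 2147483629 + 1)
}
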