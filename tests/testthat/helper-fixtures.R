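# Small fixtures shared across tests.  Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# Reduced lumpy task (16 x 16 field of view) for unit tests; the
# full-scale task (64 x 64) is exercised in the acceptance tests.
small_lumpy_task <- function() {
  model <- lumpy_model(mean_lumps = 3, amplitude = 1, width = 3, fov = 16)
  lumpy_task(
    model = model,
    prf = gaussian_prf(height = 10, width = 1.5, grid = fov_grid(16)),
    signal = gaussian_signal(amplitude = 0.5, width = 1.5, center = c(8, 8)),
    noise = noise_model(3, "real")
  )
}

# Linear-Gaussian task on an 8 x 8 grid: exact IO available in closed form.
small_linear_task <- function(k = 3, seed = 42, sigma = 1) {
  set.seed(seed)
  n <- 64
  A <- matrix(rnorm(n * k), n, k)
  gen <- linear_gaussian_generator(rep(1, n), A)
  s <- 0.5 * evaluate_gaussian_signal(
    gaussian_signal(amplitude = 1, width = 1.5, center = c(3.5, 3.5)),
    fov_grid(8))
  latent_task(gen, s, noise_model(sigma, "real"))
}

# Blob task on a 16 x 16 grid: quadrature oracle available (k = 2).
small_blob_task <- function() {
  gen <- blob_generator(k = 2, fov = 16)
  s <- evaluate_gaussian_signal(
    gaussian_signal(amplitude = 0.2, width = 2, center = c(7.5, 7.5)),
    fov_grid(16))
  latent_task(gen, s, noise_model(0.3, "real"))
}
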