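test_that("log Gaussian likelihood matches direct summation", {
  nz <- noise_model(2, "real")
  g <- rep(1, 5)
  expect_equal(log_gaussian_likelihood(g, g, nz), 0)
  expect_equal(log_gaussian_likelihood(3, 1, nz), -1 / 2)

  set.seed(1)
  g <- rnorm(10); m <- rnorm(10)
  expect_equal(log_gaussian_likelihood(g, m, nz),
               -sum((g - m)^2) / (2 * 4))

  # complex data: stacked real/imaginary components
  gc <- complex(real = rnorm(6), imaginary = rnorm(6))
  mc <- complex(real = rnorm(6), imaginary = rnorm(6))
  expect_equal(
    log_gaussian_likelihood(gc, mc, nz),
    -(sum((Re(gc) - Re(mc))^2) + sum((Im(gc) - Im(mc))^2)) / (2 * 4))

  expect_error(log_gaussian_likelihood(1:3, 1:4, nz), "mismatch")
})

test_that("log BKE likelihood ratio equals the likelihood-difference identity", {
  nz <- noise_model(1.5, "real")
  set.seed(2)
  g <- rnorm(8); b <- rnorm(8); s <- rnorm(8)

  expect_equal(log_lr_bke(g, b, rep(0, 8), nz), 0)
  expect_equal(log_lr_bke(b + s / 2, b, s, nz), 0)
  expect_equal(
    log_lr_bke(g, b, s, nz),
    log_gaussian_likelihood(g, b + s, nz) -
      log_gaussian_likelihood(g, b, nz))

  # complex case: same identity over stacked components
  gc <- complex(real = rnorm(5), imaginary = rnorm(5))
  bc <- complex(real = rnorm(5), imaginary = rnorm(5))
  sc <- complex(real = rnorm(5), imaginary = rnorm(5))
  expect_equal(
    log_lr_bke(gc, bc, sc, nz),
    log_gaussian_likelihood(gc, bc + sc, nz) -
      log_gaussian_likelihood(gc, bc, nz))
})

test_that("pCN proposal preserves the standard-normal prior", {
  z <- c(1, -2, 0.5)
  set.seed(5)
  near <- pcn_propose(z, 1e-8)
  expect_equal(near, z, tolerance = 1e-6)

  # beta = 1 is a pure prior draw, independent of z
  set.seed(6); a <- pcn_propose(z, 1)
  set.seed(6); b <- pcn_propose(100 * z, 1)
  expect_equal(a, b)

  # prior invariance: z ~ N(0,I) implies the proposal ~ N(0,I)
  set.seed(7)
  zs <- matrix(rnorm(2e5), ncol = 2)
  props <- t(apply(zs, 1, pcn_propose, beta = 0.6))
  expect_lt(max(abs(colMeans(props))), 3 / sqrt(1e5))
  expect_lt(max(abs(apply(props, 2, var) - 1)), 3 * sqrt(2 / 1e5))

  expect_error(pcn_propose(z, 0), "beta")
  expect_error(pcn_propose(z, 1.2), "beta")
})

test_that("pCN acceptance probability is the clipped H0 likelihood ratio", {
  nz <- noise_model(1, "real")
  g <- c(1, 2, 3)
  expect_equal(pcn_accept_prob(g, g + 1, g + 1, nz), 1)
  expect_equal(pcn_accept_prob(g, g + 1, g, nz), 1)
  set.seed(8)
  b1 <- g + rnorm(3); b2 <- g + rnorm(3)
  direct <- min(1, exp(-sum((g - b2)^2) / 2) / exp(-sum((g - b1)^2) / 2))
  expect_equal(pcn_accept_prob(g, b1, b2, nz), direct)
})

test_that("estimate_log_lr is the log-mean-exp of post-burn-in values", {
  expect_equal(as.numeric(estimate_log_lr(rep(2.5, 100), burn_in = 10)), 2.5)
  expect_equal(as.numeric(estimate_log_lr(c(log(1), log(3)), burn_in = 0)),
               log(2))
  set.seed(9)
  x <- rnorm(500)
  expect_equal(as.numeric(estimate_log_lr(x, burn_in = 100)),
               log(mean(exp(x[101:500]))))
  expect_error(estimate_log_lr(rep(-Inf, 50), burn_in = 10), "zero")
  expect_error(estimate_log_lr(1:5, burn_in = 10), "burn-in")
})

test_that("lumpy proposal returns the ratios that make the chain reversible", {
  model <- lumpy_model(mean_lumps = 6, fov = 64)
  p <- lumpy_params(rbind(c(10, 10), c(30, 40)))

  set.seed(10)
  reps <- replicate(200, lumpy_propose(p, model), simplify = FALSE)
  moves <- vapply(reps, `[[`, character(1), "move")
  expect_setequal(unique(moves), c("move", "birth", "death"))

  mv <- reps[[which(moves == "move")[1]]]
  expect_equal(mv$log_proposal_ratio, 0)

  bi <- reps[[which(moves == "birth")[1]]]
  expect_equal(bi$log_prior_ratio + bi$log_proposal_ratio, log(6 / 3))
  expect_equal(bi$proposal$n_lumps, 3)

  de <- reps[[which(moves == "death")[1]]]
  expect_equal(de$log_prior_ratio + de$log_proposal_ratio, log(2 / 6))

  # death with an empty configuration is auto-rejected
  empty <- lumpy_params(matrix(numeric(0), 0, 2))
  set.seed(2)
  reps0 <- replicate(100, lumpy_propose(empty, model), simplify = FALSE)
  d0 <- Filter(function(r) r$move == "death", reps0)
  expect_gt(length(d0), 0)
  expect_true(all(vapply(d0, function(r) is.null(r$proposal), logical(1))))
  expect_true(all(vapply(d0, function(r) r$log_proposal_ratio == -Inf,
                         logical(1))))
})

test_that("lumpy chain with flat likelihood samples the Poisson prior", {
  task <- small_lumpy_task()
  set.seed(21)
  sim <- simulate_measurement(task, FALSE)
  flat <- noise_model(1e9, "real")
  cfg <- chain_config(n_iterations = 60000, burn_in = 5000, seed = 3)
  ch <- run_lumpy_chain(sim$g, task$model, task$prf, task$s, flat, cfg,
                        init_params = sim$params)
  counts <- ch$n_lumps[-(1:5000)]
  # thin to reduce autocorrelation before the goodness-of-fit test
  counts <- counts[seq(1, length(counts), by = 50)]
  brk <- 0:8
  obs <- table(factor(pmin(counts, 8), levels = brk))
  p <- dpois(brk, 3)
  p[length(p)] <- 1 - ppois(7, 3)
  expect_gt(chisq.test(as.numeric(obs), p = p)$p.value, 0.01)
})

test_that("lumpy chain is reproducible and its incremental updates are exact", {
  task <- small_lumpy_task()
  set.seed(22)
  sim <- simulate_measurement(task, TRUE)
  cfg <- chain_config(n_iterations = 3000, burn_in = 500, seed = 13)
  ch1 <- run_lumpy_chain(sim$g, task$model, task$prf, task$s, task$noise,
                         cfg, init_params = sim$params)
  ch2 <- run_lumpy_chain(sim$g, task$model, task$prf, task$s, task$noise,
                         cfg, init_params = sim$params)
  expect_identical(ch1$log_lbke, ch2$log_lbke)
  expect_identical(ch1$final_params$centers, ch2$final_params$centers)

  # recompute the final background from scratch: the incrementally
  # maintained BKE value must match to near machine precision
  w2 <- task$prf$width^2 + task$model$width^2
  amp <- task$model$amplitude * task$prf$height * task$model$width^2 / w2
  b_final <- evaluate_lumpy_object(
    ch1$final_params,
    lumpy_model(task$model$mean_lumps, amp, sqrt(w2), task$model$fov),
    task$prf$grid)
  expect_equal(tail(ch1$log_lbke, 1),
               log_lr_bke(sim$g, b_final, task$s, task$noise),
               tolerance = 1e-10)
})

test_that("lumpy chain posterior concentrates near the true background", {
  task <- small_lumpy_task()
  set.seed(23)
  sim <- simulate_measurement(task, FALSE)
  cfg <- chain_config(n_iterations = 20000, burn_in = 2000, seed = 14)
  ch <- run_lumpy_chain(sim$g, task$model, task$prf, task$s, task$noise,
                        cfg, init_params = sim$params)
  # posterior-final background should correlate strongly with the truth
  w2 <- task$prf$width^2 + task$model$width^2
  amp <- task$model$amplitude * task$prf$height * task$model$width^2 / w2
  b_final <- evaluate_lumpy_object(
    ch$final_params,
    lumpy_model(task$model$mean_lumps, amp, sqrt(w2), task$model$fov),
    task$prf$grid)
  expect_gt(cor(b_final, sim$b), 0.8)
})

test_that("latent chain is reproducible and recovers the conjugate posterior", {
  task <- small_linear_task(k = 2, seed = 31)
  gen <- task$generator
  set.seed(32)
  zt <- rnorm(2)
  g <- generate_background(gen, zt) + task$s + rnorm(64)

  cfg <- chain_config(n_iterations = 2000, burn_in = 500, seed = 15)
  ch1 <- run_latent_chain(g, gen, task$s, task$noise, cfg, init_latent = zt)
  ch2 <- run_latent_chain(g, gen, task$s, task$noise, cfg, init_latent = zt)
  expect_identical(ch1$log_lbke, ch2$log_lbke)
  expect_identical(ch1$states, ch2$states)

  # conjugate Gaussian posterior: cov = (I + A'A)^-1, mean = cov A'(g - b0)
  A <- gen$mixing
  post_cov <- solve(diag(2) + crossprod(A))
  post_mean <- drop(post_cov %*% crossprod(A, g - gen$mean_image))
  cfg2 <- chain_config(n_iterations = 60000, burn_in = 5000, seed = 16,
                       state_stride = 10L)
  ch <- run_latent_chain(g, gen, task$s, task$noise, cfg2, init_latent = zt)
  zs <- ch$states[ch$state_iters > 5000, ]
  expect_lt(max(abs(colMeans(zs) - post_mean)), 0.05)
  expect_lt(max(abs(cov(zs) - post_cov)), 0.05)
})

test_that("latent chain requires an imaging operator for object-domain generators", {
  gen <- latent_generator(function(z) rep(z[1], 4), 1, 4,
                          output_domain = "object")
  cfg <- chain_config(n_iterations = 100, burn_in = 10, seed = 1)
  nz <- noise_model(1, "real")
  expect_error(
    run_latent_chain(rep(0, 4), gen, rep(0, 4), nz, cfg,
                     init_latent = 0),
    "imaging")
  # with an identity imaging operator the chain runs
  ch <- run_latent_chain(rep(0, 4), gen, rep(0, 4), nz, cfg,
                         imaging = identity, init_latent = 0)
  expect_length(ch$log_lbke, 100)
})

test_that("lumpy chain log-LR agrees with brute-force prior sampling on a tiny task", {
  model <- lumpy_model(mean_lumps = 2, amplitude = 1, width = 2, fov = 8)
  prf <- gaussian_prf(height = 8, width = 1.2, grid = fov_grid(8))
  signal <- gaussian_signal(amplitude = 0.8, width = 1.2, center = c(4, 4))
  nz <- noise_model(4, "real")
  task <- lumpy_task(model, prf, signal, nz)

  set.seed(902)
  sim <- simulate_measurement(task, signal_present = TRUE)
  cfg <- chain_config(n_iterations = 100000, burn_in = 10000, seed = 952)
  ch <- run_lumpy_chain(sim$g, model, prf, task$s, nz, cfg,
                        init_params = sim$params)
  est <- estimate_log_lr(ch)

  # independent oracle: likelihood-ratio of prior expectations over theta
  set.seed(982)
  ndraw <- 120000
  l0 <- numeric(ndraw); l1 <- numeric(ndraw)
  for (j in seq_len(ndraw)) {
    b <- image_lumpy_background(sample_lumpy_params(model), model, prf)
    l0[j] <- log_gaussian_likelihood(sim$g, b, nz)
    l1[j] <- log_gaussian_likelihood(sim$g, b + task$s, nz)
  }
  lse <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
  loo <- function(x) {
    m <- max(x); s <- sum(exp(x - m))
    m + log(pmax(s - exp(x - m), 1e-300)) - log(length(x) - 1)
  }
  oracle <- lse(l1) - lse(l0)
  jk <- loo(l1) - loo(l0)
  oracle_se <- sqrt((ndraw - 1) / ndraw * sum((jk - mean(jk))^2))
  combined <- sqrt(attr(est, "se")^2 + oracle_se^2)
  expect_lt(abs(as.numeric(est) - oracle), 3 * combined)
})

test_that("fit-latent initialization recovers a workable starting point", {
  task <- small_linear_task(k = 2, seed = 33)
  gen <- task$generator
  set.seed(34)
  zt <- rnorm(2)
  g <- generate_background(gen, zt) + rnorm(64, sd = 0.1)
  cfg <- chain_config(n_iterations = 500, burn_in = 100, seed = 17,
                      init = "fit-latent")
  ch <- run_latent_chain(g, gen, task$s, task$noise, cfg)
  expect_length(ch$log_lbke, 500)
  # the least-squares fit under low noise lands near the true latent
  fit <- idealobserver:::fit_latent_h0(g, gen$map, 2)
  expect_lt(sqrt(sum((fit - zt)^2)), 0.5)
})
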