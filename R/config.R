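# Experiment configuration, persistence and the runnable pipeline:
# simulate -> run chains -> evaluate.  File formats are plain text
# (CSV for arrays and score tables, JSON/YAML for metadata), with every
# random operation seeded from one master seed via derive_seed().

#' Read and validate an experiment configuration
#'
#' Loads a YAML experiment configuration with `task`, `observer` and
#' `study` blocks and validates the schema, naming the offending field on
#' error.  Currently supported task type: `"lumpy"`; observer engines:
#' `"hotelling"`, `"lumpy-mcmc"`.
#'
#' @param path Path to a YAML file, or a list already in configuration
#'   form.
#' @return Validated configuration list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  need <- function(block, field, default = NULL) {
    x <- cfg[[block]][[field]]
    if (is.null(x)) {
      if (is.null(default))
        stop(sprintf("experiment config: missing required field '%s.%s'",
                     block, field))
      x <- default
    }
    x
  }
  for (block in c("task", "observer", "study"))
    if (is.null(cfg[[block]]))
      stop(sprintf("experiment config: missing required block '%s'", block))
  type <- need("task", "type")
  if (!identical(type, "lumpy"))
    stop(sprintf("experiment config: unsupported task.type '%s'", type))
  engine <- need("observer", "engine")
  if (!engine %in% c("hotelling", "lumpy-mcmc"))
    stop(sprintf("experiment config: unsupported observer.engine '%s'",
                 engine))
  m <- need("task", "model", list())
  p <- need("task", "prf", list())
  sg <- need("task", "signal", list())
  nz <- need("task", "noise", list())
  model <- lumpy_model(
    mean_lumps = m$mean_lumps %||% 6, amplitude = m$amplitude %||% 1,
    width = m$width %||% 8, fov = m$fov %||% 64)
  task <- lumpy_task(
    model = model,
    prf = gaussian_prf(height = p$height %||% 35, width = p$width %||% 2,
                       grid = fov_grid(model$fov)),
    signal = gaussian_signal(
      amplitude = sg$amplitude %||% 0.3, width = sg$width %||% 2.5,
      center = unlist(sg$center) %||% c(model$fov / 2, model$fov / 2)),
    noise = noise_model(nz$sigma %||% 20, "real"))
  out <- list(
    task = task, engine = engine,
    chain = cfg$observer$chain %||% list(),
    hotelling = cfg$observer$hotelling %||% list(),
    n_h0 = need("study", "n_h0", 200L), n_h1 = need("study", "n_h1", 200L),
    seed = need("study", "seed", 1L), raw = cfg)
  class(out) <- "experiment_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_chain <- function(config) {
  ch <- config$chain
  chain_config(
    n_iterations = ch$n_iterations %||% 200000L,
    burn_in = ch$burn_in %||% 10000L,
    pcn_beta = ch$pcn_beta %||% 0.5,
    seed = config$seed,
    init = ch$init %||% "true-latent")
}

#' Simulate an experiment's measurement dataset
#'
#' Writes labeled signal-absent / signal-present measurement sets, the
#' ground-truth lumpy parameters, and a JSON manifest to `out_dir`.
#' Re-running with the same configuration reproduces identical files.
#'
#' @param config An `experiment_config` (or path to one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
simulate_experiment <- function(config, out_dir) {
  if (!inherits(config, "experiment_config"))
    config <- read_experiment_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- config$n_h0 + config$n_h1
  M <- nrow(config$task$prf$grid)
  g <- matrix(0, n, M)
  truth <- vector("list", n)
  labels <- rep(c(0L, 1L), c(config$n_h0, config$n_h1))
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i, 0L))
    sim <- simulate_measurement(config$task, signal_present = labels[i] == 1L)
    g[i, ] <- sim$g
    truth[[i]] <- sim$params$centers
  }
  utils::write.csv(g, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(truth, function(x) unname(as.data.frame(x))),
    file.path(out_dir, "truth_centers.json"), digits = NA)
  manifest <- list(
    n_records = n, n_h0 = config$n_h0, n_h1 = config$n_h1,
    labels = labels, seed = config$seed,
    fov = config$task$model$fov, created = "simulate_experiment")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run per-image Markov chains over a simulated dataset
#'
#' Runs the configured chain observer on each measurement in an index
#' range, writing one chain summary file per image (JSON with the log
#' likelihood-ratio estimate, acceptance rate and seed) plus the full log
#' BKE likelihood-ratio series as CSV.  Completed indices are skipped
#' unless `force = TRUE`, so interrupted runs are resumable.
#'
#' @param config An `experiment_config` (or path).
#' @param dataset_dir Directory written by [simulate_experiment()].
#' @param out_dir Chain output directory.
#' @param indices Image indices to process (default: all).
#' @param force Recompute existing chain files?
#' @param keep_series Also write the per-iteration series CSV?
#' @return Invisibly, the processed indices.
#' @export
run_experiment_chains <- function(config, dataset_dir, out_dir,
                                  indices = NULL, force = FALSE,
                                  keep_series = FALSE) {
  if (!inherits(config, "experiment_config"))
    config <- read_experiment_config(config)
  if (config$engine != "lumpy-mcmc")
    stop("run_experiment_chains requires a chain-based observer engine")
  manifest <- jsonlite::read_json(file.path(dataset_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- as.matrix(utils::read.csv(file.path(dataset_dir, "measurements.csv")))
  truth <- jsonlite::read_json(file.path(dataset_dir, "truth_centers.json"),
                               simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(indices)) indices <- seq_len(manifest$n_records)
  cfg0 <- config_chain(config)
  done <- integer(0)
  for (i in indices) {
    out_json <- file.path(out_dir, sprintf("chain_%04d.json", i))
    if (file.exists(out_json) && !force) next
    cfg <- cfg0
    cfg$seed <- derive_seed(config$seed, i, 1L)
    centers <- truth[[i]]
    params <- lumpy_params(if (length(centers)) as.matrix(centers) else
      matrix(numeric(0), 0, 2))
    ch <- run_lumpy_chain(g[i, ], config$task$model, config$task$prf,
                          config$task$s, config$task$noise, cfg,
                          init_params = params)
    est <- estimate_log_lr(ch)
    jsonlite::write_json(
      list(index = i, log_lr = as.numeric(est), se = attr(est, "se"),
           acceptance_rate = ch$acceptance_rate, seed = cfg$seed,
           n_iterations = cfg$n_iterations, burn_in = cfg$burn_in),
      out_json, auto_unbox = TRUE, digits = NA)
    if (keep_series)
      utils::write.csv(data.frame(log_lbke = ch$log_lbke),
                       file.path(out_dir, sprintf("chain_%04d.csv", i)),
                       row.names = FALSE)
    done <- c(done, i)
  }
  invisible(done)
}

#' Evaluate an experiment into a detection-study result
#'
#' Assembles per-image scores (chain files for MCMC engines; direct
#' scoring for the Hotelling engine) into ROC/AUC summaries, writing
#' `scores.csv` and `summary.json` to `out_dir`.
#'
#' @param config An `experiment_config` (or path).
#' @param dataset_dir Directory written by [simulate_experiment()].
#' @param chains_dir Directory written by [run_experiment_chains()]
#'   (chain engines only).
#' @param out_dir Output directory.
#' @return A `detection_study_result`-like list with `auc`, `auc_se` and
#'   score vectors.
#' @export
evaluate_experiment <- function(config, dataset_dir, chains_dir = NULL,
                                out_dir = NULL) {
  if (!inherits(config, "experiment_config"))
    config <- read_experiment_config(config)
  manifest <- jsonlite::read_json(file.path(dataset_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  labels <- manifest$labels
  n <- manifest$n_records
  if (config$engine == "hotelling") {
    g <- as.matrix(utils::read.csv(file.path(dataset_dir,
                                             "measurements.csv")))
    set.seed(derive_seed(config$seed, 0L, 2L))
    kb <- lumpy_background_covariance(
      config$task$model, config$task$prf,
      n = config$hotelling$n_covariance_samples %||% 20000L)
    tmpl <- hotelling_template(kb, config$task$noise, config$task$s)
    scores <- as.numeric(g %*% tmpl$w)
  } else {
    files <- file.path(chains_dir, sprintf("chain_%04d.json", seq_len(n)))
    missing <- which(!file.exists(files))
    if (length(missing))
      stop("missing chain files for indices: ",
           paste(missing, collapse = ", "))
    scores <- vapply(files, function(f) {
      jsonlite::read_json(f, simplifyVector = TRUE)$log_lr
    }, numeric(1), USE.NAMES = FALSE)
  }
  h0 <- scores[labels == 0L]; h1 <- scores[labels == 1L]
  a <- auc(h0, h1)
  res <- list(h0_scores = h0, h1_scores = h1,
              roc = empirical_roc(h0, h1), auc = a$auc, auc_se = a$se,
              n_failures = 0L,
              config = list(engine = config$engine, seed = config$seed,
                            n_h0 = manifest$n_h0, n_h1 = manifest$n_h1))
  class(res) <- "detection_study_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(index = seq_len(n), label = labels,
                                score = scores),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(engine = config$engine, auc = res$auc, auc_se = res$auc_se,
           n_h0 = manifest$n_h0, n_h1 = manifest$n_h1,
           seed = config$seed),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
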