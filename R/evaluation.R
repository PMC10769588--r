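#' Empirical ROC curve
#'
#' Sweeps the decision threshold over all observed score values (ties
#' grouped) and reports the false-positive fraction / true-positive
#' fraction operating points, from (0, 0) to (1, 1).
#'
#' @param h0_scores Scores of signal-absent measurements.
#' @param h1_scores Scores of signal-present measurements.
#' @return Data frame with columns `fpf` and `tpf` (a nondecreasing step
#'   curve).
#' @export
empirical_roc <- function(h0_scores, h1_scores) {
  thr <- sort(unique(c(h0_scores, h1_scores)), decreasing = TRUE)
  fpf <- vapply(thr, function(t) mean(h0_scores >= t), numeric(1))
  tpf <- vapply(thr, function(t) mean(h1_scores >= t), numeric(1))
  data.frame(fpf = c(0, fpf), tpf = c(0, tpf))
}

#' Empirical AUC with standard error
#'
#' Mann-Whitney estimator of the area under the ROC curve (ties count
#' one half), with the Hanley-McNeil analytic standard error or an
#' optional bootstrap.
#'
#' @param h0_scores,h1_scores Score sets under the two hypotheses.
#' @param se_method `"hanley-mcneil"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `se_method = "bootstrap"`.
#' @return List with `auc` and `se`.
#' @export
auc <- function(h0_scores, h1_scores,
                se_method = c("hanley-mcneil", "bootstrap"),
                n_boot = 2000L) {
  se_method <- match.arg(se_method)
  n0 <- length(h0_scores); n1 <- length(h1_scores)
  stopifnot(n0 > 0, n1 > 0)
  a <- auc_mw(h0_scores, h1_scores)
  if (se_method == "hanley-mcneil") {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                  (n0 - 1) * (q2 - a^2)) / (n0 * n1))
  } else {
    boots <- vapply(seq_len(n_boot), function(i) {
      auc_mw(sample(h0_scores, n0, replace = TRUE),
             sample(h1_scores, n1, replace = TRUE))
    }, numeric(1))
    se <- stats::sd(boots)
  }
  list(auc = a, se = se)
}

# Mann-Whitney AUC via midranks (ties contribute 1/2)
auc_mw <- function(h0_scores, h1_scores) {
  n0 <- length(h0_scores); n1 <- length(h1_scores)
  r <- rank(c(h0_scores, h1_scores))
  (sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Run a detection study
#'
#' Simulates paired signal-absent / signal-present measurement sets from a
#' detection task, scores every measurement with the configured observer,
#' and assembles the empirical ROC and AUC.  Each image gets a derived
#' seed (from the master seed and its index) for both simulation and any
#' observer-internal Markov chain, so studies are reproducible and
#' images can be processed independently.  An observer failure on an
#' image is recorded and the study continues.
#'
#' @param task A `lumpy_task` or `latent_task`.
#' @param observer An observer object (see [observer_hotelling()],
#'   [observer_lumpy_mcmc()], [observer_latent_mcmc()],
#'   [observer_analytic_io()], [observer_oracle()]).
#' @param n_h0,n_h1 Numbers of signal-absent and signal-present images
#'   (default 200 each).
#' @param seed Master seed.
#' @return An object of class `detection_study_result` with score sets,
#'   ROC points, AUC with standard error, failure count and the study
#'   configuration echo.
#' @export
run_detection_study <- function(task, observer, n_h0 = 200L, n_h1 = 200L,
                                seed = 1L) {
  stopifnot(inherits(task, "detection_task"))
  score_one <- function(index, signal_present) {
    set.seed(derive_seed(seed, index, 0L))
    sim <- simulate_measurement(task, signal_present)
    tryCatch(
      score_image(observer, sim$g, task, truth = sim,
                  seed = derive_seed(seed, index, 1L)),
      error = function(e) NA_real_
    )
  }
  h0 <- vapply(seq_len(n_h0), score_one, numeric(1), signal_present = FALSE)
  h1 <- vapply(n_h0 + seq_len(n_h1), score_one, numeric(1),
               signal_present = TRUE)
  failures <- sum(is.na(h0)) + sum(is.na(h1))
  h0 <- h0[!is.na(h0)]; h1 <- h1[!is.na(h1)]
  a <- auc(h0, h1)
  structure(
    list(h0_scores = h0, h1_scores = h1,
         roc = empirical_roc(h0, h1), auc = a$auc, auc_se = a$se,
         n_failures = failures,
         config = list(n_h0 = n_h0, n_h1 = n_h1, seed = seed,
                       observer = class(observer)[1])),
    class = "detection_study_result"
  )
}

#' @export
print.detection_study_result <- function(x, ...) {
  cat(sprintf(
    "Detection study (%s): AUC = %.3f +/- %.3f (%d + %d images%s)\n",
    x$config$observer, x$auc, x$auc_se,
    length(x$h0_scores), length(x$h1_scores),
    if (x$n_failures > 0) sprintf(", %d failures", x$n_failures) else ""))
  invisible(x)
}

#' Radially averaged power spectrum of an image ensemble
#'
#' Ensemble-averaged squared magnitude of the unitary 2D Fourier
#' transform, averaged over all angles in integer-radius frequency bins.
#' Used to compare the second-order statistics of two image ensembles
#' (for instance, training images versus images synthesized by a
#' generative object model).
#'
#' @param images List of image vectors/matrices, or a matrix with one
#'   image per row; all images must be square and equally sized.
#' @return Data frame with columns `radius` (k-space pixels) and `power`.
#' @export
radial_power_spectrum <- function(images) {
  if (is.matrix(images))
    images <- lapply(seq_len(nrow(images)), function(i) images[i, ])
  n <- sqrt(length(images[[1]]))
  if (n != round(n)) stop("images must be square")
  n <- as.integer(n)
  acc <- matrix(0, n, n)
  for (img in images) {
    m <- if (is.matrix(img)) img else matrix(img, n, n)
    acc <- acc + Mod(stats::fft(m) / n)^2
  }
  acc <- acc / length(images)
  k <- ifelse(seq_len(n) - 1 < n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  kr <- round(sqrt(outer(k^2, k^2, "+")))
  agg <- tapply(as.numeric(acc), as.numeric(kr), mean)
  data.frame(radius = as.numeric(names(agg)), power = as.numeric(agg))
}
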