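#' Staircase configuration for the simulated matching experiment
#'
#' The matching level of each trial is driven by a pair of interleaved
#' 1-up-1-down staircases, each terminating after a fixed number of
#' reversals.  A "match looks higher" response lowers the matching level, a
#' "test looks higher" response raises it, so each staircase converges on the
#' 50% point of the psychometric function — the point of subjective equality.
#' The step is larger before a staircase's first reversal to reach the
#' convergence region quickly; the two staircases start above and below the
#' nominal initial level.
#'
#' @param n_reversals Reversals at which each staircase terminates.
#' @param initial_level Nominal starting matching level, percent.
#' @param step_db_initial Step size before a staircase's first reversal, dB.
#' @param step_db Step size after the first reversal, dB.
#' @param n_interleaved Number of interleaved staircases.
#' @param start_offset_db Staircase starting levels are placed at
#'   `initial_level` +- this offset (dB), alternating.
#' @param min_level,max_level Clamps on the matching level, percent.
#' @return A `staircase_config`.
#' @export
staircase_config <- function(n_reversals = 12, initial_level = 10,
                             step_db_initial = 3, step_db = 1.5,
                             n_interleaved = 2, start_offset_db = 4,
                             min_level = 0.05, max_level = 200) {
  if (n_reversals < 1) abort("n_reversals must be positive")
  if (step_db <= 0 || step_db_initial <= 0) abort("step sizes must be positive")
  if (initial_level <= 0) abort("initial_level must be positive")
  structure(list(n_reversals = as.integer(n_reversals),
                 initial_level = initial_level,
                 step_db_initial = step_db_initial, step_db = step_db,
                 n_interleaved = as.integer(n_interleaved),
                 start_offset_db = start_offset_db,
                 min_level = min_level, max_level = max_level),
            class = "staircase_config")
}

#' Simulate a single 2IFC contrast-matching choice
#'
#' A late-noise signal-detection decision stage: the observer reports the
#' matching stimulus as higher in overall contrast when its internal response,
#' perturbed by zero-mean Gaussian noise, exceeds the (equally noisy) response
#' to the test.  Exact ties are broken at random, so equal responses give
#' P(match) = 0.5 even with zero noise.
#'
#' @param r_test,r_match Model responses to test and match (arbitrary units).
#' @param noise_sd Standard deviation of the additive response noise.
#' @return `"match"` or `"test"`.
#' @export
simulate_choice <- function(r_test, r_match, noise_sd = 0.15) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  d <- (r_match - r_test) + if (noise_sd > 0) rnorm(1, 0, noise_sd * sqrt(2)) else 0
  if (d == 0) d <- stats::runif(1) - 0.5
  if (d > 0) "match" else "test"
}

#' Run one repetition of interleaved 1-up-1-down staircases
#'
#' Simulates the trial stream of one repetition of the matching experiment for
#' a model observer: interleaved staircases control the matching level, the
#' observer's choice on each trial follows [simulate_choice()], and each
#' staircase terminates after `config$n_reversals` reversals (two 12-reversal
#' staircases yield roughly 40-50 trials).  The spatial parity of the A/B
#' assignment is re-randomised every trial for fidelity to the procedure; all
#' implemented models are permutation-symmetric, so it does not affect
#' responses.
#'
#' Uses R's global random number stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @inheritParams predict_pse
#' @param noise_sd Decision noise, see [simulate_choice()].
#' @param config A [staircase_config()].
#' @param ... Geometry and pipeline arguments passed to the response builder
#'   (as in [predict_pse()]).
#' @return A tibble of trial records: `trial`, `staircase`, `level_pct`,
#'   `parity`, `choice`, `reversal`.
#' @export
run_staircase <- function(A, B = 8, model = "ms",
                          match_mode = c("single", "dual"),
                          granularity = "toy", filtered = FALSE, j = 1,
                          params = model_params(), noise_sd = 0.15,
                          config = staircase_config(),
                          n_elements = 20, element_px = 20, px_per_deg = 48,
                          phase = "cosine", .cache = NULL) {
  match_mode <- match.arg(match_mode)
  ctx <- .condition_responses(A, B, model, match_mode, granularity, filtered,
                              j, params, n_elements, element_px, px_per_deg,
                              phase, .cache = .cache)
  ns <- config$n_interleaved
  offsets <- config$start_offset_db *
    (seq_len(ns) - (ns + 1) / 2) / max(1, (ns - 1) / 2)   # spread +-offset
  st <- lapply(seq_len(ns), function(i) {
    list(level_db = to_db(config$initial_level) + offsets[i],
         n_rev = 0L, last_dir = 0L, done = FALSE)
  })
  rows <- list()
  trial <- 0L
  lo_db <- to_db(config$min_level); hi_db <- to_db(config$max_level)
  while (any(!vapply(st, `[[`, TRUE, "done"))) {
    for (i in seq_len(ns)) {
      if (st[[i]]$done) next
      trial <- trial + 1L
      m <- contrast_from_db(st[[i]]$level_db)
      parity <- sample(0:1, 1)            # procedural fidelity only
      choice <- simulate_choice(ctx$r_test, ctx$r_match(m), noise_sd)
      dir <- if (choice == "match") -1L else 1L
      reversal <- st[[i]]$last_dir != 0L && dir != st[[i]]$last_dir
      if (reversal) st[[i]]$n_rev <- st[[i]]$n_rev + 1L
      step <- if (st[[i]]$n_rev == 0L) config$step_db_initial else config$step_db
      st[[i]]$level_db <- min(max(st[[i]]$level_db + dir * step, lo_db), hi_db)
      st[[i]]$last_dir <- dir
      if (st[[i]]$n_rev >= config$n_reversals) st[[i]]$done <- TRUE
      rows[[trial]] <- tibble(trial = trial, staircase = i, level_pct = m,
                              parity = parity, choice = choice,
                              reversal = reversal)
    }
  }
  dplyr::bind_rows(rows)
}

#' Fit a cumulative log-Gaussian psychometric function
#'
#' Two-parameter maximum-likelihood Bernoulli fit of
#' `P(choose match | level m) = pnorm((log m - log alpha) / sigma_log)` to a
#' trial table — no lapse-rate parameters.  `alpha` is the point of subjective
#' equality (the 50% point); `sigma_log` is the spread in natural-log contrast
#' units.
#'
#' @param trials A trial tibble from [run_staircase()] (needs columns
#'   `level_pct` and `choice`).
#' @return A `psychometric_fit` with `alpha`, `sigma_log`, `loglik`,
#'   `n_trials`, `converged`, `degenerate`.  Data with fewer than two distinct
#'   levels or only one response type are flagged degenerate (`alpha = NA`),
#'   never silently defaulted.
#' @export
fit_psychometric <- function(trials) {
  m <- trials$level_pct
  y <- trials$choice == "match"
  n <- length(y)
  degenerate <- length(unique(m)) < 2 || all(y) || !any(y)
  if (degenerate) {
    return(new_psychometric_fit(NA_real_, NA_real_, NA_real_, n,
                                converged = FALSE, degenerate = TRUE))
  }
  lm_ <- log(m)
  nll <- function(par) {
    pr <- pnorm((lm_ - par[1]) / exp(par[2]))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(ifelse(y, log(pr), log(1 - pr)))
  }
  starts <- lapply(c(0.05, 0.15, 0.5),
                   function(s) c(stats::weighted.mean(lm_, w = rep(1, n)), log(s)))
  fits <- lapply(starts, function(s)
    tryCatch(optim(s, nll, method = "Nelder-Mead",
                   control = list(maxit = 500)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    return(new_psychometric_fit(NA_real_, NA_real_, NA_real_, n, FALSE, FALSE))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  new_psychometric_fit(alpha = exp(best$par[1]), sigma_log = exp(best$par[2]),
                       loglik = -best$value, n_trials = n,
                       converged = best$convergence == 0, degenerate = FALSE)
}

new_psychometric_fit <- function(alpha, sigma_log, loglik, n_trials,
                                 converged, degenerate) {
  structure(list(alpha = alpha, sigma_log = sigma_log, loglik = loglik,
                 n_trials = n_trials, converged = converged,
                 degenerate = degenerate),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$degenerate) cat("Psychometric fit: degenerate data (no estimate)\n")
  else cat(sprintf(
    "Psychometric fit: PSE alpha = %.4g%%, sigma_log = %.3g, logLik = %.3f (n = %d)%s\n",
    x$alpha, x$sigma_log, x$loglik, x$n_trials,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.psychometric_fit <- function(x, ...) {
  tibble(term = c("alpha", "sigma_log"),
         estimate = c(x$alpha, x$sigma_log))
}

#' @exportS3Method generics::glance
glance.psychometric_fit <- function(x, ...) {
  tibble(alpha = x$alpha, sigma_log = x$sigma_log, logLik = x$loglik,
         n_trials = x$n_trials, converged = x$converged,
         degenerate = x$degenerate)
}

#' Estimate a PSE by simulated experiment
#'
#' Runs `n_repetitions` repetitions of the staircase procedure for a model
#' observer, fits a cumulative log-Gaussian to each repetition's trials, and
#' averages the fitted `alpha` across repetitions — the simulated counterpart
#' of [predict_pse()], closing the loop between the analytic prediction and
#' the full experimental procedure.
#'
#' @inheritParams run_staircase
#' @param n_repetitions Number of experiment repetitions to average.
#' @param seed Optional integer seed (sets the global RNG).
#' @return A `pse_estimate`: `estimate` (mean alpha, percent), per-repetition
#'   `fits`, a `repetitions` tibble, and the total trial count.
#' @examples
#' set.seed(1)
#' est <- estimate_pse(A = 4, B = 8, model = "ms", n_repetitions = 2)
#' est$estimate   # below the 8% pedestal: the paradoxical mismatch
#' @export
estimate_pse <- function(A, B = 8, model = "ms",
                         match_mode = c("single", "dual"),
                         granularity = "toy", filtered = FALSE, j = 1,
                         params = model_params(), noise_sd = 0.15,
                         config = staircase_config(), n_repetitions = 4,
                         seed = NULL, ...) {
  match_mode <- match.arg(match_mode)
  if (!is.null(seed)) set.seed(seed)
  cache <- new.env(parent = emptyenv())
  reps <- lapply(seq_len(n_repetitions), function(r) {
    trials <- run_staircase(A = A, B = B, model = model,
                            match_mode = match_mode, granularity = granularity,
                            filtered = filtered, j = j, params = params,
                            noise_sd = noise_sd, config = config,
                            .cache = cache, ...)
    list(trials = trials, fit = fit_psychometric(trials))
  })
  fits <- lapply(reps, `[[`, "fit")
  ok <- !vapply(fits, `[[`, TRUE, "degenerate")
  if (!all(ok))
    warn(sprintf("%d of %d repetitions gave degenerate psychometric data and were excluded",
                 sum(!ok), n_repetitions))
  alphas <- vapply(fits[ok], `[[`, 0, "alpha")
  rep_tbl <- tibble(
    repetition = seq_len(n_repetitions),
    alpha = vapply(fits, `[[`, 0, "alpha"),
    sigma_log = vapply(fits, `[[`, 0, "sigma_log"),
    n_trials = vapply(fits, `[[`, 0L, "n_trials"),
    degenerate = !ok)
  structure(list(estimate = if (length(alphas)) mean(alphas) else NA_real_,
                 repetitions = rep_tbl, fits = fits, seed = seed,
                 n_trials_total = sum(rep_tbl$n_trials),
                 condition = list(A = A, B = B, model = model,
                                  match_mode = match_mode, j = j,
                                  granularity = granularity,
                                  filtered = filtered, noise_sd = noise_sd)),
            class = "pse_estimate")
}

#' @export
print.pse_estimate <- function(x, ...) {
  cat(sprintf(
    "Simulated PSE: %.4g%% (%s observer, %s match, A = %g, B = %g; %d repetitions, %d trials)\n",
    x$estimate, x$condition$model, x$condition$match_mode, x$condition$A,
    x$condition$B, nrow(x$repetitions), x$n_trials_total))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pse_estimate <- function(x, ...) x$repetitions

#' @exportS3Method generics::glance
glance.pse_estimate <- function(x, ...) {
  tibble(A = x$condition$A, B = x$condition$B, model = x$condition$model,
         match_mode = x$condition$match_mode, j = x$condition$j,
         pse = x$estimate, n_repetitions = nrow(x$repetitions),
         n_trials = x$n_trials_total)
}

#' Simulated-observer matching curve
#'
#' Maps [estimate_pse()] over a condition grid, giving a reference PSE table
#' produced by the full simulated experimental procedure (the synthetic
#' counterpart of a human observer's data, usable as the `reference` of
#' [compare_models()]).
#'
#' @param conditions Data frame with column `A` and optionally `B`, `j`,
#'   `match_mode` (defaults filled from the arguments).
#' @inheritParams estimate_pse
#' @return A tibble: condition columns plus `pse` and `n_trials`.
#' @export
observer_matching_curve <- function(conditions = NULL, A = contrast_grid(),
                                    B = 8, j = 1, match_mode = "single",
                                    model = "ms", granularity = "toy",
                                    filtered = FALSE, params = model_params(),
                                    noise_sd = 0.15,
                                    config = staircase_config(),
                                    n_repetitions = 4, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conditions))
    conditions <- tidyr::expand_grid(A = A, B = B, j = j,
                                     match_mode = match_mode)
  conditions <- as_tibble(conditions)
  for (nm in c("B", "j", "match_mode"))
    if (!nm %in% names(conditions))
      conditions[[nm]] <- switch(nm, B = B, j = j, match_mode = match_mode)
  out <- purrr::pmap(conditions[, c("A", "B", "j", "match_mode")],
    function(A, B, j, match_mode) {
      est <- estimate_pse(A = A, B = B, model = model,
                          match_mode = match_mode, granularity = granularity,
                          filtered = filtered, j = j, params = params,
                          noise_sd = noise_sd, config = config,
                          n_repetitions = n_repetitions, ...)
      tibble(A = A, B = B, j = j, match_mode = match_mode, model = model,
             pse = est$estimate, n_trials = est$n_trials_total)
    })
  dplyr::bind_rows(out)
}
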