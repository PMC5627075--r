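#' Default test-contrast grid
#'
#' Octave-spaced "A"-component contrasts spanning 0-32%, used as the default
#' abscissa of matching curves (the experiments blocked eight A levels over
#' this range with the B pedestal fixed at 8%).
#'
#' @return Numeric vector of contrasts in percent.
#' @export
contrast_grid <- function() c(0, 0.5, 1, 2, 4, 8, 16, 32)

# geometry spec for a test stimulus under the given condition
.test_spec <- function(A, B, j, n_elements, element_px, px_per_deg, parity = 0L) {
  battenberg_spec(contrast_A = A, contrast_B = B, cluster_size_j = j,
                  n_elements = n_elements, element_px = element_px,
                  px_per_deg = px_per_deg, parity = parity)
}

# local contrast values of a stimulus at the requested granularity
.stimulus_map_values <- function(spec, granularity, filtered, phase) {
  if (granularity == "element") {
    map_values(element_contrast_map(spec))
  } else {
    img <- make_battenberg(spec)
    if (filtered) map_values(filter_contrast_map(img, phase = phase))
    else map_values(weber_contrast_map(img))
  }
}

# unit-level (1%) match map; linear in the matching level, so one map serves
# every level of the bisection.  Cached per condition geometry inside
# matching_curve().
.match_unit_values <- function(match_mode, granularity, filtered, spec, phase,
                               cache = NULL) {
  key <- paste(match_mode, granularity, filtered, phase,
               spec$cluster_size_j, spec$n_elements, spec$element_px,
               spec$px_per_deg, spec$parity, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  s <- spec
  s$contrast_A <- 1
  s$contrast_B <- if (match_mode == "dual") 1 else 0
  u <- .stimulus_map_values(s, granularity, filtered, phase)
  if (!is.null(cache)) cache[[key]] <- u
  u
}

# scalar response(m) along the match family, exploiting linearity of the map
# in the matching level
.match_response_fn <- function(model, match_mode, granularity, u, params) {
  if (granularity == "toy") {
    if (match_mode == "dual")
      return(function(m) toy_response(model, m, m, params))
    return(function(m) toy_response(model, m, 0, params))
  }
  if (model == "ms") {
    Sp <- sum(u^params$p); Sq <- sum(u^params$q)
    return(function(m) (m^params$p * Sp) / (params$z + m^params$q * Sq))
  }
  switch(model,
    max    = local({ u_max <- max(u);    function(m) m * u_max }),
    linsum = local({ u_sum <- sum(u);    function(m) m * u_sum }),
    energy = local({ u_ss  <- sum(u^2);  function(m) m^2 * u_ss }),
    lf     = function(m) lf_summed_response(u * m, params)
  )
}

#' Model response to a stimulus under a processing pipeline
#'
#' Evaluates a global-contrast model on a test stimulus at one of three
#' granularities: `"toy"` (the model sees only the two component contrasts),
#' `"element"` (one local contrast per element), or `"pixelwise"` (the Weber
#' contrast map of the rendered image, optionally passed through the log-Gabor
#' front end first).
#'
#' @param model One of `"max"`, `"linsum"`, `"energy"`, `"lf"`, `"ms"`.
#' @param stimulus A [battenberg_spec()] (any granularity) or a
#'   `luminance_image` (pixelwise only).
#' @param granularity `"toy"`, `"element"`, or `"pixelwise"`.
#' @param filtered Apply the log-Gabor front end (pixelwise only)?
#' @param params A [model_params()].
#' @param phase Filter phase mode, see [filter_contrast_map()].
#' @return Scalar model response (arbitrary units).
#' @export
stimulus_response <- function(model, stimulus,
                              granularity = c("toy", "element", "pixelwise"),
                              filtered = FALSE, params = model_params(),
                              phase = "cosine") {
  model <- match.arg(model, model_ids)
  granularity <- match.arg(granularity)
  if (granularity == "toy" && filtered)
    abort("the toy granularity has no image to filter; use granularity = \"pixelwise\"")
  if (granularity == "toy") {
    stopifnot(inherits(stimulus, "battenberg_spec"))
    return(toy_response(model, stimulus$contrast_A, stimulus$contrast_B, params))
  }
  vals <- if (inherits(stimulus, "luminance_image")) {
    if (granularity == "element")
      abort("element granularity needs a battenberg_spec, not a rendered image")
    if (filtered) map_values(filter_contrast_map(stimulus, phase = phase))
    else map_values(weber_contrast_map(stimulus))
  } else {
    stopifnot(inherits(stimulus, "battenberg_spec"))
    .stimulus_map_values(stimulus, granularity, filtered, phase)
  }
  map_response(model, vals, params)
}

# test response (scalar) and match-family response (function of level m)
# for one matching condition; shared by the PSE solver and the simulated
# observer
.condition_responses <- function(A, B, model, match_mode, granularity,
                                 filtered, j, params, n_elements, element_px,
                                 px_per_deg, phase, .cache = NULL) {
  if (granularity == "toy") {
    r_test <- toy_response(model, A, B, params)
    u <- NULL
  } else {
    spec <- .test_spec(A, B, j, n_elements, element_px, px_per_deg)
    r_test <- map_response(model, .stimulus_map_values(spec, granularity,
                                                       filtered, phase), params)
    u <- .match_unit_values(match_mode, granularity, filtered, spec, phase,
                            cache = .cache)
  }
  list(r_test = r_test,
       r_match = .match_response_fn(model, match_mode, granularity, u, params))
}

#' Predict the point of subjective equality for a matching condition
#'
#' Finds the matching-stimulus level `m` at which the model response to the
#' matching stimulus equals its response to the test stimulus (A and B
#' component contrasts), by bisection in log contrast on `[0, m_max]`.  The
#' match family is `"single"` (one component at `m`, the other blank) or
#' `"dual"` (both components at `m`).  Monotonicity of the match response in
#' `m` — guaranteed for `p > q` — is verified numerically on a coarse grid
#' before solving.
#'
#' The bracket deliberately extends beyond 100% physical contrast so that
#' badly over-predicting models still converge; such solutions are flagged.
#'
#' @param A,B Test component contrasts, percent.
#' @param model,granularity,filtered,params,phase See [stimulus_response()].
#' @param match_mode `"single"` or `"dual"`.
#' @param j Cluster size of the test/match geometry.
#' @param n_elements,element_px,px_per_deg Stimulus geometry.
#' @param m_max Upper bracket for the matching level, percent.
#' @param tol Relative response tolerance for convergence.
#' @param max_iter Maximum bisection iterations.
#' @param check_monotone Verify match-response monotonicity before solving?
#' @param .cache Internal memoisation environment used by [matching_curve()].
#' @return A `pse_result`: `pse` (percent), `converged`, `iterations`,
#'   `bracket`, `response_test`, `above_physical`.
#' @examples
#' predict_pse(A = 4, B = 8, model = "ms", match_mode = "single")$pse   # < 8
#' predict_pse(A = 4, B = 8, model = "energy", match_mode = "single")$pse
#' @export
predict_pse <- function(A, B = 8, model = "ms",
                        match_mode = c("single", "dual"),
                        granularity = c("toy", "element", "pixelwise"),
                        filtered = FALSE, j = 1, params = model_params(),
                        n_elements = 20, element_px = 20, px_per_deg = 48,
                        phase = "cosine", m_max = 200, tol = 1e-9,
                        max_iter = 60L, check_monotone = TRUE,
                        .cache = NULL) {
  model <- match.arg(model, model_ids)
  match_mode <- match.arg(match_mode)
  granularity <- match.arg(granularity)
  if (granularity == "toy" && filtered)
    abort("granularity = \"toy\" forbids filtered = TRUE")

  ctx <- .condition_responses(A, B, model, match_mode, granularity, filtered,
                              j, params, n_elements, element_px, px_per_deg,
                              phase, .cache = .cache)
  r_test <- ctx$r_test
  r_match <- ctx$r_match

  cond <- list(A = A, B = B, model = model, match_mode = match_mode,
               granularity = granularity, filtered = filtered, j = j)

  if (check_monotone) {
    grid <- 10^seq(log10(1e-3), log10(m_max), length.out = 40)
    rg <- vapply(grid, r_match, 0)
    if (any(diff(rg) < -1e-9 * max(abs(rg))))
      abort("match-family response is not increasing in the matching level; the PSE is not identifiable")
  }

  if (r_test <= 0) {
    return(new_pse_result(0, TRUE, 0L, c(0, 0), r_test, cond))
  }
  lo <- 1e-6; hi <- m_max
  if (r_match(hi) < r_test * (1 - tol)) {
    res <- new_pse_result(NA_real_, FALSE, 0L, c(lo, hi), r_test, cond)
    warn(sprintf("no matching level up to %g%% reaches the test response (%s model)",
                 m_max, model))
    return(res)
  }
  iter <- 0L
  converged <- FALSE
  mid <- sqrt(lo * hi)
  while (iter < max_iter) {
    iter <- iter + 1L
    mid <- sqrt(lo * hi)
    rm <- r_match(mid)
    if (abs(rm - r_test) <= tol * r_test) { converged <- TRUE; break }
    if (rm < r_test) lo <- mid else hi <- mid
  }
  new_pse_result(mid, converged, iter, c(lo, hi), r_test, cond)
}

new_pse_result <- function(pse, converged, iterations, bracket, response_test,
                           condition) {
  structure(list(pse = pse, converged = converged, iterations = iterations,
                 bracket = bracket, response_test = response_test,
                 above_physical = isTRUE(pse > 100), condition = condition),
            class = "pse_result")
}

#' @export
print.pse_result <- function(x, ...) {
  cat(sprintf("PSE: %.6g%% (%s, %s match, A = %g, B = %g)%s%s\n",
              x$pse, x$condition$model, x$condition$match_mode,
              x$condition$A, x$condition$B,
              if (x$converged) "" else "  [NOT CONVERGED]",
              if (x$above_physical) "  [above 100% physical contrast]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pse_result <- function(x, ...) {
  tibble(A = x$condition$A, B = x$condition$B, j = x$condition$j,
         match_mode = x$condition$match_mode, model = x$condition$model,
         granularity = x$condition$granularity,
         filtered = x$condition$filtered, pse = x$pse,
         converged = x$converged, above_physical = x$above_physical)
}

#' Predicted matching curve over a grid of test contrasts
#'
#' Maps [predict_pse()] over a condition grid and returns a tibble, one row
#' per condition — the model's matching function, with no free parameters.
#' Either pass a condition data frame (columns `A` and optionally `B`, `j`,
#' `match_mode`, `model`, `granularity`, `filtered`) or let the function build
#' the fully crossed grid of the vector arguments.
#'
#' @param conditions Optional condition data frame; when supplied the vector
#'   arguments below are used only as defaults for its missing columns.
#' @inheritParams predict_pse
#' @param ... Passed on to [predict_pse()] (geometry, tolerances, phase).
#' @return A tibble of class `matching_curve` with columns `A`, `B`, `j`,
#'   `match_mode`, `model`, `granularity`, `filtered`, `pse`, `converged`,
#'   `above_physical`.
#' @examples
#' matching_curve(model = "ms", match_mode = "single")
#' @export
matching_curve <- function(conditions = NULL, A = contrast_grid(), B = 8,
                           j = 1, match_mode = "single", model = "ms",
                           granularity = "toy", filtered = FALSE,
                           params = model_params(), ...) {
  if (is.null(conditions)) {
    conditions <- tidyr::expand_grid(
      A = A, B = B, j = j, match_mode = match_mode, model = model,
      granularity = granularity, filtered = filtered)
  } else {
    conditions <- as_tibble(conditions)
    defaults <- list(B = B, j = j, match_mode = match_mode, model = model,
                     granularity = granularity, filtered = filtered)
    for (nm in names(defaults))
      if (!nm %in% names(conditions)) conditions[[nm]] <- defaults[[nm]]
    if (!"A" %in% names(conditions)) abort("conditions must contain a column `A`")
  }
  cache <- new.env(parent = emptyenv())
  out <- purrr::pmap(conditions, function(A, B, j, match_mode, model,
                                          granularity, filtered, ...) {
    tidy(predict_pse(A = A, B = B, model = model, match_mode = match_mode,
                     granularity = granularity, filtered = filtered, j = j,
                     params = params, .cache = cache, ...))
  }, ...)
  out <- dplyr::bind_rows(out)
  class(out) <- c("matching_curve", class(out))
  out
}
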