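#' Parameters of the transducer-based contrast models
#'
#' Houses the free symbols of the summed Legge-Foley transducer and the
#' wide-field contrast gain-control model: excitatory (numerator) exponent
#' `p`, suppressive (denominator) exponent `q`, saturation constant `z`, and
#' an optional Minkowski exponent `k` for the Legge-Foley area-summation
#' variant.  Contrasts are expressed in percent throughout, so `z` is in
#' percent^q.
#'
#' `p > q` is required: with equal or smaller excitatory exponent the pooled
#' response saturates and the matching problem is no longer invertible.  At
#' suprathreshold contrasts `z` is negligible and can safely be set to 1 (or
#' even 0).
#'
#' @param p Excitatory exponent (default 2.4).
#' @param q Suppressive exponent (default 2.0).
#' @param z Saturation constant (default 1).
#' @param minkowski_k Optional Minkowski exponent `k >= 1`; `NULL` means
#'   linear summation over area.
#' @return An object of class `model_params`.
#' @export
model_params <- function(p = 2.4, q = 2.0, z = 1, minkowski_k = NULL) {
  if (p <= q) abort(sprintf(
    "excitatory exponent p (%g) must exceed suppressive exponent q (%g) to avoid response saturation",
    p, q))
  if (z < 0) abort("saturation constant z must be >= 0")
  if (!is.null(minkowski_k) && minkowski_k < 1)
    abort("Minkowski exponent k must be >= 1")
  structure(list(p = p, q = q, z = z, minkowski_k = minkowski_k),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Model params: p = %g, q = %g, z = %g, summation = %s\n",
              x$p, x$q, x$z,
              if (is.null(x$minkowski_k)) "linear"
              else sprintf("Minkowski k = %g", x$minkowski_k)))
  invisible(x)
}

new_contrast_map <- function(values,
                             provenance = c("weber_pixelwise", "filter_response",
                                            "element_toy")) {
  provenance <- match.arg(provenance)
  structure(list(values = values, provenance = provenance),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("Contrast map (%s): %s locations, range [%.4g, %.4g] %%\n",
              x$provenance, format(length(x$values), big.mark = ","),
              min(x$values), max(x$values)))
  invisible(x)
}

map_values <- function(map) {
  if (inherits(map, "contrast_map")) map$values else as.numeric(map)
}

img_pixels <- function(img) {
  if (inherits(img, "luminance_image")) img$pixels else as.matrix(img)
}

#' Pixelwise Weber contrast map
#'
#' Local contrast at each pixel as the rectified Weber fraction
#' `100 * |L_i - L_mean| / L_mean`, with the mean taken over the whole image.
#' This is the local contrast `C` that all the map-level global metrics pool.
#'
#' @param img A `luminance_image` (or plain luminance matrix).
#' @return A `contrast_map` with values in percent.
#' @export
weber_contrast_map <- function(img) {
  L <- img_pixels(img)
  if (length(L) == 0) abort("empty image")
  m <- mean(L)
  if (m <= 0) abort("mean luminance must be positive")
  new_contrast_map(100 * abs(L - m) / m, "weber_pixelwise")
}

#' Element-level contrast map of a Battenberg
#'
#' One entry per element at its nominal component contrast: the granularity at
#' which the two-parameter toy models generalise to arbitrary element grids.
#'
#' @param spec A [battenberg_spec()].
#' @return A `contrast_map` (provenance `"element_toy"`).
#' @export
element_contrast_map <- function(spec) {
  stopifnot(inherits(spec, "battenberg_spec"))
  mask <- checker_mask(spec$n_elements, spec$cluster_size_j, spec$parity,
                       partial = "truncate")
  new_contrast_map(
    matrix(ifelse(mask == "A", spec$contrast_A, spec$contrast_B),
           spec$n_elements, spec$n_elements),
    "element_toy")
}

#' Global contrast metrics
#'
#' Classical summary statistics of global image contrast.
#' `michelson_contrast()` and `rms_contrast()` act on luminance images:
#' Michelson contrast is `100 * (L_max - L_min) / (L_max + L_min)` and RMS
#' contrast is the standard deviation of luminance normalised by its mean (in
#' percent).  The remaining metrics pool a local-contrast map `c` (percent):
#' `contrast_energy` is the sum of squared local contrasts, `contrast_sum`
#' their sum, `contrast_average` their mean, `max_contrast` their maximum.
#'
#' @param img A `luminance_image` or luminance matrix.
#' @param map A `contrast_map` or numeric vector/matrix of local contrasts in
#'   percent.
#' @return A scalar (percent for michelson/rms/average/max; arbitrary units
#'   for energy and sum).
#' @name contrast_metrics
NULL

#' @rdname contrast_metrics
#' @export
michelson_contrast <- function(img) {
  L <- img_pixels(img)
  if (length(L) == 0) abort("empty image")
  100 * (max(L) - min(L)) / (max(L) + min(L))
}

#' @rdname contrast_metrics
#' @export
rms_contrast <- function(img) {
  L <- img_pixels(img)
  if (length(L) == 0) abort("empty image")
  m <- mean(L)
  if (m <= 0) abort("mean luminance must be positive")
  # population SD: a contrast statistic, not a sample estimate
  100 * sqrt(mean((L - m)^2)) / m
}

#' @rdname contrast_metrics
#' @export
contrast_energy <- function(map) sum(map_values(map)^2)

#' @rdname contrast_metrics
#' @export
contrast_sum <- function(map) sum(map_values(map))

#' @rdname contrast_metrics
#' @export
contrast_average <- function(map) mean(map_values(map))

#' @rdname contrast_metrics
#' @export
max_contrast <- function(map) max(map_values(map))

model_ids <- c("max", "linsum", "energy", "lf", "ms")

#' Two-parameter ("toy") global contrast models
#'
#' Closed-form model responses that see only the two component contrasts of a
#' Battenberg stimulus (percent):
#' \describe{
#'   \item{max}{`max(A, B)` — equivalent to Michelson contrast for these
#'     stimuli.}
#'   \item{linsum}{`A + B` (equivalently the average, up to a constant).}
#'   \item{energy}{`A^2 + B^2` (equivalent to RMS when test and match have
#'     the same area).}
#'   \item{lf}{summed Legge-Foley transducers
#'     `A^p/(z + A^q) + B^p/(z + B^q)`.}
#'   \item{ms}{wide-field gain control `(A^p + B^p)/(z + A^q + B^q)`:
#'     excitation and suppression are pooled separately before division.}
#' }
#'
#' @param model One of `"max"`, `"linsum"`, `"energy"`, `"lf"`, `"ms"`.
#' @param A,B Component contrasts in percent (vectorised).
#' @param params A [model_params()].
#' @return Model response in arbitrary units.
#' @examples
#' toy_response("ms", 4, 8)     # the gain-control response to the 4/8 test
#' toy_response("max", 4, 8)
#' @export
toy_response <- function(model, A, B, params = model_params()) {
  model <- match.arg(model, model_ids)
  if (any(A < 0) || any(B < 0)) abort("contrasts must be non-negative")
  p <- params$p; q <- params$q; z <- params$z
  switch(model,
    max    = pmax(A, B),
    linsum = A + B,
    energy = A^2 + B^2,
    lf     = A^p / (z + A^q) + B^p / (z + B^q),
    ms     = (A^p + B^p) / (z + A^q + B^q)
  )
}

#' Wide-field gain-control response of a contrast map
#'
#' Pools excitation and suppression separately over all map locations:
#' `sum(c^p) / (z + sum(c^q))`.  Because both sums grow with area, the
#' response of a uniform pattern is asymptotically independent of its size
#' (unlike plain energy or contrast-sum pooling), while a low-contrast
#' addition to a higher-contrast pattern can lower the response — the
#' paradoxical suppression this model is known for.
#'
#' @param map A `contrast_map` (or numeric values, percent).
#' @param params A [model_params()].
#' @return Scalar response (arbitrary units).
#' @export
gain_control_response <- function(map, params = model_params()) {
  c_ <- map_values(map)
  if (length(c_) == 0) abort("empty contrast map")
  sum(c_^params$p) / (params$z + sum(c_^params$q))
}

#' Summed Legge-Foley transducer response of a contrast map
#'
#' Applies the sigmoidal transducer `c^p / (z + c^q)` at every location and
#' pools over area, either linearly (`sum`) or by Minkowski summation
#' `(sum(r^k))^(1/k)` when `params$minkowski_k` is set (`k = 1` is the linear
#' sum; `k -> Inf` approaches the max).
#'
#' @inheritParams gain_control_response
#' @return Scalar response (arbitrary units).
#' @export
lf_summed_response <- function(map, params = model_params()) {
  c_ <- map_values(map)
  if (length(c_) == 0) abort("empty contrast map")
  r <- c_^params$p / (params$z + c_^params$q)
  k <- params$minkowski_k
  if (is.null(k) || k == 1) sum(r)
  else if (is.infinite(k)) max(r)
  else sum(r^k)^(1 / k)
}

#' Map-level response of any global contrast model
#'
#' Dispatches a contrast map to the pooling rule of the named model: max of
#' the map, sum, sum of squares, summed Legge-Foley transducers, or the
#' gain-control pool.  This is the "pixel-by-pixel" (or element-by-element)
#' generalisation of [toy_response()].
#'
#' @inheritParams gain_control_response
#' @param model One of `"max"`, `"linsum"`, `"energy"`, `"lf"`, `"ms"`.
#' @return Scalar response.
#' @export
map_response <- function(model, map, params = model_params()) {
  model <- match.arg(model, model_ids)
  switch(model,
    max    = max_contrast(map),
    linsum = contrast_sum(map),
    energy = contrast_energy(map),
    lf     = lf_summed_response(map, params),
    ms     = gain_control_response(map, params)
  )
}
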