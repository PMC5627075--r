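#' Parametric description of a Battenberg stimulus
#'
#' A Battenberg stimulus is a square grid of grating micro-patterns in which
#' two interdigitated sets of elements ("A" and "B") carry independently
#' controlled Michelson contrasts.  Each element holds a single cycle of a
#' horizontal sine-wave carrier windowed by one positive lobe of a
#' full-wave-rectified vertical sine wave of half the carrier frequency, so
#' element boundaries sit at mean luminance.  The checkerboard alternation can
#' act on single elements (`cluster_size_j = 1`) or on square clusters of
#' `j x j` elements.
#'
#' At the defaults (20 px elements at 48 px/deg) the carrier spatial frequency
#' is 2.4 cycles/deg and the whole stimulus spans 400 x 400 px (8.3 deg).
#'
#' @param contrast_A,contrast_B Michelson contrast of the "A" and "B" checker
#'   components, in percent (0-100).
#' @param cluster_size_j Elements per cluster side; one of 1, 2, 4, 8.
#' @param n_elements Grid side length in elements.
#' @param element_px Pixels per element side (one carrier cycle).
#' @param px_per_deg Spatial sampling in pixels per degree of visual angle.
#' @param parity Which checker phase carries "A": 0 or 1.  Flipping parity
#'   swaps the spatial assignment of the two components.
#' @param mean_luminance Normalised mean luminance of the image (1.0 stands
#'   for the physical mean, e.g. 60 cd/m^2).
#'
#' @return An object of class `battenberg_spec`.
#' @examples
#' spec <- battenberg_spec(contrast_A = 32, contrast_B = 8, cluster_size_j = 2)
#' img <- make_battenberg(spec)
#' michelson_contrast(img)
#' @export
battenberg_spec <- function(contrast_A = 8, contrast_B = 8, cluster_size_j = 1,
                            n_elements = 20, element_px = 20, px_per_deg = 48,
                            parity = 0L, mean_luminance = 1) {
  if (contrast_A < 0 || contrast_A > 100 || contrast_B < 0 || contrast_B > 100)
    abort("component contrasts must lie in [0, 100] percent")
  if (n_elements < 1 || element_px < 2)
    abort("n_elements must be >= 1 and element_px >= 2")
  if (!cluster_size_j %in% c(1L, 2L, 4L, 8L))
    abort(sprintf("cluster_size_j must be one of 1, 2, 4, 8 (got %s)",
                  cluster_size_j))
  if (!parity %in% c(0L, 1L)) abort("parity must be 0 or 1")
  if (mean_luminance <= 0) abort("mean_luminance must be positive")
  structure(
    list(contrast_A = contrast_A, contrast_B = contrast_B,
         cluster_size_j = as.integer(cluster_size_j),
         n_elements = as.integer(n_elements),
         element_px = as.integer(element_px),
         px_per_deg = px_per_deg, parity = as.integer(parity),
         mean_luminance = mean_luminance),
    class = "battenberg_spec"
  )
}

#' @export
print.battenberg_spec <- function(x, ...) {
  cat(sprintf(
    "Battenberg spec: A = %g%%, B = %g%%, j = %d, %d x %d elements of %d px (%.3g c/deg carrier)\n",
    x$contrast_A, x$contrast_B, x$cluster_size_j, x$n_elements, x$n_elements,
    x$element_px, x$px_per_deg / x$element_px))
  invisible(x)
}

#' Checkerboard label mask for Battenberg elements
#'
#' Assigns each element of an `n x n` grid the label "A" or "B" so that square
#' clusters of `j x j` identical labels alternate in a checkerboard.  When `j`
#' does not divide `n` (the classic case being j = 8 clusters on a 20-element
#' grid) the mask can be built on the next-larger virtual grid and
#' centre-cropped, truncating the partial clusters at the border.
#'
#' @param n_elements Grid side length in elements.
#' @param cluster_size_j Elements per cluster side.
#' @param parity 0 or 1; flipping parity swaps every label.
#' @param partial What to do when `cluster_size_j` does not divide
#'   `n_elements`: `"error"` (default) or `"truncate"`.
#' @return A character matrix of `"A"`/`"B"` labels.
#' @examples
#' checker_mask(2, 1)
#' checker_mask(20, 8, partial = "truncate")[1:4, 1:4]
#' @export
checker_mask <- function(n_elements, cluster_size_j, parity = 0L,
                         partial = c("error", "truncate")) {
  partial <- match.arg(partial)
  n <- as.integer(n_elements)
  j <- as.integer(cluster_size_j)
  if (n %% j != 0L && partial == "error")
    abort(sprintf(
      "cluster size j = %d does not divide the grid of n = %d elements; use partial = \"truncate\"",
      j, n))
  n_virtual <- as.integer(ceiling(n / j) * j)
  offset <- (n_virtual - n) %/% 2L
  idx <- offset + seq_len(n)                     # centre crop of virtual grid
  block <- (idx - 1L) %/% j
  lab <- outer(block, block, function(r, c) (r + c + parity) %% 2L)
  matrix(c("A", "B")[lab + 1L], n, n)
}

#' Generate a Battenberg luminance image
#'
#' Renders the stimulus described by a [battenberg_spec()] as a normalised
#' luminance image.  Within each element the modulation is
#' `sin(2*pi*y/element_px) * sin(pi*x/element_px)` (carrier times rectified
#' envelope), sampled on integer pixel coordinates so that element boundaries
#' are exactly at mean luminance and each element attains its nominal peak
#' contrast exactly.  Elements labelled "A" carry `contrast_A`, elements
#' labelled "B" carry `contrast_B`.
#'
#' @param spec A [battenberg_spec()].
#' @return A `luminance_image`: a list with `pixels` (matrix of normalised
#'   luminance, spatial mean equal to `mean_luminance`), `px_per_deg`, and the
#'   generating `spec`.
#' @examples
#' img <- make_battenberg(battenberg_spec(contrast_A = 32, contrast_B = 8))
#' range(img$pixels)
#' @export
make_battenberg <- function(spec) {
  stopifnot(inherits(spec, "battenberg_spec"))
  n <- spec$n_elements
  epx <- spec$element_px
  mask <- checker_mask(n, spec$cluster_size_j, spec$parity, partial = "truncate")
  c_el <- matrix(ifelse(mask == "A", spec$contrast_A, spec$contrast_B) / 100, n, n)
  # expand element-level contrasts to pixel resolution
  c_px <- c_el[rep(seq_len(n), each = epx), rep(seq_len(n), each = epx)]
  coord <- seq_len(n * epx) - 1L
  carrier <- sin(2 * pi * (coord %% epx) / epx)   # varies down rows (horizontal grating)
  envelope <- sin(pi * (coord %% epx) / epx)      # rectified half-cycle per element
  modulation <- outer(carrier, envelope)
  pixels <- spec$mean_luminance * (1 + c_px * modulation)
  new_luminance_image(pixels, spec$px_per_deg, spec$mean_luminance, spec)
}

new_luminance_image <- function(pixels, px_per_deg, mean_luminance = mean(pixels),
                                spec = NULL) {
  structure(list(pixels = pixels, px_per_deg = px_per_deg,
                 mean_luminance = mean_luminance, spec = spec),
            class = "luminance_image")
}

#' Construct a luminance image from a plain matrix
#'
#' Wraps an arbitrary grayscale array (e.g. read from a PNG) as a
#' `luminance_image` for use with the contrast metrics.  Values are treated as
#' linear luminance; if `normalise = TRUE` the array is divided by its mean so
#' that the normalised mean is 1.
#'
#' @param pixels Numeric matrix of non-negative luminance values.
#' @param px_per_deg Pixels per degree of visual angle.
#' @param normalise Divide by the spatial mean?
#' @return A `luminance_image`.
#' @export
as_luminance_image <- function(pixels, px_per_deg = 48, normalise = FALSE) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0)) abort("luminance values must be non-negative")
  if (normalise) {
    m <- mean(pixels)
    if (m <= 0) abort("cannot normalise an image with non-positive mean")
    pixels <- pixels / m
  }
  new_luminance_image(pixels, px_per_deg)
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf("Luminance image: %d x %d px at %g px/deg, mean %.6g, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$px_per_deg, mean(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Generate a matching stimulus
#'
#' The matching stimulus of the two-interval contrast-matching task: a
#' Battenberg of the same geometry as the test in which either one checker
#' component is modulated at `level` percent and the other is blank
#' (`mode = "single"`), or both components are modulated at `level`
#' (`mode = "dual"`).
#'
#' @param mode `"single"` or `"dual"`.
#' @param level Matching contrast in percent (>= 0).
#' @param spec A [battenberg_spec()] supplying the geometry (its component
#'   contrasts are ignored).
#' @return A `luminance_image`.
#' @examples
#' img <- make_matching_stimulus("single", 8, battenberg_spec(cluster_size_j = 2))
#' @export
make_matching_stimulus <- function(mode = c("single", "dual"), level,
                                   spec = battenberg_spec()) {
  mode <- match.arg(mode)
  if (level < 0) abort("matching level must be non-negative")
  spec$contrast_A <- level
  spec$contrast_B <- if (mode == "dual") level else 0
  make_battenberg(spec)
}

#' Write and read stimulus images
#'
#' Images are stored linearly (the model operates on linear luminance; display
#' gamma is assumed corrected): mean luminance maps to mid-grey, and the full
#' code range spans mean * (1 +- 1).  A plain-text sidecar (`<path>.txt`)
#' records sampling density and, when available, the generating parameters.
#' PNG export is 8-bit grayscale; for a lossless interchange format use
#' [write_stimulus_array()], a plain-text portable float array.
#'
#' @param img A `luminance_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(img, path) {
  stopifnot(inherits(img, "luminance_image"))
  lum <- img$pixels / img$mean_luminance      # 0..2 for contrasts <= 100%
  code <- pmin(pmax(lum / 2, 0), 1)
  png::writePNG(code, path, dpi = NULL)
  side <- c(sprintf("px_per_deg: %g", img$px_per_deg),
            sprintf("mean_luminance: %g", img$mean_luminance))
  if (!is.null(img$spec))
    side <- c(side,
              sprintf("contrast_A: %g", img$spec$contrast_A),
              sprintf("contrast_B: %g", img$spec$contrast_B),
              sprintf("cluster_size_j: %d", img$spec$cluster_size_j),
              sprintf("parity: %d", img$spec$parity))
  writeLines(side, paste0(path, ".txt"))
  invisible(path)
}

#' @rdname write_stimulus_png
#' @param px_per_deg Sampling density to attach when no sidecar is found.
#' @export
read_stimulus_png <- function(path, px_per_deg = 48) {
  code <- png::readPNG(path)
  if (length(dim(code)) == 3L) code <- code[, , 1L]   # grayscale channel
  sidecar <- paste0(path, ".txt")
  if (file.exists(sidecar)) {
    kv <- strsplit(readLines(sidecar), ":\\s*")
    vals <- setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                     vapply(kv, `[`, "", 1))
    if ("px_per_deg" %in% names(vals)) px_per_deg <- vals[["px_per_deg"]]
  }
  new_luminance_image(code * 2, px_per_deg, mean_luminance = 1)
}

#' Lossless plain-text stimulus interchange
#'
#' A portable float array: a one-line header `battenberg-float <rows> <cols>
#' <px_per_deg> <mean_luminance>` followed by the luminance values in row
#' order at full double precision.
#'
#' @param img A `luminance_image`.
#' @param path Output text path.
#' @return `write_stimulus_array()`: `path` invisibly;
#'   `read_stimulus_array()`: a `luminance_image`.
#' @export
write_stimulus_array <- function(img, path) {
  stopifnot(inherits(img, "luminance_image"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("battenberg-float %d %d %.17g %.17g",
                     nrow(img$pixels), ncol(img$pixels), img$px_per_deg,
                     img$mean_luminance), con)
  write(format(t(img$pixels), digits = 17), con, ncolumns = ncol(img$pixels))
  invisible(path)
}

#' @rdname write_stimulus_array
#' @export
read_stimulus_array <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), " ")[[1]]
  if (hdr[1] != "battenberg-float") abort("not a battenberg float array file")
  dims <- as.integer(hdr[2:3])
  vals <- scan(path, skip = 1, quiet = TRUE)
  new_luminance_image(matrix(vals, dims[1], dims[2], byrow = TRUE),
                      px_per_deg = as.numeric(hdr[4]),
                      mean_luminance = as.numeric(hdr[5]))
}
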