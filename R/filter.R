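#' Frequency-domain log-Gabor kernel
#'
#' Builds the single oriented log-Gabor channel used as the optional
#' spatial-filtering front end: a transfer function that is Gaussian in log
#' spatial frequency about `center_freq` (with the given full bandwidth in
#' octaves at half height) and Gaussian in orientation about the grating
#' orientation `orientation_deg` (angular spread given as half-width at half
#' height).  A log-Gabor has no DC response by construction, and the transfer
#' peaks at exactly 1 so that a full-field grating at the preferred frequency
#' and orientation with Michelson contrast C yields a peak response of C
#' (percent).
#'
#' @param dim Image dimensions `c(rows, cols)` the kernel will be applied to
#'   (after any padding).
#' @param px_per_deg Pixels per degree.
#' @param center_freq Preferred spatial frequency, cycles/deg (default 2.4,
#'   the Battenberg carrier).
#' @param bandwidth_oct Radial bandwidth, full width in octaves at half height
#'   (default 1.6).
#' @param orientation_deg Preferred grating (bar) orientation in degrees;
#'   0 is a horizontal grating (modulation along the vertical axis).
#' @param angular_hwhh_deg Angular half-width at half height, degrees
#'   (default 25).
#' @return An object of class `log_gabor`: the real even transfer `H`, the
#'   sign grid used to build the odd (quadrature) partner, and the parameters.
#' @export
make_log_gabor <- function(dim, px_per_deg = 48, center_freq = 2.4,
                           bandwidth_oct = 1.6, orientation_deg = 0,
                           angular_hwhh_deg = 25) {
  nyquist <- px_per_deg / 2
  if (center_freq <= 0 || center_freq >= nyquist)
    abort(sprintf("center_freq (%g c/deg) must lie in (0, Nyquist = %g c/deg)",
                  center_freq, nyquist))
  nr <- dim[1]; nc <- dim[2]
  fy <- fft_freqs(nr) * px_per_deg        # cycles/deg along rows
  fx <- fft_freqs(nc) * px_per_deg
  FY <- matrix(fy, nr, nc)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  fr <- sqrt(FX^2 + FY^2)

  sigma_r <- bandwidth_oct * log(2) / (2 * sqrt(2 * log(2)))
  radial <- matrix(0, nr, nc)
  nz <- fr > 0
  radial[nz] <- exp(-(log(fr[nz] / center_freq))^2 / (2 * sigma_r^2))

  # modulation direction of the preferred grating (normal to its bars)
  phi0 <- (orientation_deg + 90) * pi / 180
  ang <- atan2(FY, FX)
  dtheta <- (ang - phi0 + pi / 2) %% pi - pi / 2   # wrap to [-90, 90) deg, both lobes
  sigma_t <- (angular_hwhh_deg * pi / 180) / sqrt(2 * log(2))
  angular <- exp(-dtheta^2 / (2 * sigma_t^2))

  # sign of frequency along the modulation axis, for the Hilbert (odd) partner
  s <- sign(FX * cos(phi0) + FY * sin(phi0))
  structure(list(H = radial * angular, sign = s,
                 px_per_deg = px_per_deg, center_freq = center_freq,
                 bandwidth_oct = bandwidth_oct,
                 orientation_deg = orientation_deg,
                 angular_hwhh_deg = angular_hwhh_deg, dim = c(nr, nc)),
            class = "log_gabor")
}

# FFT bin frequencies in cycles per sample, standard ordering
fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' @export
print.log_gabor <- function(x, ...) {
  cat(sprintf(
    "log-Gabor kernel: %g c/deg, %.2g oct bandwidth, %g deg orientation (+-%g deg HWHH), %d x %d grid\n",
    x$center_freq, x$bandwidth_oct, x$orientation_deg, x$angular_hwhh_deg,
    x$dim[1], x$dim[2]))
  invisible(x)
}

#' Filter an image into a local-contrast response map
#'
#' Converts a luminance image to percent Weber contrast, convolves it with a
#' log-Gabor channel in the frequency domain, and returns the rectified
#' response as a `contrast_map`.  `phase = "cosine"` uses the even-symmetric
#' filter, `"sine"` its odd (Hilbert) partner, and `"quadrature"` the modulus
#' of the analytic pair (the local contrast envelope).
#'
#' The image is padded with mean luminance (zero contrast) to twice its size
#' before the circular convolution, emulating the mid-grey surround of a
#' framed stimulus and keeping wraparound away from the stimulus; the response
#' is cropped back to the original support.
#'
#' @param img A `luminance_image`.
#' @param kernel A [make_log_gabor()] kernel matching the padded size, or
#'   `NULL` to build one from `...` defaults.
#' @param phase `"cosine"`, `"sine"`, or `"quadrature"`.
#' @param pad Pad to twice the image size with zero contrast?
#' @param rectify Return response magnitudes (the default, as pooled by the
#'   models)?  `rectify = FALSE` gives the signed cosine/sine response, useful
#'   for linearity diagnostics; quadrature is a magnitude by construction.
#' @param ... Passed to [make_log_gabor()] when `kernel` is `NULL`.
#' @return A `contrast_map` (provenance `"filter_response"`), percent units.
#' @export
filter_contrast_map <- function(img, kernel = NULL,
                                phase = c("cosine", "sine", "quadrature"),
                                pad = TRUE, rectify = TRUE, ...) {
  phase <- match.arg(phase)
  stopifnot(inherits(img, "luminance_image"))
  L <- img$pixels
  m <- mean(L)
  cimg <- 100 * (L - m) / m          # signed Weber contrast, percent
  nr <- nrow(cimg); nc <- ncol(cimg)
  if (pad) {
    work <- matrix(0, 2 * nr, 2 * nc)
    work[seq_len(nr), seq_len(nc)] <- cimg
  } else work <- cimg
  if (is.null(kernel))
    kernel <- make_log_gabor(dim(work), px_per_deg = img$px_per_deg, ...)
  if (!all(dim(work) == kernel$dim))
    abort(sprintf("kernel grid (%d x %d) does not match the padded image (%d x %d)",
                  kernel$dim[1], kernel$dim[2], nrow(work), ncol(work)))
  FW <- fft(work)
  n_px <- length(work)
  even <- function() Re(fft(FW * kernel$H, inverse = TRUE)) / n_px
  odd  <- function() Re(fft(FW * (-1i * kernel$sign * kernel$H),
                            inverse = TRUE)) / n_px
  resp <- switch(phase,
    cosine     = if (rectify) abs(even()) else even(),
    sine       = if (rectify) abs(odd()) else odd(),
    quadrature = sqrt(even()^2 + odd()^2)
  )
  if (pad) resp <- resp[seq_len(nr), seq_len(nc)]
  new_contrast_map(resp, "filter_response")
}
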