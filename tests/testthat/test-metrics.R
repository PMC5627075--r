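test_that("Weber contrast map follows the rectified Weber fraction", {
  expect_true(all(weber_contrast_map(matrix(1, 5, 5))$values == 0))
  two <- weber_contrast_map(matrix(c(0.5, 1.5), 1, 2))
  expect_equal(as.vector(two$values), c(50, 50))
  bb <- weber_contrast_map(make_battenberg(small_spec(8, 8)))
  expect_equal(max_contrast(bb), 8, tolerance = 1e-12)
  expect_true(all(bb$values >= 0))
  expect_error(weber_contrast_map(matrix(0, 2, 2)), "mean luminance")
})

test_that("image metrics match closed forms on canonical patterns", {
  sq <- matrix(rep(c(0, 2), 50), 10, 10)        # binary square wave about 1
  expect_equal(michelson_contrast(sq), 100)
  expect_equal(rms_contrast(sq), 100)
  expect_equal(michelson_contrast(matrix(1, 3, 3)), 0)
  expect_equal(rms_contrast(matrix(1, 3, 3)), 0)

  # full-field sinusoid at Michelson C has RMS contrast C / sqrt(2)
  C <- 50
  g <- 1 + (C / 100) * sin(2 * pi * outer(0:199, rep(1, 200)) / 20)
  expect_equal(rms_contrast(g), C / sqrt(2), tolerance = 1e-12)
  expect_equal(michelson_contrast(g), C, tolerance = 1e-12)

  m <- weber_contrast_map(g)
  expect_equal(contrast_average(m), mean(m$values))
  expect_equal(contrast_energy(m), sum(m$values^2))
  expect_equal(contrast_sum(m), sum(m$values))
})

test_that("toy model responses reproduce their closed forms", {
  expect_equal(toy_response("ms", 0, 0), 0)
  expect_equal(toy_response("ms", 8, 8), 2 * 8^2.4 / (1 + 2 * 8^2))
  f <- function(C) C^2.4 / (1 + C^2)
  expect_equal(toy_response("lf", 4, 8), f(4) + f(8))
  expect_equal(toy_response("max", 4, 8), 8)
  expect_equal(toy_response("linsum", 4, 8), 12)
  expect_equal(toy_response("energy", 4, 8), 80)
  # vectorised and symmetric
  expect_equal(toy_response("ms", c(4, 8), c(8, 4)),
               rev(toy_response("ms", c(4, 8), c(8, 4))))
  expect_error(toy_response("ms", -1, 8), "non-negative")
})

test_that("gain-control pooling reduces to the toy model at matched scale", {
  prm <- model_params()
  # a single location is a one-component toy model
  expect_equal(gain_control_response(5, prm), 5^2.4 / (1 + 5^2))
  expect_equal(gain_control_response(matrix(0, 4, 4), prm), 0)

  # element map of a j=1 grid: N/2 entries at A, N/2 at B; scaling z by N/2
  # makes the pooled response equal the toy response exactly, and the pooled
  # z = 1 response equals the toy response with z shrunk by the same factor
  spec <- battenberg_spec(4, 8, 1)
  emap <- element_contrast_map(spec)
  N2 <- spec$n_elements^2 / 2
  expect_equal(gain_control_response(emap, model_params(z = N2)),
               toy_response("ms", 4, 8))
  expect_equal(gain_control_response(emap, prm),
               toy_response("ms", 4, 8, model_params(z = 1 / N2)))
  # with z = 1 the difference from the toy response is bounded by the
  # z-share of the suppressive sum (~1/(N/2 * (4^2 + 8^2)))
  expect_equal(gain_control_response(emap, prm), toy_response("ms", 4, 8),
               tolerance = 0.02)
})

test_that("Legge-Foley pooling supports linear and Minkowski summation", {
  prm <- model_params()
  f <- function(C) C^2.4 / (1 + C^2)
  expect_equal(lf_summed_response(c(4, 8), model_params(minkowski_k = 1)),
               lf_summed_response(c(4, 8), prm))
  expect_equal(lf_summed_response(c(4, 8), model_params(minkowski_k = 4)),
               (f(4)^4 + f(8)^4)^(1 / 4))
  expect_equal(lf_summed_response(c(4, 8), model_params(minkowski_k = Inf)),
               f(8))
  expect_error(model_params(minkowski_k = 0.5), "k")
})

test_that("gain-control response of a uniform map is increasing in level and area-stable", {
  prm <- model_params()
  lvls <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  r <- vapply(lvls, function(C) gain_control_response(rep(C, 100), prm), 0)
  expect_true(all(diff(r) > 0))

  # doubling the area of a uniform suprathreshold pattern barely moves the
  # response (the cure for the area-growth of plain energy/sum metrics)
  r_area <- vapply(c(100, 200, 400, 800),
                   function(N) gain_control_response(rep(8, N), prm), 0)
  expect_lt(max(abs(diff(r_area) / r_area[-1])), 1e-3)
  expect_gt(contrast_energy(rep(8, 800)) / contrast_energy(rep(8, 100)), 7.9)
})

test_that("model parameter validation enforces p > q and z >= 0", {
  expect_error(model_params(p = 2, q = 2), "saturation")
  expect_error(model_params(p = 1.6, q = 2), "saturation")
  expect_error(model_params(z = -1), "z")
  expect_silent(model_params(p = 2.0, q = 1.6))
})
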