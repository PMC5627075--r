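test_that("toy PSEs match closed-form inversions to solver tolerance", {
  # energy: m = sqrt(A^2 + B^2) single, sqrt((A^2 + B^2)/2) dual;
  # linsum: m = A + B single, (A + B)/2 dual; max: m = max(A, B) in both
  for (ab in list(c(4, 8), c(0.5, 8), c(16, 8), c(32, 8))) {
    A <- ab[1]; B <- ab[2]
    expect_equal(predict_pse(A, B, "energy", "single")$pse, sqrt(A^2 + B^2),
                 tolerance = 1e-6)
    expect_equal(predict_pse(A, B, "energy", "dual")$pse, sqrt((A^2 + B^2) / 2),
                 tolerance = 1e-6)
    expect_equal(predict_pse(A, B, "linsum", "single")$pse, A + B,
                 tolerance = 1e-6)
    expect_equal(predict_pse(A, B, "linsum", "dual")$pse, (A + B) / 2,
                 tolerance = 1e-6)
    expect_equal(predict_pse(A, B, "max", "single")$pse, max(A, B),
                 tolerance = 1e-6)
    expect_equal(predict_pse(A, B, "max", "dual")$pse, max(A, B),
                 tolerance = 1e-6)
  }
})

test_that("the solver agrees with an independent grid inversion of the gain-control model", {
  prm <- model_params()
  r_target <- toy_response("ms", 4, 8, prm)
  oracle <- grid_invert_pse(r_target, function(m) toy_response("ms", m, 0, prm),
                            lo = 5, hi = 10, n = 200001)
  expect_equal(predict_pse(4, 8, "ms", "single")$pse, oracle, tolerance = 1e-4)

  oracle_dual <- grid_invert_pse(r_target,
                                 function(m) toy_response("ms", m, m, prm),
                                 lo = 5, hi = 10, n = 200001)
  expect_equal(predict_pse(4, 8, "ms", "dual")$pse, oracle_dual,
               tolerance = 1e-4)
  # gross over-prediction of the summed Legge-Foley transducer
  expect_equal(predict_pse(4, 8, "lf", "single")$pse,
               grid_invert_pse(toy_response("lf", 4, 8, prm),
                               function(m) toy_response("lf", m, 0, prm),
                               lo = 20, hi = 40, n = 200001),
               tolerance = 1e-4)
  expect_gt(predict_pse(4, 8, "lf", "single")$pse, 25)
})

test_that("whenever the test belongs to the match family the PSE is the test level", {
  for (model in c("max", "linsum", "energy", "lf", "ms")) {
    expect_equal(predict_pse(0, 8, model, "single")$pse, 8, tolerance = 1e-7)
    expect_equal(predict_pse(8, 8, model, "dual")$pse, 8, tolerance = 1e-7)
    expect_equal(predict_pse(0, 3, model, "single")$pse, 3, tolerance = 1e-7)
  }
})

test_that("only the gain-control model shows the paradoxical mismatch", {
  expect_lt(predict_pse(4, 8, "ms", "single")$pse, 8)
  expect_lt(predict_pse(16, 8, "ms", "single")$pse, 16)
  expect_lt(predict_pse(4, 8, "ms", "dual")$pse, 8)
  grid <- contrast_grid()
  for (model in c("max", "linsum", "energy", "lf")) {
    single <- matching_curve(A = grid, model = model, match_mode = "single")
    expect_true(all(single$pse >= pmax(single$A, single$B) - 1e-6))
    for (mode in c("single", "dual")) {
      crv <- matching_curve(A = grid, model = model, match_mode = mode)
      expect_true(all(diff(crv$pse) >= -1e-9))   # no dip anywhere
    }
  }
  ms_single <- matching_curve(A = grid, model = "ms", match_mode = "single")
  expect_true(any(ms_single$pse < pmax(ms_single$A, ms_single$B) - 0.1))
})

test_that("element and pixelwise pipelines track the toy gain-control predictions", {
  toy <- predict_pse(4, 8, "ms", "single")$pse
  el <- predict_pse(4, 8, "ms", "single", granularity = "element",
                    n_elements = 10)$pse
  px <- predict_pse(4, 8, "ms", "single", granularity = "pixelwise",
                    n_elements = 10)$pse
  # element pooling over N elements is algebraically the toy model with z
  # scaled down by the number of modulated elements per component
  toy_zscaled <- predict_pse(4, 8, "ms", "single",
                             params = model_params(z = 1 / 50))$pse
  expect_equal(el, toy_zscaled, tolerance = 1e-6)
  expect_lt(abs(db_ratio(el, toy)), 0.3)
  expect_lt(abs(db_ratio(px, toy)), 0.3)
  # the max model sees the image Michelson contrast at any granularity
  expect_equal(predict_pse(4, 8, "max", "single", granularity = "pixelwise",
                           n_elements = 10)$pse, 8, tolerance = 1e-6)
})

test_that("matching curves are tidy, complete, and pass through the dual fixed point", {
  crv <- matching_curve(model = "ms", match_mode = c("single", "dual"))
  expect_s3_class(crv, "matching_curve")
  expect_s3_class(crv, "tbl_df")
  expect_identical(nrow(crv), 16L)
  expect_true(all(crv$converged))
  for (model in c("max", "linsum", "energy", "lf", "ms"))
    expect_equal(matching_curve(A = 8, model = model, match_mode = "dual")$pse,
                 8, tolerance = 1e-7)
  mx <- matching_curve(model = "max", match_mode = "single")
  expect_equal(mx$pse, pmax(mx$A, 8), tolerance = 1e-7)

  # condition-table interface fills defaults
  crv2 <- matching_curve(conditions = tibble::tibble(A = c(0, 4)), model = "ms")
  expect_identical(crv2$match_mode, c("single", "single"))
})

test_that("alternative exponent pairs barely move the gain-control predictions", {
  crv_ref <- matching_curve(model = "ms", match_mode = c("single", "dual"))
  crv_alt <- matching_curve(model = "ms", match_mode = c("single", "dual"),
                            params = model_params(p = 2.0, q = 1.6))
  expect_lt(max(abs(db_ratio(crv_alt$pse, crv_ref$pse))), 1)

  # regression: dropping the saturation constant shifts PSEs by at most
  # ~0.16 dB (largest at the dual match with A = 0, where z is the biggest
  # share of the suppressive denominator), far below inter-model differences
  crv_z0 <- matching_curve(model = "ms", match_mode = c("single", "dual"),
                           params = model_params(z = 0))
  expect_lt(max(abs(db_ratio(crv_z0$pse, crv_ref$pse))), 0.25)
})

test_that("bracket failure and above-physical solutions are flagged, not hidden", {
  expect_warning(
    res <- predict_pse(100, 100, "linsum", "single", m_max = 150),
    "no matching level")
  expect_false(res$converged)
  expect_true(is.na(res$pse))

  hi <- predict_pse(80, 80, "energy", "single")
  expect_true(hi$converged)
  expect_true(hi$above_physical)
  expect_equal(hi$pse, sqrt(2) * 80, tolerance = 1e-6)

  expect_error(predict_pse(4, 8, "ms", granularity = "toy", filtered = TRUE),
               "forbids")
})
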