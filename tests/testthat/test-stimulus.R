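test_that("checker mask alternates labels in j x j clusters", {
  expect_identical(checker_mask(2, 1),
                   matrix(c("A", "B", "B", "A"), 2, 2))

  m4 <- checker_mask(4, 2)
  # four uniform 2x2 blocks in checker arrangement
  blocks <- list(m4[1:2, 1:2], m4[1:2, 3:4], m4[3:4, 1:2], m4[3:4, 3:4])
  expect_true(all(vapply(blocks, function(b) length(unique(c(b))) == 1, TRUE)))
  expect_identical(vapply(blocks, function(b) b[1, 1], ""),
                   c("A", "B", "B", "A"))

  # parity flip swaps every label, for divisible and truncated tilings alike
  for (cfg in list(c(12, 4), c(20, 8), c(10, 1))) {
    m0 <- checker_mask(cfg[1], cfg[2], parity = 0, partial = "truncate")
    m1 <- checker_mask(cfg[1], cfg[2], parity = 1, partial = "truncate")
    expect_true(all((m0 == "A") == (m1 == "B")))
  }
})

test_that("non-divisible cluster size errors by name unless truncation is requested", {
  expect_error(checker_mask(20, 8), "8.*20")
  m <- checker_mask(20, 8, partial = "truncate")
  expect_identical(dim(m), c(20L, 20L))
  # centre crop of a 24-element virtual grid: interior clusters are full 8x8
  runs <- rle(m[, 7])$lengths
  expect_true(8 %in% runs)
})

test_that("generated Battenbergs keep exact mean luminance and Michelson contrast", {
  for (j in c(1, 2, 4, 8)) {
    for (ab in list(c(0, 0), c(8, 8), c(32, 8), c(4, 16))) {
      img <- make_battenberg(battenberg_spec(ab[1], ab[2], j))
      expect_equal(mean(img$pixels), 1, tolerance = 1e-6)
      if (max(ab) > 0)
        expect_equal(michelson_contrast(img), max(ab), tolerance = 1e-9)
      expect_true(all(img$pixels > 0))
    }
  }
  uni <- make_battenberg(battenberg_spec(0, 0))
  expect_true(all(uni$pixels == 1))
})

test_that("every element attains its nominal peak contrast and zero-contrast borders", {
  spec <- small_spec(32, 8, j = 2)
  img <- make_battenberg(spec)
  mask <- checker_mask(spec$n_elements, spec$cluster_size_j, spec$parity,
                       partial = "truncate")
  epx <- spec$element_px
  for (r in seq_len(spec$n_elements)) {
    for (cc in seq_len(spec$n_elements)) {
      el <- img$pixels[(r - 1) * epx + seq_len(epx), (cc - 1) * epx + seq_len(epx)]
      want <- if (mask[r, cc] == "A") spec$contrast_A else spec$contrast_B
      expect_equal(100 * max(abs(el - 1)), want, tolerance = 1e-9)
      # envelope and carrier zeros: first row and column of the element sit at mean
      expect_true(all(abs(el[1, ] - 1) < 1e-12))
      expect_true(all(abs(el[, 1] - 1) < 1e-12))
    }
  }
})

test_that("swapping components and parity together leaves the image unchanged", {
  for (j in c(1, 2, 4, 8)) {
    a <- make_battenberg(battenberg_spec(32, 8, j, parity = 0L))
    b <- make_battenberg(battenberg_spec(8, 32, j, parity = 1L))
    expect_identical(a$pixels, b$pixels)
  }
  # with A = B parity is irrelevant
  expect_identical(make_battenberg(small_spec(8, 8, parity = 0L))$pixels,
                   make_battenberg(small_spec(8, 8, parity = 1L))$pixels)
})

test_that("matching stimuli are the stated special cases of the test stimulus", {
  spec <- small_spec(j = 1)
  expect_identical(make_matching_stimulus("dual", 8, spec)$pixels,
                   make_battenberg(small_spec(8, 8))$pixels)
  m0 <- make_matching_stimulus("single", 0, spec)
  expect_true(all(m0$pixels == 1))
  expect_error(make_matching_stimulus("single", -1, spec), "non-negative")

  # single match at j = 1 modulates exactly half the elements
  ms <- make_matching_stimulus("single", 8, spec)
  epx <- spec$element_px
  peak <- outer(seq_len(spec$n_elements), seq_len(spec$n_elements),
                Vectorize(function(r, cc) {
                  max(abs(ms$pixels[(r - 1) * epx + seq_len(epx),
                                    (cc - 1) * epx + seq_len(epx)] - 1))
                }))
  expect_identical(sum(peak > 1e-9), as.integer(spec$n_elements^2 / 2))
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(battenberg_spec(contrast_A = -1), "0, 100")
  expect_error(battenberg_spec(contrast_B = 101), "0, 100")
  expect_error(battenberg_spec(cluster_size_j = 3), "1, 2, 4, 8")
  expect_error(battenberg_spec(parity = 2), "parity")
})

test_that("image export round-trips: PNG to quantisation, float array exactly", {
  img <- make_battenberg(small_spec(32, 8, j = 2))
  path <- withr::local_tempfile(fileext = ".png")
  write_stimulus_png(img, path)
  back <- read_stimulus_png(path)
  expect_equal(back$px_per_deg, 48)
  expect_lt(max(abs(back$pixels - img$pixels)), 2 / 255 * 1.01)
  expect_equal(michelson_contrast(back), 32, tolerance = 0.05)

  fpath <- withr::local_tempfile(fileext = ".txt")
  write_stimulus_array(img, fpath)
  fback <- read_stimulus_array(fpath)
  expect_equal(fback$pixels, img$pixels, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(fback$px_per_deg, 48)
})
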