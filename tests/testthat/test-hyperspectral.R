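# Hyperspectral LCO pipeline: projection, background, thresholding,
# morphology, ROI extraction, emission ratio.

test_that("max projection dominates every channel slice", {
  set.seed(11)
  cube <- array(runif(20 * 15 * 6), c(20, 15, 6))
  mp <- max_projection(cube)
  for (ch in 1:6) expect_true(all(mp >= cube[, , ch]))
  oracle <- matrix(0, 20, 15)
  for (i in 1:20) for (j in 1:15) oracle[i, j] <- max(cube[i, j, ])
  expect_identical(mp, oracle)
  cube2 <- array(runif(10 * 10 * 4), c(10, 10, 4))
  cube2[, , 3] <- 5
  expect_equal(max_projection(cube2), cube2[, , 3])
  expect_equal(max_projection(array(0, c(4, 4, 3))), matrix(0, 4, 4))
  expect_error(max_projection(array(0, c(0, 0, 0))), "empty")
})

test_that("background subtraction matches a direct convolution oracle and keeps sharp spots", {
  # blur of a constant is the constant (reflective padding makes it exact)
  expect_equal(subtract_background(matrix(3.7, 40, 40), sigma = 5),
               matrix(0, 40, 40), tolerance = 1e-12)
  set.seed(21)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_equal(gaussian_blur(x, 3), oracle_blur(x, 3), tolerance = 1e-10)
  # sharp small spot on a flat background: spot retained, background ~ 0
  y <- matrix(10, 64, 64); y[32, 32] <- 1000
  res <- subtract_background(y, sigma = 8)
  expect_gt(res[32, 32], 900)
  expect_lt(max(abs(res[1:10, 1:10])), 1)
  expect_true(all(subtract_background(y, sigma = 8, clamp = TRUE) >= 0))
})

test_that("Otsu threshold equals the exhaustive between-class-variance maximizer", {
  x <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  thr <- otsu_threshold(x)
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate")
  set.seed(5)
  for (i in 1:25) {
    img <- matrix(round(c(rnorm(600, runif(1, 30, 90), runif(1, 5, 25)),
                          rnorm(424, runif(1, 140, 220), runif(1, 5, 25)))),
                  32, 32)
    img <- pmin(pmax(img, 0), 255)
    if (diff(range(img)) == 0) next
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
  # planted two-Gaussian mixture: misclassification below 1 %
  set.seed(9)
  lab <- rep(c(FALSE, TRUE), each = 2500)
  v <- c(rnorm(2500, 30, 10), rnorm(2500, 180, 10))
  thr <- otsu_threshold(matrix(v, 50, 100))
  expect_lt(mean((v > thr) != lab), 0.01)
})

test_that("disk closing fills lumens, is idempotent, and leaves full masks alone", {
  m <- matrix(FALSE, 40, 40)
  m[10:30, 10:30] <- TRUE
  m[19:21, 19:21] <- FALSE          # 3-px hole inside a large blob
  closed <- close_mask(m, radius = 5)
  expect_true(all(closed[19:21, 19:21]))
  full <- matrix(TRUE, 20, 20)
  expect_equal(unclass(close_mask(full, 4)), full, ignore_attr = TRUE)
  set.seed(3)
  for (i in 1:5) {
    rnd <- matrix(runif(30 * 30) > 0.6, 30, 30)
    once <- close_mask(rnd, 3)
    expect_equal(close_mask(once, 3), once)
  }
})

test_that("ROI extraction uses 8-connectivity and exact average spectra", {
  # diagonal pixels belong to one component
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(max(label_components(d, connectivity = 8)), 1L)
  expect_equal(max(label_components(d, connectivity = 4)), 2L)

  nch <- 6
  cube <- array(0.5, c(30, 30, nch))
  specA <- seq(1, 2, length.out = nch)
  specB <- rep(3, nch)
  for (ch in seq_len(nch)) {
    cube[5:10, 5:10, ch] <- specA[ch]
    cube[20:24, 20:24, ch] <- specB[ch]
  }
  img <- suppressWarnings(hyperspectral_image(cube, seq(405, 750,
                                                        length.out = nch)))
  mask <- matrix(FALSE, 30, 30)
  mask[5:10, 5:10] <- TRUE; mask[20:24, 20:24] <- TRUE; mask[1, 1] <- TRUE
  ex <- extract_rois(mask, img, min_pixels = 2)   # single pixel dropped
  expect_length(ex$rois, 2)
  expect_setequal(vapply(ex$rois, `[[`, 1L, "n_pixels"), c(36L, 25L))
  specs <- lapply(ex$rois, `[[`, "spectrum")
  sizes <- vapply(ex$rois, `[[`, 1L, "n_pixels")
  expect_equal(specs[[which(sizes == 36)]], specA)
  expect_equal(specs[[which(sizes == 25)]], specB)
  expect_equal(ex$full_field_spectrum,
               apply(cube, 3, mean))
  # empty mask yields no ROIs
  expect_length(extract_rois(matrix(FALSE, 30, 30), img)$rois, 0)
})

test_that("the emission ratio is a scale-free two-channel mixture statistic", {
  wl <- default_wavelength_axis()
  q <- lco_endmember(wl, 500); h <- lco_endmember(wl, 580)
  rq <- spectral_ratio(q, wl); rh <- spectral_ratio(h, wl)
  expect_gt(rq, 1); expect_lt(rh, 1)
  mix <- 0.5 * q + 0.5 * h
  rmix <- spectral_ratio(mix, wl)
  expect_gt(rmix, rh); expect_lt(rmix, rq)
  expect_equal(spectral_ratio(17.3 * mix, wl), rmix)          # scale-free
  flat <- rep(2, length(wl))
  expect_equal(spectral_ratio(flat, wl), 1.0)
  expect_error(spectral_ratio(q * 0, wl), "zero denominator")
  expect_error(spectral_ratio(q, wl, at = c(300, 580)), "outside")
})

test_that("the LCO pipeline recovers planted vessels, their ratios, and is deterministic", {
  cfg <- lco_sim_config(image_size = c(192, 192), n_vessels = 3,
                        noise_frac = 0.02, seed = 31)
  sim <- generate_lco_image(cfg)
  res <- run_lco_pipeline(sim$image)
  expect_equal(nrow(res$summary), 3)
  m <- match_rois(res$labels, sim$truth$labels)
  expect_true(all(m$found_id > 0))
  rec <- res$summary$ratio_500_580[m$found_id]
  expect_true(all(abs(rec - sim$truth$ratios) / sim$truth$ratios < 0.02))
  # all-background image gives an empty summary
  empty <- generate_lco_image(lco_sim_config(image_size = c(96, 96),
                                             n_vessels = 0, seed = 1))
  # constant-free background still thresholds on noise; no ROI survives
  res0 <- run_lco_pipeline(empty$image)
  expect_equal(nrow(res0$summary), 0)
  # determinism: identical image in, bit-identical result out
  res2 <- run_lco_pipeline(sim$image)
  expect_identical(res$summary, res2$summary)
  expect_identical(res$mask, res2$mask)
})

test_that("ROI average spectra are invariant to pixel visitation order", {
  set.seed(13)
  cube <- array(runif(12 * 12 * 5), c(12, 12, 5))
  img <- suppressWarnings(hyperspectral_image(cube, seq(450, 650,
                                                        length.out = 5)))
  mask <- matrix(FALSE, 12, 12); mask[3:9, 4:8] <- TRUE
  spec <- extract_rois(mask, img, min_pixels = 1)$rois[[1]]$spectrum
  idx <- which(mask)
  flat <- matrix(cube, ncol = 5)
  for (perm in 1:3)
    expect_equal(colMeans(flat[sample(idx), , drop = FALSE]), spec)
})
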