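# MSI processing chain: normalization, peaks, integration, segmentation,
# quantification statistics, SPSC.

test_that("TIC normalization equalizes pixel sums and preserves within-pixel ratios", {
  ds <- make_msi(list(c(100, 200), c(100, 200)),
                 list(c(4, 6), c(9, 21)))        # TICs 10 and 30
  nd <- tic_normalize(ds)
  expect_equal(pixel_tic(nd), c(20, 20))
  expect_equal(attr(nd, "tic_target"), 20)
  # per-pixel multiplicative gain leaves within-pixel species ratios intact
  set.seed(2)
  mz <- c(1000, 1500, 2000)
  base <- list(c(5, 10, 15), c(2, 8, 4), c(7, 1, 3))
  gains <- c(0.5, 3, 1.7)
  ds2 <- make_msi(rep(list(mz), 3), Map(function(b, g) b * g, base, gains))
  nd2 <- tic_normalize(ds2)
  for (p in 1:3)
    expect_equal(nd2$spectra[[p]]$intensity / nd2$spectra[[p]]$intensity[1],
                 base[[p]] / base[[p]][1])
  # conservation within 1e-9 relative on a random dataset
  ds3 <- make_msi(replicate(20, sort(runif(5, 900, 4000)), simplify = FALSE),
                  replicate(20, runif(5, 0, 50), simplify = FALSE))
  nd3 <- tic_normalize(ds3)
  expect_true(all(abs(pixel_tic(nd3) / attr(nd3, "tic_target") - 1) < 1e-9))
  # zero-TIC pixels are dropped loudly; an all-zero dataset errors
  ds4 <- make_msi(list(c(1000), c(1000)), list(c(5), c(0)))
  expect_warning(nd4 <- tic_normalize(ds4), "zero-TIC")
  expect_equal(n_pixels(nd4), 1)
  expect_error(suppressWarnings(
    tic_normalize(make_msi(list(c(1000)), list(c(0))))), "zero")
})

test_that("peak detection recovers planted peaks with sensible bins", {
  grid <- seq(1000, 1100, by = 0.25)
  gauss <- function(c, a, sd = 1) a * exp(-(grid - c)^2 / (2 * sd^2))
  y <- gauss(1020, 100) + gauss(1050, 80) + gauss(1080, 120)
  bins <- detect_peaks(list(mz = grid, intensity = y))
  expect_equal(nrow(bins), 3)
  for (cen in c(1020, 1050, 1080))
    expect_true(any(bins$left <= cen & bins$right >= cen))
  # with mild noise added, the three real peaks are still found and each
  # bin still contains its generating center
  set.seed(4)
  bn <- detect_peaks(list(mz = grid,
                          intensity = y + abs(rnorm(length(grid), 0, 0.5))))
  for (cen in c(1020, 1050, 1080))
    expect_true(any(bn$left <= cen & bn$right >= cen & bn$height > 50))
  # single Gaussian: profile-mode area within 5 % of the closed form
  y1 <- gauss(1050, 100, sd = 1)
  b1 <- detect_peaks(list(mz = grid, intensity = y1))
  expect_equal(nrow(b1), 1)
  area <- integrate_spectrum(list(mz = grid, intensity = y1), b1,
                             mode = "profile")
  expect_equal(area, 100 * sqrt(2 * pi) * 1, tolerance = 0.05)
  # flat spectrum has no peaks
  expect_equal(nrow(detect_peaks(list(mz = grid,
                                      intensity = rep(2, length(grid))))), 0)
  # false-peak rate on pure noise at SNR 3 stays below 1 per spectrum
  set.seed(8)
  false_peaks <- replicate(300, {
    nrow(detect_peaks(list(mz = seq_len(256), intensity = rnorm(256))))
  })
  expect_lt(mean(false_peaks), 1)
})

test_that("bin integration is exact on centroids, linear, and rejects overlap", {
  bins <- data.frame(center = c(1000, 1500), left = c(999, 1499),
                     right = c(1001, 1501))
  ds <- make_msi(list(c(1000, 1250, 1500.5)), list(c(7, 99, 3)))
  ints <- integrate_bins(ds, bins)
  expect_equal(as.numeric(ints), c(7, 3))   # out-of-bin peak contributes 0
  # linearity: scaling the dataset scales the integrals
  ds2 <- make_msi(list(c(1000, 1250, 1500.5)), list(3.5 * c(7, 99, 3)))
  expect_equal(integrate_bins(ds2, bins), 3.5 * ints)
  bad <- data.frame(center = c(1000, 1000.5), left = c(999, 999.8),
                    right = c(1000.4, 1002))
  expect_error(integrate_bins(ds, bad), "overlap")
})

test_that("bisecting k-means matches exhaustive 2-means and behaves on edge cases", {
  set.seed(14)
  x <- rbind(matrix(rnorm(20, 0, 0.3), ncol = 2),
             matrix(rnorm(20, 4, 0.3), ncol = 2))
  bk <- bisect_kmeans(x, k = 2, seed = 5)
  oracle <- oracle_two_means(x)
  expect_equal(length(unique(bk$cluster)), 2)
  # same partition up to label swap
  agree <- mean((bk$cluster == 1) == (oracle == 1))
  expect_true(agree %in% c(0, 1))
  # k = 1 puts everything together; k > n errors
  expect_equal(bisect_kmeans(x, 1)$cluster, rep(1L, 20))
  expect_error(bisect_kmeans(x, 21), "more clusters")
  # duplicated data keeps the same partition structure
  bk2 <- bisect_kmeans(rbind(x, x), k = 2, seed = 5)
  expect_equal(bk2$cluster[1:20] == 1, bk2$cluster[21:40] == 1)
  # deterministic under a fixed seed
  expect_identical(bisect_kmeans(x, 3, seed = 9), bisect_kmeans(x, 3, seed = 9))
})

test_that("segmentation separates vessel from background pixels on planted data", {
  sim <- generate_msi_dataset(msi_sim_config(grid_size = c(70, 70),
                                             n_vessels = 5, seed = 23))
  ds <- tic_normalize(sim$dataset)
  bins <- annotate_bins(detect_peaks(average_spectrum(ds)), sim$truth$species)
  seg <- segment_msi(ds, bins, msi_config(seed = 3))
  x <- ds$coords$x + 1L; y <- ds$coords$y + 1L
  found <- matrix(FALSE, max(y), max(x))
  found[cbind(y, x)] <- seg$vessel_mask
  expect_gte(dice(found, sim$truth$labels > 0), 0.95)
  roi <- msi_vessel_rois(ds, seg)
  expect_equal(max(roi), 5)
})

test_that("relative quantification normalizes to the reference species per ROI", {
  rmat <- rbind(roi1 = c(A = 50, REF = 100), roi2 = c(A = 30, REF = 60))
  q <- relative_quant(rmat, "REF")
  expect_equal(q$relative[q$species == "A"], c(0.5, 0.5))
  expect_equal(q$relative[q$species == "REF"], c(1, 1))
  rmat2 <- rbind(roi1 = c(A = 5, REF = 10), roi2 = c(A = 3, REF = 0))
  expect_warning(q2 <- relative_quant(rmat2, "REF"), "dropped")
  expect_equal(unique(q2$roi), "roi1")
  expect_error(relative_quant(rbind(c(A = 1, REF = 0)), "REF"), "no signal")
  expect_error(relative_quant(rmat, "MISSING"), "not in intensity table")
})

test_that("subgroup fractions weight intensities within non-exclusive categories", {
  sp <- species_preset("FDD")
  # a single pyroglutamated, N-truncated species scores 100 % in both groups
  m1 <- matrix(5, 1, 1, dimnames = list("roi1", "ADan1pE-33"))
  f1 <- subgroup_fractions(m1, sp)
  expect_equal(f1$mean_pct[f1$category == "pyroglu"], 100)
  expect_equal(f1$mean_pct[f1$category == "n_truncated"], 100)
  expect_equal(f1$mean_pct[f1$category == "full_length"], 0)
  # equal split between a full-length and a C-truncated species
  m2 <- matrix(c(3, 3), 1, 2, dimnames = list("roi1", c("Abeta1-42", "Abeta1-40")))
  f2 <- subgroup_fractions(m2, sp, family = "Abeta")
  expect_equal(f2$mean_pct[f2$category == "full_length"], 50)
  expect_equal(f2$mean_pct[f2$category == "c_truncated"], 50)
  expect_error(subgroup_fractions(m2[0, , drop = FALSE], sp), "empty")
})

test_that("fractional contribution and coverage handle symmetric and degenerate cases", {
  ints <- cbind(Abeta = c(0, 0, 5, 5, 0), ADan = c(1, 1, 5, 5, 1))
  vessel <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  # zero amyloid-beta everywhere gives (0, 0)
  z <- fractional_contribution_and_coverage(
    cbind(Abeta = rep(0, 5), ADan = rep(2, 5)), vessel, "Abeta")
  expect_equal(z$signal_fraction_pct, 0)
  expect_equal(z$area_fraction_pct, 0)
  # identical planted images: 50 % of signal, 100 % coverage
  same <- cbind(Abeta = c(0, 0, 4, 6, 2), ADan = c(0, 0, 4, 6, 2))
  s <- fractional_contribution_and_coverage(same, vessel, "Abeta")
  expect_equal(s$signal_fraction_pct, 50)
  expect_equal(s$area_fraction_pct, 100)
  expect_error(fractional_contribution_and_coverage(ints, rep(FALSE, 5), "Abeta"),
               "empty vessel mask")
  expect_error(fractional_contribution_and_coverage(ints, vessel, "Nope"),
               "unknown species")
})

test_that("SPSC equals the brute-force correlation oracle and flags degeneracy", {
  set.seed(33)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  r <- spsc_matrix(x)
  expect_lt(max(abs(r - oracle_cor(x))), 1e-12)
  expect_lt(max(abs(r - stats::cor(x))), 1e-12)
  expect_equal(diag(r), setNames(rep(1, 4), colnames(x)))
  expect_true(isSymmetric(unclass(r)))
  # affine relation gives exactly 1
  y <- cbind(a = x[, 1], b = 2 * x[, 1])
  expect_equal(unname(spsc_matrix(y)["a", "b"]), 1)
  # zero-variance species yields NA rows/columns, not zeros
  z <- cbind(x[, 1:2], flat = rep(3, 50))
  rz <- spsc_matrix(z)
  expect_true(all(is.na(rz["flat", ])))
  expect_true(all(is.na(rz[, "flat"])))
  expect_false(anyNA(rz[1:2, 1:2]))
  # masking restricts the pixel set
  mask <- rep(c(TRUE, FALSE), 25)
  expect_lt(max(abs(spsc_matrix(x, mask) - stats::cor(x[mask, ]))), 1e-12)
  # spearman route
  expect_lt(max(abs(spsc_matrix(x, method = "spearman") -
                      stats::cor(x, method = "spearman"))), 1e-12)
  expect_error(spsc_matrix(x[, 1, drop = FALSE]), "2 species")
  expect_error(spsc_matrix(x[1:2, ]), "3 masked pixels")
})
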