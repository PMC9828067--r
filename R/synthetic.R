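# Seed-deterministic synthetic-data generators for both modalities, with
# analytic ground truth. Vessels are annular rings (CAA is vascular-wall
# deposition): the lumen hole makes segmentation non-trivial and exercises
# the binary-closing step.

# ---- shared geometry -------------------------------------------------------

# place n non-overlapping annuli (pairwise clearance r_i + r_j + gap);
# errors after bounded retries
.place_vessels <- function(size, n, outer_range, margin, gap,
                           max_retries = 20000L) {
  centers <- matrix(numeric(0), 0, 2)
  outer <- numeric(0)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > max_retries)
      stop("vessel placement failed after ", max_retries, " retries; ",
           "image too small for ", n, " vessels")
    r <- runif(1, outer_range[1], outer_range[2])
    cand <- c(runif(1, margin + 1, size[1] - margin),
              runif(1, margin + 1, size[2] - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= outer + r + gap)) {
      centers <- rbind(centers, cand)
      outer <- c(outer, r)
    }
  }
  list(centers = centers, outer = outer)
}

# ring and disk pixel index sets for one vessel
.vessel_pixels <- function(size, center, outer, inner) {
  r0 <- max(1L, floor(center[1] - outer)); r1 <- min(size[1], ceiling(center[1] + outer))
  c0 <- max(1L, floor(center[2] - outer)); c1 <- min(size[2], ceiling(center[2] + outer))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer(rows - center[1], cols - center[2],
              function(a, b) a^2 + b^2)
  disk <- d2 <= outer^2
  ring <- disk & d2 >= inner^2
  idx <- function(m) {
    w <- which(m, arr.ind = TRUE)
    cbind(row = rows[w[, 1]], col = cols[w[, 2]])
  }
  list(ring = idx(ring), disk = idx(disk))
}

# ---- hyperspectral LCO simulator ------------------------------------------

#' Gaussian LCO endmember emission spectrum
#'
#' Unit-peak Gaussian emission profile used for the q-FTAA-like (peak near
#' 500 nm, mature amyloid) and h-FTAA-like (peak near 580 nm, immature
#' amyloid) synthetic endmembers.
#'
#' @param wavelength Wavelengths (nm) at which to evaluate.
#' @param center Peak center (nm).
#' @param sd Peak standard deviation (nm).
#' @return Numeric vector.
#' @export
lco_endmember <- function(wavelength, center, sd = 30)
  exp(-(wavelength - center)^2 / (2 * sd^2))

#' LCO simulation configuration
#'
#' Emulates q-FTAA / h-FTAA double-stained CAA: annular vessels whose
#' pixels carry `weight * q + (1 - weight) * h` endmember mixtures sampled
#' at the 32 channel centers, on a flat dim background, with per-pixel
#' Gaussian channel noise.
#'
#' @param image_size Rows, cols.
#' @param n_vessels Number of vessels.
#' @param ratio_range Planted 500/580 ratios are drawn uniformly from this
#'   range and converted to mixing weights analytically.
#' @param q_weights Optional explicit per-vessel q weights in `[0, 1]`
#'   (overrides `ratio_range`).
#' @param outer_radius Range of vessel outer radii (pixels).
#' @param inner_radius Lumen radius (pixels); must not exceed the closing
#'   radius the pipeline will use if lumens are to be filled.
#' @param amplitude Vessel emission amplitude (a.u.).
#' @param background_frac Flat background level as a fraction of
#'   `amplitude`.
#' @param noise_frac Gaussian channel-noise SD as a fraction of
#'   `amplitude`.
#' @param q_center,q_sd,h_center,h_sd Endmember peak parameters (nm).
#' @param wavelength Spectral axis (nm).
#' @param min_gap Minimum clearance between vessel rims (pixels).
#' @param seed Random seed; generation is fully deterministic given it.
#' @return List of class `lco_sim_config`.
#' @export
lco_sim_config <- function(image_size = c(512, 512), n_vessels = 50,
                           ratio_range = c(0.5, 2.0), q_weights = NULL,
                           outer_radius = c(9, 13), inner_radius = 3,
                           amplitude = 1000, background_frac = 0.02,
                           noise_frac = 0.10,
                           q_center = 500, q_sd = 30,
                           h_center = 580, h_sd = 30,
                           wavelength = default_wavelength_axis(),
                           min_gap = 18, seed = 1L) {
  stopifnot(all(image_size >= 32), n_vessels >= 0,
            inner_radius < outer_radius[1], amplitude > 0,
            background_frac >= 0, noise_frac >= 0)
  if (!is.null(q_weights))
    stopifnot(length(q_weights) == n_vessels, all(q_weights >= 0),
              all(q_weights <= 1))
  structure(list(image_size = image_size, n_vessels = n_vessels,
                 ratio_range = ratio_range, q_weights = q_weights,
                 outer_radius = outer_radius, inner_radius = inner_radius,
                 amplitude = amplitude, background_frac = background_frac,
                 noise_frac = noise_frac,
                 q_center = q_center, q_sd = q_sd,
                 h_center = h_center, h_sd = h_sd,
                 wavelength = wavelength, min_gap = min_gap,
                 seed = as.integer(seed)),
            class = "lco_sim_config")
}

# endmember values at the channels nearest the two ratio wavelengths
.ratio_channels <- function(config, at = c(500, 580)) {
  wl <- config$wavelength
  ch <- vapply(at, function(w) which.min(abs(wl - w)), 1L)
  list(q = lco_endmember(wl[ch], config$q_center, config$q_sd),
       h = lco_endmember(wl[ch], config$h_center, config$h_sd))
}

#' Planted 500/580 ratio of an endmember mixing weight
#'
#' Evaluates the full planted vessel-pixel spectrum — the mixture
#' `w * q + (1 - w) * h` plus the flat background level — at the channels
#' nearest 500 and 580 nm and returns their ratio; the analytic ground
#' truth a perfect extractor would recover.
#'
#' @param weight q-endmember weight(s) in `[0, 1]`.
#' @param config An [lco_sim_config].
#' @return Ratio value(s).
#' @export
ratio_for_weight <- function(weight, config) {
  e <- .ratio_channels(config)
  b <- config$background_frac
  (weight * e$q[1] + (1 - weight) * e$h[1] + b) /
    (weight * e$q[2] + (1 - weight) * e$h[2] + b)
}

#' Mixing weight that plants a given 500/580 ratio
#'
#' Analytic inverse of [ratio_for_weight].
#'
#' @param ratio Target ratio(s).
#' @param config An [lco_sim_config].
#' @return Weight(s) in `[0, 1]`; errors if a ratio is unreachable.
#' @export
weight_for_ratio <- function(ratio, config) {
  e <- .ratio_channels(config)
  b <- config$background_frac
  w <- (ratio * (e$h[2] + b) - e$h[1] - b) /
    ((e$q[1] - e$h[1]) - ratio * (e$q[2] - e$h[2]))
  if (any(w < 0 | w > 1))
    stop("ratio outside the range reachable by endmember mixing")
  w
}

#' Generate a synthetic hyperspectral LCO image
#'
#' @param config An [lco_sim_config].
#' @return List: `image` (a [hyperspectral_image]) and `truth` with
#'   `labels` (planted vessel footprints as a label matrix; lumens count as
#'   vessel area), `ratios` (analytic 500/580 per vessel), `weights`,
#'   `centers`, `outer`, and the config.
#' @export
generate_lco_image <- function(config = lco_sim_config()) {
  stopifnot(inherits(config, "lco_sim_config"))
  set.seed(config$seed)
  size <- config$image_size
  nch <- length(config$wavelength)
  A <- config$amplitude
  cube <- array(config$background_frac * A, dim = c(size[1], size[2], nch))
  labels <- matrix(0L, size[1], size[2])
  weights <- ratios <- numeric(0)
  centers <- matrix(numeric(0), 0, 2)
  outer_r <- numeric(0)
  if (config$n_vessels > 0) {
    weights <- if (!is.null(config$q_weights)) config$q_weights
    else weight_for_ratio(runif(config$n_vessels, config$ratio_range[1],
                                config$ratio_range[2]), config)
    margin <- config$outer_radius[2] + ceiling(config$min_gap / 2)
    pl <- .place_vessels(size, config$n_vessels, config$outer_radius, margin,
                         config$min_gap)
    centers <- pl$centers; outer_r <- pl$outer
    qs <- lco_endmember(config$wavelength, config$q_center, config$q_sd)
    hs <- lco_endmember(config$wavelength, config$h_center, config$h_sd)
    for (v in seq_len(config$n_vessels)) {
      px <- .vessel_pixels(size, centers[v, ], outer_r[v], config$inner_radius)
      spec <- A * (weights[v] * qs + (1 - weights[v]) * hs)
      for (ch in seq_len(nch))
        cube[cbind(px$ring, ch)] <- cube[cbind(px$ring, ch)] + spec[ch]
      labels[px$disk] <- v
    }
    ratios <- ratio_for_weight(weights, config)
  }
  if (config$noise_frac > 0)
    cube <- cube + rnorm(length(cube), sd = config$noise_frac * A)
  cube[cube < 0] <- 0
  list(image = hyperspectral_image(cube, config$wavelength),
       truth = list(labels = labels, ratios = ratios, weights = weights,
                    centers = centers, outer = outer_r, config = config))
}

#' Match recovered components to planted vessels by Dice overlap
#'
#' @param found Integer label matrix of recovered components.
#' @param truth Integer label matrix of planted vessel footprints.
#' @return Data frame: `truth_id`, `found_id` (0 when nothing overlaps),
#'   `dice` (against the best-overlapping component).
#' @export
match_rois <- function(found, truth) {
  ids <- sort(unique(truth[truth > 0]))
  res <- lapply(ids, function(tid) {
    tm <- truth == tid
    overlap <- found[tm]
    overlap <- overlap[overlap > 0]
    if (!length(overlap))
      return(data.frame(truth_id = tid, found_id = 0L, dice = 0))
    fid <- as.integer(names(which.max(table(overlap))))
    data.frame(truth_id = tid, found_id = fid, dice = dice(tm, found == fid))
  })
  do.call(rbind, res)
}

# ---- MALDI-MSI simulator ---------------------------------------------------

# preset expected per-pixel relative intensities (reference species = 1)
.PRESET_ABUNDANCE <- list(
  FBD = c("ABri1-34" = 1.0, "ABri1pE-34" = 3.0, "ABri2-34" = 0.6,
          "ABri3-34" = 1.6, "ABri1-29" = 0.5, "ABri1pE-29" = 2.2,
          "ABri2-29" = 0.25, "ABri3-29" = 0.45),
  FDD = c("ADan1-34" = 1.0, "ADan1pE-34" = 2.6, "ADan3-34" = 1.17,
          "ADan1-33" = 0.6, "ADan1pE-33" = 5.2, "ADan3-33" = 2.6,
          "ADan1-29" = 0.2, "ADan1pE-29" = 1.2, "ADan1-28" = 0.13,
          "ADan1pE-28" = 0.7,
          "Abeta1-40" = 0.609, "Abeta3-40" = 1.601, "Abeta3pE-40" = 0.9,
          "Abeta1-42" = 0.609, "Abeta3-42" = 0.121, "Abeta3pE-42" = 0.36),
  CAA = c("Abeta1-37" = 0.35, "Abeta1-40" = 1.0, "Abeta2-40" = 0.15,
          "Abeta3-40" = 0.45, "Abeta3pE-40" = 0.55, "Abeta4-40" = 0.5,
          "Abeta5-40" = 0.12, "Abeta8-40" = 0.1, "Abeta9-40" = 0.08,
          "Abeta11-40" = 0.12, "Abeta11pE-40" = 0.18, "Abeta1-42" = 0.06,
          "Abeta3pE-42" = 0.12, "Abeta4-42" = 0.1, "Abeta11pE-42" = 0.08))

.PRESET_REFERENCE <- c(FBD = "ABri1-34", FDD = "ADan1-34", CAA = "Abeta1-40")

#' Block correlation matrix over a species table
#'
#' Species of the same co-deposition group (same precursor; amyloid-beta
#' additionally split by C-terminal truncation) correlate at `within`,
#' across groups at `cross`; mirrors the co-localization structure seen in
#' single-pixel correlation heatmaps.
#'
#' @param species Species table.
#' @param within,cross Correlation levels.
#' @return Correlation matrix named by `display_name`.
#' @export
default_species_correlation <- function(species, within = 0.8, cross = 0.1) {
  grp <- ifelse(species$precursor == "Abeta",
                paste0("Abeta", species$end), species$precursor)
  n <- nrow(species)
  r <- matrix(cross, n, n)
  for (g in unique(grp)) r[grp == g, grp == g] <- within
  diag(r) <- 1
  dimnames(r) <- list(species$display_name, species$display_name)
  r
}

#' MSI simulation configuration
#'
#' Emulates a MALDI-MSI acquisition of CAA-rich tissue: annular vessels on
#' a 2-D grid, per-pixel centroid spectra with one peak per proteoform
#' species (plus unassigned matrix-background peaks), log-normal species
#' intensities with a configurable cross-species latent correlation inside
#' vessels, per-pixel multiplicative TIC gain, and (for the FDD preset) an
#' amyloid-beta sub-population confined to a planted fraction of each
#' vessel's area and scaled to a planted fraction of the total amyloid
#' signal.
#'
#' @param preset `"FDD"`, `"FBD"` or `"CAA"`; sets species table, expected
#'   abundances and reference species.
#' @param grid_size Grid rows, cols.
#' @param n_vessels Number of vessels.
#' @param abundances Named expected per-pixel intensities (defaults to the
#'   preset profile).
#' @param reference Reference species name.
#' @param abeta_signal_fraction_pct Planted percentage of total amyloid
#'   signal carried by amyloid-beta species (FDD preset; `NA` disables).
#' @param abeta_area_fraction_pct Planted percentage of vessel pixels
#'   positive for amyloid-beta.
#' @param outer_radius,inner_radius,min_gap Vessel geometry (pixels).
#' @param sigma_log Pixel-level log-normal intensity sd (log scale).
#' @param vessel_sdlog Vessel-to-vessel log-normal scale sd.
#' @param correlation Latent cross-species correlation matrix (default
#'   [default_species_correlation]).
#' @param tic_gain_sdlog Per-pixel multiplicative gain sd (log scale);
#'   removed by TIC normalization.
#' @param n_background_peaks Unassigned matrix peaks per pixel.
#' @param background_intensity Mean intensity of background peaks (in
#'   reference-species units).
#' @param mz_jitter_frac Optional per-peak m/z jitter (fraction of m/z,
#'   <= 5e-4); 0 for exact centroid positions.
#' @param pitch_um Grid pitch metadata.
#' @param seed Random seed.
#' @return List of class `msi_sim_config`.
#' @export
msi_sim_config <- function(preset = c("FDD", "FBD", "CAA"),
                           grid_size = c(260, 260), n_vessels = 75,
                           abundances = NULL, reference = NULL,
                           abeta_signal_fraction_pct = 4.6,
                           abeta_area_fraction_pct = 13.3,
                           outer_radius = c(4, 6), inner_radius = 1.5,
                           min_gap = 5, sigma_log = 0.5, vessel_sdlog = 0.3,
                           correlation = NULL, tic_gain_sdlog = 0.3,
                           n_background_peaks = 6,
                           background_intensity = 0.05,
                           mz_jitter_frac = 0, pitch_um = 10, seed = 1L) {
  preset <- match.arg(preset)
  species <- species_preset(preset)
  if (is.null(abundances)) abundances <- .PRESET_ABUNDANCE[[preset]]
  abundances <- abundances[species$display_name]
  if (anyNA(abundances)) stop("abundances must cover every preset species")
  if (is.null(reference)) reference <- .PRESET_REFERENCE[[preset]]
  if (is.null(correlation)) correlation <- default_species_correlation(species)
  stopifnot(isSymmetric(unname(correlation)),
            all(eigen(correlation, only.values = TRUE)$values > -1e-8),
            all(abundances >= 0), mz_jitter_frac <= 5e-4)
  mixed <- length(unique(species$precursor)) > 1 && "Abeta" %in% species$precursor
  structure(list(preset = preset, grid_size = grid_size,
                 n_vessels = n_vessels, species = species,
                 abundances = abundances, reference = reference,
                 abeta_signal_fraction_pct =
                   if (mixed) abeta_signal_fraction_pct else NA_real_,
                 abeta_area_fraction_pct =
                   if (mixed) abeta_area_fraction_pct else NA_real_,
                 outer_radius = outer_radius, inner_radius = inner_radius,
                 min_gap = min_gap, sigma_log = sigma_log,
                 vessel_sdlog = vessel_sdlog, correlation = correlation,
                 tic_gain_sdlog = tic_gain_sdlog,
                 n_background_peaks = n_background_peaks,
                 background_intensity = background_intensity,
                 mz_jitter_frac = mz_jitter_frac, pitch_um = pitch_um,
                 seed = as.integer(seed)),
            class = "msi_sim_config")
}

# analytic ground truth derived from an msi_sim_config (no data involved)
.msi_truth_from_config <- function(config, ab) {
  species <- config$species
  is_ab <- species$precursor == "Abeta" &
    !is.na(config$abeta_signal_fraction_pct)
  area <- if (any(is_ab)) config$abeta_area_fraction_pct / 100 else 1
  # expected per-ROI integrated intensity per species (per vessel pixel)
  expected <- ifelse(is_ab, ab * area, ab)
  names(expected) <- species$display_name
  ref <- expected[[config$reference]]
  cats <- c("full_length", "c_truncated", "n_truncated", "pyroglu")
  cat_frac <- function(sel) {
    w <- expected[sel]
    sp <- species[sel, ]
    member <- vapply(seq_len(nrow(sp)), function(i)
      cats %in% classify_subgroups(as_proteoform(sp[i, ])),
      logical(length(cats)))
    setNames(100 * as.vector(member %*% w) / sum(w), cats)
  }
  subgroups <- list(all = cat_frac(rep(TRUE, nrow(species))))
  for (fam in unique(species$precursor))
    subgroups[[fam]] <- cat_frac(species$precursor == fam)
  list(relative_abundance = setNames(expected / ref, species$display_name),
       expected_intensity = expected,
       subgroup_pct = subgroups,
       correlation = config$correlation,
       abeta_signal_fraction_pct = config$abeta_signal_fraction_pct,
       abeta_area_fraction_pct = config$abeta_area_fraction_pct)
}

#' Generate a synthetic MALDI-MSI dataset
#'
#' @param config An [msi_sim_config].
#' @return List: `dataset` (an [msi_dataset]; 0-based grid coordinates,
#'   x right / y down), and `truth` with the planted vessel `labels`
#'   matrix, `abeta_positive` matrix, analytic `relative_abundance`,
#'   `subgroup_pct`, `correlation`, planted amyloid-beta signal/area
#'   fractions, the species table and the config.
#' @export
generate_msi_dataset <- function(config = msi_sim_config()) {
  stopifnot(inherits(config, "msi_sim_config"))
  set.seed(config$seed)
  size <- config$grid_size
  species <- config$species
  n_sp <- nrow(species)
  ab <- config$abundances
  is_ab <- species$precursor == "Abeta" &
    !is.na(config$abeta_signal_fraction_pct)
  if (any(is_ab)) {
    # rescale the amyloid-beta profile so the planted signal fraction holds:
    # sum(ab_beta) * area_frac / (sum(ab_beta) * area_frac + sum(others)) = f
    f <- config$abeta_signal_fraction_pct / 100
    area <- config$abeta_area_fraction_pct / 100
    need <- f / (1 - f) * sum(ab[!is_ab])
    ab[is_ab] <- ab[is_ab] * need / (sum(ab[is_ab]) * area)
    config$abundances <- ab
  }
  margin <- config$outer_radius[2] + 2
  pl <- .place_vessels(size, config$n_vessels, config$outer_radius, margin,
                       config$min_gap)
  labels <- matrix(0L, size[1], size[2])
  abeta_pos <- matrix(FALSE, size[1], size[2])
  vessel_px <- list()
  for (v in seq_len(config$n_vessels)) {
    px <- .vessel_pixels(size, pl$centers[v, ], pl$outer[v],
                         config$inner_radius)
    labels[px$ring] <- v
    vessel_px[[v]] <- px$ring
    if (any(is_ab)) {
      k <- max(1L, round(config$abeta_area_fraction_pct / 100 * nrow(px$ring)))
      seed_px <- px$ring[sample.int(nrow(px$ring), 1), ]
      d <- sqrt((px$ring[, 1] - seed_px[1])^2 + (px$ring[, 2] - seed_px[2])^2)
      abeta_pos[px$ring[order(d)[seq_len(k)], , drop = FALSE]] <- TRUE
    }
  }
  mz_sp <- species$mz
  L <- chol(config$correlation)
  sig <- config$sigma_log
  # background (matrix) peak positions, common to the acquisition
  bg_mz <- sort(runif(config$n_background_peaks,
                      min(mz_sp) - 300, max(mz_sp) + 300))
  coords <- expand.grid(x = 0:(size[2] - 1), y = 0:(size[1] - 1))
  rows <- coords$y + 1L; cols <- coords$x + 1L
  vlab <- labels[cbind(rows, cols)]
  apos <- abeta_pos[cbind(rows, cols)]
  npx <- nrow(coords)
  vscale <- exp(rnorm(config$n_vessels, -config$vessel_sdlog^2 / 2,
                      config$vessel_sdlog))
  gain <- exp(rnorm(npx, 0, config$tic_gain_sdlog))
  # species intensity matrix for vessel pixels only
  inten <- matrix(0, npx, n_sp)
  in_v <- which(vlab > 0)
  if (length(in_v)) {
    Z <- matrix(rnorm(length(in_v) * n_sp), length(in_v)) %*% L
    base <- exp(sig * Z - sig^2 / 2)
    inten[in_v, ] <- sweep(base, 2, ab, "*") * vscale[vlab[in_v]]
    if (any(is_ab)) inten[!apos, is_ab] <- 0
  }
  bg_int <- matrix(config$background_intensity *
                     exp(rnorm(npx * config$n_background_peaks, -sig^2 / 2, sig)),
                   npx)
  jit <- config$mz_jitter_frac
  spectra <- lapply(seq_len(npx), function(p) {
    keep <- inten[p, ] > 0
    mz <- c(mz_sp[keep], bg_mz)
    it <- c(inten[p, keep], bg_int[p, ])
    if (jit > 0) mz <- mz * (1 + runif(length(mz), -jit, jit))
    o <- order(mz)
    list(mz = mz[o], intensity = it[o] * gain[p])
  })
  dataset <- suppressWarnings(
    msi_dataset(coords, spectra, pitch_um = config$pitch_um))
  truth <- .msi_truth_from_config(config, ab)
  truth$labels <- labels
  truth$abeta_positive <- abeta_pos
  truth$planted_area_fraction_pct <-
    if (any(is_ab)) 100 * sum(abeta_pos) / sum(labels > 0) else NA_real_
  truth$species <- species
  truth$config <- config
  list(dataset = dataset, truth = truth)
}
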