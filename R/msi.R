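# MALDI-MSI processing: per-pixel centroid spectra on a 2-D grid,
# TIC normalization, average spectra, peak detection and binning,
# area-under-curve integration, bisecting k-means spatial segmentation.

#' Construct an MSI dataset
#'
#' Per-pixel centroid mass spectra on a regular 2-D grid. Each pixel holds
#' paired m/z and intensity vectors; m/z must be ascending (sorted on
#' construction with a warning otherwise).
#'
#' @param coords Integer matrix or data frame with columns `x`, `y`
#'   (0-based or 1-based grid indices; stored as given). Coordinates must
#'   be unique.
#' @param spectra List (one element per pixel) of lists with numeric `mz`
#'   and `intensity`.
#' @param pitch_um Grid pitch metadata in micrometers (10 for conformant
#'   acquisitions).
#' @return Object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, spectra, pitch_um = 10) {
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords)))
    stop("coords must have columns x and y")
  if (nrow(coords) == 0) stop("empty pixel list")
  if (nrow(coords) != length(spectra))
    stop("coords and spectra lengths differ")
  if (anyDuplicated(coords[, c("x", "y")]))
    stop("duplicate pixel coordinates")
  resorted <- FALSE
  spectra <- lapply(spectra, function(s) {
    mz <- as.numeric(s$mz); it <- as.numeric(s$intensity)
    if (length(mz) != length(it)) stop("mz/intensity length mismatch")
    if (any(it < 0)) stop("negative intensities")
    if (is.unsorted(mz, strictly = TRUE) && length(mz) > 1) {
      o <- order(mz)
      mz <- mz[o]; it <- it[o]
      resorted <<- TRUE
    }
    list(mz = mz, intensity = it)
  })
  if (resorted) warning("unsorted m/z axes were sorted on construction")
  structure(list(coords = coords[, c("x", "y")], spectra = spectra,
                 pitch_um = pitch_um),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat("msi_dataset: ", nrow(x$coords), " pixels, grid ",
      diff(range(x$coords$x)) + 1, " x ", diff(range(x$coords$y)) + 1,
      ", pitch ", x$pitch_um, " um\n", sep = "")
  invisible(x)
}

#' Number of pixels in an MSI dataset
#' @param dataset An [msi_dataset].
#' @return Integer pixel count.
#' @export
n_pixels <- function(dataset) nrow(dataset$coords)

#' Total ion current per pixel
#' @param dataset An [msi_dataset].
#' @return Numeric vector of per-pixel summed intensities.
#' @export
pixel_tic <- function(dataset)
  vapply(dataset$spectra, function(s) sum(s$intensity), numeric(1))

#' Total-ion-current normalization
#'
#' Rescales every pixel's spectrum so its summed intensity equals a common
#' target (by default the dataset-mean pre-normalization TIC, preserving
#' the global intensity scale). Within-pixel peak ratios are unchanged.
#' Pixels with zero TIC are dropped with a warning.
#'
#' @param dataset An [msi_dataset].
#' @param target `"mean"` (dataset-mean TIC) or a positive number.
#' @return Normalized [msi_dataset] with attribute `tic_target`.
#' @export
tic_normalize <- function(dataset, target = "mean") {
  stopifnot(inherits(dataset, "msi_dataset"))
  tic <- pixel_tic(dataset)
  keep <- tic > 0
  if (!any(keep)) stop("all pixels have zero total ion current")
  if (!all(keep)) {
    warning(sum(!keep), " zero-TIC pixel(s) dropped")
    dataset$coords <- dataset$coords[keep, , drop = FALSE]
    dataset$spectra <- dataset$spectra[keep]
    tic <- tic[keep]
  }
  tgt <- if (identical(target, "mean")) mean(tic) else {
    stopifnot(is.numeric(target), target > 0); target
  }
  dataset$spectra <- Map(function(s, f) {
    s$intensity <- s$intensity * f; s
  }, dataset$spectra, tgt / tic)
  attr(dataset, "tic_target") <- tgt
  dataset
}

#' Average spectrum of a pixel set on a regular m/z grid
#'
#' Centroid intensities are accumulated into equal-width m/z cells and
#' divided by the number of pixels, giving the mean spectrum used for peak
#' detection and bin definition.
#'
#' @param dataset An [msi_dataset].
#' @param pixels Optional integer indices of the pixels to average (default
#'   all).
#' @param bin_width Grid cell width in Da.
#' @return List with `mz` (cell centers) and `intensity`.
#' @export
average_spectrum <- function(dataset, pixels = NULL, bin_width = 0.5) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (is.null(pixels)) pixels <- seq_len(n_pixels(dataset))
  specs <- dataset$spectra[pixels]
  all_mz <- unlist(lapply(specs, `[[`, "mz"))
  if (length(all_mz) == 0) stop("no peaks in selected pixels")
  lo <- floor(min(all_mz)) - 2 * bin_width
  hi <- ceiling(max(all_mz)) + 2 * bin_width
  edges <- seq(lo, hi, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  acc <- numeric(length(centers))
  for (s in specs) {
    cell <- findInterval(s$mz, edges, rightmost.closed = TRUE)
    ok <- cell >= 1 & cell <= length(centers)
    if (any(ok)) {
      t <- tapply(s$intensity[ok], cell[ok], sum)
      acc[as.integer(names(t))] <- acc[as.integer(names(t))] + t
    }
  }
  list(mz = centers, intensity = acc / length(specs))
}

#' Detect peaks and integration bins on an average spectrum
#'
#' Local maxima above an SNR threshold become peaks; the noise level is
#' 1.4826 x the median absolute first difference of the spectrum divided by
#' sqrt(2) (a robust estimate insensitive to the peaks themselves). A
#' candidate must also rise above its flanking local minima by at least the
#' threshold (a prominence criterion), which rejects noise ripples riding
#' on the slopes of genuine peaks. Each peak's bin edges sit at the nearest
#' flanking local minima, truncated at the half-distance to the
#' neighbouring peak and capped at a maximum half-width proportional to
#' the center m/z; bins never overlap.
#'
#' @param spectrum List with `mz` and `intensity` (regular grid, e.g. from
#'   [average_spectrum]).
#' @param snr Signal-to-noise threshold.
#' @param max_halfwidth_frac Cap on the bin half-width as a fraction of the
#'   center m/z (0.0035 approximates linear-TOF peak widths near 4 kDa).
#' @return Data frame of class `peak_bins`: `center`, `left`, `right`,
#'   `height`; attribute `noise_sd`.
#' @export
detect_peaks <- function(spectrum, snr = 3, max_halfwidth_frac = 0.0035) {
  mz <- spectrum$mz; y <- spectrum$intensity
  if (length(y) == 0) stop("empty spectrum")
  empty <- data.frame(center = numeric(0), left = numeric(0),
                      right = numeric(0), height = numeric(0))
  class(empty) <- c("peak_bins", "data.frame")
  if (length(y) < 3 || diff(range(y)) == 0) return(empty)
  noise <- 1.4826 * median(abs(diff(y))) / sqrt(2)
  thr <- snr * noise
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE) & y > thr
  peaks <- which(is_max)
  if (length(peaks) == 0) {
    attr(empty, "noise_sd") <- noise
    return(empty)
  }
  # nearest flanking local minima (plateau-tolerant)
  is_min <- c(TRUE, y[2:(n - 1)] <= y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n], TRUE)
  mins <- which(is_min)
  flank <- vapply(peaks, function(p) {
    li <- mins[mins < p]; ri <- mins[mins > p]
    c(if (length(li)) max(li) else 1L, if (length(ri)) min(ri) else n)
  }, integer(2))
  prominence <- y[peaks] - pmax(y[flank[1, ]], y[flank[2, ]])
  keep <- prominence > thr
  peaks <- peaks[keep]
  if (length(peaks) == 0) {
    attr(empty, "noise_sd") <- noise
    return(empty)
  }
  left <- right <- numeric(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    li <- mins[mins < p]
    ri <- mins[mins > p]
    l <- if (length(li)) max(li) else 1L
    r <- if (length(ri)) min(ri) else n
    # truncate at half-distance to neighbouring peaks
    if (i > 1) l <- max(l, ceiling((peaks[i - 1] + p) / 2))
    if (i < length(peaks)) r <- min(r, floor((p + peaks[i + 1]) / 2))
    cap <- max_halfwidth_frac * mz[p]
    left[i] <- max(mz[l], mz[p] - cap)
    right[i] <- min(mz[r], mz[p] + cap)
  }
  # enforce strict non-overlap after capping
  if (length(peaks) > 1) {
    for (i in 2:length(peaks)) {
      if (left[i] < right[i - 1]) {
        mid <- (mz[peaks[i - 1]] + mz[peaks[i]]) / 2
        right[i - 1] <- min(right[i - 1], mid)
        left[i] <- max(left[i], mid)
      }
    }
  }
  out <- data.frame(center = mz[peaks], left = left, right = right,
                    height = y[peaks])
  class(out) <- c("peak_bins", "data.frame")
  attr(out, "noise_sd") <- noise
  out
}

#' Annotate peak bins with proteoform species
#'
#' Matches bins to the species whose `[M+H]+` m/z falls inside them (or
#' within `tol` of their center). Assignment is one-to-one by increasing
#' m/z distance, so a species annotates only its nearest candidate bin and
#' a chance unassigned peak close to a species mass cannot duplicate the
#' annotation. Unmatched bins keep `NA`.
#'
#' @param bins A `peak_bins` data frame.
#' @param species Species table with `display_name` and `mz` columns (see
#'   [species_preset]).
#' @param tol Center-match tolerance in Da.
#' @return `bins` with an added `species` column.
#' @export
annotate_bins <- function(bins, species, tol = 1.0) {
  ann <- rep(NA_character_, nrow(bins))
  cand <- do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
    d <- abs(species$mz - bins$center[i])
    ok <- (species$mz >= bins$left[i] & species$mz <= bins$right[i]) | d <= tol
    if (!any(ok)) return(NULL)
    data.frame(bin = i, sp = which(ok), dist = d[ok])
  }))
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist), , drop = FALSE]
    used_sp <- logical(nrow(species))
    for (k in seq_len(nrow(cand))) {
      b <- cand$bin[k]; s <- cand$sp[k]
      if (is.na(ann[b]) && !used_sp[s]) {
        ann[b] <- species$display_name[s]
        used_sp[s] <- TRUE
      }
    }
  }
  bins$species <- ann
  bins
}

.check_bins <- function(bins) {
  stopifnot(all(bins$left < bins$center), all(bins$center < bins$right))
  if (nrow(bins) > 1) {
    o <- order(bins$left)
    if (any(bins$left[o][-1] < bins$right[o][-nrow(bins)]))
      stop("overlapping bins")
  }
  invisible(bins)
}

#' Integrate peak bins per pixel
#'
#' Area-under-curve integration of each pixel's spectrum within each bin:
#' the sum of centroid intensities with m/z in `[left, right]`, or the
#' trapezoidal integral for profile-mode spectra.
#'
#' @param dataset An [msi_dataset].
#' @param bins Non-overlapping `peak_bins`.
#' @param mode `"centroid"` (sum) or `"profile"` (trapezoid).
#' @return Numeric matrix, pixels x bins; column names from bin species
#'   annotation when present, else bin centers.
#' @export
integrate_bins <- function(dataset, bins, mode = c("centroid", "profile")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  mode <- match.arg(mode)
  .check_bins(bins)
  out <- t(vapply(dataset$spectra, function(s)
    integrate_spectrum(s, bins, mode = mode), numeric(nrow(bins))))
  if (nrow(bins) == 1) out <- matrix(out, ncol = 1)
  mzlab <- sprintf("mz%.2f", bins$center)
  colnames(out) <- if (is.null(bins$species)) mzlab
  else ifelse(is.na(bins$species), mzlab, bins$species)
  out
}

#' Integrate one spectrum over peak bins
#'
#' @param spectrum List with `mz`, `intensity`.
#' @param bins Non-overlapping `peak_bins`.
#' @param mode `"centroid"` or `"profile"`.
#' @return Numeric vector, one value per bin.
#' @export
integrate_spectrum <- function(spectrum, bins, mode = c("centroid", "profile")) {
  mode <- match.arg(mode)
  mz <- spectrum$mz; y <- spectrum$intensity
  vapply(seq_len(nrow(bins)), function(i) {
    sel <- mz >= bins$left[i] & mz <= bins$right[i]
    if (!any(sel)) return(0)
    if (mode == "centroid") sum(y[sel])
    else if (sum(sel) < 2) 0
    else sum(diff(mz[sel]) * (y[sel][-1] + y[sel][-sum(sel)]) / 2)
  }, numeric(1))
}

#' Reconstruct ion images from per-pixel bin intensities
#'
#' @param dataset An [msi_dataset].
#' @param intensities Matrix from [integrate_bins] (pixels x bins).
#' @return List of matrices (one per bin) over the grid bounding box;
#'   missing pixels are `NA`.
#' @export
ion_images <- function(dataset, intensities) {
  x <- dataset$coords$x - min(dataset$coords$x) + 1L
  y <- dataset$coords$y - min(dataset$coords$y) + 1L
  lapply(seq_len(ncol(intensities)), function(j) {
    img <- matrix(NA_real_, max(y), max(x))
    img[cbind(y, x)] <- intensities[, j]
    img
  }) |> setNames(colnames(intensities))
}

#' MSI quantification configuration
#'
#' @param n_leaf_clusters Leaves of the bisecting k-means segmentation.
#' @param snr Peak-detection signal-to-noise threshold.
#' @param bin_halfwidth_frac Bin half-width cap (fraction of center m/z).
#' @param coverage_k Coverage threshold rule: a pixel is species-positive
#'   when its summed species signal exceeds the off-vessel background mean
#'   plus `coverage_k` background standard deviations.
#' @param cor_method `"pearson"` or `"spearman"` for SPSC.
#' @param min_roi_pixels Minimum vessel ROI size (connected component of
#'   the vessel cluster).
#' @param nstart Random restarts per 2-means bisection.
#' @param seed Seed for the segmentation restarts.
#' @return List of class `msi_config`.
#' @export
msi_config <- function(n_leaf_clusters = 2, snr = 3,
                       bin_halfwidth_frac = 0.0035, coverage_k = 2,
                       cor_method = c("pearson", "spearman"),
                       min_roi_pixels = 5, nstart = 10, seed = 1L) {
  stopifnot(n_leaf_clusters >= 1, snr > 0, bin_halfwidth_frac > 0,
            coverage_k >= 0, min_roi_pixels >= 1, nstart >= 1)
  structure(list(n_leaf_clusters = n_leaf_clusters, snr = snr,
                 bin_halfwidth_frac = bin_halfwidth_frac,
                 coverage_k = coverage_k,
                 cor_method = match.arg(cor_method),
                 min_roi_pixels = min_roi_pixels, nstart = nstart,
                 seed = as.integer(seed)),
            class = "msi_config")
}

#' Bisecting k-means clustering
#'
#' Starts from one cluster and repeatedly bisects the cluster with the
#' largest within-cluster sum of squares using 2-means (multiple random
#' restarts) until the requested number of leaves; deterministic under a
#' fixed seed.
#'
#' @param x Numeric feature matrix (observations x features).
#' @param k Number of leaf clusters.
#' @param nstart Restarts per bisection.
#' @param seed Random seed.
#' @return List with `cluster` (integer labels 1..k) and `history` (data
#'   frame of splits: `step`, `parent`, `child`, `wss_parent`).
#' @export
bisect_kmeans <- function(x, k, nstart = 10, seed = 1L) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("more clusters requested than observations")
  set.seed(seed)
  labels <- rep(1L, nrow(x))
  history <- data.frame(step = integer(0), parent = integer(0),
                        child = integer(0), wss_parent = numeric(0))
  wss <- function(idx) {
    if (length(idx) < 2) return(0)
    xm <- x[idx, , drop = FALSE]
    sum(sweep(xm, 2, colMeans(xm))^2)
  }
  step <- 0L
  while (max(labels) < k) {
    step <- step + 1L
    sizes <- tabulate(labels)
    w <- vapply(seq_len(max(labels)), function(l) wss(which(labels == l)),
                numeric(1))
    splittable <- which(sizes >= 2)
    if (length(splittable) == 0) stop("no cluster left to bisect")
    parent <- splittable[which.max(w[splittable])]
    idx <- which(labels == parent)
    ux <- unique(x[idx, , drop = FALSE])
    if (nrow(ux) < 2) stop("cluster ", parent, " is degenerate (identical rows)")
    km <- kmeans(x[idx, , drop = FALSE], centers = 2, nstart = nstart)
    child <- max(labels) + 1L
    labels[idx[km$cluster == 2]] <- child
    history <- rbind(history, data.frame(step = step, parent = parent,
                                         child = child, wss_parent = w[parent]))
  }
  list(cluster = labels, history = history)
}

#' Spatial segmentation of an MSI dataset by bisecting k-means
#'
#' Pixels are represented by their bin-integrated intensity vectors and
#' clustered by [bisect_kmeans]. Vessel clusters are designated as the
#' leaves with the highest mean summed signal over amyloid-annotated bins
#' (all bins when none is annotated).
#'
#' @param dataset An [msi_dataset] (normally TIC-normalized).
#' @param bins `peak_bins`, optionally annotated via [annotate_bins].
#' @param config An [msi_config].
#' @param n_vessel_clusters How many leaves to designate as vessel.
#' @return Object of class `msi_segmentation`: `cluster` (per-pixel
#'   labels), `history`, `vessel_clusters`, `vessel_mask` (logical per
#'   pixel), `intensities` (pixels x bins matrix used as features).
#' @export
segment_msi <- function(dataset, bins, config = msi_config(),
                        n_vessel_clusters = 1) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (n_pixels(dataset) < 2) stop("need at least 2 pixels")
  if (nrow(bins) < 1) stop("need at least one bin")
  feats <- integrate_bins(dataset, bins)
  bk <- bisect_kmeans(feats, k = config$n_leaf_clusters,
                      nstart = config$nstart, seed = config$seed)
  amyloid_cols <- if (!is.null(bins$species)) which(!is.na(bins$species))
  else seq_len(ncol(feats))
  if (length(amyloid_cols) == 0) amyloid_cols <- seq_len(ncol(feats))
  score <- vapply(seq_len(max(bk$cluster)), function(l)
    mean(rowSums(feats[bk$cluster == l, amyloid_cols, drop = FALSE])),
    numeric(1))
  vessel <- order(score, decreasing = TRUE)[seq_len(min(n_vessel_clusters,
                                                        length(score)))]
  structure(list(cluster = bk$cluster, history = bk$history,
                 vessel_clusters = vessel,
                 vessel_mask = bk$cluster %in% vessel,
                 intensities = feats),
            class = "msi_segmentation")
}

#' Vessel ROIs from an MSI segmentation
#'
#' Connected components (8-connectivity on the pixel grid) of the vessel
#' cluster pixels, keeping components with at least `min_pixels` pixels.
#'
#' @param dataset The [msi_dataset] that was segmented.
#' @param segmentation An `msi_segmentation`.
#' @param min_pixels Minimum component size.
#' @return Integer vector: per-pixel ROI id (0 = not in a vessel ROI).
#' @export
msi_vessel_rois <- function(dataset, segmentation, min_pixels = 5) {
  x <- dataset$coords$x - min(dataset$coords$x) + 1L
  y <- dataset$coords$y - min(dataset$coords$y) + 1L
  grid <- matrix(FALSE, max(y), max(x))
  grid[cbind(y, x)] <- segmentation$vessel_mask
  lab <- label_components(grid, connectivity = 8)
  roi <- lab[cbind(y, x)]
  sizes <- tabulate(roi[roi > 0])
  drop <- which(sizes < min_pixels)
  roi[roi %in% drop] <- 0L
  # renumber kept ROIs consecutively
  kept <- sort(unique(roi[roi > 0]))
  map <- integer(max(c(kept, 0L)))
  map[kept] <- seq_along(kept)
  ifelse(roi > 0, map[pmax(roi, 1L)], 0L)
}
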