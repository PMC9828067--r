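# Quantification statistics on integrated MSI intensities: relative
# abundance against a full-length reference, truncation subgroup fractions,
# fractional signal/area contribution, single-pixel signal correlation.

#' Per-ROI integrated species intensities
#'
#' Sums per-pixel bin intensities within each vessel ROI.
#'
#' @param intensities Pixels x species matrix (from [integrate_bins]).
#' @param roi_ids Per-pixel ROI id (0 = outside ROIs), e.g. from
#'   [msi_vessel_rois].
#' @return Matrix, ROIs x species.
#' @export
roi_intensities <- function(intensities, roi_ids) {
  stopifnot(nrow(intensities) == length(roi_ids))
  ids <- sort(unique(roi_ids[roi_ids > 0]))
  out <- t(vapply(ids, function(i)
    colSums(intensities[roi_ids == i, , drop = FALSE]),
    numeric(ncol(intensities))))
  if (length(ids) == 1) out <- matrix(out, nrow = 1,
                                      dimnames = list(NULL, colnames(intensities)))
  rownames(out) <- paste0("roi", ids)
  out
}

#' Relative quantification against a reference species
#'
#' Expresses every species' integrated intensity relative to a full-length
#' reference peptide within each vessel ROI (the reference maps to 1 in
#' every ROI). ROIs in which the reference is absent or zero are dropped
#' with a warning.
#'
#' @param roi_mat ROIs x species matrix (from [roi_intensities]).
#' @param reference Reference species column name.
#' @return Object of class `quant_table`: data frame with `roi`, `species`,
#'   `intensity`, `relative`.
#' @export
relative_quant <- function(roi_mat, reference) {
  if (!reference %in% colnames(roi_mat))
    stop("reference species ", reference, " not in intensity table")
  ref <- roi_mat[, reference]
  keep <- is.finite(ref) & ref > 0
  if (!any(keep)) stop("reference species has no signal in any ROI")
  if (!all(keep))
    warning(sum(!keep), " ROI(s) without reference signal dropped")
  roi_mat <- roi_mat[keep, , drop = FALSE]
  ref <- ref[keep]
  out <- data.frame(
    roi = rep(rownames(roi_mat), times = ncol(roi_mat)),
    species = rep(colnames(roi_mat), each = nrow(roi_mat)),
    intensity = as.vector(roi_mat),
    relative = as.vector(roi_mat / ref))
  attr(out, "reference") <- reference
  class(out) <- c("quant_table", "data.frame")
  out
}

#' Summarize a quant table across ROIs
#'
#' Mean and standard deviation of the relative values per species, across
#' vessels.
#'
#' @param quant A [relative_quant] table.
#' @return Data frame: `species`, `mean_relative`, `sd_relative`, `n_roi`.
#' @export
summarize_quant <- function(quant) {
  sp <- unique(quant$species)
  data.frame(
    species = sp,
    mean_relative = vapply(sp, function(s)
      mean(quant$relative[quant$species == s]), numeric(1)),
    sd_relative = vapply(sp, function(s)
      sd(quant$relative[quant$species == s]), numeric(1)),
    n_roi = vapply(sp, function(s)
      sum(quant$species == s), numeric(1)),
    row.names = NULL)
}

#' Truncation/modification subgroup fractions
#'
#' For each subgroup (full-length, C-terminally truncated, N-terminally
#' truncated, pyroglutamate-modified), computes 100 x (summed intensity of
#' species in the subgroup) / (summed intensity of all considered species)
#' per ROI, then averages across ROIs. Subgroups are not mutually
#' exclusive, so the percentages need not sum to 100.
#'
#' @param roi_mat ROIs x species matrix.
#' @param species Species table covering the columns of `roi_mat`.
#' @param family Restrict to one precursor (`"ABri"`, `"ADan"`, `"Abeta"`)
#'   or `"all"`.
#' @param pyroglu_counts_n_truncated Passed to [classify_subgroups].
#' @return Data frame `category`, `mean_pct`, `sd_pct`; attribute
#'   `per_roi` holds the ROIs x categories percentage matrix.
#' @export
subgroup_fractions <- function(roi_mat, species, family = "all",
                               pyroglu_counts_n_truncated = TRUE) {
  if (nrow(roi_mat) == 0 || ncol(roi_mat) == 0) stop("empty intensity table")
  species <- species[match(colnames(roi_mat), species$display_name), ]
  if (anyNA(species$display_name))
    stop("species table does not cover all intensity columns")
  if (family != "all") {
    sel <- species$precursor == family
    roi_mat <- roi_mat[, sel, drop = FALSE]
    species <- species[sel, , drop = FALSE]
    if (ncol(roi_mat) == 0) stop("no species of family ", family)
  }
  cats <- c("full_length", "c_truncated", "n_truncated", "pyroglu")
  membership <- vapply(seq_len(nrow(species)), function(i)
    cats %in% classify_subgroups(as_proteoform(species[i, ]),
                                 pyroglu_counts_n_truncated),
    logical(length(cats)))
  total <- rowSums(roi_mat)
  per_roi <- vapply(seq_along(cats), function(ci)
    100 * rowSums(roi_mat[, membership[ci, ], drop = FALSE]) / total,
    numeric(nrow(roi_mat)))
  if (nrow(roi_mat) == 1) per_roi <- matrix(per_roi, nrow = 1)
  colnames(per_roi) <- cats
  out <- data.frame(category = cats,
                    mean_pct = colMeans(per_roi),
                    sd_pct = apply(per_roi, 2, sd),
                    row.names = NULL)
  attr(out, "per_roi") <- per_roi
  out
}

#' Fractional signal contribution and area coverage of a species subset
#'
#' Two statistics over the vessel area: the fraction of the total amyloid
#' signal carried by a species subset (e.g. all amyloid-beta peptides), and
#' the fraction of vessel pixels positive for that subset. A pixel is
#' positive when its summed subset intensity exceeds the off-vessel
#' background mean plus `coverage_k` standard deviations.
#'
#' @param intensities Pixels x species matrix.
#' @param vessel Logical per-pixel vessel membership.
#' @param target_species Column names of the subset (e.g. the amyloid-beta
#'   species).
#' @param coverage_k Threshold multiplier on the background SD.
#' @return List: `signal_fraction_pct`, `area_fraction_pct`,
#'   `coverage_threshold`.
#' @export
fractional_contribution_and_coverage <- function(intensities, vessel,
                                                 target_species,
                                                 coverage_k = 2) {
  stopifnot(nrow(intensities) == length(vessel))
  if (!any(vessel)) stop("empty vessel mask")
  miss <- setdiff(target_species, colnames(intensities))
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  tgt <- rowSums(intensities[, target_species, drop = FALSE])
  total <- rowSums(intensities)
  signal_fraction <- 100 * sum(tgt[vessel]) / sum(total[vessel])
  bg <- tgt[!vessel]
  thr <- if (length(bg)) mean(bg) + coverage_k * sd(bg) else 0
  if (!is.finite(thr)) thr <- 0
  area_fraction <- 100 * mean(tgt[vessel] > thr)
  list(signal_fraction_pct = signal_fraction,
       area_fraction_pct = area_fraction,
       coverage_threshold = thr)
}

#' Single-pixel signal correlation (SPSC) matrix
#'
#' Pairwise correlation of species ion intensities across the pixels of a
#' mask; the co-deposition / co-localization statistic. Computed by direct
#' covariance/variance algebra; species with zero variance within the mask
#' get `NA` rows and columns (undefined, not zero).
#'
#' @param x Pixels x species matrix, or a list of ion images (matrices).
#' @param mask Logical vector over pixels (matrix rows), or a logical
#'   matrix when `x` is a list of images. `NULL` uses all pixels.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal (class
#'   `spsc_matrix`).
#' @export
spsc_matrix <- function(x, mask = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.list(x) && !is.data.frame(x)) {
    imgs <- x
    if (is.null(mask)) mask <- !is.na(imgs[[1]])
    x <- vapply(imgs, function(im) im[mask], numeric(sum(mask)))
    mask <- NULL
  }
  x <- as.matrix(x)
  if (!is.null(mask)) x <- x[mask, , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 species")
  if (nrow(x) < 3) stop("need at least 3 masked pixels")
  if (method == "spearman") x <- apply(x, 2, rank)
  n <- nrow(x)
  ctr <- sweep(x, 2, colMeans(x))
  cov <- crossprod(ctr) / (n - 1)
  v <- diag(cov)
  degenerate <- v <= 0
  s <- sqrt(ifelse(degenerate, NA_real_, v))
  r <- cov / outer(s, s)
  diag(r)[!degenerate] <- 1
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  dimnames(r) <- list(colnames(x), colnames(x))
  class(r) <- c("spsc_matrix", class(r))
  r
}

#' Run the full MSI quantification pipeline
#'
#' TIC normalization, average-spectrum peak detection and species
#' annotation, bisecting k-means segmentation, vessel ROI extraction,
#' relative quantification against the reference species, subgroup
#' fractions per precursor family, and (when a species subset is named)
#' fractional signal contribution and area coverage.
#'
#' Segmentation, relative quantification and subgroup fractions operate on
#' TIC-normalized intensities. The composition fractions
#' ([fractional_contribution_and_coverage]) are computed on the raw
#' integrated intensities: per-pixel TIC rescaling reweights pixels
#' inversely to their total ion content, which systematically compresses
#' the apparent signal share of a species confined to a sub-region of the
#' vessel wall, whereas multiplicative acquisition gain is content-independent
#' and cancels in a ratio of sums.
#'
#' @param dataset An [msi_dataset] (raw).
#' @param species Species table (e.g. [species_preset]).
#' @param reference Reference species for relative quantification.
#' @param config An [msi_config].
#' @param contribution_species Optional character vector of species whose
#'   signal/area fractions are computed (e.g. all amyloid-beta species).
#' @return List: `dataset_normalized`, `bins`, `segmentation`, `roi_ids`,
#'   `roi_matrix`, `quant`, `quant_summary`, `subgroups` (list per family
#'   and `"all"`), `contribution` (or `NULL`), `vessel_mask`.
#' @export
run_msi_pipeline <- function(dataset, species, reference,
                             config = msi_config(),
                             contribution_species = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  ds <- tic_normalize(dataset)
  avg <- average_spectrum(ds)
  bins <- annotate_bins(detect_peaks(avg, snr = config$snr,
                                     max_halfwidth_frac = config$bin_halfwidth_frac),
                        species)
  found <- bins$species[!is.na(bins$species)]
  if (length(found) == 0) stop("no species peak detected")
  seg <- segment_msi(ds, bins, config)
  roi <- msi_vessel_rois(ds, seg, min_pixels = config$min_roi_pixels)
  ints <- seg$intensities[, found, drop = FALSE]
  rmat <- roi_intensities(ints, roi)
  quant <- relative_quant(rmat, reference)
  fams <- c("all", unique(species$precursor[species$display_name %in% found]))
  subgroups <- lapply(setNames(fams, fams), function(f)
    subgroup_fractions(rmat, species, family = f))
  contribution <- NULL
  if (!is.null(contribution_species)) {
    raw_ints <- integrate_bins(dataset, bins)[, found, drop = FALSE]
    contribution <- fractional_contribution_and_coverage(
      raw_ints, seg$vessel_mask,
      intersect(contribution_species, found),
      coverage_k = config$coverage_k)
  }
  list(dataset_normalized = ds, bins = bins, segmentation = seg,
       roi_ids = roi, roi_matrix = rmat, quant = quant,
       quant_summary = summarize_quant(quant), subgroups = subgroups,
       contribution = contribution, vessel_mask = seg$vessel_mask)
}
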