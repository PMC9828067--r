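# Independent brute-force oracles used to validate the implementations.

# Otsu: exhaustive search over all histogram cut points, between-class
# variance computed directly from the per-class pixel values.
oracle_otsu <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  vals <- centers[bin]
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_len(n_bins - 1)) {
    lo <- vals[bin <= i]; hi <- vals[bin > i]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(vals)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; best_i <- i }
  }
  edges[best_i + 1L]
}

# direct O(n^2 k^2) 2-D Gaussian convolution with mirror padding
oracle_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  K <- outer(k, k)
  refl <- function(i, n) {
    per <- 2L * n - 2L
    i <- (i - 1L) %% per
    ifelse(i < n, i + 1L, per - i + 1L)
  }
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    ri <- refl(i + (-r:r), nrow(x))
    for (j in seq_len(ncol(x))) {
      cj <- refl(j + (-r:r), ncol(x))
      out[i, j] <- sum(K * x[ri, cj])
    }
  }
  out
}

# exhaustive 2-means: every pair of distinct points as initial centers,
# Lloyd iterations to convergence, keep the lowest-SSE partition
oracle_two_means <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best_sse <- Inf; best <- NULL
  sse <- function(lab) {
    s <- 0
    for (l in unique(lab)) {
      xm <- x[lab == l, , drop = FALSE]
      s <- s + sum(sweep(xm, 2, colMeans(xm))^2)
    }
    s
  }
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    c1 <- x[a, ]; c2 <- x[b, ]
    if (all(c1 == c2)) next
    lab <- rep(1L, n)
    repeat {
      d1 <- rowSums(sweep(x, 2, c1)^2)
      d2 <- rowSums(sweep(x, 2, c2)^2)
      new_lab <- ifelse(d1 <= d2, 1L, 2L)
      if (length(unique(new_lab)) < 2 || identical(new_lab, lab)) {
        lab <- new_lab; break
      }
      lab <- new_lab
      c1 <- colMeans(x[lab == 1L, , drop = FALSE])
      c2 <- colMeans(x[lab == 2L, , drop = FALSE])
    }
    if (length(unique(lab)) == 2) {
      s <- sse(lab)
      if (s < best_sse) { best_sse <- s; best <- lab }
    }
  }
  best
}

# pairwise Pearson correlation via an explicit per-pair loop
oracle_cor <- function(x) {
  p <- ncol(x)
  r <- matrix(NA_real_, p, p)
  for (i in 1:p) for (j in 1:p) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    r[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  r
}

# small manual MSI dataset builder
make_msi <- function(mz_list, int_list, xs = NULL, ys = NULL) {
  n <- length(mz_list)
  if (is.null(xs)) { xs <- (seq_len(n) - 1L); ys <- rep(0L, n) }
  msi_dataset(data.frame(x = xs, y = ys),
              Map(function(m, i) list(mz = m, intensity = i),
                  mz_list, int_list))
}
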