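#' Detection parameters
#'
#' Free parameters of the spot-detection pipeline.
#'
#' @param smoothing_sigma Gaussian pre-filter width in voxels; a single value
#'   or a named `c(x, y, z)` vector for anisotropic smoothing. Defaults are
#'   isotropic in voxel units; no automatic anisotropy correction is applied.
#' @param noise_k Multiplier on the robust noise scale; the peak-acceptance
#'   floor is `median + noise_k * scale` of the masked, smoothed background.
#' @param min_separation Minimum center-to-center spacing of accepted peaks,
#'   voxels per axis (Chebyshev); when two peaks are closer, the brighter one
#'   is kept.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(smoothing_sigma = 1, noise_k = 5,
                             min_separation = 3) {
  if (length(smoothing_sigma) == 1L) {
    smoothing_sigma <- c(x = smoothing_sigma, y = smoothing_sigma,
                         z = smoothing_sigma)
  }
  if (is.null(names(smoothing_sigma))) {
    names(smoothing_sigma) <- c("x", "y", "z")
  }
  smoothing_sigma <- smoothing_sigma[c("x", "y", "z")]
  stopifnot(all(smoothing_sigma >= 0), noise_k > 0, min_separation >= 1)
  structure(list(smoothing_sigma = smoothing_sigma, noise_k = noise_k,
                 min_separation = min_separation),
            class = "detection_params")
}

#' Isodata threshold of a 3-D volume
#'
#' Iterative intensity threshold: starting from the global mean, `T` is
#' replaced by the midpoint of the mean intensity below `T` and the mean
#' intensity at or above `T`, until the change falls below 0.5 intensity
#' levels. The result is the isodata fixed point
#' `T = (mean(v < T) + mean(v >= T)) / 2`.
#'
#' @param volume Numeric array (or vector) of intensities with at least two
#'   distinct values.
#' @return The threshold, a scalar.
#' @export
isodata_threshold_3d <- function(volume) {
  v <- as.numeric(volume)
  v <- v[is.finite(v)]
  if (length(v) == 0L || diff(range(v)) == 0) {
    sf_stop("sf_constant_volume",
            "volume has a single intensity value; no threshold exists")
  }
  t_cur <- mean(v)
  for (i in seq_len(500L)) {
    lo <- v[v < t_cur]
    hi <- v[v >= t_cur]
    m_lo <- if (length(lo)) mean(lo) else min(v)
    m_hi <- if (length(hi)) mean(hi) else max(v)
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t_cur) < 0.5) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Robust background statistics of masked voxels
#'
#' @param volume 3-D intensity array.
#' @param mask Logical array of the same shape selecting background/cell
#'   voxels; `NULL` means all voxels.
#' @return Named numeric `c(median, scale)` where `scale` is
#'   `1.4826 * MAD`, the robust normal-consistent spread estimate.
#' @export
estimate_noise_scale <- function(volume, mask = NULL) {
  x <- if (is.null(mask)) as.numeric(volume) else as.numeric(volume[mask])
  if (length(x) < 100L) {
    sf_stop("sf_too_few_voxels", sprintf(
      "need >= 100 masked voxels to estimate noise, got %d", length(x)))
  }
  c(median = stats::median(x), scale = stats::mad(x))
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve along one axis of a 3-D array with replicate padding;
# stats::filter runs each column in C so this stays fast in pure R
smooth_axis <- function(a, axis, kern) {
  if (length(kern) == 1L) return(a)
  d <- dim(a)
  r <- (length(kern) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- matrix(b, nrow = db[1])
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(mp, kern, sides = 2)
  f <- f[(r + 1L):(r + db[1]), , drop = FALSE]
  aperm(array(as.numeric(f), db), order(perm))
}

#' Separable 3-D Gaussian smoothing
#'
#' @param volume 3-D array indexed `(z, y, x)`.
#' @param sigma Named `c(x, y, z)` standard deviations in voxels; 0 disables
#'   smoothing along that axis.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth_3d <- function(volume, sigma) {
  if (length(sigma) == 1L) sigma <- c(x = sigma, y = sigma, z = sigma)
  v <- smooth_axis(volume, 1L, gaussian_kernel_1d(sigma[["z"]]))
  v <- smooth_axis(v, 2L, gaussian_kernel_1d(sigma[["y"]]))
  smooth_axis(v, 3L, gaussian_kernel_1d(sigma[["x"]]))
}

# shift a 3-D array by (dz, dy, dx), padding with `fill`
shift_3d <- function(a, dz, dy, dx, fill = -Inf) {
  d <- dim(a)
  out <- array(fill, d)
  src_z <- max(1L, 1L - dz):min(d[1], d[1] - dz)
  src_y <- max(1L, 1L - dy):min(d[2], d[2] - dy)
  src_x <- max(1L, 1L - dx):min(d[3], d[3] - dx)
  out[src_z + dz, src_y + dy, src_x + dx] <- a[src_z, src_y, src_x]
  out
}

# strict 26-neighborhood local maxima with deterministic plateau
# tie-breaking: among equal neighbors the voxel earliest in (z, y, x)
# lexicographic order wins
local_maxima_3d <- function(a) {
  ok <- array(TRUE, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0L && dy == 0L && dx == 0L) next
    nb <- shift_3d(a, dz, dy, dx)
    # neighbor at offset -(dz,dy,dx)... shift_3d moves content by +d, so
    # nb[i] is a[i - d]; voxel i's neighbor at position i - d.
    # that neighbor precedes i in scan order iff (dz,dy,dx) is
    # lexicographically positive.
    earlier <- dz > 0L || (dz == 0L && (dy > 0L || (dy == 0L && dx > 0L)))
    ok <- ok & (if (earlier) a > nb else a >= nb)
  }
  ok
}

chebyshev_prune <- function(centers, intensity, min_sep) {
  ord <- order(-intensity, centers[, 1], centers[, 2], centers[, 3])
  kept <- integer(0)
  for (i in ord) {
    if (length(kept)) {
      dmax <- apply(abs(centers[kept, , drop = FALSE] -
                          matrix(centers[i, ], length(kept), 3,
                                 byrow = TRUE)), 1, max)
      if (any(dmax < min_sep)) next
    }
    kept <- c(kept, i)
  }
  kept
}

#' Detect single-molecule RNA spots in one channel
#'
#' Pipeline: (i) Gaussian-smooth the channel; (ii) take 3x3x3 local maxima
#' inside the mask whose smoothed intensity exceeds the larger of the
#' isodata threshold of the masked voxels and the robust noise floor
#' `median + noise_k * scale` (background statistics refined by 3-sigma
#' clipping so dense spots do not inflate the scale); (iii) prune peaks
#' closer than
#' `min_separation` (per-axis), keeping the brighter; (iv) refine each
#' center by an intensity-weighted centroid over its in-mask 3x3x3 window.
#' Spots are returned in scan order (sorted by z, then y, then x).
#'
#' @param stack A [channel_stack()].
#' @param channel Channel role, `"rna1"` or `"rna2"`.
#' @param mask Logical 3-D array `(z, y, x)` delimiting the cell region;
#'   see [apply_front_mask()] / [polygon_mask()].
#' @param params A [detection_params()].
#' @return Data frame with columns `x`, `y`, `z` (0-based sub-voxel
#'   coordinates), `intensity` (smoothed peak value) and `type` (1 for
#'   rna1, 2 for rna2).
#' @export
detect_spots <- function(stack, channel = c("rna1", "rna2"), mask,
                         params = detection_params()) {
  channel <- match.arg(channel)
  stopifnot(inherits(stack, "channel_stack"),
            inherits(params, "detection_params"))
  idx <- stack$channel_map[[channel]]
  vol <- array(stack$voxels[idx, , , ], dim(stack$voxels)[2:4])
  if (!identical(dim(mask), dim(vol))) {
    sf_stop("sf_bad_mask", "mask shape must match the channel volume")
  }
  if (!any(mask)) {
    sf_stop("sf_empty_mask", "mask selects no voxels")
  }
  type <- if (channel == "rna1") 1L else 2L
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      intensity = numeric(), type = integer())

  sm <- gaussian_smooth_3d(vol, params$smoothing_sigma)
  iso_thr <- tryCatch(isodata_threshold_3d(sm[mask]),
                      sf_constant_volume = function(e) Inf)
  # Noise statistics come from the RAW channel: after smoothing, the halo
  # of every spot covers hundreds of voxels and in spot-dense cells the
  # halos blanket the mask, so no estimator on the smoothed volume can see
  # the background. On the raw volume the spot footprints are a small
  # minority relative to the unsmoothed noise and the masked MAD is
  # robust to them. The raw scale is converted to smoothed units by the
  # kernel's white-noise attenuation factor ||k||_2 (product over the
  # three separable 1-D kernels).
  ns <- estimate_noise_scale(vol, mask)
  att <- prod(vapply(c("x", "y", "z"), function(ax) {
    sqrt(sum(gaussian_kernel_1d(params$smoothing_sigma[[ax]])^2))
  }, numeric(1)))
  floor_thr <- ns[["median"]] + params$noise_k * ns[["scale"]] * att
  thr <- max(iso_thr, floor_thr)

  # candidates need a full 3x3x3 neighborhood: the 1-voxel border is
  # excluded (border smoothing is padded, its maxima unreliable)
  interior <- array(FALSE, dim(sm))
  interior[2:(dim(sm)[1] - 1L), 2:(dim(sm)[2] - 1L), 2:(dim(sm)[3] - 1L)] <- TRUE
  cand <- local_maxima_3d(sm) & mask & interior & (sm > thr)
  ci <- which(cand, arr.ind = TRUE)          # (z, y, x), 1-based
  if (nrow(ci) == 0L) return(empty)
  peak <- sm[which(cand)]                    # aligned with arr.ind order
  kept <- chebyshev_prune(ci, peak, params$min_separation)
  ci <- ci[kept, , drop = FALSE]
  peak <- peak[kept]

  d <- dim(sm)
  n <- nrow(ci)
  cz <- cy <- cx <- numeric(n)
  for (i in seq_len(n)) {
    zr <- max(1L, ci[i, 1] - 1L):min(d[1], ci[i, 1] + 1L)
    yr <- max(1L, ci[i, 2] - 1L):min(d[2], ci[i, 2] + 1L)
    xr <- max(1L, ci[i, 3] - 1L):min(d[3], ci[i, 3] + 1L)
    win <- sm[zr, yr, xr, drop = FALSE]
    m_win <- mask[zr, yr, xr, drop = FALSE]
    # subtract the in-window floor so the centroid is invariant to a
    # constant intensity offset
    w <- (win - min(win[m_win])) * m_win
    sw <- sum(w)
    if (sw <= 0) { cz[i] <- ci[i, 1]; cy[i] <- ci[i, 2]; cx[i] <- ci[i, 3]; next }
    g <- expand.grid(z = zr, y = yr, x = xr)
    cz[i] <- sum(g$z * as.numeric(w)) / sw
    cy[i] <- sum(g$y * as.numeric(w)) / sw
    cx[i] <- sum(g$x * as.numeric(w)) / sw
  }
  out <- data.frame(x = cx - 1, y = cy - 1, z = cz - 1,  # to 0-based
                    intensity = peak, type = type)
  out <- out[order(out$z, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}
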