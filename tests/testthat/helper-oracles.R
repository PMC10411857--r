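# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# nearest distance to a polyline by pure dense sampling (no refinement);
# upper-bounds the true distance, off by at most half the sample spacing
brute_force_polyline_distance <- function(p, poly, n = 1e4) {
  seg_len <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg_len))
  s <- seq(0, cum[length(cum)], length.out = n)
  e <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(poly) - 1)
  t <- (s - cum[e]) / seg_len[e]
  qx <- poly[e, 1] + t * (poly[e + 1, 1] - poly[e, 1])
  qy <- poly[e, 2] + t * (poly[e + 1, 2] - poly[e, 2])
  sqrt(min((qx - p[1])^2 + (qy - p[2])^2))
}

# two-sided exact signed-rank p-value by full sign-flip enumeration
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  (sum(Vs <= min(V, sum(r) - V)) + sum(Vs >= max(V, sum(r) - V))) / 2^n
}

# exhaustive per-level isodata scan: the integer level closest to the
# class-mean midpoint fixed point
isodata_level_scan <- function(v) {
  lv <- seq(ceiling(min(v)) + 1, floor(max(v)))
  f <- vapply(lv, function(t) {
    (mean(v[v < t]) + mean(v[v >= t])) / 2
  }, numeric(1))
  lv[which.min(abs(f - lv))]
}

# greedy matching of detected to planted spots within a radius; returns F1
match_f1 <- function(detected, truth, radius = 2.5) {
  if (nrow(truth) == 0 && nrow(detected) == 0) return(1)
  if (nrow(detected) == 0 || nrow(truth) == 0) return(0)
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((detected$x - truth$x[i])^2 + (detected$y - truth$y[i])^2 +
                (detected$z - truth$z[i])^2)
    j <- which(!used & d <= radius)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1L
    }
  }
  prec <- tp / nrow(detected)
  rec <- tp / nrow(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# render a bare volume with Gaussian spots (independent of make_scene)
render_plain_volume <- function(dim_zyx, centers, amp = 100,
                                sigma = c(xy = 1.3, z = 1.5)) {
  v <- array(0, dim_zyx)
  idx <- expand.grid(z = 0:(dim_zyx[1] - 1), y = 0:(dim_zyx[2] - 1),
                     x = 0:(dim_zyx[3] - 1))
  for (i in seq_len(nrow(centers))) {
    g <- amp * exp(-((idx$x - centers[i, "x"])^2 +
                       (idx$y - centers[i, "y"])^2) / (2 * sigma[["xy"]]^2) -
                     (idx$z - centers[i, "z"])^2 / (2 * sigma[["z"]]^2))
    v <- v + array(g, dim_zyx)
  }
  v
}

# small fixed partition: the unit square scaled to `s`, one edge per side
square_partition <- function(s = 1) {
  sq <- roi_polygon(rbind(c(0, 0), c(0, s), c(s, s), c(s, 0)))
  snap_anchors(sq, rbind(c(0, 0), c(0, s), c(s, s), c(s, 0)))
}
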