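# run expr under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# placement tilt: spot axial positions u in [0, 1] (0 = nuclear pole,
# 1 = invasive pole) follow a density proportional to exp(rate * u);
# rate 0 is uniform. polarity_bias beta in [0, 1] maps linearly onto
# rate = beta * BIAS_RATE_MAX.
BIAS_RATE_MAX <- 8

rate_from_bias <- function(beta) beta * BIAS_RATE_MAX

# E[u] under the tilted law on [0, 1]; rectangle-limit expectation of 1 - M
tilted_mean_u <- function(rate) {
  if (abs(rate) < 1e-12) return(0.5)
  1 / (1 - exp(-rate)) - 1 / rate
}

#' Polarity bias for a target invasive shift
#'
#' Solves for the bias `beta` whose placement law yields, in the
#' rectangular-cell limit, a mean normalized distance of `0.5 - shift`
#' (i.e. shifted toward the invasive edge by `shift`).
#'
#' @param shift Target decrease of M below the uniform value 0.5; in
#'   `[0, 0.37]` for the default rate ceiling.
#' @return The bias `beta` in `[0, 1]`.
#' @export
bias_for_shift <- function(shift) {
  stopifnot(shift >= 0)
  if (shift == 0) return(0)
  f <- function(r) tilted_mean_u(r) - (0.5 + shift)
  if (f(BIAS_RATE_MAX) < 0) {
    sf_stop("sf_bad_effect", sprintf(
      "shift %.3f is beyond the maximum placement tilt", shift))
  }
  stats::uniroot(f, c(1e-6, BIAS_RATE_MAX), tol = 1e-10)$root / BIAS_RATE_MAX
}

sample_tilted <- function(n, rate) {
  q <- stats::runif(n)
  if (abs(rate) < 1e-12) return(q)
  log(1 + q * (exp(rate) - 1)) / rate
}

# capsule outline: rectangle [xl, xr] x [cy-R, cy+R] with semicircular
# caps; rear (nuclear) cap at low x, invasive cap at high x
capsule_polygon <- function(xl, xr, cy, R, n_arc = 16L) {
  th_rear <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)
  th_front <- seq(-pi / 2, pi / 2, length.out = n_arc)
  v <- rbind(
    cbind(xl + R * cos(th_rear), cy + R * sin(th_rear)),   # rear cap, top->bottom
    cbind(xr + R * cos(th_front), cy + R * sin(th_front))) # front cap, bottom->top
  roi_polygon(v)
}

#' Generate a ground-truthed synthetic leader-cell scene
#'
#' Builds a 4-channel anisotropic-voxel z-stack containing an elongated
#' (capsule-shaped) cell with a nuclear disc at the rear, plants
#' diffraction-limited RNA spots at known sub-voxel coordinates, renders
#' them as 3-D Gaussian PSFs at a requested peak signal-to-noise ratio, and
#' corrupts the frame with Poisson shot noise plus Gaussian read noise.
#' Type-1 spot positions can be tilted toward the invasive pole via
#' `polarity_bias` (truncated-exponential placement; 0 = uniform).
#'
#' @param shape Integer `(z, y, x)` stack extent, at least `(8, 64, 64)`.
#' @param n_spots Integer `(n1, n2)` planted spots per RNA type.
#' @param polarity_bias `(beta1, beta2)` placement tilt per type, each in
#'   `[0, 1]`.
#' @param snr Peak amplitude of each rendered spot divided by the noise
#'   standard deviation at background.
#' @param seed Integer; the same seed regenerates a bit-identical scene.
#' @param background Baseline intensity (counts) inside the frame.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param psf_sigma Named `c(xy, z)` PSF standard deviations in voxels.
#' @param margin Spots keep this many pixels away from the outline.
#' @param min_spacing Minimum 3-D Euclidean center-to-center distance
#'   (voxels) between planted spots of the same type, so each spot is a
#'   resolvable single molecule; placement is rejection-sampled and errors
#'   if the mask cannot host the requested count.
#' @param tabular_only Skip rendering the voxel data (`stack` is `NULL`);
#'   spot placement is unchanged for a given seed. Used for large purely
#'   statistical simulations.
#' @return An object of class `synthetic_scene`: list with `stack`,
#'   `true_spots`, `polygon`, `anchors` (4 click points), `anchor_index`
#'   (their vertex indices), `segments` (the generator's own vertex-range
#'   definition of the four sides), `polarity_bias`, `noise_model`, `seed`.
#' @export
make_scene <- function(shape = c(8, 64, 64), n_spots = c(20, 20),
                       polarity_bias = c(0, 0), snr = 10, seed = 1,
                       background = 100, read_noise_sd = 2,
                       psf_sigma = c(xy = 1.3, z = 1.5), margin = 2,
                       min_spacing = 3, tabular_only = FALSE) {
  stopifnot(length(shape) == 3L, all(shape >= c(8, 64, 64)),
            all(n_spots >= 0), all(polarity_bias >= 0),
            all(polarity_bias <= 1))
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  cy <- (ny - 1) / 2
  R <- floor(ny * 0.22)
  xl <- R + 4
  xr <- nx - R - 5
  polygon <- capsule_polygon(xl, xr, cy, R)

  # clicks at the four cap/edge junctions, clockwise from the nuclear side;
  # the rear (nuclear) arc runs between the two x = xl junctions
  clicks <- rbind(c(xl, cy - R), c(xl, cy + R), c(xr, cy + R), c(xr, cy - R))
  part <- snap_anchors(polygon, clicks)   # validates click order once
  # generator's own segment bookkeeping (vertex index ranges on its outline)
  segments <- part$segments

  with_seed(seed, {
    place_one_type <- function(n, beta, type) {
      if (n == 0L) {
        return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                          intensity = numeric(), type = integer()))
      }
      Rm <- R - margin
      rate <- rate_from_bias(beta)
      xs <- ys <- zs <- numeric(n)
      placed <- 0L
      for (attempt in seq_len(4000L * n)) {
        u <- sample_tilted(1L, rate)
        x <- (xl - Rm) + u * ((xr + Rm) - (xl - Rm))
        half <- if (x < xl) sqrt(max(0, Rm^2 - (xl - x)^2))
                else if (x > xr) sqrt(max(0, Rm^2 - (x - xr)^2))
                else Rm
        y <- cy + stats::runif(1L, -1, 1) * half
        z <- stats::runif(1L, margin, nz - 1 - margin)
        if (placed > 0L && min_spacing > 0) {
          k <- seq_len(placed)
          if (min((xs[k] - x)^2 + (ys[k] - y)^2 + (zs[k] - z)^2) <
              min_spacing^2) next
        }
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y; zs[placed] <- z
        if (placed == n) break
      }
      if (placed < n) {
        sf_stop("sf_placement", sprintf(
          "could only place %d of %d type-%d spots at spacing %g",
          placed, n, type, min_spacing))
      }
      data.frame(x = xs, y = ys, z = zs, intensity = NA_real_, type = type)
    }
    sp1 <- place_one_type(n_spots[1], polarity_bias[1], 1L)
    sp2 <- place_one_type(n_spots[2], polarity_bias[2], 2L)
    true_spots <- rbind(sp1, sp2)

    noise_sd <- sqrt(background + read_noise_sd^2)
    amp <- snr * noise_sd
    true_spots$intensity <- rep(amp, nrow(true_spots))

    render_channel <- function(spots) {
      sig <- array(0, c(nz, ny, nx))
      sxy <- psf_sigma[["xy"]]; sz <- psf_sigma[["z"]]
      for (i in seq_len(nrow(spots))) {
        xs <- spots$x[i]; ys <- spots$y[i]; zs <- spots$z[i]
        zr <- max(0, floor(zs - 4 * sz)):min(nz - 1, ceiling(zs + 4 * sz))
        yr <- max(0, floor(ys - 4 * sxy)):min(ny - 1, ceiling(ys + 4 * sxy))
        xr2 <- max(0, floor(xs - 4 * sxy)):min(nx - 1, ceiling(xs + 4 * sxy))
        gz <- exp(-(zr - zs)^2 / (2 * sz^2))
        gy <- exp(-(yr - ys)^2 / (2 * sxy^2))
        gx <- exp(-(xr2 - xs)^2 / (2 * sxy^2))
        sig[zr + 1, yr + 1, xr2 + 1] <-
          sig[zr + 1, yr + 1, xr2 + 1] + amp * outer(outer(gz, gy), gx)
      }
      sig
    }

    add_noise <- function(expected) {
      v <- stats::rpois(length(expected), lambda = pmax(0, expected)) +
        stats::rnorm(length(expected), sd = read_noise_sd)
      array(pmin(BIT_DEPTH_MAX, pmax(0, round(v))), dim(expected))
    }

    stack <- NULL
    if (!tabular_only) {
      mask2 <- polygon_mask(polygon, c(ny, nx))
      cell3 <- aperm(array(mask2, c(ny, nx, nz)), c(3, 1, 2))
      # nuclear channel: bright disc behind the rear cap center
      g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1))
      nuc2 <- matrix(exp(-((g$x - xl)^2 + (g$y - cy)^2) / (2 * (R * 0.55)^2)),
                     ny, nx)
      nuc3 <- aperm(array(nuc2, c(ny, nx, nz)), c(3, 1, 2))
      vox <- array(0, c(4, nz, ny, nx))
      vox[1, , , ] <- add_noise(background + 8 * noise_sd * nuc3)
      vox[2, , , ] <- add_noise(background + 6 * noise_sd * cell3)
      vox[3, , , ] <- add_noise(background + render_channel(sp1))
      vox[4, , , ] <- add_noise(background + render_channel(sp2))
      stack <- channel_stack(vox)
    }

    structure(list(
      stack = stack, true_spots = true_spots, polygon = polygon,
      anchors = clicks, anchor_index = part$anchors, segments = segments,
      polarity_bias = polarity_bias,
      noise_model = c(poisson_gain = 1, gaussian_sigma = read_noise_sd,
                      background_level = background),
      snr = snr, seed = seed,
      geometry = c(xl = xl, xr = xr, cy = cy, R = R, margin = margin)),
      class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  size <- if (is.null(x$stack)) "tabular-only"
          else paste(dim(x$stack$voxels)[c(2, 3, 4)], collapse = "x")
  cat(sprintf(
    "synthetic_scene: %s (z,y,x), %d planted spots (%d/%d), snr %g, seed %d\n",
    size, nrow(x$true_spots), sum(x$true_spots$type == 1L),
    sum(x$true_spots$type == 2L), x$snr, x$seed))
  invisible(x)
}

# nearest distance from one point to a polyline by dense arc-length
# sampling plus 1-D refinement on the winning interval -- deliberately a
# different code path from the per-edge projection used elsewhere
polyline_sample_distance <- function(p, poly, n_samples = 2000L) {
  seg_len <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  at <- function(s) {
    s <- pmin(total, pmax(0, s))
    e <- pmax(1L, findInterval(s, cum, rightmost.closed = TRUE))
    e <- pmin(e, nrow(poly) - 1L)
    t <- (s - cum[e]) / seg_len[e]
    cbind(poly[e, 1] + t * (poly[e + 1L, 1] - poly[e, 1]),
          poly[e, 2] + t * (poly[e + 1L, 2] - poly[e, 2]))
  }
  s_grid <- seq(0, total, length.out = n_samples)
  pts <- at(s_grid)
  d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
  k <- which.min(d2)
  lo <- s_grid[max(1L, k - 1L)]; hi <- s_grid[min(n_samples, k + 1L)]
  opt <- stats::optimize(function(s) {
    q <- at(s); (q[1] - p[1])^2 + (q[2] - p[2])^2
  }, c(lo, hi), tol = 1e-12)
  sqrt(min(opt$objective, d2[k]))
}

#' Ground-truth distance table of a synthetic scene
#'
#' Exact nearest distances of every planted spot to the four boundary
#' sides, computed by dense boundary sampling with local refinement —
#' an implementation independent of [measure_all_spots()], usable as an
#' oracle for it.
#'
#' @param scene A [make_scene()] result.
#' @param n_samples Boundary samples per segment.
#' @return Data frame in the spot-distance layout (x, y, z, four distances,
#'   type, image).
#' @export
true_distance_table <- function(scene, n_samples = 2000L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  sp <- scene$true_spots
  segs <- scene$segments
  d <- vapply(SEGMENT_NAMES, function(sn) {
    vapply(seq_len(nrow(sp)), function(i) {
      polyline_sample_distance(c(sp$x[i], sp$y[i]), segs[[sn]], n_samples)
    }, numeric(1))
  }, numeric(nrow(sp)))
  if (nrow(sp) == 1L) d <- matrix(d, 1)
  out <- data.frame(x = sp$x, y = sp$y, z = sp$z,
                    d_nuclear = d[, 1], d_side1 = d[, 2],
                    d_invasive = d[, 3], d_side2 = d[, 4],
                    type = sp$type, image = 1L)
  rownames(out) <- NULL
  out
}

#' Generate a multi-image synthetic study
#'
#' A ready-to-analyze study of `n_images` leader cells in which RNA type 1
#' is shifted toward the invasive edge by `effect` (in M units) relative to
#' RNA type 2 (uniformly placed, M around 0.5). Per-image spot records are
#' computed from the planted coordinates; optionally the full image stacks
#' and outlines are rendered and written to `dir` for end-to-end runs.
#'
#' @param n_images Number of images (cells), >= 2.
#' @param effect Target difference in mean normalized distance between the
#'   two RNA types (type 1 lower).
#' @param seed Integer study seed; image i uses `seed * 1000 + i`.
#' @param n_spots `(n1, n2)` spots per type per image.
#' @param dir Optional output directory: writes `pooled.csv` plus, with
#'   `render = TRUE`, per-image TIFF stacks, polygon and anchor CSVs.
#' @param render Render and write the image stacks (slower); `FALSE` keeps
#'   the study purely tabular.
#' @param ... Passed to [make_scene()] (shape, snr, noise settings).
#' @return List with `pooled` (all spot records), `summaries`
#'   ([image_summaries()] of them), `expected` (rectangle-limit target M
#'   per type), `dir`, and with `render = TRUE` the per-image file paths.
#' @export
make_study <- function(n_images = 12L, effect = 0.25, seed = 1,
                       n_spots = c(40, 40), dir = NULL, render = FALSE,
                       ...) {
  if (n_images < 2L) {
    sf_stop("sf_bad_study", "a study needs at least 2 images")
  }
  if (n_images < 5L) {
    warning(sprintf("only %d images; the paired test will have little power",
                    n_images), call. = FALSE)
  }
  beta1 <- bias_for_shift(effect)
  tables <- vector("list", n_images)
  files <- list()
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_images)) {
    scene <- make_scene(n_spots = n_spots, polarity_bias = c(beta1, 0),
                        seed = seed * 1000 + i, tabular_only = !render, ...)
    part <- snap_anchors(scene$polygon, scene$anchors)
    tables[[i]] <- measure_all_spots(scene$true_spots, part, image_id = i)
    if (!is.null(dir) && render) {
      stem <- file.path(dir, sprintf("image%02d", i))
      write_stack(scene$stack, paste0(stem, ".tif"))
      write_polygon_csv(scene$polygon, paste0(stem, "_outline.csv"))
      utils::write.csv(data.frame(x = scene$anchors[, 1],
                                  y = scene$anchors[, 2]),
                       paste0(stem, "_anchors.csv"), row.names = FALSE)
      files[[i]] <- paste0(stem, c(".tif", "_outline.csv", "_anchors.csv"))
    }
  }
  pooled <- pool_images(tables)
  if (!is.null(dir)) {
    utils::write.csv(pooled, file.path(dir, "pooled.csv"), row.names = FALSE)
  }
  list(pooled = pooled, summaries = image_summaries(pooled),
       expected = c(M_rna1 = 0.5 - effect, M_rna2 = 0.5),
       dir = dir, files = files)
}
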