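polygon_signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# normalize vertex order to clockwise (negative shoelace area with x right,
# y up) so anchor ordering has one meaning; users may supply either
# orientation
orient_clockwise <- function(polygon) {
  if (polygon_signed_area(polygon$vertices) > 0) {
    polygon$vertices <- polygon$vertices[rev(seq_len(nrow(polygon$vertices))), ,
                                         drop = FALSE]
  }
  polygon
}

#' Point-in-polygon test
#'
#' Even-odd (crossing number) rule; points exactly on the outline count as
#' inside, so on-boundary spots are retained (a zero distance to one segment
#' is legitimate).
#'
#' @param p Numeric `(x, y)` point, or an n x 2 matrix of points.
#' @param polygon A [roi_polygon()].
#' @param tol Distance below which a point is treated as on the outline.
#' @return Logical, one value per point.
#' @export
point_in_polygon <- function(p, polygon, tol = 1e-9) {
  stopifnot(inherits(polygon, "roi_polygon"))
  pts <- if (is.null(dim(p))) matrix(p, 1) else as.matrix(p)
  v <- polygon$vertices
  n <- nrow(v)
  j <- c(2:n, 1L)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  for (e in seq_len(n)) {
    x1 <- v[e, 1]; y1 <- v[e, 2]; x2 <- v[j[e], 1]; y2 <- v[j[e], 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  # boundary convention: on-outline points are inside
  d_out <- dist_points_to_polyline(pts, v[c(seq_len(n), 1L), , drop = FALSE])
  inside | (d_out <= tol)
}

# vectorized nearest Euclidean distance from each point to a polyline
dist_points_to_polyline <- function(pts, poly) {
  pts <- if (is.null(dim(pts))) matrix(pts, 1) else as.matrix(pts)
  m <- nrow(poly)
  if (m < 2L) sf_stop("sf_degenerate_segment", "polyline needs >= 2 vertices")
  best <- rep(Inf, nrow(pts))
  for (e in seq_len(m - 1L)) {
    a <- poly[e, ]; b <- poly[e + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 +
            (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Nearest distance from a point to a boundary segment
#'
#' Minimum over the segment's edges of the point-to-edge Euclidean distance
#' in the x-y plane (perpendicular foot when it falls within the edge,
#' nearest endpoint otherwise).
#'
#' @param p Numeric `(x, y)` point.
#' @param segment Polyline: matrix of `(x, y)` vertices, >= 2 rows.
#' @return The distance, a scalar.
#' @export
distance_to_segment <- function(p, segment) {
  segment <- as.matrix(segment)
  total_len <- sum(sqrt(rowSums(diff(segment)^2)))
  if (nrow(segment) < 2L || total_len == 0) {
    sf_stop("sf_degenerate_segment", "segment has zero length")
  }
  as.numeric(dist_points_to_polyline(p, segment))
}

SEGMENT_NAMES <- c("nuclear", "side1", "invasive", "side2")

#' Partition a cell outline into the four boundary segments
#'
#' Each of the four click points snaps to its nearest polygon vertex (it is
#' not necessary to click exactly on the outline). After normalizing the
#' polygon to clockwise orientation, the four anchors must appear in strictly
#' clockwise order, starting from the nuclear side: clicks 1 and 2 bound the
#' nuclear side, clicks 3 and 4 the invasive side, so that
#' nuclear = a1->a2, side1 = a2->a3, invasive = a3->a4, side2 = a4->a1.
#' Anchor vertices belong to both adjacent segments; the four segments tile
#' the closed outline exactly once.
#'
#' @param polygon A [roi_polygon()] (either orientation accepted).
#' @param clicks 4 x 2 matrix of `(x, y)` click points, clockwise from the
#'   nuclear side.
#' @return An object of class `boundary_partition` with fields `polygon`
#'   (clockwise), `anchors` (vertex indices) and `segments` (named list of
#'   polylines).
#' @export
snap_anchors <- function(polygon, clicks) {
  stopifnot(inherits(polygon, "roi_polygon"))
  clicks <- as.matrix(clicks)
  if (nrow(clicks) != 4L || ncol(clicks) != 2L) {
    sf_stop("sf_bad_anchors", "exactly 4 (x, y) click points are required")
  }
  polygon <- orient_clockwise(polygon)
  v <- polygon$vertices
  n <- nrow(v)
  anchors <- vapply(seq_len(4L), function(k) {
    which.min((v[, 1] - clicks[k, 1])^2 + (v[, 2] - clicks[k, 2])^2)
  }, integer(1))
  if (anyDuplicated(anchors)) {
    sf_stop("sf_anchor_collision",
            "two clicks snap to the same outline vertex; re-click")
  }
  # strict clockwise (cyclically increasing) order starting at the first
  rel <- (anchors - anchors[1]) %% n
  if (is.unsorted(rel, strictly = TRUE)) {
    sf_stop("sf_anchor_order",
            "anchors are not in clockwise order; re-click clockwise starting from the nuclear side")
  }
  seg_idx <- function(i, j) {
    if (i <= j) i:j else c(i:n, 1:j)
  }
  a <- anchors
  segments <- list(
    nuclear  = v[seg_idx(a[1], a[2]), , drop = FALSE],
    side1    = v[seg_idx(a[2], a[3]), , drop = FALSE],
    invasive = v[seg_idx(a[3], a[4]), , drop = FALSE],
    side2    = v[seg_idx(a[4], a[1]), , drop = FALSE])
  structure(list(polygon = polygon, anchors = anchors, segments = segments),
            class = "boundary_partition")
}

#' @export
print.boundary_partition <- function(x, ...) {
  cat("boundary_partition:\n")
  for (s in SEGMENT_NAMES) {
    cat(sprintf("  %-8s %d vertices\n", s, nrow(x$segments[[s]])))
  }
  invisible(x)
}

#' Measure every spot's distance to the four boundary sides
#'
#' Spots whose `(x, y)` position lies inside the outline (all z retained;
#' the boundary is drawn on one slice and applied through the stack) receive
#' their nearest Euclidean distance to each of the four boundary segments.
#' Distances are computed in the x-y plane, in pixels by default.
#'
#' @param spots Data frame of spots (columns x, y, z, type; optionally
#'   intensity).
#' @param partition A [snap_anchors()] result.
#' @param image_id Integer label of the source image.
#' @param units `"px"` (default) or `"um"`; micrometer output multiplies
#'   distances by the lateral voxel size.
#' @param voxel_size Needed for `units = "um"`; named `c(x, y, z)`.
#' @return Data frame with columns x, y, z, d_nuclear, d_side1, d_invasive,
#'   d_side2, type, image — one row per in-polygon spot, detection order
#'   preserved.
#' @export
measure_all_spots <- function(spots, partition, image_id = 1L,
                              units = c("px", "um"), voxel_size = NULL) {
  units <- match.arg(units)
  stopifnot(inherits(partition, "boundary_partition"))
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      d_nuclear = numeric(), d_side1 = numeric(),
                      d_invasive = numeric(), d_side2 = numeric(),
                      type = integer(), image = integer())
  if (is.null(spots) || nrow(spots) == 0L) return(empty)
  xy <- cbind(spots$x, spots$y)
  keep <- point_in_polygon(xy, partition$polygon)
  if (!any(keep)) return(empty)
  spots <- spots[keep, , drop = FALSE]
  xy <- xy[keep, , drop = FALSE]
  scale <- 1
  if (units == "um") {
    if (is.null(voxel_size)) {
      sf_stop("sf_bad_units", "voxel_size is required for micrometer output")
    }
    scale <- unname(voxel_size[["x"]])
  }
  out <- data.frame(
    x = spots$x, y = spots$y, z = spots$z,
    d_nuclear  = dist_points_to_polyline(xy, partition$segments$nuclear) * scale,
    d_side1    = dist_points_to_polyline(xy, partition$segments$side1) * scale,
    d_invasive = dist_points_to_polyline(xy, partition$segments$invasive) * scale,
    d_side2    = dist_points_to_polyline(xy, partition$segments$side2) * scale,
    type = as.integer(spots$type), image = as.integer(image_id))
  rownames(out) <- NULL
  out
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel belongs to the mask when its center (0-based integer coordinates)
#' lies inside or on the outline.
#'
#' @param polygon A [roi_polygon()].
#' @param dim_yx Integer `(ny, nx)` image extent in pixels.
#' @return Logical `ny x nx` matrix.
#' @export
polygon_mask <- function(polygon, dim_yx) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  g <- expand.grid(y = seq_len(ny) - 1L, x = seq_len(nx) - 1L)
  inside <- point_in_polygon(cbind(g$x, g$y), polygon)
  matrix(inside, ny, nx)
}

#' Clear signal outside the cell-front outline
#'
#' Sets every voxel whose x-y pixel center falls outside the polygon to 0,
#' in all channels and throughout the whole stack — the programmatic
#' replacement for the manual clear-outside step. The same 2-D outline is
#' applied to every z-slice.
#'
#' @param stack A [channel_stack()].
#' @param polygon A [roi_polygon()] in the image's pixel frame.
#' @return The masked [channel_stack()].
#' @export
apply_front_mask <- function(stack, polygon) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$voxels)
  m2 <- polygon_mask(polygon, d[3:4])
  if (!any(m2)) {
    sf_stop("sf_polygon_outside", "polygon covers no pixel of the image")
  }
  keep <- aperm(array(m2, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  stack$voxels <- stack$voxels * keep
  stack
}

#' 3-D detection mask from a polygon
#'
#' @param polygon A [roi_polygon()].
#' @param dim_zyx Integer `(nz, ny, nx)` stack extent.
#' @return Logical `(z, y, x)` array, the 2-D mask replicated across z.
#' @export
mask_from_polygon <- function(polygon, dim_zyx) {
  m2 <- polygon_mask(polygon, dim_zyx[2:3])
  aperm(array(m2, c(dim_zyx[2], dim_zyx[3], dim_zyx[1])), c(3, 1, 2))
}
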