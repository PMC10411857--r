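# named error helper: every user-facing failure carries a distinct class so
# callers (and tests) can branch on the condition rather than on message text
sf_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "spotfront_error"), call = call))
}

CHANNEL_ROLES <- c("nuclear", "cellmask", "rna1", "rna2")

#' Default channel role mapping
#'
#' Channel roles follow the acquisition order of the protocol: channel 1 is
#' the nuclear stain, channel 2 the whole-cell stain, channels 3 and 4 the
#' two RNA smFISH channels (spot type 1 and type 2 respectively).
#'
#' @return Named integer vector mapping the roles `nuclear`, `cellmask`,
#'   `rna1`, `rna2` to channel indices 1--4.
#' @export
default_channel_map <- function() {
  c(nuclear = 1L, cellmask = 2L, rna1 = 3L, rna2 = 4L)
}

#' Default voxel size
#'
#' Physical voxel extent in micrometers, (x, y, z). The default is the
#' anisotropic confocal sampling typical for this assay: 0.1 x 0.1 x 0.3 um
#' (about half the point-spread-function width in each direction).
#'
#' @return Named numeric vector `c(x, y, z)` in micrometers.
#' @export
default_voxel_size <- function() {
  c(x = 0.1, y = 0.1, z = 0.3)
}

check_channel_map <- function(channel_map) {
  if (!all(CHANNEL_ROLES %in% names(channel_map))) {
    sf_stop("sf_bad_channel_map", sprintf(
      "channel_map must name all four roles (%s)",
      paste(CHANNEL_ROLES, collapse = ", ")))
  }
  idx <- as.integer(channel_map[CHANNEL_ROLES])
  if (anyNA(idx) || anyDuplicated(idx) || any(idx < 1L)) {
    sf_stop("sf_bad_channel_map",
            "channel_map indices must be distinct positive integers")
  }
  stats::setNames(idx, CHANNEL_ROLES)
}

#' Construct a multi-channel image stack
#'
#' The in-memory container for a 4-channel confocal z-stack. Voxels are held
#' in a 4-D array indexed `(channel, z, y, x)`; a spot coordinate `(x, y, z)`
#' addresses the center of voxel `voxels[c, z + 1, y + 1, x + 1]`
#' (coordinates are 0-based, voxel centers at integers).
#'
#' @param voxels 4-D numeric array, dimensions `(channel, z, y, x)`, all
#'   values finite and non-negative.
#' @param channel_map Named vector mapping the roles `nuclear`, `cellmask`,
#'   `rna1`, `rna2` to distinct channel indices.
#' @param voxel_size Named numeric `c(x, y, z)`, micrometers per voxel,
#'   strictly positive.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(voxels, channel_map = default_channel_map(),
                          voxel_size = default_voxel_size()) {
  if (length(dim(voxels)) != 4L) {
    sf_stop("sf_bad_stack", "voxels must be a 4-D (channel, z, y, x) array")
  }
  channel_map <- check_channel_map(channel_map)
  if (dim(voxels)[1] < max(channel_map)) {
    sf_stop("sf_channel_count", sprintf(
      "stack has %d channels but channel_map needs index %d",
      dim(voxels)[1], max(channel_map)))
  }
  if (any(dim(voxels)[2:4] < 1L)) {
    sf_stop("sf_bad_stack", "all spatial dimensions must be >= 1")
  }
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    sf_stop("sf_bad_stack", "intensities must be finite and non-negative")
  }
  voxel_size <- voxel_size[c("x", "y", "z")]
  if (anyNA(voxel_size) || any(voxel_size <= 0)) {
    sf_stop("sf_bad_stack", "voxel_size must be positive c(x, y, z)")
  }
  structure(list(voxels = voxels, channel_map = channel_map,
                 voxel_size = voxel_size),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("channel_stack: %d channels, %d z-slices, %d x %d (y x x) pixels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (um): x=%g y=%g z=%g\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"]))
  cat("  roles:", paste(sprintf("%s=%d", names(x$channel_map), x$channel_map),
                        collapse = " "), "\n")
  invisible(x)
}

# maximum representable intensity on disk (stacks are written as 16-bit)
BIT_DEPTH_MAX <- 65535

#' Read a multi-channel TIFF z-stack
#'
#' Axes are normalized to `(channel, z, y, x)` regardless of on-disk layout.
#' Two layouts are understood: interleaved (each TIFF page is one z-slice
#' with >= 4 samples per pixel, channels last) and planar (grayscale pages in
#' ImageJ hyperstack order, channel varying fastest). For planar files the
#' page count must be a multiple of the channel count; otherwise the layout
#' is ambiguous and a `sf_ambiguous_axes` error is raised.
#'
#' @param path Path to the TIFF file.
#' @param channel_map Role-to-index mapping; see [default_channel_map()].
#' @param voxel_size Voxel size `c(x, y, z)` in micrometers. TIFF carries no
#'   reliable voxel metadata for these stacks, so this comes from config.
#' @param layout `"auto"` (detect from page structure), `"interleaved"`, or
#'   `"planar"`.
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, channel_map = default_channel_map(),
                       voxel_size = default_voxel_size(),
                       layout = c("auto", "interleaved", "planar")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    sf_stop("sf_missing_file", sprintf("no such file: %s", path))
  }
  channel_map <- check_channel_map(channel_map)
  n_ch <- length(channel_map)
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  scale <- if (is.null(bits)) BIT_DEPTH_MAX else 2^bits - 1
  nd <- length(dim(pages[[1]]))
  interleaved <- nd == 3L && dim(pages[[1]])[3] >= n_ch
  if (layout == "interleaved" && !interleaved) {
    sf_stop("sf_ambiguous_axes", "file does not hold channels-last pages")
  }
  if (layout == "planar") interleaved <- FALSE
  if (interleaved) {
    nz <- length(pages)
    dyx <- dim(pages[[1]])[1:2]
    nc <- dim(pages[[1]])[3]
    if (nc < max(channel_map)) {
      sf_stop("sf_channel_count", sprintf(
        "stack has %d channels; channel_map needs index %d", nc,
        max(channel_map)))
    }
    vox <- array(0, c(nc, nz, dyx[1], dyx[2]))
    for (z in seq_len(nz)) {
      vox[, z, , ] <- aperm(pages[[z]], c(3, 1, 2))
    }
  } else {
    if (nd != 2L) {
      sf_stop("sf_ambiguous_axes",
              "pages are neither grayscale nor channels-last; cannot infer axes")
    }
    npg <- length(pages)
    if (npg < n_ch) {
      sf_stop("sf_channel_count", sprintf(
        "planar stack has %d pages; at least %d channels required", npg, n_ch))
    }
    if (npg %% n_ch != 0L) {
      sf_stop("sf_ambiguous_axes", sprintf(
        "planar stack has %d pages, not a multiple of %d channels; supply layout/config",
        npg, n_ch))
    }
    nz <- npg %/% n_ch
    dyx <- dim(pages[[1]])
    vox <- array(0, c(n_ch, nz, dyx[1], dyx[2]))
    for (z in seq_len(nz)) {
      for (ch in seq_len(n_ch)) {
        vox[ch, z, , ] <- pages[[(z - 1L) * n_ch + ch]]  # channel fastest
      }
    }
  }
  channel_stack(round(vox * scale), channel_map, voxel_size)
}

#' Write a multi-channel stack to TIFF
#'
#' Pages are written one per z-slice with channels as samples (channels-last
#' interleaved), 16-bit. Intensities are rounded to integers in
#' `[0, 65535]`; this makes [read_stack()] of a written stack an identity on
#' voxels.
#'
#' @param stack A [channel_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  v <- stack$voxels
  if (max(v) > BIT_DEPTH_MAX) {
    sf_stop("sf_bad_stack", "intensities exceed the 16-bit output range")
  }
  d <- dim(v)
  pages <- lapply(seq_len(d[2]), function(z) {
    aperm(round(v[, z, , , drop = FALSE])[, 1, , ], c(2, 3, 1)) / BIT_DEPTH_MAX
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

segments_do_intersect <- function(p1, p2, q1, q2) {
  # proper intersection of open segments (shared endpoints do not count)
  d1 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  d3 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d4 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (segments_do_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Construct a cell-outline polygon
#'
#' A closed polygon in pixel coordinates (same 0-based x/y frame as the
#' image). The closing edge from the last vertex back to the first is
#' implicit.
#'
#' @param vertices 2-column numeric matrix of `(x, y)` vertices, >= 3 rows,
#'   no two consecutive vertices identical, not self-intersecting.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    sf_stop("sf_bad_polygon", "polygon needs >= 3 (x, y) vertices")
  }
  if (!all(is.finite(vertices))) {
    sf_stop("sf_bad_polygon", "polygon vertices must be finite")
  }
  colnames(vertices) <- c("x", "y")
  nxt <- rbind(vertices[-1, , drop = FALSE], vertices[1, , drop = FALSE])
  if (any(rowSums(abs(vertices - nxt)) == 0)) {
    sf_stop("sf_bad_polygon", "consecutive duplicate vertices")
  }
  if (polygon_self_intersects(vertices)) {
    sf_stop("sf_self_intersecting", "polygon outline self-intersects")
  }
  structure(list(vertices = vertices, closed = TRUE), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("roi_polygon: %d vertices, bbox x [%g, %g] y [%g, %g]\n",
              nrow(x$vertices),
              min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2])))
  invisible(x)
}

#' Read a cell-outline polygon
#'
#' Accepts either an ImageJ `.roi` file (POLYGON or FREEHAND subtype) or a
#' two-column CSV of x,y pixel coordinates (header optional). Both encodings
#' of the same vertices load identically.
#'
#' @param path Path to a `.roi` or `.csv` file.
#' @return A [roi_polygon()].
#' @export
read_polygon <- function(path) {
  if (!file.exists(path)) {
    sf_stop("sf_missing_file", sprintf("no such file: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "roi") {
    return(read_imagej_roi(path))
  }
  if (ext %in% c("csv", "txt")) {
    first <- readLines(path, n = 1L)
    has_header <- is.na(suppressWarnings(
      as.numeric(strsplit(first, ",")[[1]][1])))
    m <- utils::read.csv(path, header = has_header)
    if (ncol(m) < 2L) {
      sf_stop("sf_bad_polygon", "polygon CSV needs two columns (x, y)")
    }
    return(roi_polygon(as.matrix(m[, 1:2])))
  }
  sf_stop("sf_unknown_format", sprintf("unknown polygon format: .%s", ext))
}

#' Write a polygon as CSV
#' @param polygon A [roi_polygon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygon_csv <- function(polygon, path) {
  stopifnot(inherits(polygon, "roi_polygon"))
  utils::write.csv(as.data.frame(polygon$vertices), path, row.names = FALSE)
  invisible(path)
}

IJ_ROI_POLYGON <- 0L
IJ_ROI_FREEHAND <- 7L

#' Read an ImageJ .roi polygon
#'
#' Minimal parser for the binary ImageJ ROI format, restricted to the
#' POLYGON and FREEHAND subtypes; any other ROI type is rejected.
#'
#' @param path Path to a `.roi` file.
#' @return A [roi_polygon()].
#' @export
read_imagej_roi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "Iout")) {
    sf_stop("sf_unknown_format", "not an ImageJ ROI file (bad magic)")
  }
  readBin(con, "integer", 1L, size = 2L, endian = "big")          # version
  type <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  readBin(con, "integer", 1L, size = 1L, signed = FALSE)          # pad
  if (!type %in% c(IJ_ROI_POLYGON, IJ_ROI_FREEHAND)) {
    sf_stop("sf_unknown_format", sprintf(
      "unsupported ImageJ ROI type %d (only POLYGON/FREEHAND)", type))
  }
  top <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  left <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  readBin(con, "integer", 2L, size = 2L, endian = "big")          # bottom,right
  n <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  readBin(con, "raw", 64L - 18L)                                  # rest of header
  xs <- readBin(con, "integer", n, size = 2L, endian = "big") + left
  ys <- readBin(con, "integer", n, size = 2L, endian = "big") + top
  roi_polygon(cbind(x = xs, y = ys))
}

#' Write a polygon as an ImageJ .roi file
#'
#' Vertices are stored as integer pixel offsets (the ImageJ encoding);
#' non-integer coordinates are rounded.
#'
#' @param polygon A [roi_polygon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(polygon, path) {
  stopifnot(inherits(polygon, "roi_polygon"))
  v <- round(polygon$vertices)
  left <- min(v[, 1]); top <- min(v[, 2])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  writeBin(228L, con, size = 2L, endian = "big")                  # version
  writeBin(as.raw(c(IJ_ROI_POLYGON, 0L)), con)
  writeBin(as.integer(c(top, left, max(v[, 2]), max(v[, 1]))), con,
           size = 2L, endian = "big")
  writeBin(nrow(v), con, size = 2L, endian = "big")
  writeBin(raw(64L - 18L), con)
  writeBin(as.integer(v[, 1] - left), con, size = 2L, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2L, endian = "big")
  invisible(path)
}

SPOT_DISTANCE_COLS <- c("x", "y", "z", "d_nuclear", "d_side1", "d_invasive",
                        "d_side2", "type")

#' Write the per-image spot tables
#'
#' Writes the three output tables of a single-image run: `Spot Distances.txt`
#' (tab-delimited; one row per spot with x, y, z, the nearest distance to
#' each of the four boundary sides, and the spot type), plus `Spots1.txt` and
#' `Spots2.txt` carrying coordinates and intensities of the type-1 and type-2
#' spots. Row order is detection order. Empty inputs yield header-only files.
#'
#' @param records Data frame of spot-distance records (see
#'   [measure_all_spots()]); may have zero rows.
#' @param spots1,spots2 Data frames of detected spots (columns x, y, z,
#'   intensity) for RNA type 1 and 2.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three file paths.
#' @export
write_spot_tables <- function(records, spots1, spots2, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) sf_stop("sf_unwritable", sprintf("cannot create %s", out_dir))
  }
  if (file.access(out_dir, 2L) != 0L) {
    sf_stop("sf_unwritable", sprintf("directory not writable: %s", out_dir))
  }
  empty_rec <- stats::setNames(
    as.data.frame(matrix(numeric(), 0, length(SPOT_DISTANCE_COLS))),
    SPOT_DISTANCE_COLS)
  empty_spot <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                           intensity = numeric())
  if (is.null(records) || nrow(records) == 0L) records <- empty_rec
  if (is.null(spots1) || nrow(spots1) == 0L) spots1 <- empty_spot
  if (is.null(spots2) || nrow(spots2) == 0L) spots2 <- empty_spot
  paths <- c(
    distances = file.path(out_dir, "Spot Distances.txt"),
    spots1 = file.path(out_dir, "Spots1.txt"),
    spots2 = file.path(out_dir, "Spots2.txt"))
  utils::write.table(records[, SPOT_DISTANCE_COLS, drop = FALSE],
                     paths["distances"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cols <- c("x", "y", "z", "intensity")
  utils::write.table(spots1[, cols, drop = FALSE], paths["spots1"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(spots2[, cols, drop = FALSE], paths["spots2"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

#' Read a pooled multi-image spot table
#'
#' The pooled table is a CSV holding every spot of every image with an
#' `image` column identifying the source image by number.
#'
#' @param path CSV path.
#' @return Data frame with the spot-distance columns plus `image`.
#' @export
read_pooled_csv <- function(path) {
  if (!file.exists(path)) {
    sf_stop("sf_missing_file", sprintf("no such file: %s", path))
  }
  df <- utils::read.csv(path)
  need <- c(SPOT_DISTANCE_COLS, "image")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    sf_stop("sf_bad_schema", sprintf(
      "pooled CSV is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  df
}
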