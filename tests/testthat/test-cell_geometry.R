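test_that("square clicks give four single-edge segments; near-clicks snap", {
  part <- square_partition()
  expect_true(all(vapply(part$segments, nrow, integer(1)) == 2L))
  sq <- roi_polygon(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  part2 <- snap_anchors(sq, rbind(c(0.1, -0.2), c(-0.1, 1.1),
                                  c(1.2, 1.1), c(0.9, -0.05)))
  expect_identical(part2$anchors, part$anchors)
})

test_that("counter-clockwise clicks and colliding clicks are named errors", {
  sq <- roi_polygon(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  expect_error(snap_anchors(sq, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
               class = "sf_anchor_order")
  expect_error(snap_anchors(sq, rbind(c(0, 0), c(0.1, 0.1), c(1, 1), c(1, 0))),
               class = "sf_anchor_collision")
})

test_that("segments tile the outline exactly once", {
  set.seed(5)
  sc <- make_scene(tabular_only = TRUE, seed = 5)
  part <- snap_anchors(sc$polygon, sc$anchors)
  n <- nrow(part$polygon$vertices)
  counted <- integer(n)
  for (seg in part$segments) {
    idx <- apply(seg, 1, function(p) {
      which(part$polygon$vertices[, 1] == p[1] &
              part$polygon$vertices[, 2] == p[2])[1]
    })
    counted[idx] <- counted[idx] + 1L
  }
  expect_identical(sum(counted[part$anchors]), 8L)   # anchors shared by 2
  expect_true(all(counted[-part$anchors] == 1L))     # interior vertices once
})

test_that("point-in-polygon follows the even-odd rule with on-edge inclusion", {
  sq <- roi_polygon(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  expect_true(point_in_polygon(c(0.5, 0.5), sq))
  expect_false(point_in_polygon(c(2, 2), sq))
  expect_true(point_in_polygon(c(0, 0.5), sq))
  expect_true(point_in_polygon(c(1, 1), sq))
})

test_that("distance to a segment: perpendicular foot and nearest endpoint", {
  expect_equal(distance_to_segment(c(0, 0), rbind(c(3, 0), c(3, 4))), 3)
  expect_equal(distance_to_segment(c(0, 0), rbind(c(3, 4), c(6, 4))), 5)
  expect_error(distance_to_segment(c(0, 0), rbind(c(1, 1), c(1, 1))),
               class = "sf_degenerate_segment")
})

test_that("distance to random polylines matches dense-sampling brute force", {
  set.seed(17)
  for (i in 1:25) {
    poly <- cbind(cumsum(runif(10, -3, 5)), cumsum(runif(10, -4, 4)))
    p <- c(runif(1, -5, 30), runif(1, -10, 10))
    fast <- distance_to_segment(p, poly)
    slow <- brute_force_polyline_distance(p, poly, n = 1e4)
    spacing <- sum(sqrt(rowSums(diff(poly)^2))) / 1e4
    expect_lt(abs(fast - slow), spacing / 2 + 1e-9)
    expect_lte(fast, slow + 1e-12)  # sampling can only overestimate
  }
})

test_that("a centered spot in the unit square is 0.5 from every side", {
  part <- square_partition()
  sp <- data.frame(x = 0.5, y = 0.5, z = 0, type = 1L)
  rec <- measure_all_spots(sp, part)
  expect_equal(unlist(rec[1, c("d_nuclear", "d_side1", "d_invasive",
                               "d_side2")], use.names = FALSE),
               rep(0.5, 4))
})

test_that("spots outside the polygon produce no record", {
  part <- square_partition()
  sp <- data.frame(x = c(0.5, 2), y = c(0.5, 2), z = 0, type = 1L)
  rec <- measure_all_spots(sp, part)
  expect_identical(nrow(rec), 1L)
  expect_identical(nrow(measure_all_spots(sp[2, , drop = FALSE], part)), 0L)
})

test_that("tiling: the min over segments equals the distance to the outline", {
  set.seed(23)
  sc <- make_scene(n_spots = c(30, 0), tabular_only = TRUE, seed = 23)
  part <- snap_anchors(sc$polygon, sc$anchors)
  rec <- measure_all_spots(sc$true_spots, part)
  v <- part$polygon$vertices
  ring <- rbind(v, v[1, , drop = FALSE])
  for (i in seq_len(nrow(rec))) {
    d_out <- distance_to_segment(c(rec$x[i], rec$y[i]), ring)
    d_min <- min(rec$d_nuclear[i], rec$d_side1[i], rec$d_invasive[i],
                 rec$d_side2[i])
    expect_equal(d_min, d_out, tolerance = 1e-12)
  }
})

test_that("distances are invariant under rigid motion of spots and polygon", {
  set.seed(29)
  sc <- make_scene(n_spots = c(20, 0), tabular_only = TRUE, seed = 29)
  part <- snap_anchors(sc$polygon, sc$anchors)
  rec <- measure_all_spots(sc$true_spots, part)
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(12, -5)
  rot <- function(m) sweep(as.matrix(m) %*% t(Rm), 2, shift, "+")
  poly2 <- roi_polygon(rot(part$polygon$vertices))
  anchors2 <- rot(sc$anchors)
  sp2 <- sc$true_spots
  xy2 <- rot(cbind(sp2$x, sp2$y))
  sp2$x <- xy2[, 1]; sp2$y <- xy2[, 2]
  rec2 <- measure_all_spots(sp2, snap_anchors(poly2, anchors2))
  cols <- c("d_nuclear", "d_side1", "d_invasive", "d_side2")
  expect_equal(as.matrix(rec2[, cols]), as.matrix(rec[, cols]),
               tolerance = 1e-9)
})

test_that("front masking clears outside voxels only, across channels and z", {
  set.seed(31)
  vox <- array(runif(4 * 4 * 20 * 20, 1, 10), c(4, 4, 20, 20))
  st <- channel_stack(vox)
  full <- roi_polygon(rbind(c(-1, -1), c(-1, 20), c(20, 20), c(20, -1)))
  expect_equal(apply_front_mask(st, full)$voxels, vox)
  tiny <- roi_polygon(rbind(c(5, 5), c(5, 9), c(9, 9), c(9, 5)))
  masked <- apply_front_mask(st, tiny)
  m3 <- mask_from_polygon(tiny, c(4, 20, 20))
  for (ch in 1:4) {
    expect_equal(sum(masked$voxels[ch, , , ]),
                 sum(vox[ch, , , ] * m3))
  }
  off <- roi_polygon(rbind(c(100, 100), c(100, 110), c(110, 110), c(110, 100)))
  expect_error(apply_front_mask(st, off), class = "sf_polygon_outside")
})

test_that("spots planted outside the outline are absent after masking", {
  set.seed(37)
  sc <- make_scene(n_spots = c(8, 0), min_spacing = 5, seed = 37)
  d <- dim(sc$stack$voxels)[2:4]
  # shrink the outline to the rear half: front spots must vanish
  v <- sc$polygon$vertices
  cut_x <- mean(range(v[, 1]))
  keep <- v[, 1] <= cut_x
  v2 <- v[keep, , drop = FALSE]
  half_poly <- roi_polygon(rbind(v2, c(cut_x, min(v2[, 2])),
                                 c(cut_x, max(v2[, 2]))))
  masked <- apply_front_mask(sc$stack, half_poly)
  mask <- mask_from_polygon(half_poly, d)
  sp <- detect_spots(masked, "rna1", mask)
  expect_true(all(sp$x <= cut_x + 1))
})
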