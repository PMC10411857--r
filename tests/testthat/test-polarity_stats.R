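hand_records <- function(nd, id, type = 1L, image = 1L) {
  data.frame(x = 0, y = 0, z = 0, d_nuclear = nd, d_side1 = 1,
             d_invasive = id, d_side2 = 1, type = type, image = image)
}

test_that("total length and M match hand computation", {
  expect_equal(total_length(hand_records(2, 8)), 10)
  expect_equal(total_length(hand_records(c(1, 3), c(9, 7))), 10)
  expect_error(total_length(hand_records(1, 1)[0, ]), class = "sf_no_records")
  rec <- hand_records(2, 8)
  expect_equal(mean_normalized_distance(rec, total_length(rec)), 0.8)
})

test_that("M hits the stated 0 (invasive) and 1 (nuclear) limits", {
  on_invasive <- hand_records(c(5, 7), c(0, 0))
  expect_equal(mean_normalized_distance(on_invasive,
                                        total_length(on_invasive)), 0)
  on_nuclear <- hand_records(0, 6)      # single spot on the nuclear edge
  expect_equal(mean_normalized_distance(on_nuclear,
                                        total_length(on_nuclear)), 1)
  expect_warning(M <- mean_normalized_distance(on_nuclear[0, ], 10),
                 "undefined")
  expect_true(is.na(M))
})

test_that("M is invariant under uniform distance rescaling", {
  set.seed(3)
  rec <- hand_records(runif(50, 0, 20), runif(50, 0, 20))
  L <- total_length(rec)
  M <- mean_normalized_distance(rec, L)
  rec2 <- rec
  rec2[, c("d_nuclear", "d_side1", "d_invasive", "d_side2")] <-
    rec2[, c("d_nuclear", "d_side1", "d_invasive", "d_side2")] * 7.3
  expect_equal(mean_normalized_distance(rec2, total_length(rec2)), M)
})

test_that("record order never affects L, M, or the test", {
  set.seed(13)
  rec <- hand_records(runif(40, 0, 10), runif(40, 0, 10),
                      type = rep(1:2, 20))
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(total_length(perm), total_length(rec))
  L <- total_length(rec)
  expect_equal(mean_normalized_distance(perm[perm$type == 1, ], L),
               mean_normalized_distance(rec[rec$type == 1, ], L))
})

test_that("pooling preserves per-image weighting and rejects duplicates", {
  big <- hand_records(runif(300), runif(300), type = 1L, image = 2L)
  small <- hand_records(runif(3), runif(3), type = 1L, image = 1L)
  pooled <- pool_images(list(small, big))
  expect_identical(nrow(pooled), 303L)
  s <- image_summaries(pooled)
  expect_identical(nrow(s), 2L)             # one (M1, M2) pair per image
  expect_error(pool_images(list(small, small)), class = "sf_duplicate_image")
  one <- pool_images(list(small))
  expect_identical(nrow(one), 3L)
  expect_true(all(one$image == 1L))
})

test_that("signed-rank p is exact: 5 all-positive pairs give 0.0625", {
  m1 <- c(0.6, 0.62, 0.65, 0.7, 0.72)
  m2 <- m1 - c(0.1, 0.12, 0.05, 0.2, 0.15)
  w <- wilcoxon_matched_pairs(m1, m2)
  expect_equal(w$p_value, 2 / 2^5)
  expect_equal(w$statistic, 15)
})

test_that("identical pairs leave no usable differences", {
  m <- runif(6)
  expect_error(wilcoxon_matched_pairs(m, m), class = "sf_too_few_pairs")
  expect_error(wilcoxon_matched_pairs(1:3 / 10, 1:4 / 10),
               class = "sf_bad_pairs")
})

test_that("exact p matches full sign-flip enumeration on random pairs", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.02, 0.1), 3)
    d <- d[d != 0]
    if (length(d) < 2) next
    w <- wilcoxon_matched_pairs(d, rep(0, length(d)))
    expect_equal(w$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12,
                 info = paste("replicate", i))
  }
})

test_that("exact p agrees with stats::wilcox.test when there are no ties", {
  set.seed(57)
  m1 <- runif(12); m2 <- m1 + rnorm(12, 0, 0.1)
  w <- wilcoxon_matched_pairs(m1, m2)
  ref <- stats::wilcox.test(m1, m2, paired = TRUE, exact = TRUE)
  expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(w$statistic, unname(ref$statistic))
})

test_that("large-n path uses the normal approximation consistently", {
  set.seed(71)
  m1 <- runif(40); m2 <- m1 + rnorm(40, 0.05, 0.1)
  w <- wilcoxon_matched_pairs(m1, m2)
  ref <- stats::wilcox.test(m1, m2, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("pairing matters: a matched design beats a shuffled one", {
  set.seed(83)
  base <- runif(10, 0.2, 0.8)               # strong per-image variation
  m1 <- base - 0.05 + rnorm(10, 0, 0.005)   # consistent within-image shift
  m2 <- base + rnorm(10, 0, 0.005)
  p_paired <- wilcoxon_matched_pairs(m1, m2)$p_value
  p_shuffled <- wilcoxon_matched_pairs(m1, sample(m2))$p_value
  expect_lt(p_paired, 0.01)
  expect_gt(p_shuffled, p_paired)
})

test_that("KDE integrates to one and modes sit at the data location", {
  s <- data.frame(image = 1:8, n1 = 10, n2 = 10, L = 10,
                  M_rna1 = 0.3 + rnorm(8, 0, 1e-4),
                  M_rna2 = 0.5 + rnorm(8, 0, 1e-4))
  pooled <- do.call(rbind, lapply(1:8, function(i)
    hand_records(runif(10, 0, 5), runif(10, 0, 5), type = rep(1:2, 5),
                 image = i)))
  res <- density_and_histograms(s, pooled)
  for (ty in c("rna1", "rna2")) {
    g <- res$kde[[ty]]
    area <- sum(diff(g$distance) * (head(g$density, -1) + tail(g$density, -1)) / 2)
    expect_lt(abs(area - 1), 1e-3)
  }
  mode1 <- res$kde$rna1$distance[which.max(res$kde$rna1$density)]
  grid_step <- diff(res$kde$rna1$distance[1:2])
  expect_lt(abs(mode1 - 0.3), grid_step + 1e-3)
})

test_that("degenerate M values skip the KDE but keep histograms", {
  s <- data.frame(image = 1:3, n1 = 2, n2 = 2, L = 10,
                  M_rna1 = 0.4, M_rna2 = 0.45)
  pooled <- do.call(rbind, lapply(1:3, function(i)
    hand_records(runif(4, 0, 5), runif(4, 0, 5), type = c(1L, 1L, 2L, 2L),
                 image = i)))
  expect_warning(res <- density_and_histograms(s, pooled), "KDE skipped")
  expect_null(res$kde$rna1)
  expect_identical(sum(res$histograms$rna1$count), 6L)
})
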