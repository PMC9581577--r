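mk_img <- function(r, g = r, b = r) {
  a <- array(0, c(nrow(r), ncol(r), 3))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  a
}
mk_hue <- function(values, scale = 2)
  structure(list(values = values, scale_um_per_px = scale,
                 sigma_low = 15, sigma_high = 300), class = "hue_map")

test_that("electrode inpainting fills dark disks from their surround", {
  base <- matrix(0.5, 80, 80)
  disk <- outer((1:80 - 40)^2, (1:80 - 40)^2, "+") <= 8^2
  dark <- base; dark[disk] <- 0
  res <- inpaint_electrodes(mk_img(dark))
  expect_true(all(res$mask[disk]))
  expect_true(all(abs(res$image[, , 1][disk] - 0.5) < 1 / 255))

  # no dark pixels: image unchanged
  flat <- mk_img(matrix(0.6, 30, 30))
  res2 <- inpaint_electrodes(flat)
  expect_identical(res2$image, flat)
  expect_false(any(res2$mask))

  expect_error(inpaint_electrodes(mk_img(matrix(0, 10, 10))), "all pixels")
})

test_that("inpainted values obey the maximum principle", {
  grad <- matrix(rep(seq(0.3, 0.9, length.out = 60), each = 60), 60, 60)
  disk <- outer((1:60 - 30)^2, (1:60 - 30)^2, "+") <= 6^2
  img <- grad; img[disk] <- 0
  res <- inpaint_electrodes(mk_img(img))
  filled <- res$image[, , 1][res$mask]
  boundary <- grad[!res$mask]
  expect_gte(min(filled), min(boundary) - 1e-6)
  expect_lte(max(filled), max(boundary) + 1e-6)
})

test_that("hue map rejects achromatic images and small speckle, keeps disks", {
  set.seed(2)
  g <- matrix(0.6 + rnorm(150 * 150, 0, 0.02), 150, 150)
  achro <- mk_img(g)                              # R = G = B
  hm <- hue_map(achro, scale_um_per_px = 2)
  expect_lt(max(abs(hm$values)), 0.05)

  # a 100 um red-shifted disk pops out over near-zero background
  r <- matrix(0.6, 200, 200); b <- matrix(0.6, 200, 200)
  disk <- outer((1:200 - 100)^2, (1:200 - 100)^2, "+") <= 25^2   # 50 px = 100 um
  r[disk] <- 0.75; b[disk] <- 0.45
  hm2 <- hue_map(mk_img(r, r, b), scale_um_per_px = 2)
  inside <- mean(hm2$values[disk])
  outside <- mean(abs(hm2$values[!disk]))
  expect_gt(inside, 5 * outside)

  # single-pixel speckle is suppressed below 10% of its raw contrast
  r3 <- matrix(0.6, 120, 120); b3 <- r3
  r3[60, 60] <- 1
  raw_contrast <- 1 / 0.6 - 1
  hm3 <- hue_map(mk_img(r3, r3, b3), scale_um_per_px = 2)
  expect_lt(max(hm3$values), 0.1 * raw_contrast)

  expect_error(hue_map(achro), "scale_um_per_px")
  # the invert flag flips the ratio orientation
  hm4 <- hue_map(mk_img(r, r, b), scale_um_per_px = 2, invert = TRUE)
  expect_lt(mean(hm4$values[disk]), 0)
})

test_that("segmentation threshold matches the Gaussian tail and erosion prunes", {
  set.seed(3)
  noise <- mk_hue(matrix(rnorm(300 * 300), 300, 300))
  cm <- segment_clusters(noise, k = 1.4)
  expect_equal(mean(cm$pre_erosion_mask), pnorm(-1.4), tolerance = 0.01)
  expect_lt(cluster_ratio(cm), mean(cm$pre_erosion_mask) / 2)
  flat <- segment_clusters(mk_hue(matrix(1, 50, 50)))
  expect_equal(cluster_ratio(flat), 0)
})

test_that("a strong disk is segmented to within 15% of its area", {
  set.seed(4)
  v <- matrix(rnorm(200 * 200, 0, 0.01), 200, 200)
  disk <- outer((1:200 - 100)^2, (1:200 - 100)^2, "+") <= 30^2
  v[disk] <- v[disk] + 0.15
  cm <- segment_clusters(mk_hue(v), k = 1.4)
  expect_lt(abs(sum(cm$mask) - sum(disk)) / sum(disk), 0.15)
  # recall and precision against the designed disk
  expect_gt(sum(cm$mask & disk) / sum(disk), 0.85)
  expect_gt(sum(cm$mask & disk) / sum(cm$mask), 0.85)
})

test_that("cluster ratio counts mask pixels", {
  expect_equal(cluster_ratio(matrix(FALSE, 10, 10)), 0)
  expect_equal(cluster_ratio(matrix(TRUE, 10, 10)), 1)
  disk <- outer((1:100 - 50)^2, (1:100 - 50)^2, "+") <= 20^2
  expect_equal(cluster_ratio(disk), pi * 20^2 / 1e4, tolerance = 0.01)
})

test_that("first-day normalization", {
  expect_equal(normalize_cluster_ratio(c(0.1, 0.1, 0.1)), c(1, 1, 1))
  expect_equal(normalize_cluster_ratio(c(0.05, 0.1, 0.2)), c(1, 2, 4))
  expect_error(normalize_cluster_ratio(c(0, 0.1)), "zero")
})

test_that("clusterness is a local Gaussian-weighted mean around each electrode", {
  lay <- mea_layout(c("a", "b"), x = c(100, 500), y = c(100, 100))
  const <- mk_hue(matrix(0.37, 400, 400), scale = 2)
  sc <- electrode_clusterness(const, lay)
  expect_equal(unname(sc), c(0.37, 0.37))

  # content farther than the window never moves the score
  v <- matrix(0, 400, 400)
  far <- v; far[200:250, 200:250] <- 5            # ~200 um from electrode a
  expect_equal(electrode_clusterness(mk_hue(v, 2), lay)[["a"]],
               electrode_clusterness(mk_hue(far, 2), lay)[["a"]])

  # a cluster on electrode a makes it score strictly highest
  on_a <- v
  d <- sqrt(outer((1:400 * 2 - 100)^2, (1:400 * 2 - 100)^2, "+"))
  on_a[d < 40] <- 1
  sc2 <- electrode_clusterness(mk_hue(on_a, 2), lay)
  expect_gt(sc2[["a"]], sc2[["b"]])

  # electrode outside the image is flagged missing
  out <- mea_layout(c("a", "b"), x = c(100, 5000), y = c(100, 100))
  expect_true(is.na(electrode_clusterness(const, out)[["b"]]))
})
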