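test_that("threshold_mask follows the 50%-of-maximum convention", {
  m <- matrix(5, 4, 4)
  expect_true(all(threshold_mask(m)))            # constant v -> all true
  expect_false(any(threshold_mask(matrix(0, 4, 4))))   # all-zero -> empty
  two <- matrix(c(10, 100, 10, 100), 2, 2)
  expect_identical(threshold_mask(two), two == 100)
  # cell mask restricts both the reference maximum and the output
  img <- channel_image(matrix(c(100, 40, 40, 40), 2, 2), 0.07,
                       cell_mask = matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  got <- threshold_mask(img)            # max inside mask is 40
  expect_identical(got, matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  # range variant: threshold halfway up the dynamic range
  rng <- threshold_mask(matrix(c(0, 10, 4, 6), 2, 2), reference = "range")
  expect_identical(rng, matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
})

test_that("label_patches measures area, centroid and equivalent diameter", {
  px <- 0.07
  mask <- matrix(FALSE, 10, 10)
  mask[3:4, 5:6] <- TRUE                   # 4-pixel square
  p <- label_patches(mask, px, min_pixels = 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$area_um2, 4 * px^2)
  expect_equal(p$centroid_x, 5 * px)       # center of columns 5:6
  expect_equal(p$centroid_y, 3 * px)       # center of rows 3:4
  expect_equal(p$eq_diameter_um, 2 * sqrt(4 * px^2 / pi))
  # two diagonally touching pixels form one 8-connected patch
  diagm <- matrix(FALSE, 5, 5)
  diagm[2, 2] <- diagm[3, 3] <- TRUE
  expect_equal(nrow(label_patches(diagm, px, min_pixels = 1)), 1)
  # a patch of area 0.126 um^2 has equivalent diameter ~0.4005 um
  expect_equal(2 * sqrt(0.126 / pi), 0.4005, tolerance = 2e-4)
  # min_pixels filters small components
  small <- matrix(FALSE, 6, 6); small[2, 2] <- TRUE
  expect_equal(nrow(label_patches(small, px, min_pixels = 4)), 0)
})

test_that("nearest-centroid distances apply the isolation cutoff", {
  ref <- data.frame(centroid_x = 0, centroid_y = 0)
  q <- data.frame(centroid_x = c(0.3, 1), centroid_y = c(0.4, 0))
  res <- nearest_centroid_distances(ref, q, cutoff = 0.756)
  expect_equal(res$distances$distance_um, 0.5)    # 3-4-5 triangle
  expect_false(res$distances$isolated)
  expect_equal(res$n_retained, 1L)
  # coincident centroids
  res0 <- nearest_centroid_distances(ref, ref, cutoff = 0.756)
  expect_equal(res0$distances$distance_um, 0)
  expect_equal(res0$mean_um, 0)
  # a single pair beyond the cutoff is isolated, with no retained mean
  far <- data.frame(centroid_x = 0.9, centroid_y = 0)
  resf <- nearest_centroid_distances(ref, far, cutoff = 0.756)
  expect_true(resf$distances$isolated)
  expect_equal(resf$n_retained, 0L)
  expect_true(is.na(resf$mean_um))
  # empty query: all isolated, undefined mean
  empty <- data.frame(centroid_x = numeric(0), centroid_y = numeric(0))
  rese <- nearest_centroid_distances(ref, empty)
  expect_equal(rese$n_isolated, 1L)
  expect_true(is.na(rese$mean_um))
  expect_error(nearest_centroid_distances(empty, ref), "reference")
})

test_that("isolation cutoff doubles the mean equivalent diameter", {
  p <- data.frame(eq_diameter_um = c(0.4, 0.4), area_um2 = pi * 0.2^2)
  expect_equal(isolation_cutoff(p), 0.8)
  p2 <- data.frame(eq_diameter_um = c(0.2, 0.4),
                   area_um2 = pi * c(0.1, 0.2)^2)
  expect_equal(isolation_cutoff(p2), 0.6)
  expect_equal(isolation_cutoff(mean_diameter = 0.378), 0.756)
  # mean-area convention differs when diameters vary
  expect_equal(isolation_cutoff(p2, convention = "mean_area"),
               2 * 2 * sqrt(mean(pi * c(0.1, 0.2)^2) / pi))
  expect_error(isolation_cutoff(data.frame()), "patch")
})

test_that("random masks land uniformly inside the cell mask", {
  cm <- matrix(FALSE, 60, 60)
  cm[15:45, 10:50] <- TRUE
  nm <- random_mask_null(cm, n = 200, pixel_size = 0.1, seed = 7)
  expect_equal(nrow(nm$centers), 200)
  nm2 <- random_mask_null(cm, n = 200, pixel_size = 0.1, seed = 7)
  expect_identical(nm$centers, nm2$centers)      # seeded determinism
  # every center lies in a TRUE pixel
  cols <- ceiling(nm$centers$x / 0.1)
  rows <- ceiling(nm$centers$y / 0.1)
  expect_true(all(cm[cbind(rows, cols)]))
  expect_error(random_mask_null(matrix(FALSE, 5, 5), 3), "empty")
})

test_that("Pearson coefficient matches hand-computed values", {
  expect_equal(pearson_coefficient(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(pearson_coefficient(c(1, 2, 3, 4), 10 - c(1, 2, 3, 4)), -1)
  expect_equal(pearson_coefficient(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(out <- pearson_coefficient(c(1, 1, 1), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(out))
})

test_that("Manders coefficients follow their definitions", {
  r <- c(10, 10, 0); g <- c(0, 10, 10)
  expect_equal(unname(manders_coefficients(r, g, r > 0, g > 0)),
               c(0.5, 0.5))
  x <- c(3, 7, 1, 9)
  expect_equal(unname(manders_coefficients(x, x, x > 0, x > 0)), c(1, 1))
  # disjoint masks
  expect_equal(unname(manders_coefficients(
    c(5, 0), c(0, 5), c(TRUE, FALSE), c(FALSE, TRUE))), c(0, 0))
  expect_warning(out <- manders_coefficients(
    c(0, 0), c(1, 1), c(TRUE, TRUE), c(TRUE, TRUE)), "denominator")
  expect_true(is.na(out[["M1"]]))
})

test_that("coefficients are invariant under the expected rescalings", {
  set.seed(12)
  for (i in 1:5) {
    r <- runif(50); g <- r + rnorm(50, 0, 0.3)
    a <- runif(1, 0.5, 5); b <- runif(1, 0, 2)
    expect_equal(pearson_coefficient(a * r + b, g),
                 pearson_coefficient(r, g), tolerance = 1e-12)
    rm_ <- r > 0.5; gm <- g > 0.5
    m0 <- manders_coefficients(r, g, rm_, gm)
    ms <- manders_coefficients(a * r, g, rm_, gm)
    expect_equal(ms[["M1"]], m0[["M1"]], tolerance = 1e-12)
    expect_equal(ms[["M2"]], m0[["M2"]], tolerance = 1e-12)
  }
})

test_that("distance histograms bin with right-open intervals", {
  res <- list(distances = data.frame(ref_id = 1, nearest_query_id = 1,
                                     distance_um = 0.1, isolated = FALSE))
  class(res) <- "proximity_result"
  h <- distance_histogram(res, bin_width = 0.05)
  expect_equal(h$count[h$bin_lo_um == 0.10], 1L)   # 0.1 falls in [0.10,0.15)
  expect_equal(sum(h$count), 1L)
  # total count equals the retained count
  set.seed(3)
  res2 <- list(distances = data.frame(ref_id = 1:40, nearest_query_id = 1,
                                      distance_um = runif(40, 0, 0.7),
                                      isolated = rep(c(FALSE, TRUE), 20)))
  class(res2) <- "proximity_result"
  h2 <- distance_histogram(res2, 0.05)
  expect_equal(sum(h2$count), 20L)
})

test_that("uniform distances yield a flat histogram (chi-square GOF)", {
  set.seed(99)
  d <- runif(1e4, 0, 1)
  res <- list(distances = data.frame(ref_id = seq_along(d),
                                     nearest_query_id = 1,
                                     distance_um = d, isolated = FALSE))
  class(res) <- "proximity_result"
  h <- distance_histogram(res, bin_width = 0.1)
  p <- stats::chisq.test(h$count)$p.value
  expect_gt(p, 0.01)
})
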