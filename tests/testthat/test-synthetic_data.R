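test_that("scenario validation guards impossible layouts", {
  expect_error(image_scenario(n_red_paired = 20, n_green = 10), "pair")
  expect_error(image_scenario(sigma = -1), "sigma")
  expect_error(image_scenario(cell_radius = 10, size_px = 100), "fit")
})

test_that("noise-free rendering is consistent with its ground truth", {
  sc <- image_scenario(sigma = 0, n_green = 14, n_red_paired = 14,
                       n_red_isolated = 0, psf_sigma = 0,
                       noise_sd = 0, seed = 42)
  cell <- generate_cell_image(sc)
  gp <- label_patches(threshold_mask(cell$green), sc$pixel_size)
  rp <- label_patches(threshold_mask(cell$red), sc$pixel_size)
  # patch counts recovered exactly
  expect_equal(nrow(gp), sc$n_green)
  expect_equal(nrow(rp), sc$n_red_paired)
  # sigma = 0: paired centroids coincide up to pixel quantization
  pr <- nearest_centroid_distances(gp, rp, cutoff = 0.756)
  expect_true(all(pr$distances$distance_um < 0.75 * sc$pixel_size))
  # measured centroids sit within half a pixel of the true centers
  nn_g <- chromsec:::nn_dist_cpp(
    as.matrix(cell$truth$green[, c("x", "y")]),
    as.matrix(gp[, c("centroid_x", "centroid_y")]))
  expect_true(all(nn_g$distance < 0.5 * sc$pixel_size))
  # areas match the true disk areas to within one pixel's area each
  ord <- nn_g$index
  true_area <- pi * (cell$truth$green$diameter_um / 2)^2
  expect_true(all(abs(gp$area_um2[ord] - true_area) <
                  1.5 * sc$pixel_size^2 +
                  pi * cell$truth$green$diameter_um * sc$pixel_size))
})

test_that("an empty red channel stays empty without noise", {
  sc <- image_scenario(n_red_paired = 0, n_red_isolated = 0,
                       noise_sd = 0, seed = 3)
  cell <- generate_cell_image(sc)
  expect_equal(max(cell$red$intensities), 0)
  expect_equal(nrow(label_patches(threshold_mask(cell$red),
                                  sc$pixel_size)), 0)
})

test_that("identical scenario and seed give bit-identical images", {
  sc <- image_scenario(noise_sd = 0.03, psf_sigma = 0.05, seed = 17)
  a <- generate_cell_image(sc)
  b <- generate_cell_image(sc)
  expect_identical(a$green$intensities, b$green$intensities)
  expect_identical(a$red$intensities, b$red$intensities)
  expect_identical(a$truth, b$truth)
})

test_that("measured displacement lengths match the Rayleigh model", {
  # moderate-n version of the acceptance check: the mean measured
  # nearest-centroid distance approaches sigma * sqrt(pi / 2)
  sigma <- 0.2
  d <- measure_paired_distances(n_cells = 25, sigma = sigma, seed0 = 300)
  expect_gt(length(d), 300)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - sigma * sqrt(pi / 2)), 3 * se)
  # and the MLE recovers sigma reasonably at this n
  expect_equal(rayleigh_sigma_mle(d), sigma, tolerance = 0.05)
})

test_that("proximity series are paired across sigma and monotone", {
  sigmas <- c(0.05, 0.2, 0.5)
  reps <- 8
  batch <- generate_proximity_series(sigmas, reps,
                                     base = image_scenario(
                                       n_red_isolated = 0, noise_sd = 0),
                                     base_seed = 50)
  expect_length(batch, length(sigmas) * reps)
  seeds <- vapply(batch, function(s) s$seed, 0)
  expect_identical(seeds[1:reps], seeds[reps + 1:reps])   # paired seeds
  means <- vapply(seq_along(sigmas), function(i) {
    idx <- (i - 1) * reps + seq_len(reps)
    mean(unlist(lapply(batch[idx], function(sc) {
      cell <- generate_cell_image(sc)
      gp <- label_patches(threshold_mask(cell$green), sc$pixel_size)
      rp <- label_patches(threshold_mask(cell$red), sc$pixel_size)
      nearest_centroid_distances(gp, rp, cutoff = Inf)$distances$distance_um
    })))
  }, 0)
  expect_true(all(diff(means) > 0))   # stochastic ordering in sigma
})

test_that("simulator scenario pairs share channel geometry", {
  base <- sim_config(pulse_s = 0.01, n_replicates = 1)
  pairs <- generate_sim_scenarios(base, c("random", "colocalized"),
                                  seeds = 1:3)
  expect_length(pairs, 3)
  dom <- cone_domain()
  for (p in pairs) {
    expect_identical(p$random$channel_seed, p$colocalized$channel_seed)
    ch_r <- place_channels(dom, base$n_channels, seed = p$random$channel_seed)
    ch_c <- place_channels(dom, base$n_channels,
                           seed = p$colocalized$channel_seed)
    expect_identical(ch_r, ch_c)
    vr <- place_vesicles(dom, ch_r, "random", base$n_vesicles,
                         seed = p$random$seed + 1)
    vc <- place_vesicles(dom, ch_c, "colocalized", base$n_vesicles,
                         seed = p$colocalized$seed + 1)
    expect_lte(placement_distance(dom, ch_c, vc),
               placement_distance(dom, ch_r, vr))
  }
})
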