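test_that("diffusion conserves ions and respects D = 0 and dt limits", {
  dom <- cone_domain(dx = 0.1)
  set.seed(1)
  ions <- sample.int(dom$n_voxels, 200, replace = TRUE)
  expect_identical(diffusion_step(ions, dom, D = 0, dt = 1e-6), ions)
  moved <- diffusion_step(ions, dom, D = 220, dt = dom$dx^2 / (6 * 220),
                          seed = 2)
  expect_length(moved, length(ions))                    # count conserved
  expect_true(all(moved >= 1 & moved <= dom$n_voxels))  # stays inside
  expect_error(diffusion_step(ions, dom, D = 220, dt = 1), "dt too large")
})

test_that("interior random walk has the textbook mean squared displacement", {
  # moderate-size check (the full-scale version runs in the acceptance
  # suite): 2000 walkers, 300 steps, far from any wall
  dom <- box_domain(4, 4, 4, dx = 0.1)
  D <- 100
  dt <- dom$dx^2 / (6 * D) / 2          # move probability 0.5
  k <- 300
  start <- dom$id_of_cell[20, 20, 20]
  ions <- rep(start, 2000)
  set.seed(33)
  for (i in seq_len(k)) ions <- diffusion_step(ions, dom, D, dt)
  disp <- dom$centers[ions, ] - matrix(dom$centers[start, ], 2000, 3,
                                       byrow = TRUE)
  r2 <- rowSums(disp^2)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 6 * D * k * dt), 3 * se)
})

test_that("reaction step handles trivial limits", {
  dom <- box_domain(0.5, 0.5, 0.5, dx = 0.1)
  buf <- buffer_field(dom, conc_total = 500)
  ions <- rep(1L, 20)
  out0 <- reaction_step(ions, buf, dt = 0)
  expect_identical(out0$ions, ions)
  expect_identical(out0$buffer$bound, buf$bound)
  # no free buffer anywhere -> binding probability 0, nothing binds
  buf0 <- buffer_field(dom, conc_total = 0)
  out <- reaction_step(ions, buf0, dt = 1e-6, seed = 1)
  expect_identical(sort(out$ions), sort(ions))
  # conservation: free + bound constant
  out2 <- reaction_step(ions, buf, dt = 1e-6, seed = 2)
  expect_equal(length(out2$ions) + sum(out2$buffer$bound), length(ions))
  # buffer totals are immutable (immobile buffer)
  expect_identical(out2$buffer$total, buf$total)
})

test_that("vesicle step honors the stated operation order and limits", {
  dom <- box_domain(0.5, 0.5, 0.5, dx = 0.1)
  v <- make_vesicles(dom, voxels = c(1L, 2L))
  # no calcium, no bound sites: nothing can happen
  out <- vesicle_step(v, integer(0), dt = 1e-4, seed = 1)
  expect_identical(out$vesicles$state, v$state)
  expect_identical(out$ions, integer(0))
  expect_identical(out$consumed, 0L)
  # a fused vesicle is absorbing
  v2 <- v
  v2$state$fused <- c(TRUE, FALSE)
  v2$state$fusion_time <- c(0.5, NA)
  out2 <- vesicle_step(v2, rep(1L, 50), dt = 1e-5, seed = 2)
  expect_true(out2$vesicles$state$fused[1])
  expect_identical(out2$vesicles$state$sites_bound[1], 0L)
})

test_that("fully bound vesicles fuse at the published hazard", {
  dom <- box_domain(1, 1, 0.2, dx = 0.1)
  n <- 5000
  v <- make_vesicles(dom, voxels = rep(1L, n))
  v$state$sites_bound <- 3L
  dt <- 1e-4
  set.seed(4)
  out <- vesicle_step(v, integer(0), dt = dt)
  frac <- mean(out$vesicles$state$fused)
  p <- 1 - exp(-1000 * dt)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  expect_identical(out$consumed, 3L * sum(out$vesicles$state$fused))
  expect_true(all(out$vesicles$state$fusion_time[out$vesicles$state$fused]
                  == 0))
})

test_that("three free sites triple the single-site first-binding hazard", {
  # fixed local calcium: each vesicle alone in its voxel with 5 free ions;
  # with n_loc ions the per-site substep probability is
  # p = 1 - exp(-k1 n_loc dt), so P(>= 1 site binds) = 1 - (1 - p)^3
  dom <- box_domain(2, 2, 0.2, dx = 0.1)
  n <- 3000
  vox <- seq_len(n)
  v <- make_vesicles(dom, voxels = vox)
  ions <- rep(vox, each = 5)
  k1 <- 8e6 * uM_per_molecule(0.1) * 1e-6
  dt <- 2e-4                    # small probabilities, no internal substepping
  set.seed(9)
  out <- vesicle_step(v, ions, dt = dt)
  bound1 <- out$vesicles$state$sites_bound >= 1
  p1 <- 1 - exp(-k1 * 5 * dt)
  p_any <- 1 - (1 - p1)^3
  expect_lt(abs(mean(bound1) - p_any), 3 * sqrt(p_any * (1 - p_any) / n))
  expect_equal(p_any / p1, 3, tolerance = 0.02)   # hazard ratio ~ 3
})

test_that("closed-box buffer equilibrium approaches the analytic fraction", {
  # quick version of the acceptance criterion: smaller counts, looser look
  dom <- box_domain(0.7, 0.7, 0.7, dx = 0.07)
  buf <- buffer_field(dom, conc_total = 500, k_on = 5e8, Kd = 10)
  set.seed(5)
  ions <- sample.int(dom$n_voxels, 800, replace = TRUE)
  n_tot <- length(ions)
  dt <- 0.005 / (buf$k_on * 500e-6)    # per-event probabilities ~ 0.005
  st <- list(ions = ions, buffer = buf)
  for (i in 1:600) st <- reaction_step(st$ions, st$buffer, dt)
  fr <- numeric(8)
  for (j in 1:8) {
    for (i in 1:150) st <- reaction_step(st$ions, st$buffer, dt)
    fr[j] <- sum(st$buffer$bound) / n_tot
  }
  ca_tot <- n_tot * uM_per_molecule(dom$dx) / dom$n_voxels
  target <- buffer_bound_fraction_oracle(500, 10, ca_tot)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - target), 3 * max(se, 0.002))
})
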