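# Shared fixtures and independent oracles used across the test files.

# A minimal two-state gating graph (open <-> b) used to probe dwell-time
# machinery at a prescribed recovery rate without the fast transitions of
# the full scheme.
two_state_graph <- function(k_in = 5, k_out = 0.3) {
  rate_graph(states = c("open", "b"),
             edges = data.frame(from = c("open", "b"),
                                to = c("b", "open"),
                                kind = c("const", "const"),
                                value = c(k_in, k_out)),
             open_state = "open", ground_state = "open", ach_conc = 0)
}

# Independent brute-force enumeration of grid points inside the cone base
# disk (slice 0), replicating only the stated grid convention: centers at
# origin + (i - 0.5) dx with nx = ny = 2 ceiling(R / dx).
brute_force_slice0_count <- function(base_radius, height, dx) {
  n <- 2L * as.integer(ceiling(base_radius / dx))
  xs <- (-n / 2 + (seq_len(n) - 0.5)) * dx
  z <- 0.5 * dx
  rmax <- base_radius * (1 - z / height)
  count <- 0L
  for (x in xs) for (y in xs)
    if (sqrt(x^2 + y^2) <= rmax) count <- count + 1L
  count
}

# Self-consistent two-state binding equilibrium: fraction of calcium bound
# to a buffer of total concentration B_tot (uM) with dissociation constant
# Kd (uM), accounting for buffer depletion by the bound calcium itself.
buffer_bound_fraction_oracle <- function(B_tot, Kd, ca_tot) {
  f <- B_tot / (B_tot + Kd)
  for (i in 1:100) {
    B_free <- B_tot - f * ca_tot
    f <- B_free / (B_free + Kd)
  }
  f
}

# Generate pooled green->red nearest-centroid distances from zero-noise
# synthetic cells with purely paired patches (no isolated reds).
measure_paired_distances <- function(n_cells, sigma, seed0 = 100,
                                     n_pairs = 14) {
  d <- numeric(0)
  for (i in seq_len(n_cells)) {
    sc <- image_scenario(n_green = n_pairs, n_red_paired = n_pairs,
                         n_red_isolated = 0, sigma = sigma,
                         psf_sigma = 0, noise_sd = 0, seed = seed0 + i)
    cell <- generate_cell_image(sc)
    gp <- label_patches(threshold_mask(cell$green), sc$pixel_size)
    rp <- label_patches(threshold_mask(cell$red), sc$pixel_size)
    pr <- nearest_centroid_distances(gp, rp, cutoff = Inf)
    d <- c(d, pr$distances$distance_um)
  }
  d
}
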