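test_that("default rate graph carries the published gating rates", {
  g <- build_rate_graph(channel_params())
  Q <- rate_generator(g)
  expect_identical(g$states, c("C0", "C1", "C2", "O", "D", "D2", "B"))
  expect_equal(Q["C2", "O"], 50600)   # opening rate beta
  expect_equal(Q["O", "C2"], 2024)    # closing rate alpha
  expect_equal(Q["O", "D"], 49)
  expect_equal(Q["D", "O"], 512)
  expect_equal(Q["B", "O"], 0.3)
  # two-site statistical factors on the binding chain at 100 uM
  expect_equal(Q["C0", "C1"], 2 * 227 * 100)
  expect_equal(Q["C1", "C2"], 227 * 100)
  expect_equal(Q["C1", "C0"], 38541)
  expect_equal(Q["C2", "C1"], 2 * 38541)
})

test_that("generator rows sum to zero for arbitrary parameters", {
  set.seed(42)
  for (i in 1:10) {
    p <- channel_params(k_plus = runif(1, 0, 500), k_minus = runif(1, 0, 5e4),
                        alpha = runif(1, 0, 5e3), beta = runif(1, 0, 1e5),
                        k_pg = runif(1, 0, 100), k_mg = runif(1, 0, 1000),
                        k_pb = runif(1, 0, 500), k_mb = runif(1, 0, 10),
                        ach_conc = runif(1, 0, 500))
    Q <- rate_generator(build_rate_graph(p))
    expect_true(all(abs(rowSums(Q)) < 1e-9))
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
  }
})

test_that("zero agonist silences ligand-dependent edges and the channel", {
  g0 <- build_rate_graph(channel_params(ach_conc = 0))
  Q0 <- rate_generator(g0)
  expect_equal(Q0["C0", "C1"], 0)
  expect_equal(sum(Q0["C0", ]), 0)          # ground state has no exit
  expect_equal(max(abs(Q0["C0", ])), 0)
  p0 <- state_distribution(setNames(c(1, 0, 0, 0, 0, 0, 0), g0$states))
  p <- propagate_distribution(p0, g0, 10)
  expect_equal(unname(unclass(p)["O"]), 0)
  tr <- sample_ensemble(50, g0, duration = 0.1, dt = 1e-3, seed = 1)
  expect_true(all(tr$open_count == 0))
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(channel_params(alpha = -1), "rate")
  expect_error(channel_params(f_ca = 1.5), "f_ca")
  expect_error(channel_params(ach_conc = -10), "ach_conc")
  expect_error(rate_graph(c("a", "b"),
                          data.frame(from = "a", to = "b", kind = "const",
                                     value = -2),
                          open_state = "a", ground_state = "b"),
               ">= 0")
  g <- build_rate_graph(channel_params())
  expect_error(propagate_distribution(stationary_distribution(g), g, -1),
               "dt")
})

test_that("master-equation propagation conserves and reaches stationarity", {
  g <- build_rate_graph(channel_params())
  pi0 <- stationary_distribution(g)
  p0 <- state_distribution(setNames(c(1, 0, 0, 0, 0, 0, 0), g$states))
  expect_equal(unclass(propagate_distribution(p0, g, 0)), unclass(p0))
  # conservation across a random propagation sequence
  set.seed(7)
  p <- p0
  for (dt in runif(8, 0, 2)) {
    p <- propagate_distribution(p, g, dt)
    expect_lt(abs(sum(unclass(p)) - 1), 1e-9)
  }
  # distribution at t = 50 s equals the null-space stationary distribution
  p50 <- propagate_distribution(p0, g, 50)
  expect_true(all(abs(unclass(p50) - unclass(pi0)) < 1e-6))
  # the stationary distribution is a fixed point of propagation
  pfix <- propagate_distribution(pi0, g, 1.7)
  expect_true(all(abs(unclass(pfix) - unclass(pi0)) < 1e-9))
})

test_that("ensemble sampling matches the deterministic oracle", {
  # fast-mixing two-state graph: stationary occupancies from the null space
  g <- two_state_graph(k_in = 10, k_out = 5)
  pi0 <- unclass(stationary_distribution(g))
  n <- 500
  tr <- sample_ensemble(n, g, duration = 2, dt = 1e-3, seed = 11)
  expect_true(all(rowSums(tr$counts) == n))       # conservation at every step
  expect_true(all(tr$counts >= 0))
  occ <- tr$counts[nrow(tr$counts), ] / n
  se <- sqrt(pi0 * (1 - pi0) / n)
  expect_true(all(abs(occ - pi0) <= 3 * se))
})

test_that("ensemble traces are reproducible and zero-size safe", {
  g <- build_rate_graph(channel_params())
  t1 <- sample_ensemble(20, g, duration = 0.01, dt = 1e-3, seed = 5)
  t2 <- sample_ensemble(20, g, duration = 0.01, dt = 1e-3, seed = 5)
  expect_identical(t1$counts, t2$counts)
  t0 <- sample_ensemble(0, g, duration = 0.01, dt = 1e-3, seed = 5)
  expect_true(all(t0$counts == 0))
})

test_that("mean dwell time in the slow-inactivated state is 1/k_mb", {
  # one channel, open <-> b at the published k_mb = 0.3 s^-1; sojourns in b
  # are the runs of open_count == 0
  g <- two_state_graph(k_in = 5, k_out = 0.3)
  dt <- 0.005
  tr <- sample_ensemble(1, g, duration = 2000, dt = dt, seed = 21)
  r <- rle(as.integer(tr$open_count))
  dwell <- r$lengths[r$values == 0] * dt
  dwell <- dwell[-length(dwell)]   # last sojourn may be censored
  expect_gt(length(dwell), 100)
  se <- sd(dwell) / sqrt(length(dwell))
  expect_lt(abs(mean(dwell) - 1 / 0.3), 3 * se)
})

test_that("calcium influx converts open channels to ions per second", {
  p <- channel_params(i_unit = 2, f_ca = 0.025)
  expect_equal(calcium_influx_rate(0, p), 0)
  # 0.05 pA of divalent charge: 0.05e-12 / (2 * 1.602176634e-19) ions/s
  expect_equal(calcium_influx_rate(1, p), 0.05e-12 / (2 * 1.602176634e-19))
  expect_equal(calcium_influx_rate(3, p), 3 * calcium_influx_rate(1, p))
  expect_error(calcium_influx_rate(-1, p), "open_count")
})

test_that("rate graphs survive a JSON round trip", {
  g <- build_rate_graph(channel_params(), b_step = "per_uM")
  path <- tempfile(fileext = ".json")
  rate_graph_to_json(g, path)
  g2 <- rate_graph_from_json(path)
  expect_equal(rate_generator(g2), rate_generator(g))
  expect_identical(g2$open_state, g$open_state)
})

test_that("ensemble CSV export has the documented columns", {
  g <- two_state_graph()
  tr <- sample_ensemble(5, g, duration = 0.02, dt = 0.01, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_ensemble_csv(tr, path)
  d <- read.csv(path, check.names = FALSE)
  expect_identical(names(d), c("time_s", g$states, "open_count"))
  expect_equal(nrow(d), length(tr$time))
})
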