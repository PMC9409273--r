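# Configuration and driver for the coupled pulse simulation: channel gating,
# Poisson ion injection at channel voxels, buffered lattice diffusion and
# vesicle fusion kinetics in the conical domain.

#' Configuration of a secretion pulse simulation
#'
#' Collects the geometric, kinetic and numerical parameters of one
#' simulated agonist pulse. Defaults reproduce the reference scenario:
#' 7 nAChR channels on the base of a 1 um x 5 um cone discretized at 70 nm,
#' 100 uM ACh for 1 s, 500 uM immobile buffer, 220 um^2/s calcium
#' diffusion, 0.1 uM basal calcium, vesicles with three 13-uM sites fusing
#' at 1000 s^-1, averaged over five replicate simulations.
#'
#' @param n_channels number of nAChR channels on slice 0 (default 7).
#' @param n_vesicles number of vesicles on slice 0 (default 10; not a
#'   published value, and all release outputs are percentages of it).
#' @param mode `"random"` or `"colocalized"` channel-vesicle geometry.
#' @param pulse_s agonist pulse duration, s (default 1).
#' @param ach_conc ACh concentration during the pulse, uM (default 100).
#' @param D_ca calcium diffusion coefficient, um^2 s^-1 (default 220).
#' @param basal_ca basal free calcium concentration, uM (default 0.1).
#' @param buffer_conc,buffer_k_on,buffer_Kd immobile endogenous buffer:
#'   concentration (uM), forward rate (M^-1 s^-1), dissociation constant
#'   (uM). Defaults 500, 5e8, 10.
#' @param ves_k_on,ves_Kd,gamma_fuse,sites_total vesicle fusion scheme:
#'   per-site forward rate (M^-1 s^-1), per-site dissociation constant
#'   (uM), fusion rate of the fully bound vesicle (s^-1), number of sites.
#'   Defaults 8e6, 13, 1000, 3.
#' @param base_radius,height,dx cone geometry and grid spacing, um.
#' @param dt master time step, s; `NULL` (default) uses the lattice bound
#'   `dx^2 / (6 D_ca)`.
#' @param record_every_s recording interval, s (default 1e-3).
#' @param pre_equil_s buffer pre-equilibration time before the pulse, s
#'   (default 0.01).
#' @param seed integer seed for the replicate runs.
#' @param channel_seed seed controlling channel placement; paired
#'   random/colocalized configs that share `channel_seed` see identical
#'   channel positions. Defaults to `seed`.
#' @param n_replicates number of replicate simulations averaged (default 5).
#' @param params a [channel_params()] object; its `ach_conc` is overridden
#'   by `ach_conc`.
#' @param b_step slow-inactivation convention passed to
#'   [build_rate_graph()].
#' @param consumed_release if `TRUE`, fusion returns the three site-bound
#'   ions to the cytosol instead of retiring them (default `FALSE`).
#'   Currently only the default is implemented by the fused kernel.
#' @param p_max maximum per-substep event probability (default 0.1).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_channels = 7, n_vesicles = 10,
                       mode = c("random", "colocalized"),
                       pulse_s = 1, ach_conc = 100,
                       D_ca = 220, basal_ca = 0.1,
                       buffer_conc = 500, buffer_k_on = 5e8, buffer_Kd = 10,
                       ves_k_on = 8e6, ves_Kd = 13, gamma_fuse = 1000,
                       sites_total = 3,
                       base_radius = 1, height = 5, dx = 0.07,
                       dt = NULL, record_every_s = 1e-3, pre_equil_s = 0.01,
                       seed = 1, channel_seed = NULL, n_replicates = 5,
                       params = NULL, b_step = "per_M",
                       consumed_release = FALSE, p_max = 0.1) {
  mode <- match.arg(mode)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (pulse_s <= 0) stop("pulse_s must be > 0")
  if (is.null(dt)) dt <- dx^2 / (6 * D_ca)
  if (D_ca > 0 && dt > dx^2 / (6 * D_ca) + 1e-15)
    stop("dt violates the lattice bound dx^2 / (6 D)")
  if (is.null(params)) params <- channel_params(ach_conc = ach_conc)
  else params$ach_conc <- ach_conc
  if (isTRUE(consumed_release))
    stop("consumed_release = TRUE is not implemented by the fused kernel")
  cfg <- list(n_channels = n_channels, n_vesicles = n_vesicles, mode = mode,
              pulse_s = pulse_s, ach_conc = ach_conc, D_ca = D_ca,
              basal_ca = basal_ca, buffer_conc = buffer_conc,
              buffer_k_on = buffer_k_on, buffer_Kd = buffer_Kd,
              ves_k_on = ves_k_on, ves_Kd = ves_Kd,
              gamma_fuse = gamma_fuse, sites_total = sites_total,
              base_radius = base_radius, height = height, dx = dx,
              dt = dt, record_every_s = record_every_s,
              pre_equil_s = pre_equil_s, seed = seed,
              channel_seed = if (is.null(channel_seed)) seed else channel_seed,
              n_replicates = n_replicates, params = params, b_step = b_step,
              consumed_release = FALSE, p_max = p_max)
  structure(cfg, class = "sim_config")
}

#' Run a simulated agonist pulse
#'
#' Couples stochastic channel gating, Poisson-sampled calcium injection at
#' the channel voxels, buffered lattice diffusion and vesicle fusion, for
#' `n_replicates` independent replicates (each replicate re-draws geometry
#' and all stochastic events from its own seed; paired configs sharing
#' `channel_seed` re-use identical channel placements per replicate).
#'
#' @param config a [sim_config()].
#' @param domain optional pre-built [cone_domain()] matching the config
#'   (rebuilt if `NULL`).
#' @return A `sim_result` with elements `time` (s), per-replicate matrices
#'   `current_pA` (calcium current through open nAChRs), `ca_slice0_uM`
#'   (mean free calcium in the 0-`dx` membrane layer), `release_pct`
#'   (cumulative fused vesicles, % of `n_vesicles`), the replicate means
#'   (`mean_*`), a conservation `ledger`, placements and seeds.
#' @export
run_pulse <- function(config, domain = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (is.null(domain))
    domain <- cone_domain(cfg$base_radius, cfg$height, cfg$dx)
  graph <- build_rate_graph(cfg$params, b_step = cfg$b_step)
  Q <- rate_generator(graph)
  open_idx <- match(graph$open_state, graph$states)
  ground_idx <- match(graph$ground_state, graph$states)
  max_exit <- max(-diag(Q))
  n_sub_gate <- max(1L, as.integer(ceiling(max_exit * cfg$dt / cfg$p_max)))
  uMm <- uM_per_molecule(cfg$dx)
  molar_per_molecule <- uMm * 1e-6
  k1_buf <- cfg$buffer_k_on * molar_per_molecule
  b_total <- as.integer(round(cfg$buffer_conc / uMm))
  koff_buf <- cfg$buffer_k_on * cfg$buffer_Kd * 1e-6
  k1_ves <- cfg$ves_k_on * molar_per_molecule
  koff_ves <- cfg$ves_k_on * cfg$ves_Kd * 1e-6
  max_react <- max(k1_buf * b_total, koff_buf, koff_ves)
  n_sub_react <- max(1L, as.integer(ceiling(max_react * cfg$dt / cfg$p_max)))
  n_steps <- as.integer(round(cfg$pulse_s / cfg$dt))
  pre_steps <- as.integer(round(cfg$pre_equil_s / cfg$dt))
  record_every <- max(1L, as.integer(round(cfg$record_every_s / cfg$dt)))
  p_move <- min(1, 6 * cfg$D_ca * cfg$dt / cfg$dx^2)
  inj_mean <- calcium_influx_rate(1, cfg$params) * cfg$dt
  basal_lambda <- cfg$basal_ca / uMm
  n_s0 <- sum(domain$slice == 0L)
  slice0_vol_uM <- uMm / n_s0   # uM per ion averaged over the slice-0 layer

  reps <- vector("list", cfg$n_replicates)
  placements <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    channels <- place_channels(domain, cfg$n_channels,
                               seed = cfg$channel_seed + 7919L * (r - 1L))
    vesicles <- place_vesicles(domain, channels, cfg$mode, cfg$n_vesicles,
                               seed = cfg$seed + 104729L * (r - 1L) + 1L)
    set.seed(cfg$seed + 15485863L * (r - 1L) + 2L)
    out <- pulse_kernel_cpp(
      dims = as.integer(domain$dims),
      id_of_cell = as.integer(domain$id_of_cell),
      slice = domain$slice, n_voxels = domain$n_voxels,
      channels = as.integer(channels), ves_vox = as.integer(vesicles),
      Q = Q, open_state = open_idx, init_state = ground_idx,
      p_move = p_move, n_steps = n_steps, pre_steps = pre_steps,
      record_every = record_every, dt = cfg$dt,
      n_sub_react = n_sub_react, n_sub_gate = n_sub_gate,
      inj_mean_per_open_step = inj_mean,
      b_total = b_total, k1_buf = k1_buf, koff_buf = koff_buf,
      k1_ves = k1_ves, koff_ves = koff_ves, gamma_fuse = cfg$gamma_fuse,
      sites_total = as.integer(cfg$sites_total),
      basal_lambda = basal_lambda)
    n <- out$n_recorded
    reps[[r]] <- data.frame(
      time_s = out$time_s[seq_len(n)],
      open_count = out$open_count[seq_len(n)],
      current_pA = out$open_count[seq_len(n)] * cfg$params$i_unit *
        cfg$params$f_ca,
      ca_slice0_uM = out$free_slice0[seq_len(n)] * slice0_vol_uM,
      release_pct = if (cfg$n_vesicles > 0)
        100 * out$fused[seq_len(n)] / cfg$n_vesicles else
        rep(0, n),
      free_ions = out$free_ions[seq_len(n)],
      buffer_bound = out$buffer_bound[seq_len(n)],
      vesicle_bound = out$vesicle_bound[seq_len(n)],
      injected = out$injected[seq_len(n)],
      consumed = out$consumed[seq_len(n)],
      basal_placed = out$basal_placed)
    placements[[r]] <- list(channels = channels, vesicles = vesicles,
                            fusion_time = out$fusion_time)
  }
  time <- reps[[1]]$time_s
  avg <- function(col) rowMeans(vapply(reps, function(d) d[[col]],
                                       numeric(length(time))))
  structure(list(
    time = time,
    replicates = reps,
    placements = placements,
    mean_current_pA = avg("current_pA"),
    mean_ca_slice0_uM = avg("ca_slice0_uM"),
    mean_release_pct = avg("release_pct"),
    config = cfg,
    seed = cfg$seed), class = "sim_result")
}

#' Conservation ledger of a simulation replicate
#'
#' At every recorded step, ions injected plus basal ions placed must equal
#' free + buffer-bound + vesicle-bound + vesicle-consumed (integer
#' identity).
#'
#' @param result a `sim_result`.
#' @param replicate replicate index.
#' @return Data frame with the ledger columns and their residual
#'   (`imbalance`, zero when mass is conserved).
#' @export
conservation_ledger <- function(result, replicate = 1) {
  stopifnot(inherits(result, "sim_result"))
  d <- result$replicates[[replicate]]
  data.frame(time_s = d$time_s,
             sources = d$injected + d$basal_placed,
             free = d$free_ions, buffer_bound = d$buffer_bound,
             vesicle_bound = d$vesicle_bound, consumed = d$consumed,
             imbalance = (d$injected + d$basal_placed) -
               (d$free_ions + d$buffer_bound + d$vesicle_bound + d$consumed))
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> mode = ", x$config$mode,
      ", ", x$config$n_channels, " channels, ",
      x$config$n_vesicles, " vesicles, pulse ", x$config$pulse_s,
      " s, ", length(x$replicates), " replicate(s)\n",
      "  final mean release: ",
      sprintf("%.1f%%", x$mean_release_pct[length(x$mean_release_pct)]),
      "; peak mean slice-0 [Ca]: ",
      sprintf("%.3g uM", max(x$mean_ca_slice0_uM)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sim_result <- function(x, ...) {
  data.frame(time_s = x$time,
             mean_current_pA = x$mean_current_pA,
             mean_ca_slice0_uM = x$mean_ca_slice0_uM,
             mean_release_pct = x$mean_release_pct)
}

#' Write a simulation result to CSV + JSON summary
#'
#' @param result a `sim_result`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_sim_result <- function(result, dir, prefix = "pulse") {
  stopifnot(inherits(result, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_mean_timeseries.csv"))
  utils::write.csv(as.data.frame(result), f1, row.names = FALSE)
  files <- f1
  for (r in seq_along(result$replicates)) {
    fr <- file.path(dir, sprintf("%s_replicate_%02d.csv", prefix, r))
    utils::write.csv(result$replicates[[r]], fr, row.names = FALSE)
    files <- c(files, fr)
  }
  cfg <- result$config
  cfg$params <- unclass(cfg$params)
  summ <- list(config = unclass(cfg), seed = result$seed,
               final_mean_release_pct =
                 result$mean_release_pct[length(result$mean_release_pct)],
               placements = lapply(result$placements, function(p)
                 list(channels = p$channels, vesicles = p$vesicles)))
  fj <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summ, fj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, fj))
}
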