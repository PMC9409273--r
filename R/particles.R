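# Particle-level operators of the secretion simulator: lattice diffusion of
# free calcium ions, probabilistic binding/unbinding to an immobile buffer,
# and the three-site non-cooperative vesicle fusion scheme. These are the
# vectorized R reference implementations; run_pulse() couples the same
# physics in a fused C++ kernel for speed.

#' Immobile endogenous calcium buffer over a voxel domain
#'
#' The buffer is immobile: each voxel holds a constant total number of
#' binding sites derived from the bulk concentration and the voxel volume,
#' of which `bound` currently hold a calcium ion.
#'
#' @param domain a `voxel_domain`.
#' @param conc_total total buffer concentration, uM (default 500).
#' @param k_on forward binding rate, M^-1 s^-1 (default 5e8).
#' @param Kd dissociation constant, uM (default 10); the unbinding rate is
#'   `k_off = k_on * Kd`.
#' @return A `buffer_field` with integer vectors `total` and `bound` (one
#'   entry per voxel).
#' @export
buffer_field <- function(domain, conc_total = 500, k_on = 5e8, Kd = 10) {
  stopifnot(inherits(domain, "voxel_domain"))
  if (conc_total < 0 || k_on < 0 || Kd < 0)
    stop("buffer parameters must be >= 0")
  per_voxel <- as.integer(round(conc_total / uM_per_molecule(domain$dx)))
  structure(list(total = rep(per_voxel, domain$n_voxels),
                 bound = integer(domain$n_voxels),
                 k_on = k_on, Kd = Kd, k_off = k_on * Kd * 1e-6,
                 dx = domain$dx),
            class = "buffer_field")
}

#' Secretory vesicles with three calcium binding sites
#'
#' Each vesicle occupies one membrane voxel, senses only that voxel's free
#' calcium, and fuses irreversibly once all three non-cooperative sites are
#' occupied.
#'
#' @param domain a `voxel_domain`.
#' @param voxels integer voxel ids (see [place_vesicles()]).
#' @param k_on per-site forward binding rate, M^-1 s^-1 (default 8e6).
#' @param Kd per-site dissociation constant, uM (default 13).
#' @param gamma_fuse fusion rate of a fully bound vesicle, s^-1
#'   (default 1000).
#' @param sites_total binding sites per vesicle (default 3).
#' @return A `vesicle_set`: data frame `state` plus kinetic parameters.
#' @export
make_vesicles <- function(domain, voxels, k_on = 8e6, Kd = 13,
                          gamma_fuse = 1000, sites_total = 3L) {
  stopifnot(inherits(domain, "voxel_domain"))
  if (k_on < 0 || Kd < 0 || gamma_fuse < 0) stop("rates must be >= 0")
  structure(list(
    state = data.frame(voxel = as.integer(voxels),
                       sites_bound = 0L, fused = FALSE, fusion_time = NA_real_),
    sites_total = as.integer(sites_total),
    k_on = k_on, Kd = Kd, k_off = k_on * Kd * 1e-6,
    gamma_fuse = gamma_fuse, dx = domain$dx),
    class = "vesicle_set")
}

# number of internal substeps so every per-event probability stays <= p_max
.n_substeps <- function(max_rate, dt, p_max) {
  n <- max(1L, as.integer(ceiling(max_rate * dt / p_max)))
  if (n > 1e6) stop("probability overflow: dt needs more than 1e6 substeps")
  n
}

#' One lattice diffusion step for free calcium ions
#'
#' Each ion attempts one move to a uniformly chosen face neighbor with
#' probability `6 D dt / dx^2`; moves whose target voxel lies outside the
#' domain are bounced (the ion stays put), so the ion count is conserved.
#' `dt` must satisfy the lattice stability bound `dt <= dx^2 / (6 D)`.
#'
#' @param ions integer vector of voxel ids (one entry per free ion).
#' @param domain a `voxel_domain`.
#' @param D diffusion coefficient, um^2 s^-1.
#' @param dt time step, s.
#' @param seed optional integer seed.
#' @return Integer vector of updated voxel ids.
#' @export
diffusion_step <- function(ions, domain, D, dt, seed = NULL) {
  stopifnot(inherits(domain, "voxel_domain"))
  if (D < 0 || dt < 0) stop("D and dt must be >= 0")
  if (D > 0 && dt > domain$dx^2 / (6 * D) + 1e-15)
    stop("dt too large: lattice bound requires dt <= dx^2 / (6 D)")
  n <- length(ions)
  if (n == 0 || D == 0 || dt == 0) return(ions)
  if (!is.null(seed)) set.seed(seed)
  p_move <- 6 * D * dt / domain$dx^2
  move <- stats::runif(n) < p_move
  if (!any(move)) return(ions)
  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]; nz <- domain$dims[["nz"]]
  cells <- which(domain$mask)   # linear cell index per voxel id
  idx <- cells[ions[move]] - 1L
  i <- idx %% nx; j <- (idx %/% nx) %% ny; k <- idx %/% (nx * ny)
  dir <- sample.int(6L, sum(move), replace = TRUE)
  di <- c(1L, -1L, 0L, 0L, 0L, 0L)[dir]
  dj <- c(0L, 0L, 1L, -1L, 0L, 0L)[dir]
  dk <- c(0L, 0L, 0L, 0L, 1L, -1L)[dir]
  ii <- i + di; jj <- j + dj; kk <- k + dk
  ok <- ii >= 0L & ii < nx & jj >= 0L & jj < ny & kk >= 0L & kk < nz
  tgt <- rep(0L, length(ii))
  tgt[ok] <- domain$id_of_cell[cbind(ii[ok] + 1L, jj[ok] + 1L, kk[ok] + 1L)]
  ok <- ok & tgt > 0L                 # outside-cone moves bounce
  out <- ions
  moved <- which(move)[ok]
  out[moved] <- tgt[ok]
  out
}

#' One buffer reaction step (binding and unbinding)
#'
#' First-order kinetics with a probabilistic per-event interpretation: over
#' a substep `dt_s`, a free ion in voxel `v` binds with probability
#' `1 - exp(-k_on [B_free]_v dt_s)` and each occupied buffer site releases
#' with probability `1 - exp(-k_off dt_s)`. Concentrations are computed
#' from integer counts and the voxel volume. The requested `dt` is
#' subdivided so all per-event probabilities stay below `p_max`.
#'
#' @param ions integer vector of voxel ids of free ions.
#' @param buffer a [buffer_field()].
#' @param dt time step, s.
#' @param seed optional integer seed.
#' @param p_max maximum per-substep event probability (default 0.1).
#' @return List with updated `ions` and `buffer`.
#' @export
reaction_step <- function(ions, buffer, dt, seed = NULL, p_max = 0.1) {
  stopifnot(inherits(buffer, "buffer_field"))
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(list(ions = ions, buffer = buffer))
  if (!is.null(seed)) set.seed(seed)
  molar_per_molecule <- uM_per_molecule(buffer$dx) * 1e-6
  k1 <- buffer$k_on * molar_per_molecule     # s^-1 per free buffer molecule
  max_rate <- max(k1 * max(buffer$total), buffer$k_off)
  n_sub <- .n_substeps(max_rate, dt, p_max)
  dt_s <- dt / n_sub
  q_off <- 1 - exp(-buffer$k_off * dt_s)
  bound <- buffer$bound
  total <- buffer$total
  for (s in seq_len(n_sub)) {
    # binding
    if (length(ions)) {
      b_free <- total[ions] - bound[ions]
      p <- 1 - exp(-k1 * b_free * dt_s)
      hit <- stats::runif(length(ions)) < p
      if (any(hit)) {
        # cap at available free sites per voxel (relevant only near saturation)
        vox_hit <- ions[hit]
        cnt <- table(vox_hit)
        over <- as.integer(names(cnt))[as.integer(cnt) >
                                         (total[as.integer(names(cnt))] -
                                          bound[as.integer(names(cnt))])]
        if (length(over)) {
          for (v in over) {
            at <- which(hit & ions == v)
            keep <- seq_len(total[v] - bound[v])
            hit[at[-keep]] <- FALSE
          }
          vox_hit <- ions[hit]
        }
        add <- tabulate(vox_hit, nbins = length(bound))
        bound <- bound + add
        ions <- ions[!hit]
      }
    }
    # unbinding
    occ <- which(bound > 0L)
    if (length(occ)) {
      rel <- stats::rbinom(length(occ), bound[occ], q_off)
      nz <- rel > 0L
      if (any(nz)) {
        bound[occ[nz]] <- bound[occ[nz]] - rel[nz]
        ions <- c(ions, rep(occ[nz], rel[nz]))
      }
    }
  }
  buffer$bound <- bound
  list(ions = ions, buffer = buffer)
}

#' One vesicle kinetics step (fusion, site unbinding, site binding)
#'
#' Operation order within the step, applied to the state at entry:
#' \enumerate{
#'   \item a vesicle with all sites bound fuses with probability
#'     `1 - exp(-gamma_fuse * dt)` (absorbing; its bound ions are retired
#'     from the ledger as "vesicle-consumed", releasing no calcium);
#'   \item each bound site releases its ion into the vesicle's voxel with
#'     probability `1 - exp(-k_off dt_s)` per substep;
#'   \item each free site binds with probability
#'     `1 - exp(-k_on [Ca]_voxel dt_s)` per substep, consuming one free ion
#'     from the vesicle's voxel.
#' }
#'
#' @param vesicles a [make_vesicles()] object.
#' @param ions integer vector of free-ion voxel ids.
#' @param dt time step, s.
#' @param seed optional integer seed.
#' @param time simulation time at the start of the step (stamped on
#'   fusions), s.
#' @param p_max maximum per-substep event probability.
#' @return List with updated `vesicles`, `ions`, and `consumed` (number of
#'   ions retired by fusions during this step).
#' @export
vesicle_step <- function(vesicles, ions, dt, seed = NULL, time = 0,
                         p_max = 0.1) {
  stopifnot(inherits(vesicles, "vesicle_set"))
  if (dt < 0) stop("dt must be >= 0")
  st <- vesicles$state
  if (dt == 0 || nrow(st) == 0)
    return(list(vesicles = vesicles, ions = ions, consumed = 0L))
  if (!is.null(seed)) set.seed(seed)
  consumed <- 0L
  # 1) fusion, evaluated on the entry state at the full dt
  p_fuse <- 1 - exp(-vesicles$gamma_fuse * dt)
  ready <- which(!st$fused & st$sites_bound == vesicles$sites_total)
  if (length(ready)) {
    fuse <- ready[stats::runif(length(ready)) < p_fuse]
    if (length(fuse)) {
      consumed <- consumed + sum(st$sites_bound[fuse])
      st$sites_bound[fuse] <- 0L
      st$fused[fuse] <- TRUE
      st$fusion_time[fuse] <- time
    }
  }
  # 2) + 3) site kinetics, substepped
  molar_per_ion <- uM_per_molecule(vesicles$dx) * 1e-6
  k1 <- vesicles$k_on * molar_per_ion   # s^-1 per free ion in the voxel
  n_sub <- .n_substeps(max(vesicles$k_off, k1), dt, p_max)
  dt_s <- dt / n_sub
  q_off <- 1 - exp(-vesicles$k_off * dt_s)
  for (s in seq_len(n_sub)) {
    live <- which(!st$fused)
    if (!length(live)) break
    # unbinding: independent Bernoulli per bound site
    nb <- st$sites_bound[live]
    has <- live[nb > 0L]
    if (length(has)) {
      rel <- stats::rbinom(length(has), st$sites_bound[has], q_off)
      nz <- rel > 0L
      if (any(nz)) {
        st$sites_bound[has[nz]] <- st$sites_bound[has[nz]] - rel[nz]
        ions <- c(ions, rep(st$voxel[has[nz]], rel[nz]))
      }
    }
    # binding: independent Bernoulli per free site, limited by local ions
    free_ct <- tabulate(ions, nbins = max(c(st$voxel, ions, 1L)))
    for (i in live) {
      nfree_sites <- vesicles$sites_total - st$sites_bound[i]
      if (nfree_sites == 0L) next
      n_loc <- free_ct[st$voxel[i]]
      if (n_loc == 0L) next
      p <- 1 - exp(-k1 * n_loc * dt_s)
      nbind <- sum(stats::runif(nfree_sites) < p)
      nbind <- min(nbind, n_loc)
      if (nbind > 0L) {
        st$sites_bound[i] <- st$sites_bound[i] + nbind
        at <- which(ions == st$voxel[i])[seq_len(nbind)]
        ions <- ions[-at]
        free_ct[st$voxel[i]] <- free_ct[st$voxel[i]] - nbind
      }
    }
  }
  vesicles$state <- st
  list(vesicles = vesicles, ions = ions, consumed = consumed)
}
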