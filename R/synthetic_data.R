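# Synthetic two-channel cortical-plane images with known ground truth:
# green secretory ("DBH-like") disk patches and red receptor ("nAChR-like")
# patches displaced from them by an isotropic Gaussian, plus isolated red
# patches and imaging noise. Used to validate every stage of the proximity
# and colocalization pipeline without experimental data.

#' Scenario for a synthetic two-channel cell image
#'
#' @param size_px image side length in pixels (square image).
#' @param pixel_size um per pixel (default 0.07, matching the simulator
#'   grid constant).
#' @param cell_radius cell disk radius, um.
#' @param n_green number of green (secretory) patches.
#' @param n_red_paired number of red (receptor) patches paired to green
#'   ones.
#' @param n_red_isolated number of unpaired red patches, placed at least
#'   `isolation_min_um` from every green patch.
#' @param green_diam_mean,green_diam_sd green patch diameter mean / SD, um
#'   (defaults 0.378 / 0.020).
#' @param red_diam_mean,red_diam_sd red patch diameter mean / SD, um
#'   (defaults 0.397 / 0.021).
#' @param sigma scale of the isotropic Gaussian displacement from a green
#'   patch to its paired red patch, um (so displacement lengths are
#'   Rayleigh(sigma), mean `sigma * sqrt(pi / 2)`).
#' @param isolation_min_um minimum distance of isolated red patches from
#'   green patches (default 0.756, the pipeline's isolation cutoff).
#' @param psf_sigma Gaussian blur SD emulating the point-spread function,
#'   um (0 = none).
#' @param noise_sd additive Gaussian noise SD, as a fraction of the patch
#'   amplitude (0 = none).
#' @param poisson_noise logical; also apply Poisson photon noise.
#' @param amplitude peak patch intensity in arbitrary units.
#' @param min_separation minimum center separation between same-channel
#'   patches, um; `NULL` = 1.2x the mean diameter (keeps patches from
#'   merging so ground truth and labeling stay comparable).
#' @param seed integer seed.
#' @return An `image_scenario` list.
#' @export
image_scenario <- function(size_px = 192, pixel_size = 0.07,
                           cell_radius = 6,
                           n_green = 14, n_red_paired = 12,
                           n_red_isolated = 2,
                           green_diam_mean = 0.378, green_diam_sd = 0.020,
                           red_diam_mean = 0.397, red_diam_sd = 0.021,
                           sigma = 0.2, isolation_min_um = 0.756,
                           psf_sigma = 0, noise_sd = 0,
                           poisson_noise = FALSE,
                           amplitude = 1000, min_separation = NULL,
                           seed = 1) {
  if (any(c(n_green, n_red_paired, n_red_isolated) < 0))
    stop("patch counts must be >= 0")
  if (n_red_paired > n_green)
    stop("cannot pair more red patches than green patches")
  if (sigma < 0 || psf_sigma < 0 || noise_sd < 0)
    stop("sigma, psf_sigma and noise_sd must be >= 0")
  if (cell_radius * 2 >= size_px * pixel_size)
    stop("cell does not fit in the image")
  if (is.null(min_separation))
    min_separation <- 1.2 * max(green_diam_mean, red_diam_mean)
  structure(as.list(environment()), class = "image_scenario")
}

# rejection-sample n points uniformly in a disk, pairwise >= min_sep apart
# and >= margin from the disk edge; errors out when the cell is too crowded
.sample_disk_points <- function(n, radius, margin, min_sep, center,
                                max_iter = 20000) {
  pts <- matrix(numeric(0), 0, 2)
  it <- 0
  while (nrow(pts) < n) {
    if ((it <- it + 1) > max_iter)
      stop("patches cannot fit: cell too small for the requested layout")
    r <- (radius - margin) * sqrt(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    p <- center + r * c(cos(a), sin(a))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep)
      pts <- rbind(pts, p)
  }
  pts
}

# separable Gaussian blur of a matrix, sigma in pixels
.gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(v) {  # replicate-pad 1D convolution
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(t(m2), 2, pad_conv))
}

# render anti-aliased filled disks onto a matrix (pixel value ~ coverage)
.render_disks <- function(size_px, pixel_size, centers, diameters,
                          amplitude) {
  img <- matrix(0, size_px, size_px)
  if (is.null(centers) || nrow(centers) == 0) return(img)
  for (i in seq_len(nrow(centers))) {
    r <- diameters[i] / 2
    cx <- centers[i, 1]; cy <- centers[i, 2]
    jr <- max(1L, floor((cx - r) / pixel_size)):
      min(size_px, ceiling((cx + r) / pixel_size + 1))
    ir <- max(1L, floor((cy - r) / pixel_size)):
      min(size_px, ceiling((cy + r) / pixel_size + 1))
    px <- (jr - 0.5) * pixel_size
    py <- (ir - 0.5) * pixel_size
    dist <- sqrt(outer(py - cy, px - cx, function(a, b) a^2 + b^2))
    cov <- pmin(1, pmax(0, (r - dist) / pixel_size + 0.5))
    img[ir, jr] <- pmax(img[ir, jr], amplitude * cov)
  }
  img
}

#' Generate a synthetic two-channel cell image with ground truth
#'
#' Renders a disk-shaped cell containing green secretory patches, paired
#' red receptor patches at Gaussian-displaced positions, unpaired
#' ("isolated") red patches, then applies PSF blur and noise. The
#' generating parameters are returned alongside the image so that every
#' measured statistic can be checked against its known truth.
#'
#' @param scenario an [image_scenario()].
#' @return List with `green`, `red` ([channel_image()] objects sharing a
#'   cell mask) and `truth` (list of `green`, `red` patch tables and the
#'   `pairs` displacement table).
#' @export
generate_cell_image <- function(scenario) {
  stopifnot(inherits(scenario, "image_scenario"))
  s <- scenario
  set.seed(s$seed)
  side_um <- s$size_px * s$pixel_size
  center <- c(side_um / 2, side_um / 2)
  margin <- max(s$green_diam_mean, s$red_diam_mean)   # keep patches inside

  gcent <- .sample_disk_points(s$n_green, s$cell_radius, margin,
                               s$min_separation, center)
  gdiam <- pmax(4 * s$pixel_size,
                stats::rnorm(s$n_green, s$green_diam_mean, s$green_diam_sd))
  rdiam_all <- pmax(4 * s$pixel_size,
                    stats::rnorm(s$n_red_paired + s$n_red_isolated,
                                 s$red_diam_mean, s$red_diam_sd))
  # paired red patches: Gaussian displacement, resampled to stay in the cell
  pair_idx <- if (s$n_red_paired > 0) seq_len(s$n_red_paired) else integer(0)
  rcent <- matrix(numeric(0), 0, 2)
  disp <- matrix(numeric(0), 0, 2)
  for (i in pair_idx) {
    repeat {
      d <- stats::rnorm(2, 0, s$sigma)
      p <- gcent[i, ] + d
      if (sqrt(sum((p - center)^2)) <= s$cell_radius - margin) break
    }
    rcent <- rbind(rcent, p)
    disp <- rbind(disp, d)
  }
  # isolated red patches: uniform, far from every green patch
  n_iso <- s$n_red_isolated
  iso <- 0
  it <- 0
  while (iso < n_iso) {
    if ((it <- it + 1) > 20000)
      stop("patches cannot fit: no room for isolated red patches")
    r <- (s$cell_radius - margin) * sqrt(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    p <- center + r * c(cos(a), sin(a))
    dg <- min(sqrt((gcent[, 1] - p[1])^2 + (gcent[, 2] - p[2])^2))
    dr <- if (nrow(rcent)) min(sqrt((rcent[, 1] - p[1])^2 +
                                    (rcent[, 2] - p[2])^2)) else Inf
    if (dg >= s$isolation_min_um && dr >= s$min_separation) {
      rcent <- rbind(rcent, p)
      iso <- iso + 1
    }
  }
  g_img <- .render_disks(s$size_px, s$pixel_size, gcent, gdiam, s$amplitude)
  r_img <- .render_disks(s$size_px, s$pixel_size, rcent, rdiam_all,
                         s$amplitude)
  blur_px <- s$psf_sigma / s$pixel_size
  g_img <- .gaussian_blur(g_img, blur_px)
  r_img <- .gaussian_blur(r_img, blur_px)
  if (s$poisson_noise) {
    g_img <- matrix(stats::rpois(length(g_img), pmax(g_img, 0)),
                    nrow(g_img))
    r_img <- matrix(stats::rpois(length(r_img), pmax(r_img, 0)),
                    nrow(r_img))
  }
  if (s$noise_sd > 0) {
    g_img <- g_img + stats::rnorm(length(g_img), 0,
                                  s$noise_sd * s$amplitude)
    r_img <- r_img + stats::rnorm(length(r_img), 0,
                                  s$noise_sd * s$amplitude)
  }
  g_img <- pmax(g_img, 0); r_img <- pmax(r_img, 0)

  jj <- matrix((seq_len(s$size_px) - 0.5) * s$pixel_size,
               s$size_px, s$size_px, byrow = TRUE)
  ii <- matrix((seq_len(s$size_px) - 0.5) * s$pixel_size,
               s$size_px, s$size_px)
  cell_mask <- (jj - center[1])^2 + (ii - center[2])^2 <= s$cell_radius^2

  truth <- list(
    green = data.frame(id = seq_len(s$n_green), x = gcent[, 1],
                       y = gcent[, 2], diameter_um = gdiam),
    red = data.frame(id = seq_len(nrow(rcent)), x = rcent[, 1],
                     y = rcent[, 2], diameter_um = rdiam_all,
                     paired = seq_len(nrow(rcent)) <= s$n_red_paired),
    pairs = if (s$n_red_paired > 0)
      data.frame(green_id = pair_idx, red_id = pair_idx,
                 dx = disp[, 1], dy = disp[, 2],
                 distance_um = sqrt(disp[, 1]^2 + disp[, 2]^2))
    else data.frame(green_id = integer(0), red_id = integer(0),
                    dx = numeric(0), dy = numeric(0),
                    distance_um = numeric(0)))
  list(green = channel_image(g_img, s$pixel_size, "green", cell_mask),
       red = channel_image(r_img, s$pixel_size, "red", cell_mask),
       truth = truth, scenario = s)
}

#' Batch of scenarios across displacement scales
#'
#' Generates `reps` scenarios per displacement scale sigma, with seeds
#' fixed per replicate so that comparisons across sigma are paired.
#'
#' @param sigmas increasing vector of displacement scales, um.
#' @param reps replicates per sigma.
#' @param base a template [image_scenario()]; its `sigma` and `seed` are
#'   overridden.
#' @param base_seed first replicate seed.
#' @return List of `image_scenario` objects of length
#'   `length(sigmas) * reps`, with attributes `sigma` and `rep` per entry.
#' @export
generate_proximity_series <- function(sigmas, reps,
                                      base = image_scenario(),
                                      base_seed = 1) {
  if (is.unsorted(sigmas)) stop("sigmas must be sorted increasing")
  out <- list()
  for (si in seq_along(sigmas)) {
    for (r in seq_len(reps)) {
      sc <- base
      sc$sigma <- sigmas[si]
      sc$seed <- base_seed + r - 1    # same seed across sigmas: paired
      attr(sc, "sigma") <- sigmas[si]
      attr(sc, "rep") <- r
      out[[length(out) + 1]] <- sc
    }
  }
  out
}

#' Paired simulator scenario batch (random vs. colocalized)
#'
#' For each seed, produces one config per requested geometry mode, sharing
#' the channel-placement seed so that the vesicle geometry is the only
#' difference within a pair.
#'
#' @param base a [sim_config()] template.
#' @param modes character vector of geometry modes.
#' @param seeds integer vector of seeds (one pair per seed).
#' @return List (one element per seed) of lists of `sim_config`s.
#' @export
generate_sim_scenarios <- function(base = sim_config(),
                                   modes = c("random", "colocalized"),
                                   seeds = 1:5) {
  stopifnot(inherits(base, "sim_config"))
  modes <- match.arg(modes, c("random", "colocalized"), several.ok = TRUE)
  lapply(seeds, function(s) {
    stats::setNames(lapply(modes, function(m) {
      cfg <- unclass(base)
      cfg$mode <- m
      cfg$seed <- s
      cfg$channel_seed <- s
      structure(cfg, class = "sim_config")
    }), modes)
  })
}

#' Maximum-likelihood Rayleigh scale from displacement lengths
#'
#' The MLE of the Rayleigh scale sigma given lengths `d` is
#' `sqrt(sum(d^2) / (2 n))`; the mean displacement length is
#' `sigma * sqrt(pi / 2)`.
#'
#' @param d non-negative displacement lengths.
#' @return The estimated sigma.
#' @export
rayleigh_sigma_mle <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no distances supplied")
  if (any(d < 0)) stop("distances must be >= 0")
  sqrt(sum(d^2) / (2 * length(d)))
}
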