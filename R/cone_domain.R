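# Discretized simulation domains. The production domain is a cone whose base
# represents the plasma membrane; an axis-aligned box domain is provided for
# free-diffusion checks far from walls. Both share the "voxel_domain" class:
# a regular orthogonal grid of spacing dx clipped by an inside predicate.

.make_voxel_domain <- function(inside, nx, ny, nz, dx, origin, kind, meta) {
  # voxel centers: x = origin[1] + (i - 0.5) dx for i in 1..nx, etc.
  xs <- origin[1] + (seq_len(nx) - 0.5) * dx
  ys <- origin[2] + (seq_len(ny) - 0.5) * dx
  zs <- origin[3] + (seq_len(nz) - 0.5) * dx
  ctr <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  mask <- inside(ctr$x, ctr$y, ctr$z)
  dim(mask) <- c(nx, ny, nz)
  id_of_cell <- array(0L, c(nx, ny, nz))
  id_of_cell[mask] <- seq_len(sum(mask))
  keep <- which(mask)
  centers <- as.matrix(ctr[keep, , drop = FALSE])
  rownames(centers) <- NULL
  slice <- as.integer((keep - 1L) %/% (nx * ny))  # 0-based z slice
  structure(list(dx = dx, dims = c(nx = nx, ny = ny, nz = nz),
                 origin = origin, mask = mask, id_of_cell = id_of_cell,
                 centers = centers, slice = slice,
                 n_voxels = length(keep), kind = kind, meta = meta),
            class = "voxel_domain")
}

#' Discretize a conical sub-membrane domain
#'
#' Builds a regular orthogonal 3D grid of spacing `dx` clipped to a cone
#' whose base (slice 0) represents the plasma membrane and whose apex points
#' into the cell interior. A voxel belongs to the domain when its center
#' satisfies the cone inequality `r(z) <= base_radius * (1 - z / height)`.
#'
#' @param base_radius radius of the membrane-side base, um (default 1).
#' @param height height of the cone, um (default 5).
#' @param dx grid spacing, um (default 0.07). Must satisfy `0 < dx <
#'   base_radius`.
#' @return A `voxel_domain` with fields `centers` (um), `slice` (0 = base),
#'   `mask`, `n_voxels`, `dx`.
#' @export
#' @examples
#' dom <- cone_domain()
#' sum(dom$slice == 0)   # membrane voxels
cone_domain <- function(base_radius = 1, height = 5, dx = 0.07) {
  if (!is.finite(dx) || dx <= 0) stop("dx must be > 0")
  if (!is.finite(base_radius) || !is.finite(height) ||
      base_radius <= 0 || height <= 0)
    stop("degenerate geometry: base_radius and height must be > 0")
  if (dx >= base_radius)
    stop("degenerate grid: dx must be smaller than base_radius")
  nx <- ny <- 2L * as.integer(ceiling(base_radius / dx))
  nz <- as.integer(ceiling(height / dx))
  origin <- c(-nx / 2 * dx, -ny / 2 * dx, 0)
  inside <- function(x, y, z)
    sqrt(x^2 + y^2) <= base_radius * (1 - z / height) & z < height
  .make_voxel_domain(inside, nx, ny, nz, dx, origin, "cone",
                     list(base_radius = base_radius, height = height))
}

#' Discretize an axis-aligned box domain
#'
#' Convenience domain (same voxel bookkeeping as [cone_domain()]) used for
#' property checks that need particles far away from any wall.
#'
#' @param lx,ly,lz box edge lengths, um.
#' @param dx grid spacing, um.
#' @return A `voxel_domain`.
#' @export
box_domain <- function(lx, ly, lz, dx) {
  if (!is.finite(dx) || dx <= 0) stop("dx must be > 0")
  if (min(lx, ly, lz) <= 0) stop("degenerate geometry")
  nx <- as.integer(ceiling(lx / dx)); ny <- as.integer(ceiling(ly / dx))
  nz <- as.integer(ceiling(lz / dx))
  origin <- c(-nx / 2 * dx, -ny / 2 * dx, 0)
  .make_voxel_domain(function(x, y, z) rep(TRUE, length(x)),
                     nx, ny, nz, dx, origin, "box",
                     list(lx = lx, ly = ly, lz = lz))
}

#' @export
print.voxel_domain <- function(x, ...) {
  cat("<voxel_domain:", x$kind, "> ", x$n_voxels, " voxels, dx = ",
      x$dx, " um, grid ", paste(x$dims, collapse = "x"), "\n", sep = "")
  invisible(x)
}

# map voxel ids (1..n_voxels) to 0-based (i,j,k) cell coordinates
.voxel_cells <- function(domain) {
  keep <- which(domain$mask) - 1L
  nx <- domain$dims[["nx"]]; ny <- domain$dims[["ny"]]
  cbind(i = keep %% nx,
        j = (keep %/% nx) %% ny,
        k = keep %/% (nx * ny))
}

#' Place nAChR channels on the membrane slice of a domain
#'
#' Channels occupy distinct voxels of slice 0 (the base of the cone),
#' sampled uniformly without replacement.
#'
#' @param domain a `voxel_domain`.
#' @param n_channels number of channels; must not exceed the slice-0 voxel
#'   count.
#' @param seed optional integer seed.
#' @return Integer vector of voxel ids (length `n_channels`).
#' @export
place_channels <- function(domain, n_channels = 7, seed = NULL) {
  stopifnot(inherits(domain, "voxel_domain"))
  base <- which(domain$slice == 0L)
  if (n_channels < 0) stop("n_channels must be >= 0")
  if (n_channels > length(base))
    stop("too many channels: slice 0 has only ", length(base), " voxels")
  if (!is.null(seed)) set.seed(seed)
  sort(sample(base, n_channels, replace = FALSE))
}

#' Place secretory vesicles on the membrane slice
#'
#' Vesicles occupy distinct slice-0 voxels not already taken by channels.
#' In `"random"` mode the voxels are drawn uniformly; in `"colocalized"`
#' mode the available voxels closest (Euclidean distance between voxel
#' centers) to any channel are taken greedily, with ties broken in a
#' seed-reproducible random order.
#'
#' @param domain a `voxel_domain`.
#' @param channels integer vector of channel voxel ids (see
#'   [place_channels()]).
#' @param mode `"random"` or `"colocalized"`.
#' @param n_vesicles number of vesicles.
#' @param seed optional integer seed.
#' @return Integer vector of vesicle voxel ids.
#' @export
place_vesicles <- function(domain, channels, mode = c("random", "colocalized"),
                           n_vesicles = 10, seed = NULL) {
  stopifnot(inherits(domain, "voxel_domain"))
  mode <- match.arg(mode)
  avail <- setdiff(which(domain$slice == 0L), channels)
  if (n_vesicles < 0) stop("n_vesicles must be >= 0")
  if (n_vesicles > length(avail))
    stop("capacity exceeded: only ", length(avail),
         " free slice-0 voxels available")
  if (n_vesicles == 0) return(integer(0))
  if (!is.null(seed)) set.seed(seed)
  if (mode == "random") return(sort(sample(avail, n_vesicles)))
  if (length(channels) == 0)
    stop("colocalized mode requires at least one channel")
  ca <- domain$centers[avail, c("x", "y"), drop = FALSE]
  cc <- domain$centers[channels, c("x", "y"), drop = FALSE]
  d2 <- vapply(seq_len(nrow(cc)), function(i)
    (ca[, 1] - cc[i, 1])^2 + (ca[, 2] - cc[i, 2])^2, numeric(nrow(ca)))
  dmin <- if (is.matrix(d2)) do.call(pmin, as.data.frame(d2)) else d2
  ord <- order(dmin, stats::runif(length(dmin)))
  sort(avail[ord[seq_len(n_vesicles)]])
}

#' Mean vesicle-to-nearest-channel distance of a placement
#'
#' @param domain a `voxel_domain`.
#' @param channels,vesicles voxel-id vectors.
#' @return Mean Euclidean XY distance (um).
#' @export
placement_distance <- function(domain, channels, vesicles) {
  cv <- domain$centers[vesicles, c("x", "y"), drop = FALSE]
  cc <- domain$centers[channels, c("x", "y"), drop = FALSE]
  dmin <- vapply(seq_len(nrow(cv)), function(i)
    sqrt(min((cc[, 1] - cv[i, 1])^2 + (cc[, 2] - cv[i, 2])^2)), 0)
  mean(dmin)
}
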