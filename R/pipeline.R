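# End-to-end workflows: the proximity / colocalization study over a batch
# of (synthetic or supplied) two-channel cell images, and the paired
# random-vs-colocalized secretion study. Both write plain-text artifacts
# plus a run manifest sufficient to reproduce all stochastic outputs.

#' Proximity and colocalization study over a batch of cell images
#'
#' For each cell: threshold both channels at 50% of the within-cell
#' maximum, extract patches, measure green-to-nearest-red centroid
#' distances with the isolation cutoff, repeat against a matched
#' random-mask null (as many masks as real red patches, mask diameter =
#' mean red patch diameter), and compute whole-cell Pearson / Manders
#' coefficients on the thresholded channels. Cell-level real and null
#' means are then compared with a one-sided paired Wilcoxon test.
#'
#' @param cells list of cells; each cell is either a list with elements
#'   `green` and `red` ([channel_image()] objects) or an
#'   [image_scenario()] (rendered via [generate_cell_image()]).
#' @param cutoff isolation cutoff, um, or `"auto"` (twice the mean green
#'   patch diameter pooled over cells).
#' @param null_diameter random mask diameter, um, or `"auto"` (mean red
#'   patch diameter pooled over cells).
#' @param min_pixels minimum patch size in pixels.
#' @param bin_width histogram bin width, um.
#' @param seed seed for the randomization null.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return A `proximity_study` with per-cell tables, pooled histograms,
#'   colocalization table, the paired test, and the manifest (if written).
#' @export
run_proximity_study <- function(cells, cutoff = "auto",
                                null_diameter = "auto",
                                min_pixels = 4, bin_width = 0.05,
                                seed = 1, out_dir = NULL) {
  if (length(cells) == 0) stop("empty image set: supply at least one cell")
  cells <- lapply(cells, function(ce) {
    if (inherits(ce, "image_scenario")) generate_cell_image(ce) else ce
  })
  bad <- !vapply(cells, function(ce)
    is.list(ce) && inherits(ce$green, "channel_image") &&
      inherits(ce$red, "channel_image"), TRUE)
  if (any(bad))
    stop("each cell must carry 'green' and 'red' channel_image objects ",
         "(or be an image_scenario)")

  per <- lapply(cells, function(ce) {
    gm <- threshold_mask(ce$green)
    rm_ <- threshold_mask(ce$red)
    px <- ce$green$pixel_size
    list(green = label_patches(gm, px, min_pixels),
         red = label_patches(rm_, px, min_pixels),
         gmask = gm, rmask = rm_, px = px,
         cell_mask = ce$green$cell_mask,
         gimg = ce$green$intensities, rimg = ce$red$intensities)
  })
  g_diams <- unlist(lapply(per, function(p) p$green$eq_diameter_um))
  r_diams <- unlist(lapply(per, function(p) p$red$eq_diameter_um))
  if (identical(cutoff, "auto")) {
    if (length(g_diams) == 0) stop("no green patches found in any cell")
    cutoff <- 2 * mean(g_diams)
  }
  if (identical(null_diameter, "auto")) {
    null_diameter <- if (length(r_diams)) mean(r_diams) else 0.397
  }

  set.seed(seed)
  cell_rows <- list()
  real_res <- list()
  null_res <- list()
  coloc_rows <- list()
  for (i in seq_along(per)) {
    p <- per[[i]]
    if (nrow(p$green) == 0 || nrow(p$red) == 0) next
    real <- nearest_centroid_distances(p$green, p$red, cutoff)
    cm <- if (is.null(p$cell_mask))
      matrix(TRUE, nrow(p$gimg), ncol(p$gimg)) else p$cell_mask
    nmask <- random_mask_null(cm, n = nrow(p$red),
                              diameter = null_diameter, pixel_size = p$px)
    null <- nearest_centroid_distances(p$green,
                                       as.matrix(nmask$centers), cutoff)
    pear <- suppressWarnings(
      pearson_coefficient(p$rimg[cm], p$gimg[cm]))
    mand <- suppressWarnings(
      manders_coefficients(p$rimg, p$gimg, p$rmask, p$gmask))
    real$distances$cell <- i
    real_res[[length(real_res) + 1]] <- real
    null_res[[length(null_res) + 1]] <- null
    cell_rows[[length(cell_rows) + 1]] <- data.frame(
      cell = i, n_green = nrow(p$green), n_red = nrow(p$red),
      real_mean_um = real$mean_um, real_retained = real$n_retained,
      real_isolated = real$n_isolated,
      null_mean_um = null$mean_um, null_retained = null$n_retained,
      null_isolated = null$n_isolated)
    coloc_rows[[length(coloc_rows) + 1]] <- data.frame(
      roi_id = i, pearson = pear, m1 = mand[["M1"]], m2 = mand[["M2"]])
  }
  if (length(cell_rows) == 0)
    stop("no cell produced patches in both channels")
  cell_tab <- do.call(rbind, cell_rows)
  coloc_tab <- do.call(rbind, coloc_rows)
  ok <- stats::complete.cases(cell_tab[, c("real_mean_um", "null_mean_um")])
  test <- if (sum(ok) >= 3)
    suppressWarnings(stats::wilcox.test(cell_tab$real_mean_um[ok],
                                        cell_tab$null_mean_um[ok],
                                        paired = TRUE,
                                        alternative = "less"))
  else NULL

  res <- structure(list(
    cells = cell_tab, coloc = coloc_tab,
    cutoff_um = cutoff, null_diameter_um = null_diameter,
    real_hist = distance_histogram(real_res, bin_width),
    null_hist = distance_histogram(null_res, bin_width),
    real_mean_um = mean(cell_tab$real_mean_um[ok]),
    null_mean_um = mean(cell_tab$null_mean_um[ok]),
    test = test, p_value = if (is.null(test)) NA_real_ else test$p.value,
    seed = seed), class = "proximity_study")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(cells = file.path(out_dir, "cells.csv"),
               distances = file.path(out_dir, "distances.csv"),
               coloc = file.path(out_dir, "coloc.csv"),
               real_hist = file.path(out_dir, "real_histogram.csv"),
               null_hist = file.path(out_dir, "null_histogram.csv"))
    utils::write.csv(cell_tab, files["cells"], row.names = FALSE)
    utils::write.csv(do.call(rbind, lapply(real_res, `[[`, "distances")),
                     files["distances"], row.names = FALSE)
    utils::write.csv(coloc_tab, files["coloc"], row.names = FALSE)
    utils::write.csv(res$real_hist, files["real_hist"], row.names = FALSE)
    utils::write.csv(res$null_hist, files["null_hist"], row.names = FALSE)
    res$manifest <- write_manifest(
      out_dir, command = "run_proximity_study",
      config = list(cutoff = cutoff, null_diameter = null_diameter,
                    min_pixels = min_pixels, bin_width = bin_width,
                    n_cells = length(cells)),
      seeds = seed, files = files)
  }
  res
}

#' @export
print.proximity_study <- function(x, ...) {
  cat("<proximity_study> ", nrow(x$cells), " cells; cutoff ",
      sprintf("%.3f um", x$cutoff_um), "\n",
      "  real mean distance: ", sprintf("%.3f um", x$real_mean_um),
      "; null mean distance: ", sprintf("%.3f um", x$null_mean_um), "\n",
      "  one-sided paired Wilcoxon (real < null): p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Paired random-vs-colocalized secretion study
#'
#' Runs the pulse simulation for each seed in both geometries (channel
#' placements shared within each pair), averages the curves, tabulates the
#' per-seed release difference, and applies a one-sided paired Wilcoxon
#' signed-rank test to the hypothesis that the colocalized geometry
#' releases earlier (larger area under the cumulative-release curve).
#'
#' @param base a [sim_config()] template (its `mode`, `seed` and
#'   `channel_seed` are overridden per run).
#' @param seeds integer vector of paired seeds.
#' @param out_dir optional output directory.
#' @return A `secretion_study` with mean curves per mode, the per-seed
#'   difference table, and the test.
#' @export
run_secretion_study <- function(base = sim_config(n_replicates = 1),
                                seeds = 1:20, out_dir = NULL) {
  stopifnot(inherits(base, "sim_config"))
  domain <- cone_domain(base$base_radius, base$height, base$dx)
  pairs <- generate_sim_scenarios(base, c("random", "colocalized"), seeds)
  rows <- list()
  curves <- list(random = NULL, colocalized = NULL)
  time <- NULL
  for (i in seq_along(pairs)) {
    res_r <- run_pulse(pairs[[i]]$random, domain = domain)
    res_c <- run_pulse(pairs[[i]]$colocalized, domain = domain)
    if (is.null(time)) time <- res_r$time
    auc <- function(y) sum(diff(time) * (y[-length(y)] + y[-1]) / 2)
    rows[[i]] <- data.frame(
      seed = seeds[i],
      release_random_pct = res_r$mean_release_pct[length(time)],
      release_coloc_pct = res_c$mean_release_pct[length(time)],
      auc_random = auc(res_r$mean_release_pct),
      auc_coloc = auc(res_c$mean_release_pct),
      dist_random_um = mean(vapply(seq_along(res_r$placements), function(r)
        placement_distance(domain, res_r$placements[[r]]$channels,
                           res_r$placements[[r]]$vesicles), 0)),
      dist_coloc_um = mean(vapply(seq_along(res_c$placements), function(r)
        placement_distance(domain, res_c$placements[[r]]$channels,
                           res_c$placements[[r]]$vesicles), 0)))
    curves$random <- if (is.null(curves$random)) res_r$mean_release_pct
      else curves$random + res_r$mean_release_pct
    curves$colocalized <- if (is.null(curves$colocalized))
      res_c$mean_release_pct else
      curves$colocalized + res_c$mean_release_pct
  }
  tab <- do.call(rbind, rows)
  curves <- lapply(curves, function(v) v / length(seeds))
  dif <- tab$auc_coloc - tab$auc_random
  test <- if (any(dif != 0))
    suppressWarnings(stats::wilcox.test(dif, alternative = "greater"))
  else NULL
  res <- structure(list(
    time = time, mean_release = curves, pairs = tab,
    test = test, p_value = if (is.null(test)) NA_real_ else test$p.value,
    config = base, seeds = seeds), class = "secretion_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(pairs = file.path(out_dir, "paired_release.csv"),
               curves = file.path(out_dir, "mean_release_curves.csv"))
    utils::write.csv(tab, files["pairs"], row.names = FALSE)
    utils::write.csv(data.frame(time_s = time,
                                release_random_pct = curves$random,
                                release_colocalized_pct =
                                  curves$colocalized),
                     files["curves"], row.names = FALSE)
    res$manifest <- write_manifest(
      out_dir, command = "run_secretion_study",
      config = unclass(base)[setdiff(names(base), "params")],
      seeds = seeds, files = files)
  }
  res
}

#' @export
print.secretion_study <- function(x, ...) {
  n <- length(x$time)
  cat("<secretion_study> ", nrow(x$pairs), " paired seeds, pulse ",
      x$config$pulse_s, " s\n",
      "  final release: random ",
      sprintf("%.1f%%", x$mean_release$random[n]), ", colocalized ",
      sprintf("%.1f%%", x$mean_release$colocalized[n]), "\n",
      "  one-sided paired Wilcoxon (colocalized earlier): p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seeds, package version,
#' output file digests and a timestamp; re-running the same command with
#' the same seeds reproduces the artifacts bit for bit.
#'
#' @param out_dir directory the manifest describes.
#' @param command name of the generating function.
#' @param config configuration list (must be JSON-serializable).
#' @param seeds integer seed(s).
#' @param files named character vector of artifact paths.
#' @return The manifest list, invisibly; written as `manifest.json`.
#' @export
write_manifest <- function(out_dir, command, config, seeds, files) {
  man <- list(command = command, config = config, seeds = seeds,
              package = "chromsec",
              version = as.character(utils::packageVersion("chromsec")),
              files = as.list(stats::setNames(
                unname(tools::md5sum(files)), names(files))),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Write / read an intensity matrix as CSV
#'
#' Plain-text stand-in for TIFF I/O (no TIFF reader is available in the
#' supported dependency set): a headerless CSV of intensities, row =
#' image row.
#'
#' @param m numeric matrix.
#' @param path CSV path.
#' @return `path` invisibly (write) or the matrix (read).
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(is.matrix(m))
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
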