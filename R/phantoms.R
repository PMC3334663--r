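#' Phantom ground truth record
#'
#' Every phantom generator returns, next to its mask, the analytic ground
#' truth of the morphometric quantities it controls. Quantities a generator
#' does not control are `NA`.
#'
#' @param bvtv_true bone volume fraction (0-1).
#' @param thickness_true_um structure thickness in micrometres.
#' @param separation_true_um marrow separation in micrometres.
#' @param plate_thickness_true_um plate thickness in micrometres.
#' @param plate_porosity_true_pct plate porosity in percent.
#' @param description generator name, parameters and seed.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(bvtv_true = NA_real_, thickness_true_um = NA_real_,
                          separation_true_um = NA_real_,
                          plate_thickness_true_um = NA_real_,
                          plate_porosity_true_pct = NA_real_,
                          description = "") {
  if (!is.na(bvtv_true) && (bvtv_true < 0 || bvtv_true > 1))
    stop("bvtv_true must lie in [0, 1]")
  for (v in c(thickness_true_um, separation_true_um, plate_thickness_true_um))
    if (!is.na(v) && v <= 0) stop("true lengths must be positive")
  if (!is.na(plate_porosity_true_pct) &&
      (plate_porosity_true_pct < 0 || plate_porosity_true_pct > 100))
    stop("plate_porosity_true_pct must lie in [0, 100]")
  structure(list(bvtv_true = bvtv_true,
                 thickness_true_um = thickness_true_um,
                 separation_true_um = separation_true_um,
                 plate_thickness_true_um = plate_thickness_true_um,
                 plate_porosity_true_pct = plate_porosity_true_pct,
                 description = description),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>", x$description, "\n")
  vals <- unlist(x[1:5])
  for (nm in names(vals))
    if (!is.na(vals[nm])) cat(sprintf("  %s: %.4g\n", nm, vals[nm]))
  invisible(x)
}

#' Write a phantom's ground truth as JSON next to an exported volume
#'
#' @param truth a [phantom_truth()].
#' @param path path of the exported volume; the truth is written to
#'   `<path>.truth.json`.
#' @export
write_phantom_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parallel-slab phantom with known thickness and separation
#'
#' Periodic bone slabs normal to the z axis (period `thickness_um +
#' gap_um`), rasterised by strict voxel-centre inclusion so the analytic
#' thickness is recovered exactly by the direct method at integer
#' voxel multiples. Truth: `bvtv = thickness / (thickness + gap)`,
#' `Tb.Th = thickness`, `Tb.Sp = gap`.
#'
#' @param thickness_um slab thickness in micrometres (>= 2 voxel spacings).
#' @param gap_um marrow gap in micrometres (>= 2 voxel spacings).
#' @param spacing_um voxel spacing in micrometres.
#' @param dims volume dimensions `c(nx, ny, nz)`; must hold >= 3 periods
#'   along z.
#' @return List with `mask` ([binary_volume()]) and `truth`
#'   ([phantom_truth()]).
#' @export
make_slab_phantom <- function(thickness_um, gap_um, spacing_um,
                              dims = c(64L, 64L, 96L)) {
  check_spacing(spacing_um)
  if (thickness_um < 2 * spacing_um)
    stop("unresolvable structure: slab thinner than 2 voxels")
  if (gap_um < 2 * spacing_um)
    stop("unresolvable structure: gap thinner than 2 voxels")
  period <- thickness_um + gap_um
  if (dims[3] * spacing_um < 3 * period - 1e-6)
    stop("dims must accommodate at least 3 slab periods along z")
  zc <- (seq_len(dims[3]) - 0.5) * spacing_um
  bone_plane <- (zc %% period) < thickness_um
  vox <- array(rep(bone_plane, each = dims[1] * dims[2]), dim = dims)
  list(mask = binary_volume(vox, spacing_um),
       truth = phantom_truth(
         bvtv_true = thickness_um / period,
         thickness_true_um = thickness_um,
         separation_true_um = gap_um,
         description = sprintf("slab(thickness=%g, gap=%g, spacing=%g)",
                               thickness_um, gap_um, spacing_um)))
}

#' Square-lattice rod phantom
#'
#' z-aligned solid cylinders of radius `radius_um` on a square lattice of
#' pitch `pitch_um`. Truth before discretisation: `Tb.Th = 2 radius`,
#' `bvtv = pi radius^2 / pitch^2`.
#'
#' @param radius_um rod radius in micrometres (>= 2 voxel spacings).
#' @param pitch_um lattice pitch in micrometres (> 2 radius).
#' @param spacing_um voxel spacing in micrometres.
#' @param dims volume dimensions `c(nx, ny, nz)`.
#' @return List with `mask` and `truth`.
#' @export
make_rod_phantom <- function(radius_um, pitch_um, spacing_um,
                             dims = c(90L, 90L, 60L)) {
  check_spacing(spacing_um)
  if (radius_um < 2 * spacing_um)
    stop("unresolvable structure: rod radius under 2 voxels")
  if (pitch_um < 2 * radius_um)
    stop("overlapping rods: pitch must be >= 2 radius")
  p_vox <- pitch_um / spacing_um
  r_vox <- radius_um / spacing_um
  xc <- seq_len(dims[1]) - 0.5
  yc <- seq_len(dims[2]) - 0.5
  # rod axes sit on voxel centres (half-integer coordinates) so the digital
  # cylinder contains the full inscribed sphere of its analytic radius
  c0 <- floor(p_vox / 2) + 0.5
  dx <- abs(((xc - c0 + p_vox / 2) %% p_vox) - p_vox / 2)
  dy <- abs(((yc - c0 + p_vox / 2) %% p_vox) - p_vox / 2)
  in_rod <- outer(dx^2, dy^2, `+`) < r_vox^2
  vox <- array(rep(in_rod, times = dims[3]), dim = dims)
  list(mask = binary_volume(vox, spacing_um),
       truth = phantom_truth(
         bvtv_true = pi * radius_um^2 / pitch_um^2,
         thickness_true_um = 2 * radius_um,
         description = sprintf("rod(radius=%g, pitch=%g, spacing=%g)",
                               radius_um, pitch_um, spacing_um)))
}

#' Thresholded Gaussian-random-field phantom
#'
#' White noise smoothed with a Gaussian kernel of standard deviation equal to
#' the correlation length, then thresholded at the empirical quantile that
#' yields the target bone fraction exactly (to 1 voxel; ties broken
#' deterministically). Reproducible under `seed`.
#'
#' @param target_bvtv target bone volume fraction in (0, 1).
#' @param corr_length_um correlation length (Gaussian sigma) in micrometres.
#' @param spacing_um voxel spacing in micrometres.
#' @param dims volume dimensions.
#' @param seed integer seed.
#' @return List with `mask` and `truth` (truth records the achieved
#'   fraction).
#' @export
make_grf_phantom <- function(target_bvtv, corr_length_um, spacing_um,
                             dims = c(64L, 64L, 64L), seed = 1L) {
  check_spacing(spacing_um)
  if (!(target_bvtv > 0 && target_bvtv < 1))
    stop("target_bvtv must lie strictly between 0 and 1")
  if (any(dims < 8L)) stop("degenerate dims for a random-field phantom")
  n <- prod(dims)
  field <- with_seed(seed, array(stats::rnorm(n), dim = dims))
  field <- gaussian_smooth3d(field, corr_length_um / spacing_um)
  n_bone <- round(target_bvtv * n)
  ord <- order(field, decreasing = TRUE)
  vox <- array(FALSE, dim = dims)
  vox[ord[seq_len(n_bone)]] <- TRUE
  list(mask = binary_volume(vox, spacing_um),
       truth = phantom_truth(
         bvtv_true = n_bone / n,
         description = sprintf(
           "grf(target=%g, corr_length=%g, spacing=%g, seed=%d)",
           target_bvtv, corr_length_um, spacing_um, seed)))
}

#' Subchondral plate-over-trabeculae phantom
#'
#' A solid plate of given thickness at the articular (low-z) face, with
#' cylindrical through-pores drilled to remove exactly `pore_fraction_pct`
#' percent of the plate-region volume (to 1 voxel), separated from a
#' trabecular rod compartment by a marrow gap. A grayscale rendition (bone
#' 200, marrow 50, Gaussian blur + noise) is returned for segmentation
#' tests.
#'
#' @param plate_thickness_um plate thickness in micrometres.
#' @param pore_fraction_pct percent of the plate volume to drill out
#'   (0 <= f < 50).
#' @param spacing_um voxel spacing in micrometres.
#' @param dims volume dimensions `c(nx, ny, nz)`.
#' @param gap_um marrow gap between plate and trabeculae (default 174 um).
#' @param rod_radius_um,rod_pitch_um trabecular compartment geometry.
#' @param pore_radius_um nominal pore radius (default 26.1 um).
#' @param blur_sigma_vox,noise_sd grayscale rendition parameters.
#' @param seed integer seed (grayscale noise).
#' @return List with `gray` ([gray_volume()]), `mask` ([binary_volume()])
#'   and `truth`.
#' @export
make_subchondral_phantom <- function(plate_thickness_um, pore_fraction_pct,
                                     spacing_um, dims = c(60L, 60L, 72L),
                                     gap_um = 174, rod_radius_um = 43.5,
                                     rod_pitch_um = 174,
                                     pore_radius_um = 26.1,
                                     blur_sigma_vox = 0.5, noise_sd = 8,
                                     seed = 1L) {
  check_spacing(spacing_um)
  if (pore_fraction_pct < 0 || pore_fraction_pct >= 50)
    stop("pore_fraction_pct must lie in [0, 50): larger fractions disconnect the plate")
  n_plate_z <- round(plate_thickness_um / spacing_um)
  if (n_plate_z < 2L) stop("unresolvable structure: plate thinner than 2 voxels")
  n_gap_z <- round(gap_um / spacing_um)
  if (n_plate_z + n_gap_z + 4L > dims[3])
    stop("dims too small for plate + gap + trabeculae")

  nx <- dims[1]; ny <- dims[2]
  vox <- array(FALSE, dim = dims)
  vox[, , seq_len(n_plate_z)] <- TRUE

  # drill through-pores: rank in-plane pixels by distance to the nearest pore
  # centre and remove exactly the target count
  n_target <- round(pore_fraction_pct / 100 * nx * ny)
  if (n_target > 0L) {
    area_per_pore <- pi * (pore_radius_um / spacing_um)^2
    n_pores <- max(1L, round(n_target / area_per_pore))
    side <- ceiling(sqrt(n_pores))
    cx <- (seq_len(side) - 0.5) * nx / side
    cy <- (seq_len(side) - 0.5) * ny / side
    centers <- cbind(rep(cx, times = side), rep(cy, each = side))
    centers <- centers[seq_len(n_pores), , drop = FALSE]
    px <- rep(seq_len(nx) - 0.5, times = ny)
    py <- rep(seq_len(ny) - 0.5, each = nx)
    dmin <- rep(Inf, nx * ny)
    for (i in seq_len(nrow(centers)))
      dmin <- pmin(dmin, (px - centers[i, 1])^2 + (py - centers[i, 2])^2)
    pore_px <- order(dmin)[seq_len(n_target)]
    pore_plane <- array(FALSE, dim = c(nx, ny))
    pore_plane[pore_px] <- TRUE
    for (z in seq_len(n_plate_z)) vox[, , z][pore_plane] <- FALSE
  }

  # trabecular compartment: z-aligned rods below the marrow gap
  rods <- make_rod_phantom(rod_radius_um, rod_pitch_um, spacing_um,
                           dims = c(nx, ny, dims[3] - n_plate_z - n_gap_z))
  vox[, , (n_plate_z + n_gap_z + 1L):dims[3]] <- rods$mask$voxels

  achieved_por <- if (n_target > 0L)
    100 * n_target / (nx * ny) else 0
  mask <- binary_volume(vox, spacing_um)

  g <- array(50, dim = dims)
  g[vox] <- 200
  g <- gaussian_smooth3d(g, blur_sigma_vox)
  g <- g + with_seed(seed, array(stats::rnorm(prod(dims), sd = noise_sd),
                                 dim = dims))
  gray <- gray_volume(array(as.integer(pmax(0, pmin(255, round(g)))),
                            dim = dims), spacing_um)

  list(gray = gray, mask = mask,
       truth = phantom_truth(
         bvtv_true = mean(vox),
         plate_thickness_true_um = n_plate_z * spacing_um,
         plate_porosity_true_pct = achieved_por,
         description = sprintf(
           "subchondral(plate=%g, pores=%g%%, spacing=%g, seed=%d)",
           plate_thickness_um, pore_fraction_pct, spacing_um, seed)),
       plate_slices = n_plate_z, gap_slices = n_gap_z)
}
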