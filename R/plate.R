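#' Separate the subchondral plate from trabecular bone
#'
#' Column-scan separation: within the analysis region, each in-plane column
#' is scanned from the articular side (lowest z). The plate extends from the
#' first bone voxel down to the first marrow gap longer than `gap_bridge_um`;
#' shorter gaps (intra-plate pores) are bridged. All bone below the first
#' long gap is trabecular. Plate and trabecular masks are disjoint and
#' together cover all bone in the region.
#'
#' @param mask a [binary_volume()] with the articular surface facing the
#'   lowest z planes.
#' @param region optional in-plane region: either `NULL` (whole section), a
#'   logical `nx x ny` matrix, or a list from [plate_region()].
#' @param gap_bridge_um marrow gaps up to this length (micrometres) are
#'   treated as intra-plate pores; default 52.2 um (6 voxels at 8.7 um).
#' @return List with `plate` and `trabecular` [binary_volume()] masks and the
#'   `gap_bridge_um` used.
#' @export
separate_plate <- function(mask, region = NULL, gap_bridge_um = 52.2) {
  stopifnot(inherits(mask, "binary_volume"))
  d <- dim(mask$voxels)
  reg <- resolve_region(region, d)
  if (!any(reg)) stop("empty analysis region")
  gap_vox <- floor(gap_bridge_um / mask$spacing_um + 1e-9)

  vox <- mask$voxels
  plate <- array(FALSE, dim = d)
  cols <- which(reg, arr.ind = TRUE)
  any_bone <- FALSE
  nz <- d[3]
  for (i in seq_len(nrow(cols))) {
    x <- cols[i, 1]; y <- cols[i, 2]
    col <- vox[x, y, ]
    if (!any(col)) next
    any_bone <- TRUE
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    first_bone <- which(r$values)[1]
    stop_at <- nz
    k <- first_bone + 1L
    while (k <= length(r$values)) {
      if (!r$values[k] && r$lengths[k] > gap_vox) {
        stop_at <- starts[k] - 1L
        break
      }
      k <- k + 1L
    }
    zz <- starts[first_bone]:stop_at
    plate[x, y, zz] <- col[zz]
  }
  if (!any_bone) stop("analysis region contains no bone")
  trab <- vox & !plate
  trab[!array(reg, dim = d)] <- FALSE
  pl <- vox & plate
  list(plate = binary_volume(pl, mask$spacing_um, threshold = mask$threshold),
       trabecular = binary_volume(trab, mask$spacing_um,
                                  threshold = mask$threshold),
       gap_bridge_um = gap_bridge_um)
}

resolve_region <- function(region, d) {
  if (is.null(region)) return(matrix(TRUE, d[1], d[2]))
  if (is.matrix(region)) {
    if (!identical(dim(region), d[1:2]))
      stop("region matrix must match the in-plane dimensions")
    return(region)
  }
  if (is.list(region) && !is.null(region$x_range) && !is.null(region$y_range)) {
    m <- matrix(FALSE, d[1], d[2])
    xr <- region$x_range; yr <- region$y_range
    if (xr[1] < 1 || xr[2] > d[1] || yr[1] < 1 || yr[2] > d[2])
      stop("region rectangle outside the volume")
    m[xr[1]:xr[2], yr[1]:yr[2]] <- TRUE
    return(m)
  }
  stop("region must be NULL, a logical matrix, or a plate_region() rectangle")
}

#' In-plane analysis rectangle for plate morphometry
#'
#' Builds the rectangular analysis region used for plate thickness and
#' porosity: a box of given medio-lateral width and antero-posterior length,
#' anchored at the posterior edge of the compartment's bounding box (the
#' standard protocol measures "from the posterior side"; the anchor is
#' user-adjustable).
#'
#' @param width_mm medio-lateral width (x) in millimetres.
#' @param length_mm antero-posterior length (y) in millimetres.
#' @param spacing_um voxel spacing in micrometres.
#' @param shape volume dims `c(nx, ny, nz)`.
#' @param x_offset 1-based x index where the rectangle starts (default 1).
#' @param anchor `"posterior"` (rectangle ends at max y) or `"anterior"`.
#' @return A list with `x_range` and `y_range` (1-based inclusive), usable as
#'   `region` in [separate_plate()] and [plate_porosity()].
#' @export
plate_region <- function(width_mm, length_mm, spacing_um, shape,
                         x_offset = 1L, anchor = c("posterior", "anterior")) {
  anchor <- match.arg(anchor)
  wx <- max(1L, round(width_mm * 1000 / spacing_um))
  ly <- max(1L, round(length_mm * 1000 / spacing_um))
  wx <- min(wx, shape[1] - x_offset + 1L)
  x_range <- c(x_offset, x_offset + wx - 1L)
  if (anchor == "posterior") y_range <- c(shape[2] - min(ly, shape[2]) + 1L, shape[2])
  else y_range <- c(1L, min(ly, shape[2]))
  list(x_range = as.integer(x_range), y_range = as.integer(y_range))
}

#' Mean subchondral plate thickness
#'
#' Direct-3D mean local thickness (maximal-sphere method) over the plate
#' voxels, in micrometres. Pores are excluded from the domain by
#' construction.
#'
#' @param plate plate [binary_volume()] from [separate_plate()].
#' @return Pl.Th in micrometres.
#' @export
plate_thickness <- function(plate) {
  stopifnot(inherits(plate, "binary_volume"))
  if (!any(plate$voxels)) stop("empty plate")
  mean_thickness(local_thickness(plate, "bone"))
}

#' Subchondral plate porosity
#'
#' The plate envelope is taken per in-plane column as the span from the first
#' to the last plate voxel; pores are the non-bone voxels inside that span
#' (short gaps already bridged by [separate_plate()]). Through-pore columns
#' with no plate bone belong to the envelope only when enclosed by
#' plate-bearing columns on all four in-plane sides (interior holes); their
#' span is the median span of the plate-bearing columns in the region.
#' Unenclosed no-bone columns (outside the plate footprint) are excluded.
#' Porosity is 100 x pore volume over total envelope volume (pores + bone).
#'
#' @param plate plate [binary_volume()] from [separate_plate()].
#' @param region optional region restriction (same forms as in
#'   [separate_plate()]).
#' @return Pl.Por in percent.
#' @export
plate_porosity <- function(plate, region = NULL) {
  stopifnot(inherits(plate, "binary_volume"))
  d <- dim(plate$voxels)
  reg <- resolve_region(region, d)
  vox <- plate$voxels
  has_bone <- apply(vox, c(1, 2), any) & reg

  n_env <- 0L
  n_bone <- 0L
  tops <- integer(0)
  bots <- integer(0)
  cols <- which(has_bone, arr.ind = TRUE)
  if (nrow(cols) == 0L) stop("empty plate envelope")
  for (i in seq_len(nrow(cols))) {
    w <- which(vox[cols[i, 1], cols[i, 2], ])
    tops <- c(tops, w[1]); bots <- c(bots, w[length(w)])
    n_env <- n_env + (w[length(w)] - w[1] + 1L)
    n_bone <- n_bone + length(w)
  }

  # interior holes: no-bone columns enclosed by plate on all four sides
  holes <- reg & !has_bone
  if (any(holes)) {
    left <- apply(has_bone, 2, cummax)
    right <- apply(has_bone[rev(seq_len(d[1])), , drop = FALSE], 2, cummax)[
      rev(seq_len(d[1])), , drop = FALSE]
    up <- t(apply(has_bone, 1, cummax))
    down <- t(apply(has_bone[, rev(seq_len(d[2])), drop = FALSE], 1,
                    cummax))[, rev(seq_len(d[2])), drop = FALSE]
    enclosed <- holes & (left == 1) & (right == 1) & (up == 1) & (down == 1)
    span <- stats::median(bots) - stats::median(tops) + 1
    n_env <- n_env + sum(enclosed) * span
  }
  100 * (n_env - n_bone) / n_env
}

#' Total-compartment value from medial and lateral values
#'
#' Plate metrics for the total compartment are the arithmetic mean of the
#' medial and lateral compartment values.
#'
#' @param medial,lateral numeric values (scalars or equal-length vectors).
#' @return Their arithmetic mean.
#' @export
total_compartment <- function(medial, lateral) {
  if (missing(medial) || missing(lateral) || is.null(medial) || is.null(lateral))
    stop("both medial and lateral values are required")
  if (anyNA(medial) || anyNA(lateral)) stop("missing compartment value")
  (medial + lateral) / 2
}

#' Plate metrics per compartment
#'
#' Runs plate separation, thickness and porosity on medial and lateral
#' analysis regions and averages them for the total compartment.
#'
#' @param mask a [binary_volume()].
#' @param regions named list with `medial` and `lateral` region entries
#'   (matrices or [plate_region()] rectangles).
#' @param gap_bridge_um gap-bridging length for [separate_plate()].
#' @return A data.frame with one row per compartment and columns
#'   `compartment`, `pl_th_um`, `pl_por_pct`.
#' @export
compute_plate_metrics <- function(mask, regions, gap_bridge_um = 52.2) {
  if (!all(c("medial", "lateral") %in% names(regions)))
    stop("regions must contain medial and lateral entries")
  one <- function(nm) {
    sep <- separate_plate(mask, regions[[nm]], gap_bridge_um)
    data.frame(compartment = nm,
               pl_th_um = plate_thickness(sep$plate),
               pl_por_pct = plate_porosity(sep$plate, regions[[nm]]),
               stringsAsFactors = FALSE)
  }
  med <- one("medial"); lat <- one("lateral")
  tot <- data.frame(compartment = "total",
                    pl_th_um = total_compartment(med$pl_th_um, lat$pl_th_um),
                    pl_por_pct = total_compartment(med$pl_por_pct,
                                                   lat$pl_por_pct),
                    stringsAsFactors = FALSE)
  rbind(med, lat, tot)
}
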