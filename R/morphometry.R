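#' Bone volume, total volume and bone volume fraction within a VOI
#'
#' `BV` is the volume of voxels segmented as bone inside the VOI, `TV` the
#' VOI volume, both in cubic millimetres; `BV/TV` is their ratio in percent.
#'
#' @param mask a [binary_volume()].
#' @param voi a [voi_mask()] sharing shape and spacing with `mask`.
#' @return A list with `bv_mm3`, `tv_mm3`, `bvtv_pct`.
#' @export
bone_volume <- function(mask, voi) {
  check_same_grid(mask, voi)
  n_voi <- sum(voi$voxels)
  if (n_voi == 0L) stop("empty VOI")
  vx_mm3 <- (mask$spacing_um / 1000)^3
  n_bone <- sum(mask$voxels & voi$voxels)
  list(bv_mm3 = n_bone * vx_mm3,
       tv_mm3 = n_voi * vx_mm3,
       bvtv_pct = 100 * n_bone / n_voi)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("volumes must share the same voxel grid")
  if (abs(a$spacing_um - b$spacing_um) > 1e-9)
    stop("volumes must share the same voxel spacing")
  invisible(TRUE)
}

#' Direct-3D local thickness map
#'
#' For every voxel of the chosen domain, the diameter (in micrometres) of the
#' largest sphere fully contained in the domain that covers the voxel,
#' computed from the exact Euclidean distance transform followed by
#' distance-ridge sphere propagation (the maximal-sphere direct method).
#' Values are diameters; the minimal attainable value is two voxel spacings
#' (an isolated voxel). Voxels outside the domain are `NA`.
#'
#' With `domain = "bone"` the map is computed on the full bone mask, with the
#' volume border treated as open marrow space (a structure touching the
#' border is not artificially thickened), and is meant to be averaged over
#' the VOI only. With `domain = "background"` the domain is the marrow space
#' restricted to the VOI (`voi & !bone`) and the field boundary acts as a
#' hard wall, so separation never extends into out-of-field space. In both
#' cases fitted spheres are confined to the image field.
#'
#' @param mask a [binary_volume()].
#' @param domain `"bone"` for Tb.Th-type maps, `"background"` for Tb.Sp.
#' @param voi a [voi_mask()]; required for the background domain, optional
#'   (full volume) for bone.
#' @return An object of class `thickness_map`: a 3D array of micrometre
#'   diameters with `NA` outside the domain, plus spacing and domain info.
#' @export
local_thickness <- function(mask, domain = c("bone", "background"),
                            voi = NULL) {
  stopifnot(inherits(mask, "binary_volume"))
  domain <- match.arg(domain)
  d <- dim(mask$voxels)
  if (domain == "bone") {
    dom <- mask$voxels
  } else {
    if (is.null(voi)) stop("background domain requires a VOI")
    check_same_grid(mask, voi)
    dom <- voi$voxels & !mask$voxels
  }
  if (!any(dom)) stop("empty thickness domain")
  # the field boundary always bounds the fitted spheres: open marrow space
  # for bone (no artificial thickening) and a hard wall for the marrow
  # domain (separation never extends out of field)
  th_vox <- local_thickness_cpp(as.vector(dom), d, TRUE)
  structure(list(values = array(th_vox * mask$spacing_um, dim = d),
                 spacing_um = mask$spacing_um, domain = domain),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<thickness_map> %s domain, %d voxels, mean %.1f um (range %.1f-%.1f)\n",
              x$domain, length(v), mean(v), min(v), max(v)))
  invisible(x)
}

#' Mean local thickness over a domain
#'
#' Arithmetic (hence volume-weighted) mean of the local thickness map,
#' optionally restricted to a VOI; this is the direct-method Tb.Th / Tb.Sp /
#' Pl.Th estimator.
#'
#' @param map a [local_thickness()] map.
#' @param voi optional [voi_mask()]; averaging is restricted to it.
#' @return Mean thickness in micrometres.
#' @export
mean_thickness <- function(map, voi = NULL) {
  stopifnot(inherits(map, "thickness_map"))
  v <- map$values
  if (!is.null(voi)) {
    stopifnot(inherits(voi, "voi_mask"))
    v[!voi$voxels] <- NA
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty domain: no thickness values to average")
  mean(v)
}

#' Trabecular number from BV/TV and Tb.Th
#'
#' `Tb.N = (BV/TV) / Tb.Th`, with BV/TV as a fraction and Tb.Th in
#' millimetres, giving trabeculae per millimetre.
#'
#' @param bvtv_pct bone volume fraction in percent.
#' @param tbth_um mean trabecular thickness in micrometres (> 0).
#' @return Tb.N in 1/mm.
#' @export
trabecular_number <- function(bvtv_pct, tbth_um) {
  if (any(tbth_um <= 0)) stop("Tb.Th must be > 0")
  (bvtv_pct / 100) / (tbth_um / 1000)
}

#' Full trabecular morphometry for medial, lateral and total compartments
#'
#' Computes BV, TV, BV/TV, Tb.Th (bone-domain mean local thickness), Tb.Sp
#' (background-domain mean local thickness) and Tb.N per compartment. The
#' total compartment is the union of medial and lateral, so total BV equals
#' the sum of the parts. The bone thickness map is computed once on the full
#' mask and averaged per VOI.
#'
#' @param mask a [binary_volume()].
#' @param vois named list with `medial` and `lateral` [voi_mask()] entries
#'   (as produced by [rasterize_voi()]); `total` is rebuilt as their union.
#' @return A data.frame of class `morphometry_table` with one row per
#'   compartment and columns `compartment`, `bv_mm3`, `tv_mm3`, `bvtv_pct`,
#'   `tbth_um`, `tbsp_um`, `tbn_per_mm`.
#' @export
compute_morphometry <- function(mask, vois) {
  if (!all(c("medial", "lateral") %in% names(vois)))
    stop("vois must contain medial and lateral compartments")
  med <- vois$medial; lat <- vois$lateral
  if (any(med$voxels & lat$voxels)) stop("medial and lateral VOIs overlap")
  tot <- voi_mask(med$voxels | lat$voxels, "total", med$spacing_um)
  comp <- list(medial = med, lateral = lat, total = tot)

  th_bone <- local_thickness(mask, "bone")
  rows <- lapply(names(comp), function(nm) {
    voi <- comp[[nm]]
    bvl <- bone_volume(mask, voi)
    any_bone <- any(mask$voxels & voi$voxels)
    tbth <- if (any_bone) mean_thickness(th_bone, voi) else NA_real_
    any_bg <- any(voi$voxels & !mask$voxels)
    tbsp <- if (any_bg)
      mean_thickness(local_thickness(mask, "background", voi)) else NA_real_
    tbn <- if (any_bone) trabecular_number(bvl$bvtv_pct, tbth) else 0
    data.frame(compartment = nm, bv_mm3 = bvl$bv_mm3, tv_mm3 = bvl$tv_mm3,
               bvtv_pct = bvl$bvtv_pct, tbth_um = tbth, tbsp_um = tbsp,
               tbn_per_mm = tbn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- mask$threshold
  class(out) <- c("morphometry_table", "data.frame")
  out
}

#' @export
print.morphometry_table <- function(x, digits = 4, ...) {
  cat("Trabecular morphometry (direct 3D)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "threshold")))
    cat("threshold:", attr(x, "threshold"), "\n")
  invisible(x)
}
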