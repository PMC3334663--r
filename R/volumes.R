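#' Construct a grayscale micro-CT volume
#'
#' A `gray_volume` is a 3D array of 8-bit intensities (0-255) with isotropic
#' voxel spacing in micrometres. Axis order is `(z, y, x)` conceptually, with
#' the R array indexed `[x, y, z]` (first index fastest); `z` is the slice
#' index, increasing distally (toward the growth plate). Indices are 0-based
#' in all file formats and voxel-centred.
#'
#' @param voxels 3D numeric/integer array with values in 0-255.
#' @param spacing_um voxel edge length in micrometres (isotropic, > 0).
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(voxels, spacing_um) {
  voxels <- check_volume_array(voxels)
  check_spacing(spacing_um)
  if (any(voxels < 0 | voxels > 255))
    stop("gray_volume intensities must lie in 0-255")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing_um = spacing_um),
            class = "gray_volume")
}

#' Construct a binary bone mask
#'
#' A `binary_volume` is a 3D logical array (`TRUE` = bone) sharing the shape
#' and spacing of the grayscale volume it derives from. The threshold used to
#' derive it (if any) is carried as provenance.
#'
#' @param voxels 3D logical array.
#' @param spacing_um voxel edge length in micrometres.
#' @param threshold optional grey-level threshold recorded as provenance.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(voxels, spacing_um, threshold = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  check_spacing(spacing_um)
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask may not contain NA")
  structure(list(voxels = voxels, spacing_um = spacing_um,
                 threshold = threshold),
            class = "binary_volume")
}

check_spacing <- function(spacing_um) {
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L ||
      !is.finite(spacing_um) || spacing_um <= 0)
    stop("spacing_um must be a single positive number")
  invisible(spacing_um)
}

check_volume_array <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (anyNA(voxels)) stop("volume may not contain NA")
  voxels
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<gray_volume> %d x %d x %d voxels (x, y, z), %.4g um spacing\n",
              d[1], d[2], d[3], x$spacing_um))
  cat(sprintf("  intensity range %d-%d\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_volume> %d x %d x %d voxels, %.4g um spacing\n",
              d[1], d[2], d[3], x$spacing_um))
  cat(sprintf("  %d bone voxels (%.2f%%)%s\n", sum(x$voxels),
              100 * mean(x$voxels),
              if (is.null(x$threshold)) "" else
                sprintf(", threshold %s", format(x$threshold))))
  invisible(x)
}

#' @export
dim.gray_volume <- function(x) dim(x$voxels)

#' @export
dim.binary_volume <- function(x) dim(x$voxels)

sidecar_path <- function(path) paste0(path, ".meta.json")

read_sidecar_spacing <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  meta <- jsonlite::read_json(sp)
  if (is.null(meta$spacing_um)) return(NULL)
  as.numeric(meta$spacing_um)
}

write_sidecar_spacing <- function(path, spacing_um) {
  jsonlite::write_json(list(spacing_um = spacing_um), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
}

slice_to_matrix <- function(img, path) {
  # tiff::readTIFF returns doubles in [0,1]; grayscale slices must be 2D
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L &&
        !all(abs(img[, , 1] - img[, , min(2, dim(img)[3])]) < 1e-12))
      stop("unsupported format: multi-channel slice in ", path)
    img <- img[, , 1]
  }
  if (length(dim(img)) != 2L)
    stop("unsupported format: slice in ", path, " is not 2D grayscale")
  round(img * 255)
}

#' Read a 3D volume from a multi-page TIFF or a slice directory
#'
#' Slices are stacked in page order (multi-page TIFF) or lexicographic
#' filename order (directory of single-page TIFFs). Voxel spacing is taken
#' from the `spacing_um` argument when given, otherwise from the JSON sidecar
#' (`<path>.meta.json`, key `spacing_um`) written by [write_volume()].
#'
#' @param path a multi-page TIFF file or a directory of 2D TIFF slices.
#' @param spacing_um voxel spacing in micrometres; overrides the sidecar.
#' @return A [gray_volume()].
#' @export
read_volume <- function(path, spacing_um = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (is.null(spacing_um)) spacing_um <- read_sidecar_spacing(path)
  if (is.null(spacing_um))
    stop("voxel spacing not given and no sidecar metadata found for ", path)
  check_spacing(spacing_um)

  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    pages <- lapply(files, function(f)
      slice_to_matrix(tiff::readTIFF(f), f))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, slice_to_matrix, path = path)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions across the stack")
  # readTIFF matrices are row (y) x column (x); store as [x, y, z]
  nz <- length(pages)
  ny <- dims[1, 1]; nx <- dims[2, 1]
  vox <- array(0L, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) vox[, , k] <- t(pages[[k]])
  gray_volume(vox, spacing_um)
}

#' Write a volume as a multi-page 8-bit TIFF with a spacing sidecar
#'
#' @param vol a [gray_volume()] or [binary_volume()]; masks are written as
#'   8-bit 0/255.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_volume")) {
    vox <- array(as.integer(vol$voxels) * 255L, dim = dim(vol$voxels))
  } else if (inherits(vol, "gray_volume")) {
    vox <- vol$voxels
  } else stop("vol must be a gray_volume or binary_volume")
  pages <- lapply(seq_len(dim(vox)[3]),
                  function(k) t(vox[, , k]) / 255)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  write_sidecar_spacing(path, vol$spacing_um)
  invisible(path)
}

#' Read a bone mask from a TIFF written by [write_volume()]
#'
#' @param path TIFF path.
#' @param spacing_um voxel spacing, overriding the sidecar.
#' @param threshold provenance threshold to attach, if known.
#' @return A [binary_volume()].
#' @export
read_mask <- function(path, spacing_um = NULL, threshold = NULL) {
  g <- read_volume(path, spacing_um)
  vals <- unique(as.vector(g$voxels))
  if (!all(vals %in% c(0L, 255L)))
    stop("unsupported format: mask TIFF must contain only 0 and 255")
  binary_volume(g$voxels == 255L, g$spacing_um, threshold = threshold)
}

#' Construct a stacked per-slice ROI set
#'
#' Each entry holds a closed simple polygon in 0-based pixel coordinates of
#' voxel centres, its 0-based slice index and its compartment label. Slice
#' indices must be strictly increasing within a compartment, and the medial
#' and lateral polygons of one slice must not overlap.
#'
#' @param slices list of `list(slice=, compartment=, vertices=)` entries where
#'   `vertices` is an n x 2 matrix of `(x, y)` vertex coordinates.
#' @return An object of class `roi_stack`.
#' @export
roi_stack <- function(slices) {
  if (length(slices) == 0L) stop("empty ROI stack")
  for (s in slices) {
    if (!all(c("slice", "compartment", "vertices") %in% names(s)))
      stop("each ROI entry needs slice, compartment, vertices")
    if (!s$compartment %in% c("medial", "lateral"))
      stop("compartment must be 'medial' or 'lateral'")
    v <- s$vertices
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L)
      stop("vertices must be an n x 2 matrix with n >= 3")
    if (polygon_self_intersects(v))
      stop("ROI polygon is self-intersecting on slice ", s$slice)
  }
  for (cmp in c("medial", "lateral")) {
    idx <- vapply(slices, function(s) as.integer(s$slice), integer(1))
    sel <- vapply(slices, function(s) s$compartment == cmp, logical(1))
    if (any(sel) && any(diff(idx[sel]) <= 0))
      stop("slice indices must be strictly increasing within a compartment")
  }
  structure(list(slices = slices,
                 n_slices = length(unique(vapply(
                   slices, function(s) as.integer(s$slice), integer(1))))),
            class = "roi_stack")
}

#' @export
print.roi_stack <- function(x, ...) {
  cat(sprintf("<roi_stack> %d polygons over %d slices\n",
              length(x$slices), x$n_slices))
  invisible(x)
}

#' Read/write ROI stacks as JSON
#'
#' The on-disk format is a JSON list of
#' `{slice, compartment, vertices: [[x, y], ...]}` with 0-based voxel-centre
#' pixel coordinates.
#'
#' @param path JSON file path.
#' @return [read_roi_json()] returns a [roi_stack()].
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  slices <- lapply(raw, function(s) {
    v <- s$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    list(slice = as.integer(s$slice), compartment = s$compartment,
         vertices = matrix(as.numeric(v), ncol = 2))
  })
  roi_stack(slices)
}

#' @rdname read_roi_json
#' @param rois a [roi_stack()].
#' @export
write_roi_json <- function(rois, path) {
  out <- lapply(rois$slices, function(s)
    list(slice = s$slice, compartment = s$compartment,
         vertices = unname(s$vertices)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Rounded view used for report CSVs: integers for lengths/volumes, one
# decimal for percentages, Tb.N and percent differences.
round_report <- function(df) {
  rounded <- df
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    if (grepl("(_um$|_mm3$|^pl_th|^tbth|^tbsp|^bv$|^tv$)", nm)) {
      rounded[[nm]] <- round(df[[nm]])
    } else if (grepl("(_pct$|^bvtv|^pl_por|^tbn|pct_diff|^value$)", nm)) {
      rounded[[nm]] <- round(df[[nm]], 1)
    }
  }
  rounded
}

#' Write a morphometry report as CSV
#'
#' Writes one row per animal-limb-timepoint-compartment record at full
#' precision, plus a companion `<stem>_rounded.csv` view following the usual
#' publication rounding (integers for micrometre and cubic-millimetre
#' columns, one decimal for percentages, Tb.N and percent differences).
#'
#' @param records a non-empty data.frame of morphometry records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  records <- records[, sort_report_columns(names(records)), drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE)
  stem <- sub("\\.csv$", "", path)
  utils::write.csv(round_report(records), paste0(stem, "_rounded.csv"),
                   row.names = FALSE)
  invisible(path)
}

# deterministic column order: identifiers first, then parameters alphabetically
sort_report_columns <- function(nms) {
  ids <- c("animal", "limb", "week", "timepoint", "compartment", "parameter")
  c(intersect(ids, nms), sort(setdiff(nms, ids)))
}
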