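#' Segment a grayscale volume with a uniform global threshold
#'
#' A voxel is classified as bone when its intensity is greater than or equal
#' to the threshold (the `>=` rule is fixed so results are bit-exact). The
#' same study-wide threshold should be applied to all volumes of a
#' longitudinal series for comparability.
#'
#' @param gray a [gray_volume()].
#' @param threshold grey-level threshold in 0-255.
#' @return A [binary_volume()] with the threshold recorded as provenance.
#' @export
apply_threshold <- function(gray, threshold) {
  stopifnot(inherits(gray, "gray_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255)
    stop("threshold must be a single value in 0-255")
  binary_volume(gray$voxels >= threshold, gray$spacing_um,
                threshold = threshold)
}

#' Suggest a global threshold by maximising between-class variance
#'
#' Computes the 256-bin intensity histogram of the whole volume and returns
#' the split maximising the between-class variance (Otsu's criterion over the
#' pooled 3D histogram, so one study-wide value, not per-slice thresholds).
#' The returned value is meant for the `>=` bone rule of
#' [apply_threshold()]: bone is everything at or above it.
#'
#' @param gray a [gray_volume()] with at least two distinct intensities.
#' @return A single integer threshold in 1-255.
#' @export
suggest_threshold <- function(gray) {
  stopifnot(inherits(gray, "gray_volume"))
  counts <- tabulate(as.vector(gray$voxels) + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("constant image: threshold undefined")
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)                       # class-0 mass for split at k
  mu <- cumsum(p * levels)                 # class-0 first moment
  mu_t <- mu[256]
  # between-class variance for background = {0..k}, bone = {k+1..255}
  k <- seq_len(255L)
  valid <- omega[k] > 0 & omega[k] < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * omega[k][valid] - mu[k][valid])^2 /
    (omega[k][valid] * (1 - omega[k][valid]))
  split <- which.max(sigma_b)              # first maximum: deterministic
  as.integer(split)                        # bone rule: intensity >= split
}

#' Remove small speckles from a bone mask
#'
#' Deletes 26-connected bone components smaller than `min_size` voxels and
#' fills 6-connected background cavities smaller than `min_size` (the
#' standard complementary connectivity pair). Disabled in the pipeline by
#' default (`min_size = 0` is the identity).
#'
#' @param mask a [binary_volume()].
#' @param min_size minimum component size, in voxels, to keep.
#' @return A cleaned [binary_volume()].
#' @export
despeckle <- function(mask, min_size = 0L) {
  stopifnot(inherits(mask, "binary_volume"))
  if (min_size < 0) stop("min_size must be >= 0")
  if (min_size == 0L) return(mask)
  vox <- mask$voxels
  d <- dim(vox)
  small_components <- function(v, conn) {
    lab <- label3d_cpp(as.vector(v), d, conn)
    sizes <- tabulate(lab)
    array(lab > 0L & sizes[pmax(lab, 1L)] < min_size, dim = d)
  }
  vox[small_components(vox, 26L)] <- FALSE
  vox[small_components(!vox, 6L)] <- TRUE
  binary_volume(vox, mask$spacing_um, threshold = mask$threshold)
}
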