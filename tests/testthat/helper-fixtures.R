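# Shared fixture builders. Everything is generated in code; no binary files.

SP <- 8.7  # study voxel spacing, um

# VOI covering the whole grid of a mask
full_voi <- function(mask, compartment = "total") {
  voi_mask(array(TRUE, dim(mask$voxels)), compartment, mask$spacing_um)
}

# clean two-class grayscale rendition of a mask (bone 200, marrow 50)
mask_to_gray <- function(mask, bone = 200L, marrow = 50L) {
  vox <- array(marrow, dim = dim(mask$voxels))
  vox[mask$voxels] <- bone
  gray_volume(vox, mask$spacing_um)
}

# axis-aligned square ROI polygon, boundary inclusive: (x0..x1) x (y0..y1)
square_poly <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

square_rois <- function(slices, compartment, x0, y0, x1, y1) {
  lapply(slices, function(z)
    list(slice = z, compartment = compartment,
         vertices = square_poly(x0, y0, x1, y1)))
}

# single-cell longitudinal design (one parameter, one compartment)
one_cell_design <- function(weeks, mia_mean, mia_sd, ctl_mean, ctl_sd,
                            n_animals = 12L, correlation = 0.7, seed = 1L) {
  cohort_design(
    data.frame(parameter = "par", compartment = "total", week = weeks,
               mia_mean = mia_mean, mia_sd = mia_sd,
               ctl_mean = ctl_mean, ctl_sd = ctl_sd,
               stringsAsFactors = FALSE),
    n_animals = n_animals, correlation = correlation, seed = seed)
}
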