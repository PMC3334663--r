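test_that("plate separation recovers constructed geometry exactly", {
  p <- make_subchondral_phantom(104.4, 0, SP, dims = c(40L, 40L, 72L))
  sep <- separate_plate(p$mask, gap_bridge_um = 52.2)
  truth <- array(FALSE, dim(p$mask$voxels))
  truth[, , 1:p$plate_slices] <- TRUE
  expect_identical(sep$plate$voxels, truth)
  expect_identical(sep$trabecular$voxels, p$mask$voxels & !truth)
  # partition within the region
  expect_false(any(sep$plate$voxels & sep$trabecular$voxels))
  expect_identical(sep$plate$voxels | sep$trabecular$voxels, p$mask$voxels)
})

test_that("degenerate and bridged columns follow the column-scan rules", {
  # solid half-space: no gap, everything is plate
  vox <- array(FALSE, c(10L, 10L, 30L)); vox[, , 11:30] <- TRUE
  sep <- separate_plate(binary_volume(vox, SP))
  expect_identical(sep$plate$voxels, vox)
  expect_false(any(sep$trabecular$voxels))

  # 1-voxel internal pore inside the plate is bridged
  vox2 <- array(FALSE, c(5L, 5L, 40L)); vox2[, , 1:12] <- TRUE
  vox2[3, 3, 6] <- FALSE                         # pore < gap_bridge
  vox2[, , 30:40] <- TRUE                        # trabecular block below
  sep2 <- separate_plate(binary_volume(vox2, SP), gap_bridge_um = 52.2)
  expect_true(all(sep2$plate$voxels[3, 3, c(1:5, 7:12)]))
  expect_false(sep2$plate$voxels[3, 3, 6])       # the pore is not bone
  expect_false(any(sep2$plate$voxels[, , 30:40]))

  expect_error(separate_plate(binary_volume(array(FALSE, c(4, 4, 4)), SP)),
               "no bone")
})

test_that("plate thickness uses the direct-3D mean over plate voxels", {
  p <- make_subchondral_phantom(104.4, 0, SP, dims = c(40L, 40L, 72L))
  sep <- separate_plate(p$mask, gap_bridge_um = 52.2)
  expect_lt(abs(plate_thickness(sep$plate) - 104.4), SP)

  one <- array(FALSE, c(10L, 10L, 5L)); one[, , 1] <- TRUE
  expect_equal(plate_thickness(binary_volume(one, SP)), 2 * SP)  # minimal

  # pores excluded from the thickness domain
  pd <- make_subchondral_phantom(104.4, 20, SP, dims = c(60L, 60L, 72L))
  plate_only <- binary_volume(pd$mask$voxels[, , 1:pd$plate_slices, drop = FALSE],
                              SP)
  th <- local_thickness(plate_only, "bone")
  expect_true(all(is.na(th$values[!plate_only$voxels])))
  expect_error(plate_thickness(binary_volume(array(FALSE, c(3, 3, 3)), SP)),
               "empty")
})

test_that("plate porosity matches the drilled fraction and envelope rules", {
  pd <- make_subchondral_phantom(104.4, 20, SP, dims = c(60L, 60L, 72L))
  plate_only <- binary_volume(pd$mask$voxels[, , 1:pd$plate_slices, drop = FALSE],
                              SP)
  expect_lt(abs(plate_porosity(plate_only) - 20), 0.5)

  solid <- binary_volume(array(TRUE, c(20L, 20L, 12L)), SP)
  expect_equal(plate_porosity(solid), 0)

  # unenclosed no-bone columns are excluded from the envelope
  half <- array(FALSE, c(20L, 20L, 12L)); half[1:10, , ] <- TRUE
  expect_equal(plate_porosity(binary_volume(half, SP)), 0)
})

test_that("porosity ignores trabecular bone below the plate", {
  # plate with small internal (bridged) pores, alone vs over trabeculae
  base <- array(FALSE, c(20L, 20L, 40L))
  base[, , 1:12] <- TRUE
  set.seed(17)
  holes <- cbind(sample(2:19, 30, TRUE), sample(2:19, 30, TRUE),
                 sample(4:9, 30, TRUE))
  base[holes] <- FALSE
  alone <- separate_plate(binary_volume(base, SP), gap_bridge_um = 52.2)
  with_trab <- base
  with_trab[, , 30:40] <- TRUE
  below <- separate_plate(binary_volume(with_trab, SP), gap_bridge_um = 52.2)
  expect_identical(alone$plate$voxels, below$plate$voxels)
  expect_equal(plate_porosity(below$plate), plate_porosity(alone$plate))
  expect_gt(plate_porosity(alone$plate), 0)
})

test_that("growing gap_bridge never shrinks the plate", {
  vox <- array(FALSE, c(8L, 8L, 60L))
  vox[, , 1:6] <- TRUE
  vox[, , 10:12] <- TRUE                         # 3-voxel gap above
  vox[, , 40:60] <- TRUE                         # far trabecular block
  m <- binary_volume(vox, SP)
  prev <- separate_plate(m, gap_bridge_um = 0)$plate$voxels
  for (gb in c(2, 4, 30) * SP) {
    cur <- separate_plate(m, gap_bridge_um = gb)$plate$voxels
    expect_true(all(cur | !prev))                # superset of the previous
    prev <- cur
  }
})

test_that("total compartment metrics average medial and lateral", {
  expect_equal(total_compartment(146, 130), 138)
  expect_equal(total_compartment(7.3, 7.3), 7.3)
  expect_equal(total_compartment(0, 100), 50)
  expect_error(total_compartment(146), "required")
  expect_error(total_compartment(NA, 130), "missing")
})

test_that("compute_plate_metrics reports all three compartments", {
  p <- make_subchondral_phantom(104.4, 0, SP, dims = c(40L, 40L, 72L))
  regions <- list(medial = list(x_range = c(1L, 20L), y_range = c(1L, 40L)),
                  lateral = list(x_range = c(21L, 40L), y_range = c(1L, 40L)))
  pm <- compute_plate_metrics(p$mask, regions)
  expect_equal(pm$compartment, c("medial", "lateral", "total"))
  expect_equal(pm$pl_th_um[3], mean(pm$pl_th_um[1:2]))
  expect_equal(pm$pl_por_pct[3], mean(pm$pl_por_pct[1:2]))
})
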