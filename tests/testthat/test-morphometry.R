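test_that("bone volume fractions come from exact voxel counting", {
  dims <- c(20L, 20L, 20L)
  vox <- array(FALSE, dims)
  vox[seq_len(1234)] <- TRUE
  m <- binary_volume(vox, SP)
  voi <- voi_mask(array(TRUE, dims), "total", SP)
  bv <- bone_volume(m, voi)
  expect_equal(bv$bvtv_pct, 100 * 1234 / 8000)       # 15.425
  expect_equal(bv$tv_mm3, 8000 * (SP / 1000)^3)
  expect_equal(bv$bv_mm3, 1234 * (SP / 1000)^3)

  allb <- binary_volume(array(TRUE, dims), SP)
  expect_equal(bone_volume(allb, voi)$bvtv_pct, 100)
  empty <- voi_mask(array(FALSE, dims), "total", SP)
  expect_error(bone_volume(m, empty), "empty VOI")
})

test_that("local thickness recovers analytic shapes", {
  # solid sphere, radius 10 voxels, centred on a voxel centre
  dims <- c(31L, 31L, 31L)
  ctr <- c(15.5, 15.5, 15.5)
  co <- expand.grid(x = seq_len(dims[1]) - 0.5, y = seq_len(dims[2]) - 0.5,
                    z = seq_len(dims[3]) - 0.5)
  d2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2
  sphere <- binary_volume(array(d2 < 100, dims), SP)
  th <- local_thickness(sphere, "bone")
  expect_lt(abs(th$values[16, 16, 16] - 20 * SP), SP)        # centre diameter
  expect_lt(abs(mean_thickness(th) - 20 * SP), SP)           # interior mean

  # slab: exact 10 voxels away from the lateral borders
  s <- make_slab_phantom(87, 87, SP, dims = c(40L, 40L, 80L))
  ths <- local_thickness(s$mask, "bone")
  interior <- ths$values[15:25, 15:25, ]
  interior <- interior[!is.na(interior)]
  expect_true(all(abs(interior - 87) < 1e-9))

  # minimal element: an isolated voxel sits at the convention floor
  single <- array(FALSE, c(7, 7, 7)); single[4, 4, 4] <- TRUE
  tm <- local_thickness(binary_volume(single, SP), "bone")
  expect_equal(tm$values[4, 4, 4], 2 * SP)
})

test_that("mean thickness averages the map over its domain", {
  s <- make_slab_phantom(104.4, 261, SP, dims = c(64L, 64L, 126L))
  tbth <- mean_thickness(local_thickness(s$mask, "bone"))
  expect_lt(abs(tbth - 104.4), SP)                           # within 1 voxel

  # equal-volume mixture of 10- and 20-voxel slabs -> mean 15 voxels +- 1
  dims <- c(96L, 20L, 60L)
  vox <- array(FALSE, dims)
  vox[1:64, , 21:30] <- TRUE
  vox[65:96, , 21:40] <- TRUE
  mix <- binary_volume(vox, SP)
  expect_equal(sum(vox[1:64, , ]), sum(vox[65:96, , ]))      # equal volumes
  got <- mean_thickness(local_thickness(mix, "bone"))
  expect_lt(abs(got - 15 * SP), SP)

  uni <- local_thickness(binary_volume(array(TRUE, c(5, 5, 30)), SP), "bone")
  uni$values[] <- 87
  expect_equal(mean_thickness(uni), 87)
})

test_that("Tb.Sp equals the thickness of the marrow space (complementarity)", {
  s <- make_slab_phantom(87, 87, SP, dims = c(30L, 30L, 80L))
  voi <- full_voi(s$mask)
  map <- local_thickness(s$mask, "background", voi)
  # away from field corners the gap thickness is exact
  central <- map$values[10:20, 10:20, ]
  expect_true(all(abs(central[!is.na(central)] - 87) < 1e-9))
  expect_lt(abs(mean_thickness(map) - 87), SP)
  # Tb.Sp of the mask equals Tb.Th of its complement on the same domain
  comp <- binary_volume(!s$mask$voxels, SP)
  thc <- local_thickness(comp, "bone")
  expect_equal(thc$values[10:20, 10:20, ], central)
})

test_that("trabecular number follows (BV/TV)/Tb.Th with unit conversion", {
  expect_equal(round(trabecular_number(16.8, 94), 1), 1.8)
  expect_equal(trabecular_number(0, 94), 0)
  expect_equal(trabecular_number(50, 100), 5)
  expect_error(trabecular_number(10, 0), "> 0")
})

test_that("compute_morphometry keeps compartments additive and symmetric", {
  s <- make_slab_phantom(87, 87, SP, dims = c(24L, 20L, 80L))
  med <- array(FALSE, dim(s$mask$voxels)); med[1:10, , ] <- TRUE
  lat <- array(FALSE, dim(s$mask$voxels)); lat[15:24, , ] <- TRUE  # mirror-symmetric
  vois <- list(medial = voi_mask(med, "medial", SP),
               lateral = voi_mask(lat, "lateral", SP))
  mt <- compute_morphometry(s$mask, vois)
  expect_equal(nrow(mt), 3L)
  bv <- setNames(mt$bv_mm3, mt$compartment)
  expect_equal(bv[["total"]], bv[["medial"]] + bv[["lateral"]])
  # symmetric phantom: identical medial and lateral rows
  for (col in c("bv_mm3", "bvtv_pct", "tbth_um", "tbsp_um", "tbn_per_mm"))
    expect_equal(mt[[col]][1], mt[[col]][2])
  expect_equal(mt$tbn_per_mm,
               (mt$bvtv_pct / 100) / (mt$tbth_um / 1000))

  g <- make_grf_phantom(0.2, 26.1, SP, dims = c(48L, 48L, 48L), seed = 2)
  medg <- array(FALSE, dim(g$mask$voxels)); medg[1:24, , ] <- TRUE
  latg <- array(FALSE, dim(g$mask$voxels)); latg[25:48, , ] <- TRUE
  mtg <- compute_morphometry(g$mask, list(
    medial = voi_mask(medg, "medial", SP),
    lateral = voi_mask(latg, "lateral", SP)))
  expect_lt(abs(mtg$bvtv_pct[mtg$compartment == "total"] - 20), 0.5)
})

test_that("morphometry is scale-equivariant in the voxel spacing", {
  g <- make_grf_phantom(0.3, 26.1, SP, dims = c(32L, 32L, 32L), seed = 5)
  m1 <- g$mask
  m2 <- binary_volume(m1$voxels, 2 * SP)
  v1 <- full_voi(m1); v2 <- full_voi(m2)
  b1 <- bone_volume(m1, v1); b2 <- bone_volume(m2, v2)
  expect_equal(b2$bv_mm3, 8 * b1$bv_mm3)
  expect_equal(b2$bvtv_pct, b1$bvtv_pct)
  t1 <- mean_thickness(local_thickness(m1, "bone"))
  t2 <- mean_thickness(local_thickness(m2, "bone"))
  expect_equal(t2, 2 * t1)
  expect_equal(trabecular_number(b2$bvtv_pct, t2),
               trabecular_number(b1$bvtv_pct, t1) / 2)
})

test_that("thickness never exceeds the largest inscribed sphere", {
  g <- make_grf_phantom(0.25, 17.4, SP, dims = c(40L, 40L, 40L), seed = 11)
  th <- local_thickness(g$mask, "bone")
  edt <- bonemorph:::edt_sq_cpp(as.vector(g$mask$voxels),
                                dim(g$mask$voxels), TRUE)
  cap <- (2 * sqrt(max(edt)) + 1) * SP
  expect_lte(max(th$values, na.rm = TRUE), cap)
  expect_true(all(th$values[g$mask$voxels] > 0))
  expect_true(all(is.na(th$values[!g$mask$voxels])))
})
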