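test_that("feature registry exposes the fixed 100-feature catalogue", {
  reg <- featureRegistry()
  counts <- table(reg$class)
  expect_equal(unname(counts["first-order"]), 18L)
  expect_equal(unname(counts["shape"]), 14L)
  expect_equal(sum(counts[c("glcm", "glrlm", "glszm", "gldm")]), 68L)
  expect_equal(nrow(reg), 100L)
  expect_false(anyDuplicated(paste(reg$class, reg$feature)) > 0)
})

test_that("discretization follows the fixed-bin-width floor rule", {
  v <- imageVolume(array(c(0, 24.9, 25, 74, rep(0, 23)), c(3, 3, 3)))
  m <- voiMask(array(c(rep(TRUE, 4), rep(FALSE, 23)), c(3, 3, 3)))
  lev <- discretizeVolume(v, m, discretizationParams(binWidth = 25))
  expect_equal(lev[1:4], c(1L, 1L, 2L, 3L))
  expect_equal(attr(lev, "Ng"), 3L)

  const <- discretizeVolume(imageVolume(array(7, c(2, 2, 2))),
                            voiMask(array(TRUE, c(2, 2, 2))))
  expect_equal(attr(const, "Ng"), 1L)
  expect_true(all(const == 1L))
  expect_error(discretizeVolume(v, voiMask(array(FALSE, c(3, 3, 3)))),
               "empty")
})

test_that("isotropic resampling is exact on identities and linear ramps", {
  v <- imageVolume(array(rnorm(27), c(3, 3, 3)))
  m <- voiMask(array(TRUE, c(3, 3, 3)))
  out <- resampleIsotropic(v, m)
  expect_identical(out$volume@values, v@values)

  cv <- imageVolume(array(4.2, c(3, 3, 3)), spacing = c(2, 3, 1.5))
  outc <- resampleIsotropic(cv, m)
  expect_true(all(abs(outc$volume@values - 4.2) < 1e-12))

  ramp <- imageVolume(array(rep(seq(0, 6, by = 2), 4), c(4, 2, 2)),
                      spacing = c(2, 1, 1))
  outr <- resampleIsotropic(ramp, voiMask(array(TRUE, c(4, 2, 2))))
  # midpoints of a 2 mm ramp are the means of their neighbours
  expect_equal(outr$volume@values[2, 1, 1],
               mean(ramp@values[1:2, 1, 1]))
  expect_equal(outr$volume@values[4, 1, 1],
               mean(ramp@values[2:3, 1, 1]))
})

test_that("peritumoral dilation matches lattice-ball enumeration", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  tum <- voiMask(m)
  # lattice points with 0 < x^2+y^2+z^2 <= 4: 6 + 12 + 8 + 6 = 32
  peri <- dilatePeritumor(tum, c(1, 1, 1), radiusMm = 2)
  expect_equal(sum(peri@mask), 32L)
  expect_false(any(peri@mask & tum@mask))

  expect_equal(sum(dilatePeritumor(tum, c(1, 1, 1), 0)@mask), 0L)
  expect_error(dilatePeritumor(tum, c(1, 1, 1), -1), "non-negative")
  expect_error(dilatePeritumor(voiMask(array(FALSE, c(3, 3, 3))),
                               c(1, 1, 1)), "empty")

  allcover <- voiMask(array(TRUE, c(7, 7, 7)))
  expect_equal(sum(dilatePeritumor(tum, c(1, 1, 1), 2,
                                   exclusion = allcover)@mask), 0L)

  # nesting: shell of radius r1 is contained in shell of radius r2 >= r1
  p1 <- dilatePeritumor(tum, c(1, 1, 1), 1.5)@mask
  p2 <- dilatePeritumor(tum, c(1, 1, 1), 3)@mask
  expect_true(all(p2[p1]))
})

test_that("first-order features match hand computation and conventions", {
  m4 <- voiMask(array(c(rep(TRUE, 4), rep(FALSE, 23)), c(3, 3, 3)))
  fo <- firstOrderFeatures(imageVolume(array(c(1, 2, 3, 4, rep(0, 23)),
                                             c(3, 3, 3))), m4)
  expect_equal(length(fo), 18L)
  expect_equal(unname(fo["Mean"]), 2.5)
  expect_equal(unname(fo["Range"]), 3)
  expect_equal(unname(fo["Minimum"]), 1)
  expect_equal(unname(fo["Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(fo["Variance"]), mean((1:4 - 2.5)^2))

  cc <- firstOrderFeatures(imageVolume(array(5, c(2, 2, 2))),
                           voiMask(array(TRUE, c(2, 2, 2))))
  expect_equal(unname(cc["Minimum"]), 5)
  expect_equal(unname(cc["Variance"]), 0)
  expect_equal(unname(cc["Skewness"]), 0)
  expect_equal(unname(cc["Kurtosis"]), 0)
})

test_that("shape features follow face-counting geometry", {
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  sf <- shapeFeatures(voiMask(single), c(1, 1, 1))
  expect_equal(length(sf), 14L)
  expect_equal(unname(sf["SurfaceVolumeRatio"]), 6)
  expect_equal(unname(sf["VoxelVolume"]), 1)

  cube <- array(FALSE, c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- TRUE
  sf2 <- shapeFeatures(voiMask(cube), c(1, 1, 1))
  expect_equal(unname(sf2["SurfaceArea"]), 24)
  expect_equal(unname(sf2["SurfaceVolumeRatio"]), 3)
  expect_equal(unname(sf2["Maximum3DDiameter"]), sqrt(3))

  # anisotropic spacing scales the physical measurements
  sf3 <- shapeFeatures(voiMask(single), c(2, 1, 1))
  expect_equal(unname(sf3["VoxelVolume"]), 2)
  expect_equal(unname(sf3["SurfaceArea"]), 2 * 1 + 2 * 2 + 2 * 2)
})

test_that("texture features take their degenerate values on constant VOIs", {
  lev <- discretizeVolume(imageVolume(array(9, c(3, 3, 3))),
                          voiMask(array(TRUE, c(3, 3, 3))))
  g <- glcmFeatures(lev)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["Idn"]), 1)
  expect_equal(unname(g["Idmn"]), 1)
  expect_equal(unname(g["Correlation"]), 1)
  tx <- textureFeatures(lev)
  expect_equal(nrow(tx), 68L)
  expect_equal(as.vector(table(tx$class)[c("glcm", "glrlm", "glszm",
                                           "gldm")]), c(22L, 16L, 16L, 14L))
})

test_that("all four texture families match brute-force enumeration", {
  for (seed in 1:6) {
    lev <- random_levels(c(4, 4, 3), ng = 4, seed = seed)
    expect_equal(glcmFeatures(lev),
                 oracle_glcm_features(lev, 4), tolerance = 1e-12)
    expect_equal(glrlmFeatures(lev),
                 oracle_glrlm_features(lev, 4), tolerance = 1e-12)
    expect_equal(glszmFeatures(lev),
                 oracle_glszm_features(lev, 4), tolerance = 1e-12)
    expect_equal(gldmFeatures(lev),
                 oracle_gldm_features(lev, 4), tolerance = 1e-12)
  }
})

test_that("texture is invariant to a constant intensity offset", {
  set.seed(31)
  vals <- array(sample(seq(0, 150, by = 10), 60, TRUE), c(5, 4, 3))
  m <- voiMask(array(runif(60) > 0.2, c(5, 4, 3)))
  l1 <- discretizeVolume(imageVolume(vals), m)
  l2 <- discretizeVolume(imageVolume(vals + 500), m)
  expect_identical(l1[m@mask], l2[m@mask])
  expect_equal(textureFeatures(l1)$value, textureFeatures(l2)$value)
})

test_that("multi-view extraction yields 400 annotated columns", {
  cfg <- cohortConfig(nPatients = 4, seed = 21, makeVolumes = TRUE,
                      volumeDim = c(26L, 26L, 16L),
                      lesionRadiusMm = c(5, 4.5, 4))
  vols <- generateVolumes(cfg)
  ft <- suppressWarnings(extractMultiview(vols, radiusMm = 4))
  expect_s4_class(ft, "MultiViewFeatureTable")
  expect_equal(ncol(featureValues(ft)), 400L)
  expect_equal(sort(unique(featureInfo(ft)$view)), paste0("type", 1:4))
  expect_equal(nrow(featureValues(ft)), 4L)

  # all-constant single patient: z-scoring impossible, constant columns
  flat <- list(P1 = list(
    arterial = imageVolume(array(50, c(12, 12, 8))),
    venous = imageVolume(array(70, c(12, 12, 8))),
    tumor = voiMask(array(c(rep(TRUE, 64), rep(FALSE, 1088)),
                          c(12, 12, 8)))))
  flat$P1$tumor@mask[] <- FALSE
  flat$P1$tumor@mask[5:8, 5:8, 3:6] <- TRUE
  expect_warning(ft1 <- extractMultiview(flat, radiusMm = 2),
                 "fewer than 2 patients")
  expect_equal(nrow(featureValues(ft1)), 1L)
})
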