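mk4 <- function(..., shape = c(2, 2, 1)) {
  vals <- list(...)
  arr <- array(0, dim = c(shape, length(vals)),
               dimnames = list(NULL, NULL, NULL, names(vals)))
  for (a in names(vals)) arr[, , , a] <- vals[[a]]
  arr
}

test_that("weighted ATT is the flow-weighted mean of per-artery ATTs", {
  # single-artery voxel: weighted ATT equals that artery's ATT
  pa <- list(cbf = mk4(RICA = 40, LICA = 0),
             att = mk4(RICA = 1.2, LICA = 2.0),
             artery_ids = c("RICA", "LICA"))
  expect_equal(unique(as.numeric(weighted_att(pa))), 1.2)
  # equal flows average the transit times
  pa2 <- list(cbf = mk4(RICA = 25, LICA = 25),
              att = mk4(RICA = 1.0, LICA = 1.4),
              artery_ids = c("RICA", "LICA"))
  expect_equal(unique(as.numeric(weighted_att(pa2))), 1.2)
  # zero total flow is masked
  pa3 <- list(cbf = mk4(RICA = 0, LICA = 0),
              att = mk4(RICA = 1, LICA = 1))
  expect_true(all(is.na(weighted_att(pa3))))
})

test_that("weighted ATT stays within the per-artery ATT range", {
  set.seed(41)
  shape <- c(5, 4, 3)
  cbf <- array(stats::runif(prod(shape) * 3, 0, 60), dim = c(shape, 3),
               dimnames = list(NULL, NULL, NULL, c("A", "B", "C")))
  att <- array(stats::runif(prod(shape) * 3, 0.5, 2.5), dim = c(shape, 3),
               dimnames = dimnames(cbf))
  wa <- weighted_att(list(cbf = cbf, att = att))
  lo <- pmin(att[, , , 1], att[, , , 2], att[, , , 3])
  hi <- pmax(att[, , , 1], att[, , , 2], att[, , , 3])
  expect_true(all(wa >= lo - 1e-12 & wa <= hi + 1e-12))
})

test_that("Direct/Indirect split depends on the chosen ipsilateral ICA", {
  pa <- list(cbf = mk4(RICA = 30, LICA = 10, RVA = 5, LVA = 5),
             att = NULL, artery_ids = c("RICA", "LICA", "RVA", "LVA"))
  d1 <- direct_indirect(pa, "RICA")
  expect_equal(unique(as.numeric(d1$direct_cbf)), 30)
  expect_equal(unique(as.numeric(d1$indirect_cbf)), 20)
  d2 <- direct_indirect(pa, "LICA")
  expect_equal(unique(as.numeric(d2$direct_cbf)), 10)
  expect_equal(unique(as.numeric(d2$indirect_cbf)), 40)
  # direct + indirect = total, exactly, and zero maps stay zero
  expect_equal(d1$direct_cbf + d1$indirect_cbf, d1$total_cbf)
  pz <- list(cbf = mk4(RICA = 0, LICA = 0, RVA = 0, LVA = 0),
             att = NULL, artery_ids = c("RICA", "LICA", "RVA", "LVA"))
  dz <- direct_indirect(pz, "RICA")
  expect_true(all(dz$total_cbf == 0))
  expect_error(direct_indirect(pa, "basilar"), "unknown")
})

test_that("ADC core selection thresholds and keeps the largest component", {
  shape <- c(10, 10, 4)
  adc <- array(800e-6, dim = shape)
  expect_false(any(core_from_adc(adc)))
  adc[3:5, 3:5, 2] <- 500e-6
  core <- core_from_adc(adc)
  expect_equal(sum(core), 9)
  expect_true(all(which(core) %in% which(adc < 620e-6)))
  # a 3-voxel satellite is dropped in favor of the larger component
  adc2 <- adc
  adc2[8:10, 9, 4] <- 500e-6
  core2 <- core_from_adc(adc2)
  expect_equal(sum(core2), 9)
  expect_false(any(core2[8:10, 9, 4]))
  core3 <- core_from_adc(adc2, largest_component = FALSE)
  expect_equal(sum(core3), 12)
})

test_that("shell ROIs match brute-force spherical dilation", {
  # single voxel, radius 5 mm, isotropic 5 mm voxels: the 6 face neighbors
  m <- array(FALSE, dim = c(5, 5, 5)); m[3, 3, 3] <- TRUE
  sh <- shell_roi(m, 5, c(5, 5, 5))
  expect_equal(sum(sh), 6)
  expect_true(sh[2, 3, 3] && sh[4, 3, 3] && sh[3, 2, 3] && sh[3, 4, 3] &&
                sh[3, 3, 2] && sh[3, 3, 4])
  expect_false(any(shell_roi(array(FALSE, c(4, 4, 4)), 10, c(3.4, 3.4, 5))))
  set.seed(61)
  for (radius in c(5, 10, 20)) {
    mask <- array(stats::runif(16^3) < 0.01, dim = c(16, 16, 16))
    got <- shell_roi(mask, radius, c(3.4, 3.4, 5))
    want <- brute_dilate(mask, radius, c(3.4, 3.4, 5)) & !mask
    expect_identical(got, want)
    expect_false(any(got & mask))
  }
  expect_error(shell_roi(m, 0, c(5, 5, 5)), "positive")
})

test_that("mirroring reflects across the midline and is an involution", {
  shape <- c(11, 6, 3)
  mid <- 6
  m <- array(FALSE, dim = shape); m[mid + 3, 2, 1] <- TRUE
  mm <- mirror_mask(m, mid)
  expect_true(mm[mid - 3, 2, 1])
  expect_equal(sum(mm), 1)
  expect_identical(mirror_mask(mm, mid), m)
  # symmetric masks are fixed points
  sym <- array(FALSE, dim = shape)
  sym[c(4, 8), 3, 2] <- TRUE
  expect_identical(mirror_mask(sym, mid), sym)
  expect_error(mirror_mask(m, 40), "midline")
})

test_that("gray-matter restriction uses a strict threshold", {
  shape <- c(6, 5, 2)
  m <- array(TRUE, dim = shape)
  gm <- array(0.5, dim = shape)
  expect_false(any(restrict_to_gm(m, gm)))
  gm1 <- array(1, dim = shape)
  expect_identical(restrict_to_gm(m, gm1), m)
  set.seed(71)
  gmr <- array(stats::runif(prod(shape)), dim = shape)
  mr <- array(stats::runif(prod(shape)) < 0.5, dim = shape)
  expect_identical(restrict_to_gm(mr, gmr), mr & (gmr > 0.5))
  expect_error(restrict_to_gm(m, array(1, c(2, 2, 2))), "differ")
})

test_that("the ROI set obeys its exclusion and hemisphere contracts", {
  truth <- generate_truth(tiny_spec())
  core <- core_from_adc(truth$adc)
  rois <- suppressMessages(
    build_roi_set(core, truth$infarct, truth$gm_pv, truth$voxel_size_mm,
                  surviving_radius_mm = 10, peri_core_radius_mm = 10)
  )
  expect_false(any(rois$surviving_tissue & rois$final_infarct))
  expect_false(any(rois$peri_core & rois$ischemic_core))
  expect_true(all(truth$gm_pv[rois$surviving_tissue] > 0.5))
  expect_true(all(truth$gm_pv[rois$peri_core] > 0.5))
  mid <- (dim(core)[1] + 1) / 2
  xs <- slice.index(array(0, dim(core)), 1)
  # the lesion is on the low-x (right) side: ipsilateral ROIs stay there
  expect_true(all(xs[rois$surviving_tissue] < mid))
  expect_true(all(xs[rois$peri_core] < mid))
  expect_true(all(xs[rois$surviving_tissue_contra] > mid))
  expect_true(all(xs[rois$peri_core_contra] > mid))
  # mirrored anatomy makes the contralateral ROIs mirror images
  flip <- function(a) a[dim(a)[1]:1, , ]
  expect_identical(unname(rois$peri_core_contra),
                   unname(flip(rois$peri_core)))
  # an empty infarct yields an empty surviving-tissue ROI
  empty <- array(FALSE, dim(core))
  rois0 <- suppressMessages(
    build_roi_set(core, empty, truth$gm_pv, truth$voxel_size_mm)
  )
  expect_false(any(rois0$surviving_tissue))
  expect_error(build_roi_set(core, empty, array(1, c(2, 2, 2)), c(3, 3, 5)),
               "share")
})
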