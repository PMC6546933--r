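test_that("a lesion-free phantom is baseline supply with an empty core", {
  truth <- generate_truth(tiny_spec("none"))
  expect_false(any(truth$core))
  total <- apply(truth$cbf, 1:3, sum)
  base <- (truth$spec$cbf_wm +
             (truth$spec$cbf_gm - truth$spec$cbf_wm) * truth$gm_pv) *
    truth$brain
  expect_equal(total, base, tolerance = 1e-12, ignore_attr = TRUE)
  # transit times sit at the artery baselines everywhere
  expect_true(all(truth$att[, , , "RICA"] == truth$spec$att_ica_s))
  expect_true(all(truth$att[, , , "LVA"] == truth$spec$att_va_s))
})

test_that("ICA occlusion reroutes the territory to the contralateral ICA", {
  truth <- generate_truth(tiny_spec("ica-occlusion"))
  expect_true(all(truth$cbf[, , , "RICA"] == 0))
  # right anterior territory is now fed by the LICA
  right_ant <- truth$weights[, , , "RICA"] == 1 & truth$brain &
    !truth$lesion
  expect_true(all(truth$cbf[, , , "LICA"][right_ant] > 0))
})

test_that("phantom generation is deterministic under a fixed seed", {
  t1 <- generate_truth(tiny_spec(seed = 13))
  t2 <- generate_truth(tiny_spec(seed = 13))
  expect_identical(t1$cbf, t2$cbf)
  expect_identical(t1$infarct, t2$infarct)
  t3 <- generate_truth(tiny_spec(seed = 14))
  expect_false(identical(t1$infarct, t3$infarct))
  proto <- default_protocol(); mat <- build_encoding_matrix()
  s1 <- synthesize_series(t1, proto, mat, noise_sd = 2, seed = 5)
  s2 <- synthesize_series(t1, proto, mat, noise_sd = 2, seed = 5)
  expect_identical(s1$data, s2$data)
})

test_that("phantom structure honors its own invariants", {
  truth <- generate_truth(tiny_spec())
  expect_true(all(truth$cbf >= 0))
  expect_true(all(truth$adc > 0))
  # core lies inside the low-ADC region and inside the final infarct
  expect_true(all(truth$adc[truth$core] < 620e-6))
  expect_true(all(truth$infarct[truth$core]))
  # mirror symmetry of the anatomy (not the lesion): gray matter and brain
  flip <- function(a) a[dim(a)[1]:1, , ]
  expect_equal(truth$brain, flip(truth$brain), ignore_attr = TRUE)
  expect_equal(truth$gm_pv, flip(truth$gm_pv), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(generate_truth(tiny_spec(lesion_center_mm = c(500, 0, 0))),
               "outside")
})

test_that("non-selective difference equals twice the summed artery signal", {
  truth <- generate_truth(tiny_spec())
  proto <- default_protocol()
  mat <- build_encoding_matrix()
  ser <- synthesize_series(truth, proto, mat, noise_sd = 0)
  sched <- ser$schedule
  cst <- kinetic_constants()
  p <- 3L
  ctrl <- ser$data[, , , sched$volume[sched$pld_index == p &
                                        sched$cycle_name == "control"][1]]
  labl <- ser$data[, , , sched$volume[sched$pld_index == p &
                                        sched$cycle_name == "label"][1]]
  # rebuild the per-voxel total difference signal with scalar kinetic
  # model calls and slice timing
  tau <- proto$label_duration_s
  shape <- dim(truth$brain)
  expected <- array(0, dim = shape)
  for (k in seq_len(shape[3])) {
    sl <- round(seq(0, proto$n_slices - 1, length.out = shape[3]))[k]
    t <- tau + slice_pld(proto, p, sl)
    for (a in truth$artery_ids) {
      expected[, , k] <- expected[, , k] + matrix(
        mapply(function(cc, aa) delta_m(t, cc, aa, truth$m0_blood, tau, cst),
               truth$cbf[, , k, a], truth$att[, , k, a]),
        nrow = shape[1])
    }
  }
  expect_equal(ctrl - labl, 2 * expected, tolerance = 1e-9)
})

test_that("a zero-flow phantom synthesizes pure static tissue plus noise", {
  spec <- tiny_spec("none", cbf_gm = 0, cbf_wm = 0)
  truth <- generate_truth(spec)
  proto <- default_protocol(); mat <- build_encoding_matrix()
  ser <- synthesize_series(truth, proto, mat, noise_sd = 0,
                           static_signal = 700)
  for (v in c(1L, 50L, 96L)) {
    expect_equal(ser$data[, , , v], 700 * truth$brain,
                 ignore_attr = TRUE)
  }
})

test_that("series round trips through NIfTI + sidecar files", {
  truth <- generate_truth(tiny_spec())
  proto <- default_protocol(); mat <- build_encoding_matrix()
  ser <- synthesize_series(truth, proto, mat, noise_sd = 1, seed = 3)
  prefix <- file.path(withr::local_tempdir(), "asl")
  write_series(ser, prefix)
  ser2 <- read_series(prefix)
  expect_equal(ser2$data, ser$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ser2$matrix$weights, ser$matrix$weights)
  expect_equal(ser2$schedule$cycle_index, ser$schedule$cycle_index)
  expect_equal(ser2$protocol, ser$protocol)
})
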