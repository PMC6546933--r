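test_that("noiseless single-artery signals are decoded exactly", {
  mat <- build_encoding_matrix()
  classes <- decode_classes(colnames(mat$weights))
  dm_true <- 6.5
  static <- 640
  y <- static + mat$weights[, "RVA"] * dm_true
  res <- decode_voxel(y, mat, classes, noise_sd = 0.01,
                      amplitude_prior_sd = 50)
  expect_equal(res$class, "RVA")
  expect_equal(unname(res$dm["RVA"]), dm_true, tolerance = 1e-10)
  expect_equal(unname(res$dm[c("RICA", "LICA", "LVA")]), rep(0, 3))
  expect_equal(res$static, static, tolerance = 1e-8)
})

test_that("a zero signal vector selects the empty class", {
  mat <- build_encoding_matrix()
  res <- decode_voxel(rep(0, 8), mat, noise_sd = 1,
                      amplitude_prior_sd = 50)
  expect_equal(res$class, character(0))
  expect_equal(unname(res$dm), rep(0, 4))
})

test_that("MAP class selection matches the exhaustive dense-route oracle", {
  set.seed(21)
  mat <- build_encoding_matrix()
  classes <- decode_classes(colnames(mat$weights))
  for (i in 1:40) {
    support <- sample(0:2, 1)
    idx <- sample(4, support)
    amps <- stats::runif(support, 2, 10)
    y <- rep(500, 8)
    for (j in seq_len(support)) y <- y + mat$weights[, idx[j]] * amps[j]
    y <- y + stats::rnorm(8, 0, 1)
    res <- decode_voxel(y, mat, classes, noise_sd = 1,
                        amplitude_prior_sd = 40)
    ora <- oracle_decode(y, mat, classes, noise_sd = 1,
                         amplitude_prior_sd = 40)
    expect_equal(which.max(res$log_posterior), ora$best,
                 ignore_attr = TRUE)
    expect_equal(res$log_posterior, ora$scores, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(res$dm, ora$dm, tolerance = 1e-8)
  }
})

test_that("with noiseless data the selected class has the smallest residual", {
  set.seed(31)
  mat <- build_encoding_matrix()
  classes <- decode_classes(colnames(mat$weights))
  for (i in 1:10) {
    idx <- sample(4, 2)
    y <- 300 + mat$weights[, idx[1]] * 8 + mat$weights[, idx[2]] * 5
    res <- decode_voxel(y, mat, classes, noise_sd = 1e-6,
                        amplitude_prior_sd = 40)
    rss <- vapply(classes, function(cl) {
      X <- cbind(mat$weights[, cl, drop = FALSE], 1)
      sum(stats::lm.fit(X, y)$residuals^2)
    }, numeric(1))
    expect_equal(rss[which.max(res$log_posterior)], min(rss),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("decoding is equivariant under artery relabeling", {
  mat <- build_encoding_matrix()
  perm <- c(3, 1, 4, 2)
  mat2 <- mat
  mat2$weights <- mat$weights[, perm]
  y <- 400 + mat$weights[, "LICA"] * 7 + rep(c(0.3, -0.2), 4)
  r1 <- decode_voxel(y, mat, noise_sd = 0.5, amplitude_prior_sd = 40)
  r2 <- decode_voxel(y, mat2, noise_sd = 0.5, amplitude_prior_sd = 40)
  expect_equal(r2$dm, r1$dm[perm])
  expect_equal(sort(r2$class), sort(r1$class))
})

test_that("noiseless series decoding recovers the generator's signals", {
  truth <- generate_truth(tiny_spec())
  proto <- default_protocol(); mat <- build_encoding_matrix()
  ser <- synthesize_series(truth, proto, mat, noise_sd = 0)
  dec <- decode_series(ser, mask = truth$brain)
  dm_true <- vepcasl:::phantom_dm(truth, proto, kinetic_constants())
  # compare within voxels whose true support is in the class set (<= 2)
  supp <- apply(truth$cbf > 0, 1:3, sum)
  ok <- truth$brain & supp <= 2
  err <- 0
  for (a in seq_along(truth$artery_ids)) {
    for (p in seq_len(6)) {
      d <- abs(dec$dm[, , , a, p] - dm_true[, , , a, p])
      err <- max(err, max(d[ok]))
    }
  }
  expect_lt(err, 1e-6)
})

test_that("an all-zero-perfusion series decodes to near-zero signals", {
  spec <- tiny_spec("none", cbf_gm = 0, cbf_wm = 0)
  truth <- generate_truth(spec)
  proto <- default_protocol(); mat <- build_encoding_matrix()
  ser <- synthesize_series(truth, proto, mat, noise_sd = 0.5, seed = 9,
                           static_signal = 700)
  dec <- decode_series(ser, mask = truth$brain)
  expect_lt(max(abs(dec$dm)), 5 * 0.5)
  # the vast majority of voxels should land in the empty class
  expect_gt(mean(dec$class_map[truth$brain] == 1), 0.9)
})

test_that("permuting volumes with a corrected sidecar changes nothing", {
  truth <- generate_truth(tiny_spec())
  proto <- default_protocol(); mat <- build_encoding_matrix()
  ser <- synthesize_series(truth, proto, mat, noise_sd = 1, seed = 4)
  set.seed(5)
  perm <- sample(96)
  ser2 <- ser
  ser2$data <- ser$data[, , , perm]
  ser2$schedule <- ser$schedule[perm, ]
  ser2$schedule$volume <- seq_len(96)
  d1 <- decode_series(ser, mask = truth$brain)
  d2 <- decode_series(ser2, mask = truth$brain)
  expect_identical(d1$class_map, d2$class_map)
  expect_equal(d1$dm, d2$dm)
})

test_that("volume/schedule mismatches are reported as input errors", {
  truth <- generate_truth(tiny_spec())
  proto <- default_protocol(); mat <- build_encoding_matrix()
  ser <- synthesize_series(truth, proto, mat)
  ser$data <- ser$data[, , , 1:90]
  expect_error(decode_series(ser), "90 volumes")
})
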