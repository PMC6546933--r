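mk_derived <- function(direct, indirect) {
  shape <- dim(direct)
  structure(list(total_cbf = direct + indirect, direct_cbf = direct,
                 indirect_cbf = indirect, weighted_att = NULL,
                 ipsilateral_artery_id = "RICA"),
            class = "derived_maps")
}

test_that("indirect fraction is the ROI-sum ratio", {
  shape <- c(2, 1, 1)
  roi <- array(TRUE, shape)
  d0 <- mk_derived(array(30, shape), array(0, shape))
  expect_equal(indirect_fraction(d0, roi), 0)
  d1 <- mk_derived(array(0, shape), array(30, shape))
  expect_equal(indirect_fraction(d1, roi), 1)
  # voxels (direct 30, indirect 10) and (direct 0, indirect 20): 30/60
  d2 <- mk_derived(array(c(30, 0), shape), array(c(10, 20), shape))
  expect_equal(indirect_fraction(d2, roi), 0.5)
  # invariant to uniform rescaling of all maps
  d3 <- mk_derived(array(c(30, 0), shape) * 3.7,
                   array(c(10, 20), shape) * 3.7)
  expect_equal(indirect_fraction(d3, roi), 0.5)
  # voxelwise-mean variant: mean(10/40, 20/20)
  expect_equal(indirect_fraction(d2, roi, method = "voxel_mean"),
               mean(c(0.25, 1)))
  expect_error(indirect_fraction(d2, array(FALSE, shape)), "empty")
  dz <- mk_derived(array(0, shape), array(0, shape))
  expect_error(indirect_fraction(dz, roi), "no flow")
})

test_that("survival table counts match exhaustive enumeration on a toy", {
  # 20 voxels with hand-chosen bins, survival and direct-CBF exclusion
  shape <- c(20, 1, 1)
  direct <- array(c(rep(10, 16), 30, 26, 25, 24), shape)
  indirect <- array(c(5, 15, 15, 25, 35, 35, 35, 45, 55, 65,
                      75, 85, 95, 5, 15, 25, 40, 50, 60, 70), shape)
  infarct <- array(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE), shape)
  peri <- array(TRUE, shape)
  tab <- survival_table(direct, indirect, infarct, peri, min_count = 1)
  # voxels 17 and 18 are excluded (direct > 25); 25.0 is retained
  kept <- c(1:16, 19, 20)
  for (b in seq_len(nrow(tab))) {
    lo <- tab$bin_low[b]; hi <- tab$bin_high[b]
    in_bin <- kept[indirect[kept] >= lo & indirect[kept] < hi]
    expect_equal(tab$total[b], length(in_bin))
    expect_equal(tab$surviving[b], sum(!infarct[in_bin]))
  }
  # top bin is open-ended
  expect_equal(tab$total[tab$bin_low == 80], 2)
  # all-survivors toy: every non-empty bin has fraction 1
  tab1 <- survival_table(direct, indirect, array(FALSE, shape), peri,
                         min_count = 1)
  expect_true(all(tab1$fraction[tab1$total > 0] == 1))
  # sparse bins fall below the reporting threshold
  tab10 <- survival_table(direct, indirect, infarct, peri, min_count = 10)
  expect_true(all(is.na(tab10$fraction[tab10$total < 10])))
})

test_that("the split test reproduces the pooled two-proportion z-test", {
  tab <- data.frame(bin_low = c(0, 30), bin_high = c(10, 40),
                    total = c(100, 100), surviving = c(50, 50))
  res <- binomial_split_test(tab, split = 25)
  expect_equal(res$p_value, 1)
  expect_equal(res$z, 0)
  # textbook cross-check: z^2 equals the uncorrected chi-square statistic
  tab2 <- data.frame(bin_low = c(0, 30), bin_high = c(10, 40),
                     total = c(10, 10), surviving = c(6, 9))
  res2 <- binomial_split_test(tab2, split = 25)
  pt <- suppressWarnings(stats::prop.test(c(6, 9), c(10, 10),
                                          correct = FALSE))
  expect_equal(res2$z^2, unname(pt$statistic))
  expect_equal(res2$p_value, pt$p.value)
  # independent formula evaluation
  p_pool <- 15 / 20
  z_want <- (0.9 - 0.6) / sqrt(p_pool * (1 - p_pool) * (1 / 10 + 1 / 10))
  expect_equal(res2$z, z_want)
  tab3 <- data.frame(bin_low = c(30, 40), bin_high = c(40, 50),
                     total = c(10, 10), surviving = c(5, 5))
  expect_error(binomial_split_test(tab3, split = 25), "no voxels")
})

test_that("relative survival increase follows its printed definition", {
  tab <- data.frame(bin_low = c(0, 70), bin_high = c(10, 80),
                    total = c(50, 50), surviving = c(25, 25),
                    fraction = c(0.5, 0.5))
  expect_equal(relative_increase(tab), 0)
  tab$fraction <- c(0.5, 0.725)
  expect_equal(relative_increase(tab), 45)
  tab$fraction <- c(0, 0.7)
  expect_error(relative_increase(tab), "zero")
  tab$fraction <- c(NA, 0.7)
  expect_error(relative_increase(tab), "empty")
})

test_that("two-way ANOVA matches hand-computed sums of squares", {
  # balanced 2x2 design: closed-form main-effect SS
  vals <- c(10, 12, 14, 16, 20, 22, 24, 26)
  df <- data.frame(
    patient_id = rep(1:4, 2),
    timepoint = rep(c("presentation", "month1"), each = 4),
    roi = rep(c("surviving", "contralateral"), 4),
    indirect_frac = (vals - min(vals)) / 20,
    mean_watt = vals / 20
  )
  res <- two_way_anova(df, response = "mean_watt")
  y <- df$mean_watt
  ss_roi <- sum(tapply(y, df$roi, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_tp <- sum(tapply(y, df$timepoint,
                      function(v) length(v) * (mean(v) - mean(y))^2))
  expect_equal(res$anova["roi", "Sum Sq"], ss_roi, tolerance = 1e-10)
  expect_equal(res$anova["timepoint", "Sum Sq"], ss_tp, tolerance = 1e-10)
})

test_that("identical ROI values give a null ROI effect and no post-hocs", {
  set.seed(5)
  base <- stats::runif(6, 0.2, 0.8)
  df <- data.frame(
    patient_id = rep(1:6, 2),
    timepoint = rep(rep(c("presentation", "month1"), 3), 2),
    roi = rep(c("surviving", "contralateral"), each = 6),
    indirect_frac = rep(base, 2),
    mean_watt = rep(base, 2)
  )
  res <- two_way_anova(df, response = "indirect_frac")
  expect_lt(res$anova["roi", "F value"], 1e-10)
  expect_gt(res$roi_p, 0.99)
  expect_null(res$posthoc)
})

test_that("significant ROI effects trigger per-timepoint t-tests", {
  set.seed(6)
  df <- do.call(rbind, lapply(1:8, function(pid) {
    rbind(
      patient_summary(pid, "presentation", "surviving",
                      0.4 + stats::rnorm(1, 0, 0.02), 1.35),
      patient_summary(pid, "presentation", "contralateral",
                      0.2 + stats::rnorm(1, 0, 0.02), 1.22),
      patient_summary(pid, "month1", "surviving",
                      0.3 + stats::rnorm(1, 0, 0.02), 1.28),
      patient_summary(pid, "month1", "contralateral",
                      0.2 + stats::rnorm(1, 0, 0.02), 1.22)
    )
  }))
  res <- two_way_anova(df, response = "indirect_frac")
  expect_lt(res$roi_p, 0.05)
  expect_s3_class(res$posthoc, "data.frame")
  expect_equal(sort(res$posthoc$timepoint),
               sort(c("presentation", "month1")))
  expect_true(all(res$posthoc$p_value < 0.05))
  expect_error(two_way_anova(df[df$roi == "surviving", ]), "two levels")
})
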