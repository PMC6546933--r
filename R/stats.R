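#' Indirect CBF as a proportion of total CBF in a region
#'
#' The ROI-sum ratio `sum(indirect) / sum(total)` over the region. A
#' sum-ratio (rather than the mean of voxelwise ratios) is robust to
#' near-zero-flow voxels; the voxelwise-mean variant is available via
#' `method = "voxel_mean"`.
#'
#' @param derived A `derived_maps` object.
#' @param roi Logical 3D array, non-empty, with positive total flow.
#' @param method `"sum_ratio"` (default) or `"voxel_mean"` (mean of
#'   voxelwise ratios over voxels with positive total flow).
#' @return Scalar fraction in `[0, 1]`.
#' @export
indirect_fraction <- function(derived, roi,
                              method = c("sum_ratio", "voxel_mean")) {
  method <- match.arg(method)
  roi <- roi > 0
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  tot <- derived$total_cbf[roi]
  ind <- derived$indirect_cbf[roi]
  if (sum(tot) <= 0) stop("no flow in ROI", call. = FALSE)
  if (method == "sum_ratio") {
    sum(ind) / sum(tot)
  } else {
    pos <- tot > 0
    mean(ind[pos] / tot[pos])
  }
}

#' Voxel-level tissue-survival table
#'
#' Bins Peri-Core voxels by CBF and tabulates the fraction that survived
#' (fell outside the final infarct). In the default (collateral) analysis,
#' voxels receiving more than `direct_cutoff` of Direct CBF are excluded
#' first — the exclusion is strictly "more than", so a voxel exactly at
#' the cutoff is retained — and binning is on Indirect CBF. Setting
#' `axis = "direct"` with `direct_cutoff = NULL` gives the
#' both-axes variant over all Peri-Core voxels.
#'
#' @param direct,indirect 3D CBF maps, ml/100 g/min.
#' @param infarct Logical final-infarct mask.
#' @param peri_core Logical Peri-Core ROI.
#' @param direct_cutoff Exclude voxels with Direct CBF strictly above this
#'   value (default 25); `NULL` disables the exclusion.
#' @param bin_width Bin width, ml/100 g/min (default 10).
#' @param max_bin Lower edge of the open-ended top bin (default 80).
#' @param axis Which CBF map to bin on: `"indirect"` (default) or
#'   `"direct"`.
#' @param min_count Minimum voxels per bin to report a fraction (smaller
#'   bins keep their counts but get `NA` fractions).
#' @param group Optional grouping label stored with the table.
#' @return A `survival_table` data.frame: `bin_low`, `bin_high` (Inf for
#'   the top bin), `total`, `surviving`, `fraction`, `group`, `axis`.
#' @export
survival_table <- function(direct, indirect, infarct, peri_core,
                           direct_cutoff = 25, bin_width = 10,
                           max_bin = 80,
                           axis = c("indirect", "direct"),
                           min_count = 10, group = "all") {
  axis <- match.arg(axis)
  stopifnot(identical(dim(direct), dim(indirect)),
            identical(dim(direct), dim(infarct)),
            identical(dim(direct), dim(peri_core)))
  sel <- peri_core > 0
  if (!is.null(direct_cutoff)) sel <- sel & !(direct > direct_cutoff)
  vals <- if (axis == "indirect") indirect[sel] else direct[sel]
  surv <- !(infarct[sel] > 0)
  edges <- seq(0, max_bin, by = bin_width)
  bin_low <- edges
  bin_high <- c(edges[-1], Inf)
  bin_of <- pmin(floor(vals / bin_width), length(edges) - 1L) + 1L
  total <- tabulate(bin_of, nbins = length(edges))
  surviving <- tabulate(bin_of[surv], nbins = length(edges))
  fraction <- ifelse(total >= min_count, surviving / total, NA_real_)
  structure(
    data.frame(bin_low = bin_low, bin_high = bin_high,
               total = total, surviving = surviving,
               fraction = fraction,
               group = group, axis = axis,
               stringsAsFactors = FALSE),
    class = c("survival_table", "data.frame")
  )
}

#' Two-proportion test of survival above vs below a CBF split
#'
#' Pools the survival-table bins below and above `split` and compares the
#' two survival proportions with a pooled two-proportion z-test
#' (two-sided). Bins are assigned by their lower edge, so the bin starting
#' at the split value counts as "above".
#'
#' @param table A `survival_table`.
#' @param split CBF split point, ml/100 g/min (default 25). Bins are
#'   pooled by their lower edge (`bin_low < split` goes to the low side),
#'   so with the default 10-wide bins the 20-30 bin counts as "below 25".
#' @return List with `p_low`, `p_high` (survival proportions), `n_low`,
#'   `n_high`, `z`, `p_value`.
#' @export
binomial_split_test <- function(table, split = 25) {
  lo <- table$bin_low < split
  n1 <- sum(table$total[lo]); s1 <- sum(table$surviving[lo])
  n2 <- sum(table$total[!lo]); s2 <- sum(table$surviving[!lo])
  if (n1 == 0 || n2 == 0) {
    stop("one side of the split contains no voxels", call. = FALSE)
  }
  p1 <- s1 / n1
  p2 <- s2 / n2
  p_pool <- (s1 + s2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p2 - p1) / se
  list(p_low = p1, p_high = p2, n_low = n1, n_high = n2,
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Relative increase in survival fraction between two bins
#'
#' `100 * (fraction_high - fraction_low) / fraction_low`, the percent
#' change in tissue survival between a low and a high collateral-flow bin.
#'
#' @param table A `survival_table`.
#' @param low_bin,high_bin Lower edges of the two bins to compare
#'   (defaults 0 and 70, i.e. the 0-10 and 70-80 ml/100 g/min bins).
#' @return Percent change (scalar).
#' @export
relative_increase <- function(table, low_bin = 0, high_bin = 70) {
  f_lo <- table$fraction[match(low_bin, table$bin_low)]
  f_hi <- table$fraction[match(high_bin, table$bin_low)]
  if (is.na(f_lo) || is.na(f_hi)) {
    stop("requested bins are empty or below the reporting threshold",
         call. = FALSE)
  }
  if (f_lo == 0) stop("low-bin survival fraction is zero", call. = FALSE)
  100 * (f_hi - f_lo) / f_lo
}

#' Patient-level summary row
#'
#' One measurement of the collateral and arrival-time state of a patient
#' at one timepoint in one ROI.
#'
#' @param patient_id,timepoint,roi_label Identifiers; `roi_label` is
#'   typically `"surviving"` or `"contralateral"`.
#' @param indirect_frac Indirect CBF fraction in `[0, 1]`.
#' @param mean_watt Mean weighted ATT in the ROI, seconds.
#' @param reperfusion `"reperfuser"` (mTICI 2b/3) or `"non-reperfuser"`
#'   (mTICI 0/1/2a); consumed as an input label.
#' @return One-row data.frame.
#' @export
patient_summary <- function(patient_id, timepoint, roi_label,
                            indirect_frac, mean_watt,
                            reperfusion = NA_character_) {
  stopifnot(indirect_frac >= 0, indirect_frac <= 1)
  data.frame(patient_id = patient_id, timepoint = timepoint,
             roi = roi_label, indirect_frac = indirect_frac,
             mean_watt = mean_watt, reperfusion = reperfusion,
             stringsAsFactors = FALSE)
}

#' Two-way ANOVA of a patient-level measure with post-hoc t-tests
#'
#' Compares a measure (Indirect CBF fraction or mean weighted ATT) between
#' the Surviving-Tissue and contralateral ROIs across timepoints with a
#' two-way ANOVA (factors ROI and timepoint, Type-II sums of squares, no
#' interaction term, suitable for the unbalanced designs that arise when
#' patients miss follow-ups). If the ROI effect is significant at
#' `alpha`, unpaired two-sample t-tests compare the ROIs within each
#' timepoint.
#'
#' @param summaries Data.frame of [patient_summary()] rows.
#' @param response Column to analyze: `"indirect_frac"` or `"mean_watt"`.
#' @param alpha Gate for the post-hoc tests (default 0.05).
#' @return List with `anova` (Type-II ANOVA table), `roi_p` (p-value of
#'   the ROI effect), and `posthoc` (data.frame of per-timepoint t-tests,
#'   or `NULL` when the ROI effect is not significant).
#' @export
two_way_anova <- function(summaries,
                          response = c("indirect_frac", "mean_watt"),
                          alpha = 0.05) {
  response <- match.arg(response)
  summaries$roi <- factor(summaries$roi)
  summaries$timepoint <- factor(summaries$timepoint)
  if (nlevels(summaries$roi) < 2L || nlevels(summaries$timepoint) < 2L) {
    stop("both ROI and timepoint need at least two levels", call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~ roi + timepoint"))
  fit <- stats::lm(fml, data = summaries)
  tab <- car::Anova(fit, type = 2)
  roi_p <- tab["roi", "Pr(>F)"]
  posthoc <- NULL
  if (is.finite(roi_p) && roi_p < alpha) {
    posthoc <- do.call(rbind, lapply(levels(summaries$timepoint), function(tp) {
      sub <- summaries[summaries$timepoint == tp, ]
      if (length(unique(sub$roi)) < 2L ||
          min(table(sub$roi)) < 2L) {
        return(NULL)
      }
      tt <- stats::t.test(stats::as.formula(paste(response, "~ roi")),
                          data = sub)
      data.frame(timepoint = tp,
                 mean_diff = unname(diff(rev(tt$estimate))),
                 t = unname(tt$statistic),
                 p_value = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(anova = tab, roi_p = roi_p, posthoc = posthoc)
}
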