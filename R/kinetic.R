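#' Kinetic and calibration constants
#'
#' Physiological and sequence constants used by the ASL kinetic model and
#' the CSF-based calibration of the equilibrium magnetization of blood.
#' Defaults are conventional 3 T values and are all overridable; the
#' apparent tissue T1 (`t1_tissue_apparent_s`, often written T1') governs
#' post-arrival decay and saturation of the inflowing bolus. Whether a
#' tissue or blood relaxation constant is more appropriate after arrival is
#' genuinely ambiguous, which is why it is exposed rather than fixed.
#'
#' @param t1_blood_s Longitudinal relaxation time of arterial blood, s.
#' @param t1_tissue_apparent_s Apparent tissue T1 after arrival, s.
#' @param labeling_efficiency Inversion efficiency alpha in (0, 1].
#' @param blood_water_density_ratio Blood/CSF water partition factor.
#' @param t2_csf_s,t2_blood_s Transverse relaxation times, s.
#' @param echo_time_s Readout echo time, s.
#' @return An object of class `kinetic_constants`.
#' @export
kinetic_constants <- function(t1_blood_s = 1.65,
                              t1_tissue_apparent_s = 1.6,
                              labeling_efficiency = 0.85,
                              blood_water_density_ratio = 0.87,
                              t2_csf_s = 0.75,
                              t2_blood_s = 0.15,
                              echo_time_s = 0.014) {
  vals <- c(t1_blood_s, t1_tissue_apparent_s, labeling_efficiency,
            blood_water_density_ratio, t2_csf_s, t2_blood_s)
  stopifnot(all(vals > 0), echo_time_s >= 0,
            labeling_efficiency <= 1)
  structure(
    list(
      t1_blood_s = t1_blood_s,
      t1_tissue_apparent_s = t1_tissue_apparent_s,
      labeling_efficiency = labeling_efficiency,
      blood_water_density_ratio = blood_water_density_ratio,
      t2_csf_s = t2_csf_s,
      t2_blood_s = t2_blood_s,
      echo_time_s = echo_time_s
    ),
    class = "kinetic_constants"
  )
}

#' ASL difference signal of one arterial component
#'
#' The general ASL kinetic model for continuous labeling without
#' dispersion. With flow `f` (ml/100 g/min, converted to 1/s by dividing
#' by 6000), transit time `att` (s), labeling duration `tau` (s), blood T1
#' `T1b`, apparent tissue T1 `T1p`, inversion efficiency `alpha` and blood
#' equilibrium magnetization `M0b`, the difference signal at time `t` since
#' the start of labeling is
#' \deqn{\Delta M(t) = 0, \quad t < \Delta t}
#' \deqn{\Delta M(t) = 2 M_{0b} \alpha \frac{f}{6000} T_1'
#'   e^{-\Delta t / T_{1b}} (1 - e^{-(t - \Delta t)/T_1'}),
#'   \quad \Delta t \le t < \Delta t + \tau}
#' \deqn{\Delta M(t) = 2 M_{0b} \alpha \frac{f}{6000} T_1'
#'   e^{-\Delta t / T_{1b}} (1 - e^{-\tau/T_1'})
#'   e^{-(t - \Delta t - \tau)/T_1'}, \quad t \ge \Delta t + \tau}
#' which is continuous in `t`.
#'
#' @param t Time(s) since the start of labeling, seconds (vectorized).
#' @param cbf Flow f, ml/100 g/min.
#' @param att Arterial transit time, seconds.
#' @param m0_blood Equilibrium magnetization of blood, signal units.
#' @param tau Labeling duration, seconds.
#' @param constants A `kinetic_constants` object.
#' @return Difference signal, same length as `t`.
#' @export
delta_m <- function(t, cbf, att, m0_blood, tau,
                    constants = kinetic_constants()) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  stopifnot(cbf >= 0, att >= 0, m0_blood > 0, tau > 0)
  t1b <- constants$t1_blood_s
  t1p <- constants$t1_tissue_apparent_s
  alpha <- constants$labeling_efficiency
  pre <- 2 * m0_blood * alpha * (cbf / 6000) * t1p * exp(-att / t1b)
  out <- numeric(length(t))
  during <- t >= att & t < att + tau
  after <- t >= att + tau
  out[during] <- pre * (1 - exp(-(t[during] - att) / t1p))
  out[after] <- pre * (1 - exp(-tau / t1p)) *
    exp(-(t[after] - att - tau) / t1p)
  out
}

# Unit-flow kinetic curve: delta_m at cbf = 1, m0_blood = 1. The model is
# linear in cbf * m0_blood, which the fitting grid search exploits.
delta_m_unit <- function(t, att, tau, constants) {
  delta_m(t, cbf = 1, att = att, m0_blood = 1, tau = tau,
          constants = constants)
}

#' Convert a CSF signal into the equilibrium magnetization of blood
#'
#' Calibration converts the mean ventricular CSF signal of the calibration
#' image into the equilibrium magnetization of arterial blood, correcting
#' for T2 decay at the echo time and for the relative water density:
#' `M0b = S_csf * exp(TE * (1/T2csf - 1/T2blood)) * density_ratio`.
#'
#' @param csf_signal Positive CSF signal estimate.
#' @param constants A `kinetic_constants` object.
#' @return M0 of blood in the same signal units.
#' @export
calibrate_m0_blood <- function(csf_signal, constants = kinetic_constants()) {
  if (!is.numeric(csf_signal) || length(csf_signal) != 1L ||
      csf_signal <= 0) {
    stop("calibration failure: csf_signal must be a positive scalar",
         call. = FALSE)
  }
  csf_signal *
    exp(constants$echo_time_s *
          (1 / constants$t2_csf_s - 1 / constants$t2_blood_s)) *
    constants$blood_water_density_ratio
}

#' Robust mean CSF signal within a ventricle mask
#'
#' A 10% two-sided trimmed mean of the calibration-image voxels inside the
#' ventricle mask, guarding against partial-volume contamination at the
#' mask edge.
#'
#' @param calibration_volume 3D numeric array.
#' @param ventricle_mask 3D logical/0-1 array of the same shape.
#' @param trim Two-sided trim fraction (default 0.1).
#' @return Scalar signal estimate.
#' @export
mean_csf_signal <- function(calibration_volume, ventricle_mask, trim = 0.1) {
  if (!identical(dim(calibration_volume), dim(ventricle_mask))) {
    stop("calibration volume and ventricle mask shapes differ",
         call. = FALSE)
  }
  vox <- calibration_volume[ventricle_mask > 0]
  if (length(vox) == 0L) {
    stop("ventricle mask is empty on this grid", call. = FALSE)
  }
  mean(vox, trim = trim)
}
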