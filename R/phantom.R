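#' Digital phantom specification
#'
#' Describes a synthetic head with four vascular territories (RICA, LICA,
#' RVA, LVA), an optional hypoperfused MCA-like lesion with configurable
#' collateral (Indirect) supply, spatially varying arterial transit times
#' with a peri-lesional delay, and matched ADC / final-infarct /
#' gray-matter maps. The phantom stands in for patient data: it emulates
#' the phenomenology the pipeline must handle (territorial supply,
#' collateral flow, delayed arrival, infarction linked to perfusion), not
#' anatomy.
#'
#' Scenarios:
#' \describe{
#'   \item{`"none"`}{no lesion; baseline supply everywhere.}
#'   \item{`"no-collateral"`}{ipsilateral-ICA flow reduced inside the
#'     lesion with no replacement.}
#'   \item{`"inter-hemispheric"`}{reduced direct flow plus collateral
#'     supply from the contralateral ICA, strongest at the lesion edge and
#'     absent at its center (where the ischemic core forms).}
#'   \item{`"ica-occlusion"`}{the ipsilateral ICA is occluded; its whole
#'     territory is taken over by the contralateral ICA, with additional
#'     vertebral collateral inside the lesion.}
#' }
#'
#' @param grid_shape Integer vector (nx, ny, nz).
#' @param voxel_size_mm Numeric vector (dx, dy, dz), millimetres.
#' @param scenario One of `"none"`, `"no-collateral"`,
#'   `"inter-hemispheric"`, `"ica-occlusion"`.
#' @param cbf_gm,cbf_wm Baseline CBF at gray-matter partial volume 1 and 0,
#'   ml/100 g/min (voxel baseline interpolates linearly in GM PV).
#' @param att_ica_s,att_va_s Baseline transit times of carotid and
#'   vertebral supply, seconds.
#' @param lesion_center_mm,lesion_radius_mm Lesion sphere in centered
#'   physical coordinates (x right-negative, y posterior-negative), mm.
#' @param core_radius_mm Radius of the ADC-defined ischemic core at the
#'   lesion center, mm.
#' @param direct_reduction Multiplicative factor on ipsilateral-ICA flow
#'   inside the lesion.
#' @param collateral_cbf Peak collateral (Indirect) CBF at the lesion edge,
#'   ml/100 g/min.
#' @param peri_att_delay_s Additional transit delay applied within
#'   `peri_att_range_mm` of the lesion boundary, seconds.
#' @param peri_att_range_mm Peri-lesional band half-width around the lesion
#'   boundary, mm.
#' @param border_mm Half-width of the linear blending band between vascular
#'   territories, mm (voxels further than this from a border are
#'   single-artery).
#' @param posterior_y_mm Anterior/posterior territory boundary, mm.
#' @param adc_normal,adc_core ADC values outside/inside the core, mm^2/s.
#' @param survival_k,survival_c Logistic tissue-survival rule: a voxel in
#'   the at-risk region survives with probability
#'   `plogis(survival_k * (totalCBF - survival_c))`; `survival_k` in
#'   (ml/100 g/min)^-1, `survival_c` in ml/100 g/min.
#' @param m0_blood Equilibrium magnetization of blood used to scale the
#'   synthesized signal.
#' @param seed Integer seed; fixed seed gives byte-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 24L),
                         voxel_size_mm = c(3.4, 3.4, 5),
                         scenario = c("inter-hemispheric", "none",
                                      "no-collateral", "ica-occlusion"),
                         cbf_gm = 50,
                         cbf_wm = 20,
                         att_ica_s = 1.2,
                         att_va_s = 1.3,
                         lesion_center_mm = c(-55, 10, 0),
                         lesion_radius_mm = 25,
                         core_radius_mm = 8,
                         direct_reduction = 0.2,
                         collateral_cbf = 75,
                         peri_att_delay_s = 0.3,
                         peri_att_range_mm = 20,
                         border_mm = 4,
                         posterior_y_mm = -33,
                         adc_normal = 800e-6,
                         adc_core = 500e-6,
                         survival_k = 0.15,
                         survival_c = 20,
                         m0_blood = 1000,
                         seed = 42L) {
  scenario <- match.arg(scenario)
  stopifnot(
    length(grid_shape) == 3L, all(grid_shape >= 2L),
    length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
    cbf_gm >= 0, cbf_wm >= 0, att_ica_s > 0, att_va_s > 0,
    lesion_radius_mm > 0, core_radius_mm > 0,
    core_radius_mm < lesion_radius_mm,
    direct_reduction >= 0, collateral_cbf >= 0,
    adc_normal > 0, adc_core > 0, m0_blood > 0
  )
  structure(
    list(
      grid_shape = as.integer(grid_shape),
      voxel_size_mm = as.numeric(voxel_size_mm),
      scenario = scenario,
      cbf_gm = cbf_gm, cbf_wm = cbf_wm,
      att_ica_s = att_ica_s, att_va_s = att_va_s,
      lesion_center_mm = lesion_center_mm,
      lesion_radius_mm = lesion_radius_mm,
      core_radius_mm = core_radius_mm,
      direct_reduction = direct_reduction,
      collateral_cbf = collateral_cbf,
      peri_att_delay_s = peri_att_delay_s,
      peri_att_range_mm = peri_att_range_mm,
      border_mm = border_mm,
      posterior_y_mm = posterior_y_mm,
      adc_normal = adc_normal, adc_core = adc_core,
      survival_k = survival_k, survival_c = survival_c,
      m0_blood = m0_blood,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Centered physical coordinates (mm) of voxel centers along each axis.
grid_coords_mm <- function(grid_shape, voxel_size_mm) {
  lapply(1:3, function(i) {
    (seq_len(grid_shape[i]) - (grid_shape[i] + 1) / 2) * voxel_size_mm[i]
  })
}

# 3D arrays of the x/y/z coordinate at every voxel.
coord_arrays <- function(grid_shape, voxel_size_mm) {
  cc <- grid_coords_mm(grid_shape, voxel_size_mm)
  list(
    x = array(rep(cc[[1]], times = prod(grid_shape[2:3])), dim = grid_shape),
    y = array(rep(rep(cc[[2]], each = grid_shape[1]), times = grid_shape[3]),
              dim = grid_shape),
    z = array(rep(cc[[3]], each = prod(grid_shape[1:2])), dim = grid_shape)
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate the phantom ground truth
#'
#' Builds per-artery CBF and ATT maps from the territory layout and the
#' scenario, plus the matched ADC map, ischemic-core mask, stochastic
#' final-infarct mask, gray-matter partial-volume map, ventricle mask and
#' calibration volume. The final infarct is drawn voxelwise: inside the
#' at-risk region (lesion plus a 10 mm margin) a voxel survives with
#' probability `plogis(survival_k * (totalCBF - survival_c))`; the ischemic
#' core always infarcts and tissue outside the at-risk region always
#' survives. The left hemisphere mirrors the right so mirrored-ROI code is
#' exactly testable.
#'
#' @param spec A `phantom_spec`.
#' @param constants A `kinetic_constants` object (used for the calibration
#'   volume so that [calibrate_m0_blood()] recovers `spec$m0_blood`).
#' @return An object of class `phantom_truth`: arrays `cbf` and `att`
#'   (nx x ny x nz x n_arteries), `weights` (territory supply fractions),
#'   masks `brain`, `core`, `infarct`, `ventricles`, maps `gm_pv`, `adc`,
#'   `calibration`, plus `artery_ids`, `voxel_size_mm` and the spec.
#' @export
generate_truth <- function(spec, constants = kinetic_constants()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  vox <- spec$voxel_size_mm
  co <- coord_arrays(shape, vox)
  half_extent <- shape * vox / 2
  if (any(abs(spec$lesion_center_mm) > half_extent)) {
    stop("lesion center lies outside the phantom grid", call. = FALSE)
  }
  artery_ids <- c("RICA", "LICA", "RVA", "LVA")

  # Head: ellipsoid; ventricles: small central ellipsoid; gray matter:
  # cortical shell (high GM PV) over a deep low-PV compartment.
  semi <- c(0.44 * shape[1] * vox[1], 0.48 * shape[2] * vox[2],
            0.48 * shape[3] * vox[3])
  r_norm <- sqrt((co$x / semi[1])^2 + (co$y / semi[2])^2 +
                   (co$z / semi[3])^2)
  brain <- r_norm <= 1
  vent_semi <- pmax(c(0.15, 0.24, 0.21) * semi, 1.2 * vox)
  ventricles <- sqrt((co$x / vent_semi[1])^2 + (co$y / vent_semi[2])^2 +
                       (co$z / vent_semi[3])^2) <= 1
  gm_pv <- (0.2 + 0.7 * stats::plogis((r_norm - 0.55) / 0.05)) * brain
  gm_pv[ventricles] <- 0

  # Territory supply fractions: left/right split at x = 0, anterior
  # (carotid) / posterior (vertebral) split at posterior_y_mm, each with a
  # linear blending band of half-width border_mm.
  s_left <- clamp01(0.5 + co$x / (2 * spec$border_mm))
  s_ant <- clamp01(0.5 + (co$y - spec$posterior_y_mm) / (2 * spec$border_mm))
  weights <- array(0, dim = c(shape, 4),
                   dimnames = list(NULL, NULL, NULL, artery_ids))
  weights[, , , "RICA"] <- s_ant * (1 - s_left)
  weights[, , , "LICA"] <- s_ant * s_left
  weights[, , , "RVA"] <- (1 - s_ant) * (1 - s_left)
  weights[, , , "LVA"] <- (1 - s_ant) * s_left

  # Baseline perfusion scales with gray-matter partial volume.
  cbf_base <- (spec$cbf_wm + (spec$cbf_gm - spec$cbf_wm) * gm_pv) * brain
  cbf <- weights
  for (a in seq_along(artery_ids)) {
    cbf[, , , a] <- weights[, , , a] * cbf_base
  }

  dist_lesion <- sqrt((co$x - spec$lesion_center_mm[1])^2 +
                        (co$y - spec$lesion_center_mm[2])^2 +
                        (co$z - spec$lesion_center_mm[3])^2)
  lesion <- dist_lesion <= spec$lesion_radius_mm & brain
  core <- dist_lesion <= spec$core_radius_mm & brain
  has_lesion <- spec$scenario != "none"

  if (has_lesion) {
    # Collateral ramp: zero at the core edge, maximal at the lesion edge —
    # the core is the region collaterals fail to reach.
    ramp <- clamp01((dist_lesion - spec$core_radius_mm) /
                      (spec$lesion_radius_mm - spec$core_radius_mm))
    coll <- spec$collateral_cbf * ramp * (gm_pv / max(gm_pv, 1e-9)) *
      lesion
    if (spec$scenario == "ica-occlusion") {
      # Whole RICA territory taken over by the LICA; vertebral collateral
      # inside the lesion.
      cbf[, , , "LICA"] <- cbf[, , , "LICA"] + cbf[, , , "RICA"]
      cbf[, , , "RICA"] <- 0
      red <- cbf[, , , "LICA"]
      red[lesion] <- red[lesion] * spec$direct_reduction
      cbf[, , , "LICA"] <- red
      cbf[, , , "RVA"] <- cbf[, , , "RVA"] + 0.5 * coll
      cbf[, , , "LVA"] <- cbf[, , , "LVA"] + 0.5 * coll
    } else {
      red <- cbf[, , , "RICA"]
      red[lesion] <- red[lesion] * spec$direct_reduction
      cbf[, , , "RICA"] <- red
      if (spec$scenario == "inter-hemispheric") {
        cbf[, , , "LICA"] <- cbf[, , , "LICA"] + coll
      }
    }
  } else {
    core[] <- FALSE
  }

  # Transit times: carotid vs vertebral baseline plus a peri-lesional
  # delay within peri_att_range_mm of the lesion boundary.
  att_base <- c(RICA = spec$att_ica_s, LICA = spec$att_ica_s,
                RVA = spec$att_va_s, LVA = spec$att_va_s)
  att <- array(0, dim = c(shape, 4),
               dimnames = list(NULL, NULL, NULL, artery_ids))
  peri <- has_lesion &
    abs(dist_lesion - spec$lesion_radius_mm) <= spec$peri_att_range_mm
  for (a in seq_along(artery_ids)) {
    att[, , , a] <- att_base[a] + spec$peri_att_delay_s * (peri & brain)
  }

  adc <- array(spec$adc_normal, dim = shape)
  adc[core] <- spec$adc_core
  adc[!brain] <- spec$adc_normal

  total_cbf <- apply(cbf, 1:3, sum)
  at_risk <- has_lesion &
    dist_lesion <= spec$lesion_radius_mm + 10 & brain
  set.seed(spec$seed)
  p_survive <- stats::plogis(spec$survival_k * (total_cbf - spec$survival_c))
  draw <- array(stats::runif(prod(shape)), dim = shape)
  infarct <- (at_risk & draw > p_survive) | core

  csf_signal <- spec$m0_blood /
    (exp(constants$echo_time_s *
           (1 / constants$t2_csf_s - 1 / constants$t2_blood_s)) *
       constants$blood_water_density_ratio)
  calibration <- array(0.6 * csf_signal, dim = shape) * brain
  calibration[ventricles] <- csf_signal

  structure(
    list(
      spec = spec,
      artery_ids = artery_ids,
      voxel_size_mm = vox,
      cbf = cbf, att = att, weights = weights,
      brain = brain, gm_pv = gm_pv, adc = adc,
      core = core, infarct = infarct,
      lesion = lesion,
      ventricles = ventricles,
      calibration = calibration,
      m0_blood = spec$m0_blood
    ),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom truth: %s grid, scenario '%s'\n",
              paste(dim(x$brain), collapse = "x"), x$spec$scenario))
  cat(sprintf("  brain %d voxels, core %d, infarct %d\n",
              sum(x$brain), sum(x$core), sum(x$infarct)))
  invisible(x)
}

#' Mask of gray-matter voxels supplied by a single artery
#'
#' Voxels where exactly one artery has positive true flow (so the
#' scenario's collateral supply counts: a lesion voxel fed by both its
#' territorial artery and a collateral source is not single-artery) and
#' whose gray-matter partial volume exceeds `gm_threshold`. Used to
#' evaluate parameter recovery where ground truth is unambiguous.
#'
#' @param truth A `phantom_truth`.
#' @param artery Artery id (the sole supplier), or `NULL` for any
#'   single-artery voxel.
#' @param gm_threshold GM partial-volume threshold.
#' @return Logical 3D array.
#' @export
single_artery_mask <- function(truth, artery = NULL, gm_threshold = 0.5) {
  stopifnot(inherits(truth, "phantom_truth"))
  supplied <- truth$cbf > 0
  n_suppliers <- array(0L, dim = dim(truth$brain))
  for (a in seq_along(truth$artery_ids)) {
    n_suppliers <- n_suppliers + supplied[, , , a]
  }
  single <- n_suppliers == 1L
  if (!is.null(artery)) {
    single <- single & supplied[, , , artery]
  }
  single & truth$gm_pv > gm_threshold
}

# Per-voxel kinetic difference signal for one artery at scalar time t.
delta_m_field <- function(t, cbf, att, m0_blood, tau, constants) {
  t1b <- constants$t1_blood_s
  t1p <- constants$t1_tissue_apparent_s
  alpha <- constants$labeling_efficiency
  pre <- 2 * m0_blood * alpha * (cbf / 6000) * t1p * exp(-att / t1b)
  during <- t >= att & t < att + tau
  after <- t >= att + tau
  out <- numeric(length(cbf))
  out[during] <- pre[during] * (1 - exp(-(t - att[during]) / t1p))
  out[after] <- pre[after] * (1 - exp(-tau / t1p)) *
    exp(-(t - att[after] - tau) / t1p)
  out
}

# Noiseless per-artery signal table dm[voxel, artery, pld] honoring
# per-slice timing. Internal workhorse shared by synthesis and tests.
phantom_dm <- function(truth, protocol, constants) {
  shape <- dim(truth$brain)
  n_pld <- length(protocol$nominal_plds_s)
  n_art <- length(truth$artery_ids)
  tau <- protocol$label_duration_s
  dm <- array(0, dim = c(shape, n_art, n_pld))
  slice_of <- round(seq(0, protocol$n_slices - 1,
                        length.out = shape[3]))
  for (p in seq_len(n_pld)) {
    for (k in seq_len(shape[3])) {
      t <- tau + slice_pld(protocol, p, slice_of[k])
      for (a in seq_len(n_art)) {
        cbf_s <- truth$cbf[, , k, a]
        att_s <- truth$att[, , k, a]
        dm[, , k, a, p] <- delta_m_field(t, as.numeric(cbf_s),
                                         as.numeric(att_s),
                                         truth$m0_blood, tau, constants)
      }
    }
  }
  dm
}

#' Noise level for a target temporal SNR
#'
#' Returns the Gaussian noise standard deviation (per acquired volume)
#' giving a chosen temporal SNR on the non-selective control-minus-label
#' difference, defined as the median over gray-matter brain voxels of the
#' maximal (over PLDs) difference signal divided by the noise sd of the
#' difference (`sqrt(2) * noise_sd`).
#'
#' @param truth A `phantom_truth`.
#' @param protocol An `asl_protocol`.
#' @param constants A `kinetic_constants` object.
#' @param snr Target temporal SNR (default 5).
#' @return Scalar noise sd in signal units.
#' @export
noise_sd_for_snr <- function(truth, protocol, constants = kinetic_constants(),
                             snr = 5) {
  dm <- phantom_dm(truth, protocol, constants)
  shape <- dim(truth$brain)
  n_art <- length(truth$artery_ids)
  n_pld <- length(protocol$nominal_plds_s)
  dim(dm) <- c(prod(shape), n_art, n_pld)
  total <- vapply(seq_len(n_pld),
                  function(p) rowSums(dm[, , p]),
                  numeric(prod(shape)))
  peak <- do.call(pmax, lapply(seq_len(n_pld), function(p) total[, p]))
  gm <- as.logical(truth$gm_pv > 0.5)
  signal <- stats::median(2 * peak[gm])
  signal / (sqrt(2) * snr)
}

#' Synthesize a vessel-encoded multi-delay ASL series
#'
#' Generates the 4D acquisition from the phantom ground truth: the volume
#' for encoding cycle `e` at a given PLD and voxel is
#' `static + sum_a w[e, a] * dM_a(t_slice) + N(0, noise_sd)`, where
#' `dM_a` is the kinetic difference signal of artery `a` evaluated at that
#' voxel's slice-specific time and `w` is the encoding matrix (+1 control,
#' -1 label). The 96 volumes follow [protocol_schedule()]. The static
#' tissue signal is a constant (default 100 x the peak difference signal):
#' decoding removes it, so only its dynamic range matters.
#'
#' @param truth A `phantom_truth`.
#' @param protocol An `asl_protocol`.
#' @param matrix An `encoding_matrix` whose columns match
#'   `truth$artery_ids`.
#' @param constants A `kinetic_constants` object.
#' @param noise_sd Gaussian noise sd in signal units; 0 for a noiseless
#'   series.
#' @param seed Integer seed for the noise draw.
#' @param static_scale Static tissue signal as a multiple of the peak
#'   difference signal.
#' @param static_signal Absolute static tissue signal; overrides
#'   `static_scale` when given (needed e.g. for zero-flow phantoms, whose
#'   peak difference signal is zero).
#' @return An object of class `asl_series`: list with `data`
#'   (nx x ny x nz x n_volumes array), `schedule`, `protocol`, `matrix`,
#'   `noise_sd`, `voxel_size_mm`.
#' @export
synthesize_series <- function(truth, protocol, matrix,
                              constants = kinetic_constants(),
                              noise_sd = 0, seed = truth$spec$seed + 1L,
                              static_scale = 100, static_signal = NULL) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(protocol, "asl_protocol"),
            inherits(matrix, "encoding_matrix"))
  if (!identical(colnames(matrix$weights), truth$artery_ids)) {
    stop("encoding matrix arteries do not match phantom arteries",
         call. = FALSE)
  }
  shape <- dim(truth$brain)
  dm <- phantom_dm(truth, protocol, constants)
  static_val <- if (is.null(static_signal)) static_scale * max(dm) else
    static_signal
  static <- static_val * truth$brain
  sched <- protocol_schedule(protocol)
  w <- matrix$weights
  n_vol <- nrow(sched)
  data <- array(0, dim = c(shape, n_vol))
  set.seed(seed)
  for (v in seq_len(n_vol)) {
    p <- sched$pld_index[v]
    e <- sched$cycle_index[v]
    vol <- static
    for (a in seq_len(ncol(w))) {
      if (w[e, a] != 0) vol <- vol + w[e, a] * dm[, , , a, p]
    }
    if (noise_sd > 0) {
      vol <- vol + array(stats::rnorm(prod(shape), 0, noise_sd), dim = shape)
    }
    data[, , , v] <- vol
  }
  structure(
    list(data = data, schedule = sched, protocol = protocol,
         matrix = matrix, noise_sd = noise_sd,
         voxel_size_mm = truth$voxel_size_mm),
    class = "asl_series"
  )
}
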