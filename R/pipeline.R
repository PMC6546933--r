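#' Pipeline configuration
#'
#' Gathers every knob of the phantom-to-statistics pipeline: the phantom
#' specification, acquisition protocol, kinetic constants, the analysis
#' thresholds (ADC core cutoff 620e-6 mm^2/s; Direct-CBF exclusion cutoff
#' 25 ml/100 g/min; shell radii 10 and 20 mm; gray-matter partial-volume
#' threshold 0.5; survival bin width 10 ml/100 g/min), the target
#' temporal SNR of the synthesized data, and the seed.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Integer master seed; the phantom truth and noise draws are
#'   derived from it.
#' @param phantom Named list of [phantom_spec()] overrides.
#' @param snr Target temporal SNR of the synthesized series.
#' @param ipsilateral Ipsilateral ICA id (the lesion side's carotid).
#' @param contralateral Contralateral ICA id.
#' @param adc_threshold ADC core threshold, mm^2/s.
#' @param direct_cutoff Direct-CBF exclusion cutoff, ml/100 g/min.
#' @param surviving_radius_mm,peri_core_radius_mm ROI shell radii, mm.
#' @param gm_threshold Gray-matter partial-volume threshold.
#' @param bin_width Survival-table bin width, ml/100 g/min.
#' @param split CBF split for the binomial proportion test.
#' @param write_nifti Write NIfTI volumes for each stage?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("vepcasl_"),
                            seed = 42L,
                            phantom = list(),
                            snr = 5,
                            ipsilateral = "RICA",
                            contralateral = "LICA",
                            adc_threshold = 620e-6,
                            direct_cutoff = 25,
                            surviving_radius_mm = 10,
                            peri_core_radius_mm = 20,
                            gm_threshold = 0.5,
                            bin_width = 10,
                            split = 25,
                            write_nifti = TRUE) {
  stopifnot(adc_threshold > 0, direct_cutoff > 0,
            surviving_radius_mm > 0, peri_core_radius_mm > 0,
            gm_threshold > 0, bin_width > 0, snr > 0)
  structure(
    list(outdir = outdir, seed = as.integer(seed), phantom = phantom,
         snr = snr, ipsilateral = ipsilateral,
         contralateral = contralateral,
         adc_threshold = adc_threshold, direct_cutoff = direct_cutoff,
         surviving_radius_mm = surviving_radius_mm,
         peri_core_radius_mm = peri_core_radius_mm,
         gm_threshold = gm_threshold, bin_width = bin_width,
         split = split, write_nifti = write_nifti),
    class = "pipeline_config"
  )
}

pipeline_stages <- function() {
  c("simulate", "decode", "fit", "maps", "rois", "stats")
}

#' Run the phantom-to-statistics pipeline
#'
#' Executes, in order: phantom simulation, vessel decoding, kinetic-model
#' fitting, derived-map computation, ROI construction and the survival /
#' patient-level statistics, writing each stage's outputs (NIfTI volumes
#' and CSV tables) under `config$outdir` together with a provenance
#' sidecar (config YAML and its MD5 hash). Fully deterministic under a
#' fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param through Last stage to execute (one of `"simulate"`, `"decode"`,
#'   `"fit"`, `"maps"`, `"rois"`, `"stats"`, or `"all"` = `"stats"`).
#' @param quiet Suppress stage progress messages?
#' @return A result bundle (list with the objects of every executed
#'   stage), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), through = "all",
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (through == "all") through <- "stats"
  stages <- pipeline_stages()
  if (!through %in% stages) {
    stop("unknown stage: ", through, call. = FALSE)
  }
  todo <- stages[seq_len(match(through, stages))]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage_clock <- function(stage) {
    say("[%s] %s (t+%.1fs)", format(Sys.time(), "%H:%M:%S"), stage,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  cfg_path <- file.path(config$outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                     package_version =
                       as.character(utils::packageVersion("vepcasl")))
  yaml::write_yaml(provenance, file.path(config$outdir, "provenance.yaml"))

  out <- list(config = config)
  constants <- kinetic_constants()
  protocol <- default_protocol()
  geometry <- artery_geometry()
  matrix <- build_encoding_matrix(geometry)
  out$protocol <- protocol
  out$matrix <- matrix

  run <- function(stage, expr) {
    stage_clock(stage)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if ("simulate" %in% todo) {
    run("simulate", {
      spec <- do.call(phantom_spec, c(list(seed = config$seed),
                                      config$phantom))
      truth <- generate_truth(spec, constants)
      noise_sd <- noise_sd_for_snr(truth, protocol, constants,
                                   snr = config$snr)
      series <- synthesize_series(truth, protocol, matrix, constants,
                                  noise_sd = noise_sd,
                                  seed = config$seed + 1L)
      if (config$write_nifti) {
        write_series(series, file.path(config$outdir, "asl"))
        for (nm in c("adc", "gm_pv", "calibration")) {
          write_volume(truth[[nm]],
                       file.path(config$outdir, paste0(nm, ".nii.gz")),
                       truth$voxel_size_mm)
        }
        for (nm in c("core", "infarct", "ventricles", "brain")) {
          write_volume(truth[[nm]] * 1,
                       file.path(config$outdir, paste0(nm, ".nii.gz")),
                       truth$voxel_size_mm)
        }
      }
      total_true <- apply(truth$cbf, 1:3, sum)
      utils::write.csv(
        data.frame(
          region = c("brain", "gray_matter", "lesion", "core"),
          n_voxels = c(sum(truth$brain), sum(truth$gm_pv > 0.5),
                       sum(truth$lesion), sum(truth$core)),
          mean_total_cbf = c(
            mean(total_true[truth$brain]),
            mean(total_true[truth$gm_pv > 0.5]),
            if (any(truth$lesion)) mean(total_true[truth$lesion]) else NA,
            if (any(truth$core)) mean(total_true[truth$core]) else NA
          )
        ),
        file.path(config$outdir, "truth_summary.csv"), row.names = FALSE)
      out$truth <- truth
      out$series <- series
      out$noise_sd <- noise_sd
    })
  }
  if ("decode" %in% todo) {
    run("decode", {
      out$decoded <- decode_series(out$series, mask = out$truth$brain)
      if (config$write_nifti) {
        write_volume(out$decoded$class_map,
                     file.path(config$outdir, "vascular_territory.nii.gz"),
                     out$truth$voxel_size_mm)
      }
    })
  }
  if ("fit" %in% todo) {
    run("fit", {
      csf <- mean_csf_signal(out$truth$calibration, out$truth$ventricles)
      m0b <- calibrate_m0_blood(csf, constants)
      maps <- fit_maps(out$decoded, m0b, constants)
      out$m0_blood <- m0b
      out$maps <- maps
      if (config$write_nifti) {
        for (a in maps$artery_ids) {
          write_volume(maps$cbf[, , , a],
                       file.path(config$outdir,
                                 sprintf("cbf_%s.nii.gz", a)),
                       out$truth$voxel_size_mm)
        }
      }
    })
  }
  if ("maps" %in% todo) {
    run("maps", {
      out$derived <- direct_indirect(out$maps, config$ipsilateral)
      out$derived_contra <- direct_indirect(out$maps,
                                             config$contralateral)
      if (config$write_nifti) {
        d <- out$derived
        write_volume(d$total_cbf,
                     file.path(config$outdir, "total_cbf.nii.gz"),
                     out$truth$voxel_size_mm)
        write_volume(d$direct_cbf,
                     file.path(config$outdir, "direct_cbf.nii.gz"),
                     out$truth$voxel_size_mm)
        write_volume(d$indirect_cbf,
                     file.path(config$outdir, "indirect_cbf.nii.gz"),
                     out$truth$voxel_size_mm)
        wa <- d$weighted_att
        wa[is.na(wa)] <- 0
        write_volume(wa, file.path(config$outdir, "weighted_att.nii.gz"),
                     out$truth$voxel_size_mm)
      }
    })
  }
  if ("rois" %in% todo) {
    run("rois", {
      core <- core_from_adc(out$truth$adc, config$adc_threshold)
      rois <- build_roi_set(core, out$truth$infarct, out$truth$gm_pv,
                            out$truth$voxel_size_mm,
                            surviving_radius_mm = config$surviving_radius_mm,
                            peri_core_radius_mm = config$peri_core_radius_mm,
                            gm_threshold = config$gm_threshold)
      out$rois <- rois
      if (config$write_nifti) {
        for (nm in c("surviving_tissue", "peri_core",
                     "surviving_tissue_contra", "peri_core_contra")) {
          write_volume(rois[[nm]] * 1,
                       file.path(config$outdir, paste0(nm, ".nii.gz")),
                       out$truth$voxel_size_mm)
        }
      }
    })
  }
  if ("stats" %in% todo) {
    run("stats", {
      rois <- out$rois
      surv_tab <- survival_table(
        out$derived$direct_cbf, out$derived$indirect_cbf,
        out$truth$infarct, rois$peri_core,
        direct_cutoff = config$direct_cutoff,
        bin_width = config$bin_width)
      split_test <- binomial_split_test(surv_tab, split = config$split)
      frac_ipsi <- indirect_fraction(out$derived, rois$surviving_tissue)
      frac_contra <- indirect_fraction(out$derived_contra,
                                       rois$surviving_tissue_contra)
      watt <- out$derived$weighted_att
      mean_watt <- function(roi) mean(watt[roi & !is.na(watt)])
      summary_tab <- rbind(
        patient_summary("phantom", "presentation", "surviving",
                        frac_ipsi, mean_watt(rois$surviving_tissue)),
        patient_summary("phantom", "presentation", "contralateral",
                        frac_contra, mean_watt(rois$surviving_tissue_contra))
      )
      utils::write.csv(surv_tab,
                       file.path(config$outdir, "survival_table.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(split_test),
                       file.path(config$outdir, "split_test.csv"),
                       row.names = FALSE)
      utils::write.csv(summary_tab,
                       file.path(config$outdir, "patient_summary.csv"),
                       row.names = FALSE)
      out$survival_table <- surv_tab
      out$split_test <- split_test
      out$patient_summary <- summary_tab
    })
  }
  stage_clock("done")
  invisible(out)
}
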