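# Configured, deterministic end-to-end pipeline:
# simulate -> pwv -> separate -> maps -> icc -> glm -> vesselreg -> mediate.

pipeline_stages <- c("simulate", "pwv", "separate", "maps", "icc", "glm",
                     "vesselreg", "mediate")

#' Validate and complete a pipeline configuration
#'
#' Fills defaults (discard 4 frames, 4 noise components, 0.001-0.08 Hz band,
#' 6-mm FWHM, 10,000 permutations, 1,000 bootstrap iterations) and rejects
#' contradictory settings.
#'
#' @param raw named list (possibly empty) of overrides, e.g. parsed from a
#'   YAML or JSON file via [read_config()].
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(raw = list()) {
  if (inherits(raw, "pipeline_config")) raw <- unclass(raw)
  defaults <- list(
    seed = 1L,
    n_parent = 20L, n_offspring = 20L,
    dims = c(12L, 12L, 6L), n_frames = 100L, tr = 4,
    path_length = 0.356, waveform_noise_sd = 5,
    discard = 4L, compcor_k = 4L, band = c(0.001, 0.08),
    fwhm = 6, voxel_size = c(3.44, 3.44, 6),
    outlier_k = 5, outlier_mode = "default",
    gkm = list(tau = 1.5, pld = 1.0, t1b = 1.65, alpha = 0.85, lambda = 0.9),
    icc_clip = 0.9999, icc_chunk = NULL,
    n_perm = 10000L, direction = "negative",
    tfce_E = 0.5, tfce_H = 2, tfce_dh = NULL, tfce_connectivity = 26L,
    glm_targets = "bold_var",
    glm_covariates = character(0),
    n_boot = 1000L,
    truth = list(),
    stages = pipeline_stages,
    out_dir = NULL
  )
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    config_error(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)

  nyq <- 1 / (2 * cfg$tr)
  if (length(cfg$band) != 2L || cfg$band[1] >= cfg$band[2])
    config_error("band must be increasing [lo, hi]")
  if (cfg$band[2] >= nyq)
    config_error(sprintf("band hi (%g Hz) must be below Nyquist (%g Hz) for TR = %g s",
                         cfg$band[2], nyq, cfg$tr))
  if (cfg$discard %% 2L != 0L) config_error("discard must be even")
  if (cfg$n_frames %% 2L != 0L) config_error("n_frames must be even")
  if (!cfg$direction %in% c("negative", "positive"))
    config_error("direction must be 'negative' or 'positive'")
  if (!all(cfg$stages %in% pipeline_stages))
    config_error("unknown stage name(s)")
  if (!all(cfg$glm_targets %in% c("bold_var", "cbf_var", "cbf_quant", "icc")))
    config_error("glm_targets must be among bold_var, cbf_var, cbf_quant, icc")
  structure(cfg, class = "pipeline_config")
}

stage_dependency <- function(cfg, stage, needed) {
  missing <- setdiff(needed, cfg$stages)
  if (length(missing) > 0)
    dependency_error(sprintf("stage '%s' requires disabled stage(s): %s",
                             stage, paste(missing, collapse = ", ")))
}

# md5 of an arbitrary R object via a temporary serialization
object_checksum <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order: cohort simulation, PWV
#' estimation from the flow waveforms (two raters averaged), signal
#' separation, fluctuation/CBF maps, intrinsic connectivity, voxelwise GLM of
#' the map stacks on PWV (age-adjusted) with TFCE permutation correction,
#' vessel-probability regression and overlap, and bootstrap mediation of the
#' PWV-BOLD-variance association by CBF variance. Identical configurations
#' (including seeds) give identical outputs and manifest checksums.
#'
#' @param config a [validate_config()] result (or raw list of overrides).
#' @return A `pipeline_result` list with per-stage outputs and a `manifest`
#'   data frame (stage, outputs, checksum, wall time in seconds).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  res <- list(config = cfg)
  manifest <- list()
  note <- function(stage, obj, t0) {
    manifest[[stage]] <<- data.frame(
      stage = stage, outputs = paste(names(obj), collapse = ","),
      checksum = object_checksum(obj),
      wall_s = round(as.numeric(Sys.time()) - t0, 3))
  }

  ## simulate ---------------------------------------------------------------
  stage_dependency(cfg, "pwv", "simulate")
  t0 <- as.numeric(Sys.time())
  truth <- do.call(ground_truth, utils::modifyList(list(seed = cfg$seed),
                                                   cfg$truth))
  cohort <- generate_cohort(cfg$n_parent, cfg$n_offspring, truth,
                            dims = cfg$dims, n_frames = cfg$n_frames,
                            seed = cfg$seed, path_length = cfg$path_length,
                            waveform_noise_sd = cfg$waveform_noise_sd)
  res$cohort <- cohort
  cov <- cohort$covariates
  if ("simulate" %in% cfg$stages)
    note("simulate", list(covariates = cov, atlas = cohort$atlas), t0)

  ## pwv --------------------------------------------------------------------
  if ("pwv" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    est <- lapply(cohort$waveforms, function(w)
      rate_pwv_twice(w$arch, w$abdominal, path_length = cfg$path_length))
    cov$pwv <- vapply(est, function(e) e$pwv, numeric(1))[cov$subject_id]
    res$pwv_estimates <- est
    note("pwv", list(pwv = cov$pwv), t0)
  } else {
    cov$pwv <- cov$pwv_true
  }
  res$covariates <- cov

  ## separate ---------------------------------------------------------------
  if (any(c("separate", "maps", "icc", "glm", "mediate") %in% cfg$stages)) {
    stage_dependency(cfg, "separate", "simulate")
    t0 <- as.numeric(Sys.time())
    sep <- lapply(cohort$series, function(s)
      separate_signals(s, discard = cfg$discard, compcor_k = cfg$compcor_k,
                       band = cfg$band, fwhm = cfg$fwhm,
                       voxel_size = cfg$voxel_size))
    res$separated <- sep
    if ("separate" %in% cfg$stages)
      note("separate", list(provenance = sep[[1]]$provenance), t0)
  }

  atlas <- cohort$atlas
  gm <- atlas$gm

  ## maps -------------------------------------------------------------------
  if (any(c("maps", "glm", "mediate") %in% cfg$stages)) {
    stage_dependency(cfg, "maps", c("simulate", "separate"))
    t0 <- as.numeric(Sys.time())
    maps <- lapply(res$separated, function(ds) {
      bold_var <- variance_map(ds$bold, atlas$brain, outlier_k = cfg$outlier_k)
      cbf_var <- cbf_variance_map(ds$cbf_signal, gm, outlier_k = cfg$outlier_k)
      keep <- reject_outlier_volumes(ds$delta_m, gm, mode = cfg$outlier_mode)
      mean_dm <- apply(keep$series, 1:3, mean)
      m0 <- apply(ds$raw_echo1, 1:3, mean)
      cbf_q <- quantify_cbf(mean_dm, m0, do.call(gkm_params, cfg$gkm),
                            mask = gm)
      list(bold_var = bold_var, cbf_var = cbf_var, cbf_quant = cbf_q)
    })
    res$maps <- maps
    if ("maps" %in% cfg$stages)
      note("maps", list(kinds = names(maps[[1]])), t0)
  }

  ## icc --------------------------------------------------------------------
  if ("icc" %in% cfg$stages) {
    stage_dependency(cfg, "icc", c("simulate", "separate"))
    t0 <- as.numeric(Sys.time())
    res$icc <- lapply(res$separated, function(ds)
      icc_map(ds$bold, gm, clip = cfg$icc_clip, chunk = cfg$icc_chunk))
    note("icc", list(n = length(res$icc)), t0)
  }

  ## glm --------------------------------------------------------------------
  if ("glm" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    # primary analysis: PWV against the maps; covariates (e.g. age) can be
    # added for the adjusted secondary model
    design <- cbind(intercept = 1, pwv = cov$pwv)
    for (cc in cfg$glm_covariates) design <- cbind(design, cov[[cc]])
    contrast <- c(0, 1, rep(0, length(cfg$glm_covariates)))
    res$glm <- list()
    for (target in cfg$glm_targets) {
      if (target == "icc") {
        stage_dependency(cfg, "glm", "icc")
        stack <- group_icc_stack(res$icc, cov$subject_id)
        mask <- gm
      } else {
        stage_dependency(cfg, "glm", "maps")
        stack <- group_icc_stack(lapply(res$maps, `[[`, target),
                                 cov$subject_id)
        mask <- if (target == "bold_var") atlas$brain else gm
      }
      res$glm[[target]] <- permutation_correct(
        stack$data, design, contrast, n_perm = cfg$n_perm, seed = cfg$seed,
        direction = cfg$direction, mask = mask, E = cfg$tfce_E, H = cfg$tfce_H,
        dh = cfg$tfce_dh, connectivity = cfg$tfce_connectivity)
    }
    note("glm", lapply(res$glm, function(g)
      min(g$pcorr_map$values[g$pcorr_map$mask])), t0)
  }

  ## vesselreg --------------------------------------------------------------
  if ("vesselreg" %in% cfg$stages) {
    stage_dependency(cfg, "vesselreg", "glm")
    t0 <- as.numeric(Sys.time())
    g <- res$glm[[cfg$glm_targets[1]]]
    sig <- g$pcorr_map$values < 0.05 & g$pcorr_map$mask
    res$vesselreg <- if (any(sig)) {
      vr <- tryCatch(
        vessel_bin_regression(g$tmap, atlas$vessel_prob, sig),
        pwvfmri_error = function(e) NULL)
      list(regression = vr,
           overlap_pct = overlap_fraction(sig, atlas$vessel_prob > 0))
    } else list(regression = NULL, overlap_pct = NA_real_)
    note("vesselreg", res$vesselreg["overlap_pct"], t0)
  }

  ## mediate ----------------------------------------------------------------
  if ("mediate" %in% cfg$stages) {
    stage_dependency(cfg, "mediate", c("simulate", "maps"))
    t0 <- as.numeric(Sys.time())
    roi <- cohort$effect_roi
    m_vals <- vapply(res$maps, function(mm) roi_mean(mm$cbf_var, roi),
                     numeric(1))[cov$subject_id]
    y_vals <- vapply(res$maps, function(mm) roi_mean(mm$bold_var, roi),
                     numeric(1))[cov$subject_id]
    res$mediation <- mediate(cov$pwv, m_vals, y_vals,
                             n_boot = cfg$n_boot, seed = cfg$seed)
    res$roi_values <- data.frame(subject_id = cov$subject_id, pwv = cov$pwv,
                                 cbf_var = m_vals, bold_var = y_vals)
    note("mediate", list(ab = res$mediation$ab, p = res$mediation$p_boot), t0)
  }

  res$manifest <- do.call(rbind, manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}
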