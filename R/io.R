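# File interfaces: NIfTI-1 volumes, CSV tables, JSON sidecars, YAML/JSON
# configuration.

#' Read a pipeline configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file of overrides.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                config_error("config must be a .yaml/.yml or .json file"))
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' Write a 3-D/4-D array as NIfTI-1
#'
#' @param arr numeric array (logical arrays are stored as 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(arr, path, voxel_size = c(3.44, 3.44, 6)) {
  if (is.logical(arr)) arr <- array(as.numeric(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr, pixdim = rep_len(voxel_size, 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return Numeric array (dimensions as stored).
#' @export
read_volume_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a dual-echo series with its frame-role sidecar
#'
#' Stores both echoes as 4-D NIfTI volumes and the acquisition metadata
#' (frame roles, TR, echo times, labeling timing) as a JSON sidecar.
#'
#' @param s a `dual_echo_series`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param voxel_size voxel size in mm.
#' @return Named character vector of written paths, invisibly.
#' @export
write_series_nifti <- function(s, dir, prefix = "subject",
                               voxel_size = c(3.44, 3.44, 6)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_echo1.nii.gz"))
  p2 <- file.path(dir, paste0(prefix, "_echo2.nii.gz"))
  pj <- file.path(dir, paste0(prefix, "_series.json"))
  write_volume_nifti(s$echo1, p1, voxel_size)
  write_volume_nifti(s$echo2, p2, voxel_size)
  jsonlite::write_json(list(frame_role = s$frame_role, tr = s$tr,
                            te_cbf = s$te_cbf, te_bold = s$te_bold,
                            tau = s$tau, pld = s$pld),
                       pj, auto_unbox = TRUE, digits = NA)
  invisible(c(echo1 = p1, echo2 = p2, sidecar = pj))
}

#' Read a dual-echo series written by [write_series_nifti()]
#'
#' @param dir directory containing the files.
#' @param prefix file-name prefix used when writing.
#' @param masks optional mask list to attach.
#' @return A `dual_echo_series`.
#' @export
read_series_nifti <- function(dir, prefix = "subject", masks = NULL) {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_series.json")),
                              simplifyVector = TRUE)
  structure(list(
    echo1 = read_volume_nifti(file.path(dir, paste0(prefix, "_echo1.nii.gz"))),
    echo2 = read_volume_nifti(file.path(dir, paste0(prefix, "_echo2.nii.gz"))),
    frame_role = meta$frame_role, tr = meta$tr, te_cbf = meta$te_cbf,
    te_bold = meta$te_bold, tau = meta$tau, pld = meta$pld, masks = masks
  ), class = "dual_echo_series")
}

#' Read a flow waveform from a two-column CSV
#'
#' Expects columns `time_ms` and `flow_ml_s` (header row).
#'
#' @param path CSV file.
#' @param plane_label `"arch"` or `"abdominal"`.
#' @return A `flow_waveform`.
#' @export
read_flow_waveform_csv <- function(path, plane_label = c("arch", "abdominal")) {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "flow_ml_s") %in% names(d)))
    arg_error("waveform CSV needs columns time_ms, flow_ml_s")
  flow_waveform(d$time_ms, d$flow_ml_s, match.arg(plane_label))
}

#' Write a flow waveform to CSV
#'
#' @param w a `flow_waveform`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_waveform_csv <- function(w, path) {
  utils::write.csv(data.frame(time_ms = w$time_ms, flow_ml_s = w$flow),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write covariates as CSV
#'
#' @param cov covariate data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(cov, path) {
  utils::write.csv(cov, path, row.names = FALSE)
  invisible(path)
}

#' Write key pipeline outputs to disk
#'
#' Covariates (CSV), ground-truth sidecar (JSON), atlas volumes and group
#' statistical maps (NIfTI), model/mediation summaries (JSON) and the run
#' manifest (CSV).
#'
#' @param res a `pipeline_result`.
#' @param dir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vx <- res$config$voxel_size
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }
  write_covariates_csv(res$covariates, w(file.path(dir, "covariates.csv")))
  truth <- res$cohort$truth
  jsonlite::write_json(truth[!vapply(truth, is.array, logical(1))],
                       w(file.path(dir, "ground_truth.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  atlas <- res$cohort$atlas
  for (nm in c("gm", "wm", "csf", "vessel_prob"))
    write_volume_nifti(atlas[[nm]],
                       w(file.path(dir, paste0("atlas_", nm, ".nii.gz"))), vx)
  for (target in names(res$glm)) {
    g <- res$glm[[target]]
    write_volume_nifti(g$tmap$values,
                       w(file.path(dir, paste0(target, "_tstat.nii.gz"))), vx)
    write_volume_nifti(g$pcorr_map$values,
                       w(file.path(dir, paste0(target, "_pcorr.nii.gz"))), vx)
  }
  if (!is.null(res$mediation))
    jsonlite::write_json(
      res$mediation[c("a", "b", "c", "c_prime", "ab", "ci95", "p_boot",
                      "n_boot", "seed")],
      w(file.path(dir, "mediation.json")), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$manifest))
    utils::write.csv(res$manifest, w(file.path(dir, "manifest.csv")),
                     row.names = FALSE)
  invisible(paths)
}
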