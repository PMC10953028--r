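# Lightweight file interfaces: NIfTI magnitude volumes and MIPs, PNG mask
# previews, YAML configuration, JSON/CSV metric reports.

#' Write a magnitude volume (or MIP) as NIfTI
#'
#' @param volume 3D volume or 2D image; complex input is stored as modulus.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_mm Voxel spacing in mm (recycled to 3).
#' @return Invisibly, `path`.
#' @export
write_volume_nifti <- function(volume, path, voxel_mm = c(1, 1, 1)) {
  m <- Mod(volume)
  if (length(dim(m)) == 2) dim(m) <- c(dim(m), 1)
  img <- RNifti::asNifti(m, pixdim = rep_len(voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a magnitude volume from NIfTI
#'
#' @param path Input NIfTI path.
#' @return Numeric array.
#' @export
read_volume_nifti <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Write a sampling mask as a PNG preview
#'
#' @param mask A `sampling_mask`.
#' @param path Output `.png` path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  img <- t(mask$grid[nrow(mask$grid):1, , drop = FALSE]) * 1.0
  png::writePNG(img, path)
  invisible(path)
}

#' Save / load a k-space simulation container
#'
#' Serializes the complex k-space data together with the operator that
#' produced it (RDS container).
#'
#' @param ksim A `ksim` object from [simulate_acquisition()].
#' @param path Output `.rds` path.
#' @return Invisibly, `path`.
#' @export
write_ksim <- function(ksim, path) {
  stopifnot(inherits(ksim, "ksim"))
  saveRDS(ksim, path)
  invisible(path)
}

#' @rdname write_ksim
#' @export
read_ksim <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "ksim"))
  x
}

#' Write / read a wave trajectory as CSV
#'
#' Four columns (`t_ms`, `kx`, `ky_wave`, `kz_wave`; k in cycles/m) with
#' the readout FOV recorded in a header comment line.
#'
#' @param traj A `wave_trajectory`.
#' @param path Output `.csv` path.
#' @return Invisibly, `path` (write) or the `wave_trajectory` (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "wave_trajectory"))
  con <- file(path, "w")
  writeLines(sprintf("# fov_x_mm=%g", traj$fov_x), con)
  utils::write.csv(data.frame(t_ms = traj$t, kx = traj$kx,
                              ky_wave = traj$ky_wave,
                              kz_wave = traj$kz_wave),
                   con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fov_x <- as.numeric(sub("# fov_x_mm=", "", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(t = df$t_ms, kx = df$kx, ky_wave = df$ky_wave,
                 kz_wave = df$kz_wave, fov_x = fov_x, params = NULL),
            class = "wave_trajectory")
}

#' Read wave parameters from a YAML/JSON config
#'
#' Reads the `wave:` block of a configuration file; missing fields fall
#' back to the [wave_params()] defaults.
#'
#' @param path YAML (or JSON) configuration file.
#' @return A [wave_params()] object.
#' @export
read_wave_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  w <- cfg$wave
  if (is.null(w)) stop("config has no 'wave:' block")
  do.call(wave_params, w[intersect(names(w),
                                   names(formals(wave_params)))])
}

#' Write an experiment metric table
#'
#' @param experiment A `wave_experiment` (or its `metrics` data frame).
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the metrics data frame.
#' @export
write_metrics <- function(experiment, csv_path = NULL, json_path = NULL) {
  m <- if (inherits(experiment, "wave_experiment")) experiment$metrics
  else experiment
  if (!is.null(csv_path)) utils::write.csv(m, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(m, json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(m)
}
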