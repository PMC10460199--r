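#' Write a velocity series to NIfTI stacks plus a JSON sidecar
#'
#' The velocity and the mask each go to one multi-frame NIfTI stack; timing,
#' spacing, the velocity scale and the sign convention go to a JSON sidecar
#' with keys `rr_interval_ms`, `trigger_times_ms`, `pixel_spacing_mm`,
#' `velocity_scale_cm_per_s`, `roi_label`, `forward_sign`. Velocities are
#' stored as `velocity / velocity_scale_cm_per_s` so a scaled acquisition can
#' round-trip; the default scale of 1 stores cm/s directly.
#'
#' @param series a [velocity_series()].
#' @param velocity_path,mask_path,sidecar_path output file paths (`.nii` or
#'   `.nii.gz` for the stacks, `.json` for the sidecar).
#' @param velocity_scale_cm_per_s cm/s per stored unit (default 1).
#' @return the sidecar path, invisibly.
#' @export
write_velocity_series <- function(series, velocity_path, mask_path,
                                  sidecar_path,
                                  velocity_scale_cm_per_s = 1) {
  validate_velocity_series(series)
  RNifti::writeNifti(series$velocity / velocity_scale_cm_per_s, velocity_path,
                     datatype = "double")
  RNifti::writeNifti(array(as.integer(series$mask), dim(series$mask)),
                     mask_path, datatype = "uint8")
  sidecar <- list(
    rr_interval_ms = series$rr_interval_ms,
    trigger_times_ms = series$trigger_times_ms,
    pixel_spacing_mm = series$pixel_spacing_mm,
    velocity_scale_cm_per_s = velocity_scale_cm_per_s,
    roi_label = series$roi_label,
    forward_sign = series$forward_sign
  )
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}

#' Load a velocity series from NIfTI stacks and a JSON sidecar
#'
#' Reads the stacks, applies the sidecar velocity scale so the returned
#' velocities are cm/s, and validates every container invariant. Missing
#' sidecar keys, geometry mismatches between stack and sidecar or stack and
#' mask, and non-monotone trigger times each raise a distinct classed error
#' (`aortaflow_error_metadata`, `aortaflow_error_shape`,
#' `aortaflow_error_timing`).
#'
#' @param velocity_path,mask_path,sidecar_path paths written by
#'   [write_velocity_series()] (or any files of the same layout).
#' @return a [velocity_series()].
#' @export
load_velocity_series <- function(velocity_path, mask_path, sidecar_path) {
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required <- c("rr_interval_ms", "trigger_times_ms", "pixel_spacing_mm",
                "velocity_scale_cm_per_s", "roi_label", "forward_sign")
  missing <- setdiff(required, names(sidecar))
  if (length(missing)) {
    abort(paste0("sidecar is missing key(s): ", paste(missing, collapse = ", ")),
          class = "aortaflow_error_metadata")
  }
  vel <- array(as.numeric(RNifti::readNifti(velocity_path)),
               dim = dim(RNifti::readNifti(velocity_path)))
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(vel)) != 3L) {
    abort("velocity stack is not 3-D.", class = "aortaflow_error_shape")
  }
  if (length(sidecar$trigger_times_ms) != dim(vel)[3L]) {
    abort(sprintf("sidecar lists %d trigger times for a %d-frame stack.",
                  length(sidecar$trigger_times_ms), dim(vel)[3L]),
          class = "aortaflow_error_shape")
  }
  velocity_series(
    velocity = vel * sidecar$velocity_scale_cm_per_s,
    mask = array(msk != 0, dim(msk)),
    trigger_times_ms = sidecar$trigger_times_ms,
    rr_interval_ms = sidecar$rr_interval_ms,
    pixel_spacing_mm = sidecar$pixel_spacing_mm,
    roi_label = sidecar$roi_label,
    forward_sign = sidecar$forward_sign
  )
}

cohort_required_cols <- c("id", "age", "sex", "bsa", "lvef")
cohort_numeric_cols <- c(
  "age", "height", "weight", "bsa", "lvef", "pvo2", "mets", "ve_vco2_slope",
  "ffi", "bfi", "sff", "srf", "sfrr", "rac", "fds_avg", "fdls_avg", "fdd_avg",
  "fdps", "delta_ra", "rsls_avg", "pwv"
)

#' Read a subject-level cohort table from CSV
#'
#' Expects RFC-4180 CSV with at least the columns `id`, `age`, `sex`, `bsa`,
#' `lvef`; the optional columns (`height`, `weight`, `pvo2`, `mets`,
#' `ve_vco2_slope` and any flow-metric column such as `ffi`, `fds_avg`,
#' `sfrr`, `pwv`) are parsed as numeric when present and left absent (`NA`)
#' when missing from a row — never silently zero. Units follow the field
#' convention: age in years, height cm, weight kg, BSA m^2, LVEF %, PVO2 in
#' mL/kg/min.
#'
#' @param path CSV file path.
#' @return a tibble, one row per subject.
#' @export
load_cohort_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cohort_required_cols, names(tab))
  if (length(missing)) {
    abort(paste0("cohort table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "aortaflow_error_metadata")
  }
  for (col in intersect(cohort_numeric_cols, names(tab))) {
    v <- tab[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad)) {
        abort(sprintf("non-numeric value '%s' in numeric column '%s' (row %d).",
                      v[bad[1L]], col, bad[1L]),
              class = "aortaflow_error_value")
      }
      v <- parsed
    }
    tab[[col]] <- as.numeric(v)
  }
  bad_bsa <- which(!is.na(tab$bsa) & tab$bsa <= 0)
  if (length(bad_bsa)) {
    abort(sprintf("bsa must be > 0 (row %d).", bad_bsa[1L]),
          class = "aortaflow_error_value")
  }
  bad_lvef <- which(!is.na(tab$lvef) & (tab$lvef <= 0 | tab$lvef > 100))
  if (length(bad_lvef)) {
    abort(sprintf("lvef must lie in (0, 100] (row %d).", bad_lvef[1L]),
          class = "aortaflow_error_value")
  }
  if ("pvo2" %in% names(tab) && any(tab$pvo2 < 0, na.rm = TRUE)) {
    abort("pvo2 must be >= 0.", class = "aortaflow_error_value")
  }
  tab
}

#' Write a cohort table to CSV
#' @param table a data frame of subject records.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Read an aortic-arch centerline polyline
#'
#' CSV with columns `x_mm`, `y_mm`, `z_mm`: ordered 3-D points along the arch
#' between the ascending and descending measurement planes.
#'
#' @param path CSV file path.
#' @return tibble with columns `x_mm`, `y_mm`, `z_mm`.
#' @export
read_centerline <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("x_mm", "y_mm", "z_mm"), names(tab))
  if (length(missing)) {
    abort(paste0("centerline is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "aortaflow_error_metadata")
  }
  validate_centerline(tab)
  tab
}

validate_centerline <- function(points) {
  if (nrow(points) < 2L) {
    abort("a centerline needs at least 2 points.",
          class = "aortaflow_error_shape")
  }
  seg <- as.matrix(points[-1L, c("x_mm", "y_mm", "z_mm")]) -
    as.matrix(points[-nrow(points), c("x_mm", "y_mm", "z_mm")])
  if (any(rowSums(seg^2) == 0)) {
    abort("consecutive centerline points must be distinct.",
          class = "aortaflow_error_value")
  }
  invisible(points)
}

#' Write a centerline polyline to CSV
#' @param points tibble with `x_mm`, `y_mm`, `z_mm`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_centerline <- function(points, path) {
  readr::write_csv(points, path, progress = FALSE)
  invisible(path)
}
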