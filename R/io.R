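#' Write a frame schedule to a JSON sidecar
#'
#' The sidecar is `{"frame_starts_s": [...], "frame_durations_s": [...]}`.
#'
#' @param schedule A [frame_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  jsonlite::write_json(list(frame_starts_s = schedule$frame_starts,
                            frame_durations_s = schedule$frame_durations),
                       path, digits = NA)
  invisible(path)
}

#' Read a frame schedule from a JSON sidecar
#' @param path JSON file written by [write_frame_schedule()].
#' @return A [frame_schedule()].
#' @export
read_frame_schedule <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("frame_starts_s", "frame_durations_s") %in% names(j)))
    stop("schedule sidecar must contain frame_starts_s and frame_durations_s")
  frame_schedule(j$frame_starts_s, j$frame_durations_s)
}

#' Write an image array as NIfTI-1
#'
#' @param img 3D or 4D numeric array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_size_mm Isotropic voxel edge, mm.  Default 3.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size_mm = 3) {
  nd <- length(dim(img))
  pix <- c(rep(voxel_size_mm, 3), if (nd == 4L) 1)
  RNifti::writeNifti(RNifti::asNifti(img, pixdim = pix), path)
  invisible(path)
}

#' Read a NIfTI image as a plain array
#' @param path NIfTI file path.
#' @return Numeric array (header dropped).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Read a dynamic PET series with its frame schedule
#'
#' @param nifti_path 4D NIfTI path.
#' @param schedule_path JSON sidecar path.
#' @return List with `dynamic` (4D array) and `schedule`
#'   (a [frame_schedule()]); errors if the frame counts disagree.
#' @export
read_dynamic <- function(nifti_path, schedule_path) {
  dynamic <- read_nifti(nifti_path)
  if (length(dim(dynamic)) != 4L) stop("expected a 4D dynamic image")
  schedule <- read_frame_schedule(schedule_path)
  if (dim(dynamic)[4] != length(schedule$frame_starts))
    stop(sprintf("frame count mismatch: image has %d volumes, schedule %d frames",
                 dim(dynamic)[4], length(schedule$frame_starts)))
  list(dynamic = dynamic, schedule = schedule)
}

#' Write an agreement table to CSV
#' @param table Data frame as from [simulate_agreement_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_agreement_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read an agreement table from CSV
#' @param path CSV with columns participant, kidney, day, scan, modality,
#'   perfusion_ml_min_100ml.
#' @return Data frame.
#' @export
read_agreement_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "kidney", "day", "scan", "modality",
            "perfusion_ml_min_100ml")
  if (!all(need %in% names(tab)))
    stop("agreement CSV must contain columns: ", paste(need, collapse = ", "))
  tab
}
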