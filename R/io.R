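#' Write a synthetic subject to NIfTI files
#'
#' Writes the 4D dynamic image, the brain mask, the ROI atlas and the
#' ground-truth DVR volume as gzipped NIfTI, plus the frame schedule as a CSV
#' sidecar (`columns start_s,duration_s`). File names are prefixed with the
#' subject id.
#'
#' @param subject a [generate_subject()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_subject_nifti <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- subject$subject_id
  vox <- subject$dynamic_image$voxel_size_mm
  paths <- c(
    dynamic = file.path(dir, paste0(id, "_dynamic.nii.gz")),
    mask = file.path(dir, paste0(id, "_mask.nii.gz")),
    atlas = file.path(dir, paste0(id, "_atlas.nii.gz")),
    true_dvr = file.path(dir, paste0(id, "_true_dvr.nii.gz")),
    schedule = file.path(dir, paste0(id, "_frames.csv")))
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr, reference = NULL)
    RNifti::pixdim(img) <- c(vox, rep(1, length(dim(arr)) - 3))
    RNifti::writeNifti(img, path)
  }
  wr(subject$dynamic_image$data, paths["dynamic"])
  wr(subject$brain_mask, paths["mask"])
  wr(subject$atlas, paths["atlas"])
  wr(subject$true_dvr, paths["true_dvr"])
  write_frame_schedule(subject$dynamic_image$schedule, paths["schedule"])
  invisible(paths)
}

#' Read a dynamic PET image from NIfTI + timing sidecar
#'
#' @param nifti_path path to a 4D NIfTI volume.
#' @param schedule_path path to the frame-timing CSV sidecar
#'   (`start_s,duration_s`).
#' @return a [dynamic_pet_image()].
#' @export
read_dynamic_pet <- function(nifti_path, schedule_path) {
  img <- RNifti::readNifti(nifti_path)
  sched <- read_frame_schedule(schedule_path)
  vox <- RNifti::pixdim(img)[1:3]
  dynamic_pet_image(array(as.numeric(img), dim(img)), sched,
                    voxel_size_mm = vox)
}

#' Read a 3D NIfTI volume as a plain array
#' @param path NIfTI file path.
#' @return numeric array.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write / read a feature table as TSV
#'
#' Columns: `subject_id`, `group`, then one column per feature. An optional
#' `# key: value` comment header records provenance (e.g. the config hash);
#' comment lines are skipped on read.
#'
#' @param table a [feature_table()].
#' @param path TSV file path.
#' @param comments optional named character vector written as `# name: value`
#'   header lines.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the validated data.frame.
#' @export
write_feature_table <- function(table, path, comments = NULL) {
  table <- feature_table(table)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) {
    writeLines(sprintf("# %s: %s", names(comments), comments), con)
  }
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  feature_table(utils::read.delim(path, comment.char = "#"))
}
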