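# NIfTI and table I/O. Volumes are stored with the axial stacking axis
# first and pixdim = (inter-slice distance, in-plane, in-plane) in mm; the
# cohort manifest carries the full geometry so a round trip is exact.

#' Write a mask or intensity volume to NIfTI
#'
#' @param x A [label_volume] or [intensity_volume].
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return `file`, invisibly.
#' @export
write_volume_nifti <- function(x, file) {
  acq <- x$geometry
  arr <- if (inherits(x, "label_volume")) array(as.integer(x$mask), dim(x$mask))
         else x$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(acq$inter_slice_distance, acq$in_plane_spacing,
                           acq$in_plane_spacing)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a binary tumor mask from NIfTI
#'
#' Voxels > 0.5 are foreground. Spacings come from the NIfTI pixdim (axis 1
#' = inter-slice distance); the slice thickness is not representable there,
#' so it defaults to the inter-slice distance (zero gap) unless supplied.
#'
#' @param file NIfTI path.
#' @param scan_time Scan time in years attached to the volume.
#' @param slice_thickness Optional slice thickness in mm.
#' @return A [label_volume].
#' @export
read_label_volume <- function(file, scan_time = NA_real_,
                              slice_thickness = NULL) {
  img <- RNifti::readNifti(file)
  pd <- RNifti::pixdim(img)
  if (is.null(slice_thickness)) slice_thickness <- pd[1]
  acq <- acquisition_params(pd[2], slice_thickness, pd[1], dim(img))
  label_volume(array(as.array(img) > 0.5, dim(img)), acq, scan_time,
               check = FALSE)
}

#' Write a generated cohort to disk
#'
#' One NIfTI mask (and intensity volume, when rendered) per scan plus a
#' tab-delimited manifest: subject, scan index, time, file paths, geometry,
#' and the ground-truth change-point.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (subj in cohort) {
    for (k in seq_along(subj$scans)) {
      sc <- subj$scans[[k]]
      acq <- sc$label$geometry
      mask_file <- file.path(dir, sprintf("%s_scan%02d_mask.nii.gz", subj$subject, k))
      write_volume_nifti(sc$label, mask_file)
      int_file <- NA_character_
      if (!is.null(sc$intensity)) {
        int_file <- file.path(dir, sprintf("%s_scan%02d_intensity.nii.gz", subj$subject, k))
        write_volume_nifti(sc$intensity, int_file)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj$subject, scan_index = k, time = sc$label$scan_time,
        mask_file = basename(mask_file), intensity_file = basename(int_file),
        in_plane_spacing = acq$in_plane_spacing,
        slice_thickness = acq$slice_thickness,
        inter_slice_distance = acq$inter_slice_distance,
        true_change_index = subj$true_change_index,
        true_onset_time = subj$true_onset_time,
        true_volume_cm3 = subj$true_volumes_cm3[k])
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest and its mask volumes
#'
#' @param manifest_path Path to a `manifest.tsv` written by [write_cohort()].
#' @return A cohort list in the [generate_cohort()] layout (labels only).
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.delim(manifest_path)
  dir <- dirname(manifest_path)
  lapply(split(man, man$subject), function(ms) {
    ms <- ms[order(ms$scan_index), ]
    scans <- lapply(seq_len(nrow(ms)), function(i) {
      lv <- read_label_volume(file.path(dir, ms$mask_file[i]),
                              scan_time = ms$time[i],
                              slice_thickness = ms$slice_thickness[i])
      list(label = lv)
    })
    list(subject = ms$subject[1], scans = scans,
         true_volumes_cm3 = ms$true_volume_cm3,
         true_change_index = ms$true_change_index[1],
         true_onset_time = ms$true_onset_time[1])
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
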