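#' Write a synthetic subject to disk
#'
#' Writes the dynamic series as a 4D NIfTI (x, y, z=1, time; `double`
#' datatype so HU values round-trip bit-exactly), one 0/1 NIfTI label image
#' per ROI mask, the ground-truth table as CSV and a JSON sidecar
#' (`subject.json`) carrying the frame times (NIfTI time metadata is
#' unreliable across tools), the seed and the AIF parameters.
#'
#' @param subject a `synthetic_subject` from [rasterize_subject()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [read_subject()]
#' @export
write_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "synthetic_subject"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(subject$series$voxels)
  vol4d <- aperm(array(subject$series$voxels, dim = c(d[1], d[2], d[3], 1)),
                 c(2, 3, 4, 1))
  RNifti::writeNifti(RNifti::asNifti(vol4d), file.path(dir, "series.nii.gz"),
                     datatype = "double")
  for (nm in names(subject$masks)) {
    m <- subject$masks[[nm]]$mask
    arr <- array(as.integer(m), dim = c(dim(m), 1))
    RNifti::writeNifti(RNifti::asNifti(arr),
                       file.path(dir, paste0("mask_", nm, ".nii.gz")),
                       datatype = "uint8")
  }
  utils::write.csv(subject$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  sidecar <- list(
    frame_times = subject$series$times,
    seed = subject$seed,
    aif_params = unclass(subject$aif_params),
    masks = lapply(subject$masks, function(m)
      list(label = m$label, shape_kind = m$shape_kind))
  )
  jsonlite::write_json(sidecar, file.path(dir, "subject.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic subject written by [write_subject()]
#'
#' @param dir subject directory.
#' @return a `synthetic_subject` (the noise-free `aif_true` is rebuilt from
#'   the stored AIF parameters).
#' @export
read_subject <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "subject.json"),
                                 simplifyVector = TRUE)
  vol4d <- as.array(RNifti::readNifti(file.path(dir, "series.nii.gz")))
  voxels <- aperm(vol4d, c(4, 1, 2, 3))
  dim(voxels) <- dim(voxels)[1:3]
  series <- dynamic_series(voxels, sidecar$frame_times)

  mask_files <- list.files(dir, pattern = "^mask_.*\\.nii\\.gz$")
  if (length(mask_files) == 0) stop(sprintf("no mask files found in %s", dir))
  masks <- list()
  for (f in mask_files) {
    nm <- sub("^mask_(.*)\\.nii\\.gz$", "\\1", f)
    meta <- sidecar$masks[[nm]]
    if (is.null(meta)) stop(sprintf("mask '%s' missing from subject.json", nm))
    arr <- as.array(RNifti::readNifti(file.path(dir, f)))
    dim(arr) <- dim(arr)[1:2]
    masks[[nm]] <- roi_mask(arr > 0, meta$label, meta$shape_kind)
  }
  ap <- do.call(aif_params, sidecar$aif_params[
    c("baseline", "onset", "shape_alpha", "scale_beta", "amplitude")])
  structure(list(
    series = series, masks = masks,
    aif_true = make_aif(ap, series$times), aif_params = ap,
    ground_truth = utils::read.csv(file.path(dir, "ground_truth.csv")),
    seed = as.integer(sidecar$seed)
  ), class = "synthetic_subject")
}

#' Write a cohort of synthetic subjects
#'
#' One `subject_NN/` directory per subject (see [write_subject()]) plus a
#' `manifest.csv` and the pooled `ground_truth.csv`.
#'
#' @param cohort list of `synthetic_subject` objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- sprintf("subject_%02d", seq_along(cohort))
  for (i in seq_along(cohort)) write_subject(cohort[[i]], file.path(dir, ids[i]))
  utils::write.csv(data.frame(subject = seq_along(cohort), path = ids,
                              seed = vapply(cohort, `[[`, integer(1), "seed")),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort_ground_truth(cohort),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory with a `manifest.csv`.
#' @return list of `synthetic_subject` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(manifest$path, function(p) read_subject(file.path(dir, p)))
}

#' Write sweep results as tidy CSV plus a JSON summary
#'
#' `records.csv` (one row per timing), `bf_table.csv` (timing x tissue x ROI
#' kind), `cov.csv`, and `summary.json` with the optimum range, COV values
#' and skipped subjects.
#'
#' @param result a `sweep_result` from [run_sweep()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sweep_result <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(result$bf_table, file.path(dir, "bf_table.csv"), row.names = FALSE)
  cov_df <- do.call(rbind, lapply(names(result$cov), function(nm) {
    data.frame(series = nm,
               per_subject_mean = result$cov[[nm]][["per_subject_mean"]],
               cohort_mean = result$cov[[nm]][["cohort_mean"]])
  }))
  utils::write.csv(cov_df, file.path(dir, "cov.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_subjects = result$n_subjects, skipped = result$skipped,
         optimum = result$optimum, cov = result$cov,
         thresholds = list(mean = result$sweep$r_threshold_mean,
                           voxel = result$sweep$r_threshold_voxel)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
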