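#' Write a simulated subject to disk
#'
#' Serialises a [LaminarSubject-class] in portable formats: every run as
#' a 4-D NIfTI volume (voxels flattened onto a 1 x 1 x nVoxels lattice,
#' time as the fourth dimension), a sidecar JSON with the TR, seed and
#' per-voxel ground truth, and the task design as one BIDS-style events
#' TSV per run (`onset`, `duration`, `trial_type` columns, with
#' `trial_type = condition_colour`).
#'
#' @param subject a [LaminarSubject-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSubjectData <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  writeRun <- function(ts, name) {
    arr <- array(ts, dim = c(1L, 1L, nrow(ts), ncol(ts)))
    p <- file.path(dir, paste0(name, ".nii.gz"))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(1, 1, 1)
    RNifti::writeNifti(img, p)
    p
  }
  for (r in seq_along(taskRuns(subject)))
    paths <- c(paths, writeRun(taskRuns(subject)[[r]],
                               sprintf("task_run-%02d_bold", r)))
  for (kind in names(retinotopyRuns(subject)))
    paths <- c(paths, writeRun(retinotopyRuns(subject)[[kind]],
                               paste0(kind, "_bold")))
  ev <- designEvents(subjectDesign(subject))
  for (r in unique(ev$run)) {
    sub <- ev[ev$run == r, ]
    p <- file.path(dir, sprintf("task_run-%02d_events.tsv", r))
    utils::write.table(
      data.frame(onset = sub$onset, duration = sub$duration,
                 trial_type = paste(sub$condition, sub$colour, sep = "_")),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  side <- file.path(dir, "subject.json")
  jsonlite::write_json(
    list(trS = subject@trS, seed = subject@seed,
         truth = subjectTruth(subject)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read a BIDS-style events TSV
#'
#' Parses an events table with `onset`, `duration` and `trial_type`
#' columns; `trial_type` values of the form `condition_colour` are split
#' back into the two label columns.
#'
#' @param path path to the TSV file.
#' @param run run index to record in the returned table.
#' @return data.frame with columns `run`, `condition`, `colour`, `onset`,
#'   `duration`.
#' @export
readEventsTsv <- function(path, run = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(tab)))
  parts <- strsplit(tab$trial_type, "_", fixed = TRUE)
  data.frame(run = run,
             condition = vapply(parts, `[`, "", 1),
             colour = vapply(parts, function(p)
               if (length(p) > 1) p[2] else NA_character_, ""),
             onset = tab$onset, duration = tab$duration,
             stringsAsFactors = FALSE)
}

#' Serialise an ROI to JSON (and back)
#'
#' Stores the region geometry, the member voxel indices with their
#' completion flags, and the r2 threshold used.
#'
#' @param roi an [ROI-class].
#' @param path output (input) JSON path.
#' @return `writeRoiJson` returns `path` invisibly; `readRoiJson` the
#'   reconstructed [ROI-class].
#' @export
writeRoiJson <- function(roi, path) {
  jsonlite::write_json(
    list(name = roi@name, region = roi@region,
         voxels = roi@voxels, completed = roi@completed,
         r2Threshold = roi@r2Threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiJson
#' @export
readRoiJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ROI", name = x$name, region = as.list(x$region),
      voxels = as.integer(x$voxels), completed = as.logical(x$completed),
      r2Threshold = as.numeric(x$r2Threshold))
}

#' Export a projection map as a NIfTI image
#'
#' Writes the pixel grid of a [ProjectionMap-class] as a 2-D NIfTI image
#' whose pixel size equals the grid spacing in degrees.
#'
#' @param map a [ProjectionMap-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeProjectionNifti <- function(map, path) {
  img <- RNifti::asNifti(projectionValues(map))
  RNifti::pixdim(img) <- rep(pixelSpacing(map@grid), 2)
  RNifti::writeNifti(img, path)
  invisible(path)
}
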