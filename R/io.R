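#' @include AllGenerics.R
NULL

#' Construct a LabelVolume
#'
#' @param labels 3-D array of integer label values (see [labelScheme()]).
#' @param spacing Voxel edge lengths in mm along each axis, all > 0.
#' @param patient,timePoint,rater Identifiers; `timePoint` must be one of
#'   [timePointLevels()] when given.
#' @return A [LabelVolume-class].
#' @export
LabelVolume <- function(labels, spacing = c(1, 1, 1),
                        patient = NA_character_, timePoint = NA_character_,
                        rater = NA_character_) {
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop("label map contains non-integer values")
    storage.mode(labels) <- "integer"
  }
  if (!is.na(timePoint)) timePoint <- match.arg(timePoint, timePointLevels())
  new("LabelVolume", labels = labels, spacing = as.numeric(spacing),
      patient = as.character(patient), timePoint = as.character(timePoint),
      rater = as.character(rater))
}

#' Read a segmentation label map from NIfTI
#'
#' Reads a 3-D integer-valued NIfTI image, extracts the voxel spacing from
#' the header, and validates the label values against [labelScheme()].
#' Non-integer data, 4-D images and unknown label values are errors.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param patient,timePoint,rater Identifiers attached to the result.
#' @return A [LabelVolume-class].
#' @seealso [writeLabelVolume()]
#' @export
readLabelVolume <- function(path, patient = NA_character_,
                            timePoint = NA_character_, rater = NA_character_) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D label map, got ", length(d), "-D image: ", path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  arr <- array(as.vector(img), dim = d)
  LabelVolume(arr, spacing = spacing, patient = patient,
              timePoint = timePoint, rater = rater)
}

#' Write a label map to NIfTI
#'
#' @param lv A [LabelVolume-class].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
writeLabelVolume <- function(lv, path) {
  stopifnot(is(lv, "LabelVolume"))
  img <- RNifti::asNifti(lv@labels)
  RNifti::pixdim(img) <- lv@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("labelData", "LabelVolume", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x, ...) x@spacing)

#' @describeIn accessors Physical volume of one voxel in mm^3.
#' @export
setMethod("voxelVolume", "LabelVolume", function(x, ...) prod(x@spacing))

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume %s / %s / %s: %s voxels at (%s) mm\n",
              object@patient, object@timePoint, object@rater,
              paste(dim(object@labels), collapse = "x"),
              paste(format(object@spacing), collapse = ", ")))
  tab <- table(factor(as.vector(object@labels), levels = .labelScheme,
                      labels = names(.labelScheme)))
  print(tab)
})

.recordCols <- c("patient", "time_point", "rater", "compartment", "volume_mm3")

.validateRecords <- function(df) {
  missing <- setdiff(.recordCols, names(df))
  if (length(missing))
    stop("volume table lacks column(s): ", paste(missing, collapse = ", "))
  badTp <- setdiff(unique(df$time_point), timePointLevels())
  if (length(badTp))
    stop("unknown time point(s): ", paste(badTp, collapse = ", "))
  badC <- setdiff(unique(df$compartment), compartmentLevels())
  if (length(badC))
    stop("unknown compartment(s): ", paste(badC, collapse = ", "))
  if (any(!is.finite(df$volume_mm3)) || any(df$volume_mm3 < 0))
    stop("volumes must be finite and >= 0")
  df
}

#' Read a long-format volume table
#'
#' Reads a CSV with columns `patient`, `time_point`, `rater`, `compartment`
#' and `volume_mm3` and validates every record (volumes >= 0, known time
#' points and compartments). Where a (patient, time point, rater) has
#' `EDEMA` and `NONENH` rows but no `NCE_T2` row, the merged non-enhancing
#' T2-hyperintense volume is synthesized as their sum.
#'
#' @param path Path to a CSV file.
#' @param synthesizeNCET2 Add missing `NCE_T2` rows from `EDEMA + NONENH`
#'   (default `TRUE`).
#' @return A `data.frame` of validated volume records.
#' @seealso [writeVolumeTable()]
#' @export
loadVolumeTable <- function(path, synthesizeNCET2 = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .validateRecords(df)
  if (synthesizeNCET2) df <- addMergedCompartment(df)
  df
}

#' Synthesize the merged NCE_T2 compartment
#'
#' Adds an `NCE_T2` record (edema + non-enhancing tumor) for every
#' (patient, time point, rater) that has both components but no `NCE_T2`
#' row yet. Existing `NCE_T2` rows are left untouched.
#'
#' @param records Volume record `data.frame` (see [loadVolumeTable()]).
#' @return The records with any derived `NCE_T2` rows appended.
#' @export
addMergedCompartment <- function(records) {
  key <- function(d) paste(d$patient, d$time_point, d$rater, sep = "\r")
  ed <- records[records$compartment == "EDEMA", ]
  ne <- records[records$compartment == "NONENH", ]
  have <- key(records[records$compartment == "NCE_T2", ])
  common <- setdiff(intersect(key(ed), key(ne)), have)
  if (!length(common)) return(records)
  ed <- ed[match(common, key(ed)), ]
  ne <- ne[match(common, key(ne)), ]
  derived <- ed
  derived$compartment <- "NCE_T2"
  derived$volume_mm3 <- ed$volume_mm3 + ne$volume_mm3
  out <- rbind(records, derived)
  rownames(out) <- NULL
  out
}

#' Write a long-format volume table
#'
#' @param records Volume record `data.frame`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeVolumeTable <- function(records, path) {
  .validateRecords(records)
  utils::write.csv(records[, .recordCols], path, row.names = FALSE)
  invisible(path)
}
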