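#' @import methods
NULL

#' Ordered time-point codes of the acquisition grid
#'
#' The seven-point longitudinal grid used throughout the package:
#' preoperative scan, immediate postoperative scan, and follow-up scans at
#' 1, 3, 6, 9 and 12 months after surgery. The ordinal rank of a code is its
#' position in this vector minus one, so `PRE` has rank 0.
#'
#' @return Character vector of the seven codes in temporal order.
#' @examples
#' timePointLevels()
#' @export
timePointLevels <- function() {
  c("PRE", "POST", "M1", "M3", "M6", "M9", "M12")
}

#' Tumor compartment codes
#'
#' The four base compartments of a glioma segmentation (necrosis, edema,
#' non-enhancing tumor, contrast-enhancing tumor) plus the merged
#' compartments used in the analysis: `NCE_T2` (edema + non-enhancing
#' tumor, the non-enhancing T2-hyperintense tissue), `CORE` (necrosis +
#' non-enhancing + enhancing) and `COMPLETE` (all four).
#'
#' @return Character vector of valid compartment codes.
#' @export
compartmentLevels <- function() {
  c("NECROSIS", "EDEMA", "NONENH", "CET", "NCE_T2", "CORE", "COMPLETE")
}

# integer label scheme for label maps: 0 background/unaffected (healthy
# subclasses collapse to 0), then the four tumor classes
.labelScheme <- c(
  BACKGROUND = 0L, NECROSIS = 1L, EDEMA = 2L, NONENH = 3L, CET = 4L
)

#' Integer label scheme for segmentation label maps
#'
#' Maps label-map integers to tissue classes: 0 = background/unaffected
#' (healthy tissue subclasses are collapsed), 1 = necrosis, 2 = edema,
#' 3 = non-enhancing tumor, 4 = contrast-enhancing tumor.
#'
#' @return Named integer vector.
#' @export
labelScheme <- function() .labelScheme

#' Label set of a compartment
#'
#' @param compartment A compartment code (see [compartmentLevels()]).
#' @return Integer vector of label values belonging to the compartment.
#' @examples
#' compartmentLabels("NCE_T2")  # edema + non-enhancing tumor
#' @export
compartmentLabels <- function(compartment) {
  compartment <- match.arg(compartment, compartmentLevels())
  switch(compartment,
    NECROSIS = 1L,
    EDEMA    = 2L,
    NONENH   = 3L,
    CET      = 4L,
    NCE_T2   = c(2L, 3L),
    CORE     = c(1L, 3L, 4L),
    COMPLETE = 1:4
  )
}

#' AcquisitionSchedule: per-patient presence over the time-point grid
#'
#' An S4 container recording which of the seven ordered time points each
#' patient of a cohort was scanned at. Every patient must have the
#' preoperative (`PRE`) acquisition. Transitions are counted between
#' consecutive *available* acquisitions, so a patient with `PRE`, `M1`,
#' `M3` contributes the two transitions PRE->M1 and M1->M3.
#'
#' @slot present Logical matrix, patients in rows (rownames are patient
#'   identifiers), the seven time points in columns, in grid order.
#' @seealso [loadSchedule()], [table1Schedule()], [countAcquisitions()]
#' @export
setClass("AcquisitionSchedule", representation(present = "matrix"))

setValidity("AcquisitionSchedule", function(object) {
  p <- object@present
  msgs <- character()
  if (!is.logical(p))
    msgs <- c(msgs, "'present' must be a logical matrix")
  if (!identical(colnames(p), timePointLevels()))
    msgs <- c(msgs, "'present' columns must be the seven time points in grid order")
  if (nrow(p) > 0) {
    if (is.null(rownames(p)) || anyDuplicated(rownames(p)))
      msgs <- c(msgs, "patient identifiers (rownames) must be unique and non-empty")
    if (any(is.na(p)))
      msgs <- c(msgs, "'present' must not contain NA")
    else if (!all(p[, "PRE"]))
      msgs <- c(msgs, "every patient must have the preoperative (PRE) acquisition")
  }
  if (length(msgs)) msgs else TRUE
})

#' LabelVolume: a 3-D segmentation label map with voxel spacing
#'
#' An S4 container for one rater's segmentation of one acquisition: a 3-D
#' array of small non-negative integer labels (see [labelScheme()]) plus
#' the voxel edge lengths in mm along each axis and the identifying
#' (patient, time point, rater) triple.
#'
#' @slot labels 3-D integer array of label values.
#' @slot spacing Numeric length-3, voxel edge lengths in mm, all > 0.
#' @slot patient,timePoint,rater Character identifiers.
#' @seealso [readLabelVolume()], [compartmentVolume()], [diceCoefficient()]
#' @export
setClass("LabelVolume", representation(
  labels = "array", spacing = "numeric",
  patient = "character", timePoint = "character", rater = "character"
))

setValidity("LabelVolume", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "'labels' must be a 3-D array")
  if (!is.integer(object@labels))
    msgs <- c(msgs, "'labels' must be integer-valued")
  else {
    bad <- setdiff(unique(as.vector(object@labels)), .labelScheme)
    if (length(bad))
      msgs <- c(msgs, paste0("label values outside the scheme {",
                             paste(.labelScheme, collapse = ","), "}: ",
                             paste(sort(bad), collapse = ", ")))
  }
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "'spacing' must be three positive finite values (mm)")
  if (length(msgs)) msgs else TRUE
})

#' TrajectorySet: one patient's per-rater volume curves
#'
#' An S4 container holding, for a single patient, every rater's compartment
#' volume at each of the patient's present time points. All raters share the
#' same ordered time-point list.
#'
#' @slot patient Character patient identifier.
#' @slot timePoints Character vector, the patient's present time points in
#'   grid order.
#' @slot volumes `data.frame` with columns `rater`, `compartment`,
#'   `timePoint`, `volume` (mm^3, >= 0); complete over
#'   raters x compartments x timePoints.
#' @seealso [buildTrajectories()], [volumeSeries()], [transitionStats()]
#' @export
setClass("TrajectorySet", representation(
  patient = "character", timePoints = "character", volumes = "data.frame"
))

setValidity("TrajectorySet", function(object) {
  msgs <- character()
  tps <- object@timePoints
  if (!all(tps %in% timePointLevels()) ||
      is.unsorted(match(tps, timePointLevels()), strictly = TRUE))
    msgs <- c(msgs, "'timePoints' must be distinct codes in grid order")
  v <- object@volumes
  need <- c("rater", "compartment", "timePoint", "volume")
  if (!all(need %in% names(v))) {
    msgs <- c(msgs, "'volumes' must have columns rater, compartment, timePoint, volume")
  } else {
    if (any(v$volume < 0, na.rm = TRUE))
      msgs <- c(msgs, "volumes must be >= 0")
    grid <- table(v$rater, v$compartment)
    if (nrow(v) && any(grid != length(tps)))
      msgs <- c(msgs, "every (rater, compartment) series must cover all time points exactly once")
  }
  if (length(msgs)) msgs else TRUE
})

#' DisagreementMatrix: cohort-level rater-by-rater disagreement totals
#'
#' A symmetric rater x rater grid. Each off-diagonal entry of `totals` is
#' the sum, over all patients and transitions where the two raters' volume
#' trends had opposite signs, of the absolute difference of their log10
#' volume ratios; `counts` holds the number of such disagreements.
#'
#' @slot compartment Compartment code the matrix was computed for.
#' @slot totals,counts Numeric matrices with rater dimnames; symmetric with
#'   zero diagonal.
#' @seealso [disagreementMatrix()], [detectDisagreements()]
#' @export
setClass("DisagreementMatrix", representation(
  compartment = "character", totals = "matrix", counts = "matrix"
))

setValidity("DisagreementMatrix", function(object) {
  msgs <- character()
  t <- object@totals; n <- object@counts
  if (!identical(dim(t), dim(n)) || !identical(dimnames(t), dimnames(n)))
    msgs <- c(msgs, "'totals' and 'counts' must share dimensions and rater names")
  if (nrow(t) != ncol(t))
    msgs <- c(msgs, "matrices must be square")
  else {
    if (!isTRUE(all.equal(t, base::t(t))) || !isTRUE(all.equal(n, base::t(n))))
      msgs <- c(msgs, "matrices must be symmetric")
    if (any(diag(t) != 0) || any(diag(n) != 0))
      msgs <- c(msgs, "diagonal must be zero")
    if (any(t < 0) || any(n < 0))
      msgs <- c(msgs, "entries must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})
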