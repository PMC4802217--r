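#' @include AllGenerics.R
NULL

#' Compartment volume of a label map
#'
#' Volume in mm^3: the number of voxels whose label belongs to the
#' compartment's label set (merged compartments allowed, see
#' [compartmentLabels()]) times the physical volume of one voxel. Computed
#' in the native grid of the label map; no resampling.
#'
#' @param lv A [LabelVolume-class].
#' @param compartment Compartment code (see [compartmentLevels()]).
#' @return Volume in mm^3.
#' @examples
#' arr <- array(0L, dim = c(5, 5, 5)); arr[1:4, 1, 1] <- 2L
#' compartmentVolume(LabelVolume(arr, spacing = c(1, 1, 3)), "EDEMA")
#' @export
compartmentVolume <- function(lv, compartment) {
  stopifnot(is(lv, "LabelVolume"))
  labs <- compartmentLabels(compartment)
  sum(lv@labels %in% labs) * prod(lv@spacing)
}

#' Volume records of a set of label maps
#'
#' Tabulates [compartmentVolume()] for each label map and compartment into
#' the long record format used by the rest of the pipeline.
#'
#' @param labelVolumes List of [LabelVolume-class] objects with patient,
#'   time point and rater identifiers set.
#' @param compartments Compartment codes to tabulate.
#' @return Volume record `data.frame` with columns `patient`, `time_point`,
#'   `rater`, `compartment`, `volume_mm3`.
#' @export
labelVolumesToRecords <- function(labelVolumes,
                                  compartments = compartmentLevels()) {
  rows <- lapply(labelVolumes, function(lv) {
    data.frame(patient = lv@patient, time_point = lv@timePoint,
               rater = lv@rater, compartment = compartments,
               volume_mm3 = vapply(compartments, compartmentVolume, 0, lv = lv),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build per-patient trajectory sets
#'
#' Groups validated volume records into one [TrajectorySet-class] per
#' patient, with each (rater, compartment) series ordered along the grid.
#' A record for an acquisition absent from the schedule, or a scheduled
#' acquisition lacking a record for some rater/compartment, is an error
#' naming the offending patient, time point and rater.
#'
#' @param records Volume record `data.frame` (see [loadVolumeTable()]).
#' @param schedule An [AcquisitionSchedule-class].
#' @param raters,compartments Raters and compartments to include; default
#'   all present in `records`.
#' @return Named list of [TrajectorySet-class], one per patient.
#' @export
buildTrajectories <- function(records, schedule,
                              raters = sort(unique(records$rater)),
                              compartments = sort(unique(records$compartment))) {
  stopifnot(is(schedule, "AcquisitionSchedule"))
  records <- .validateRecords(records)
  records <- records[records$rater %in% raters &
                     records$compartment %in% compartments, ]
  extraPat <- setdiff(unique(records$patient), patients(schedule))
  if (length(extraPat))
    stop("records for patient(s) absent from the schedule: ",
         paste(extraPat, collapse = ", "))
  pm <- presentMap(schedule)
  off <- !pm[cbind(match(records$patient, patients(schedule)),
                   match(records$time_point, colnames(pm)))]
  if (any(off)) {
    bad <- unique(paste0(records$patient[off], "/", records$time_point[off]))
    stop("records for acquisition(s) absent from the schedule: ",
         paste(bad, collapse = ", "))
  }
  out <- lapply(patients(schedule), function(p) {
    tps <- presentTimePoints(schedule, p)
    sub <- records[records$patient == p, ]
    grid <- expand.grid(rater = raters, compartment = compartments,
                        timePoint = tps, stringsAsFactors = FALSE)
    idx <- match(paste(grid$rater, grid$compartment, grid$timePoint),
                 paste(sub$rater, sub$compartment, sub$time_point))
    if (anyNA(idx)) {
      m <- grid[is.na(idx), ][1, ]
      stop(sprintf("missing record for patient %s, time point %s, rater %s, compartment %s",
                   p, m$timePoint, m$rater, m$compartment))
    }
    grid$volume <- sub$volume_mm3[idx]
    grid <- grid[order(match(grid$rater, raters),
                       match(grid$compartment, compartments),
                       match(grid$timePoint, timePointLevels())), ]
    rownames(grid) <- NULL
    new("TrajectorySet", patient = p, timePoints = tps, volumes = grid)
  })
  names(out) <- patients(schedule)
  out
}

#' @rdname accessors
#' @export
setMethod("patients", "TrajectorySet", function(x, ...) x@patient)

#' @rdname accessors
#' @export
setMethod("raters", "TrajectorySet", function(x, ...) unique(x@volumes$rater))

#' @rdname accessors
#' @export
setMethod("compartments", "TrajectorySet", function(x, ...)
  unique(x@volumes$compartment))

#' @rdname accessors
#' @export
setMethod("presentTimePoints", "TrajectorySet", function(x, ...) x@timePoints)

#' @describeIn accessors One rater's ordered volume series (named numeric,
#'   mm^3) for one compartment.
#' @param rater,compartment Identifiers selecting the series.
#' @export
setMethod("volumeSeries", "TrajectorySet", function(x, rater, compartment, ...) {
  sub <- x@volumes[x@volumes$rater == rater &
                   x@volumes$compartment == compartment, ]
  if (!nrow(sub))
    stop("no series for rater ", rater, ", compartment ", compartment)
  stats::setNames(sub$volume, sub$timePoint)[x@timePoints]
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet patient %s: %d time points (%s), raters %s, compartments %s\n",
              object@patient, length(object@timePoints),
              paste(object@timePoints, collapse = " "),
              paste(raters(object), collapse = ", "),
              paste(compartments(object), collapse = ", ")))
})

#' Preoperative-normalized trajectory
#'
#' Expresses one rater's compartment series relative to the same rater's
#' preoperative volume, so the curve starts at exactly 1. A zero
#' preoperative volume cannot be normalized: the series is refused with a
#' warning and `NULL` is returned rather than imputing.
#'
#' @param ts A [TrajectorySet-class].
#' @param rater,compartment Identifiers selecting the series.
#' @return `data.frame` with columns `timePoint` and `ratio`, or `NULL`
#'   when the preoperative volume is zero.
#' @export
relativeTrajectory <- function(ts, rater, compartment) {
  stopifnot(is(ts, "TrajectorySet"))
  v <- volumeSeries(ts, rater, compartment)
  if (names(v)[1] != "PRE" || v[["PRE"]] <= 0) {
    warning(sprintf("patient %s, rater %s, compartment %s: zero preoperative volume, series not normalizable",
                    ts@patient, rater, compartment))
    return(NULL)
  }
  data.frame(timePoint = names(v), ratio = unname(v / v[["PRE"]]),
             stringsAsFactors = FALSE)
}
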