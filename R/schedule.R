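#' @include AllGenerics.R
NULL

.truthy <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  x <- trimws(as.character(x))
  tolower(x) %in% c("true", "t", "1", "x", "yes", "y", "✓")
}

#' Construct an acquisition schedule
#'
#' @param present Logical matrix or data.frame with patient identifiers as
#'   rownames and time-point codes as column names. Columns may be any
#'   subset of [timePointLevels()] that includes `PRE`; missing columns are
#'   treated as absent acquisitions.
#' @return An [AcquisitionSchedule-class] object.
#' @examples
#' m <- cbind(PRE = c(TRUE, TRUE), M3 = c(TRUE, FALSE))
#' rownames(m) <- c("p1", "p2")
#' countAcquisitions(AcquisitionSchedule(m))
#' @export
AcquisitionSchedule <- function(present) {
  present <- as.matrix(present)
  tps <- timePointLevels()
  unknown <- setdiff(colnames(present), tps)
  if (length(unknown))
    stop("unknown time-point column(s): ", paste(unknown, collapse = ", "))
  if (!"PRE" %in% colnames(present))
    stop("schedule must have a PRE column")
  full <- matrix(FALSE, nrow(present), length(tps),
                 dimnames = list(rownames(present), tps))
  storage.mode(full) <- "logical"
  for (tp in colnames(present)) full[, tp] <- .truthy(present[, tp])
  new("AcquisitionSchedule", present = full)
}

#' Read an acquisition schedule from CSV
#'
#' Expects one row per patient with a `patient` column (or the first column
#' if unnamed) and one column per time point holding truthy/falsy cells
#' (logical, 0/1, or marks such as "x"; "-", "" and 0 mean absent). Unknown
#' time-point columns, a missing `PRE` column and duplicate patient
#' identifiers are hard errors.
#'
#' @param path Path to a CSV file with a header row.
#' @return An [AcquisitionSchedule-class].
#' @seealso [writeSchedule()], [table1Schedule()]
#' @export
loadSchedule <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- if ("patient" %in% names(df)) "patient" else names(df)[1]
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids))
    stop("duplicate patient identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, setdiff(names(df), idcol), drop = FALSE])
  rownames(m) <- ids
  AcquisitionSchedule(m)
}

#' Write an acquisition schedule to CSV
#'
#' Inverse of [loadSchedule()]: writes one row per patient with logical
#' presence flags, so write-then-read reproduces the presence map exactly.
#'
#' @param schedule An [AcquisitionSchedule-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "AcquisitionSchedule"))
  df <- data.frame(patient = patients(schedule),
                   schedule@present, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' The printed 14-patient study schedule
#'
#' The exact presence pattern of the 14-patient glioblastoma cohort the
#' analysis design is based on: every patient has a preoperative scan, and
#' column totals over the grid are 14, 12, 9, 13, 8, 4, 4 acquisitions for
#' PRE, POST, M1, M3, M6, M9, M12 — 64 acquisitions and 50 transitions in
#' total.
#'
#' @return An [AcquisitionSchedule-class] with patients `p01`..`p14`.
#' @examples
#' countAcquisitions(table1Schedule())
#' @export
table1Schedule <- function() {
  rows <- list(
    p01 = c("PRE", "POST", "M3"),
    p02 = c("PRE", "M1", "M3"),
    p03 = c("PRE", "POST", "M1", "M3"),
    p04 = c("PRE", "POST", "M1", "M3", "M6"),
    p05 = c("PRE", "POST", "M3", "M6", "M9", "M12"),
    p06 = c("PRE", "POST", "M3", "M6", "M9", "M12"),
    p07 = c("PRE", "POST", "M1", "M3", "M6"),
    p08 = c("PRE", "POST", "M3", "M6", "M12"),
    p09 = c("PRE", "POST", "M3", "M6", "M9", "M12"),
    p10 = c("PRE", "M1", "M3"),
    p11 = c("PRE", "POST", "M1"),
    p12 = c("PRE", "POST", "M1", "M3"),
    p13 = c("PRE", "POST", "M1", "M3", "M6"),
    p14 = c("PRE", "POST", "M1", "M3", "M6", "M9")
  )
  m <- t(vapply(rows, function(tp) timePointLevels() %in% tp,
                logical(length(timePointLevels()))))
  colnames(m) <- timePointLevels()
  AcquisitionSchedule(m)
}

#' Count acquisitions and transitions of a schedule
#'
#' A transition is a pair of consecutive *available* acquisitions for one
#' patient, so each patient contributes (number of present time points) - 1
#' transitions and cohort-wide `transitions = acquisitions - patients`.
#'
#' @param schedule An [AcquisitionSchedule-class].
#' @return Named numeric vector with elements `acquisitions` and
#'   `transitions`.
#' @export
countAcquisitions <- function(schedule) {
  stopifnot(is(schedule, "AcquisitionSchedule"))
  per <- rowSums(schedule@present)
  c(acquisitions = sum(per), transitions = sum(pmax(per - 1, 0)))
}

#' @rdname accessors
#' @export
setMethod("patients", "AcquisitionSchedule", function(x, ...) {
  if (nrow(x@present) == 0) character() else rownames(x@present)
})

#' @rdname accessors
#' @export
setMethod("presentMap", "AcquisitionSchedule", function(x, ...) x@present)

#' @describeIn accessors Present time points of one patient, in grid order.
#' @param patient Patient identifier.
#' @export
setMethod("presentTimePoints", "AcquisitionSchedule", function(x, patient, ...) {
  if (!patient %in% patients(x)) stop("unknown patient: ", patient)
  timePointLevels()[x@present[patient, ]]
})

setMethod("show", "AcquisitionSchedule", function(object) {
  n <- countAcquisitions(object)
  cat(sprintf("AcquisitionSchedule: %d patients, %d acquisitions, %d transitions\n",
              nrow(object@present), n[["acquisitions"]], n[["transitions"]]))
  if (nrow(object@present)) {
    cat("acquisitions per time point:\n")
    print(colSums(object@present))
  }
})
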