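#' @include AllGenerics.R
NULL

#' Per-transition slope signs and volume ratios
#'
#' For each rater and each pair of consecutive available time points of one
#' patient, measures the direction of volume change and its relative
#' magnitude. The slope sign is `sign(V(t[i+1]) - V(t[i]))`: negative and
#' positive slopes correspond to shrinking and growing volumes, zero to an
#' exactly stable volume. The relative change `delta_rel = V(t[i+1]) /
#' V(t[i])` is defined when the earlier volume is positive; its decimal
#' logarithm additionally needs the later volume positive. Undefined values
#' are `NA`. Only the order of time points matters: the sign is invariant
#' to any positive time denominator, so ordinal time (unit spacing) is
#' used.
#'
#' @param ts A [TrajectorySet-class] with at least 2 time points.
#' @param compartment Compartment code.
#' @param raters Raters to include (default all in `ts`).
#' @return `data.frame` with one row per rater per transition: `patient`,
#'   `from`, `to`, `rater`, `compartment`, `v_from`, `v_to`, `slope_sign`,
#'   `delta_rel`, `log10_delta_rel`.
#' @export
transitionStats <- function(ts, compartment, raters = NULL) {
  stopifnot(is(ts, "TrajectorySet"))
  if (length(ts@timePoints) < 2)
    return(.emptyTransitionStats())
  if (is.null(raters)) raters <- raters(ts)
  rows <- lapply(raters, function(r) {
    v <- volumeSeries(ts, r, compartment)
    n <- length(v)
    vFrom <- unname(v[-n]); vTo <- unname(v[-1])
    deltaRel <- ifelse(vFrom > 0, vTo / vFrom, NA_real_)
    data.frame(patient = ts@patient,
               from = names(v)[-n], to = names(v)[-1],
               rater = r, compartment = compartment,
               v_from = vFrom, v_to = vTo,
               slope_sign = sign(vTo - vFrom),
               delta_rel = deltaRel,
               log10_delta_rel = ifelse(!is.na(deltaRel) & vTo > 0,
                                        log10(deltaRel), NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyTransitionStats <- function() {
  data.frame(patient = character(), from = character(), to = character(),
             rater = character(), compartment = character(),
             v_from = numeric(), v_to = numeric(), slope_sign = numeric(),
             delta_rel = numeric(), log10_delta_rel = numeric(),
             stringsAsFactors = FALSE)
}

#' Transition statistics over a whole cohort
#'
#' Applies [transitionStats()] to every patient's trajectory for each
#' requested compartment. The default compartments are the two the
#' disagreement analysis is designed around: contrast-enhancing tumor and
#' merged non-enhancing T2-hyperintense tissue (necrosis is excluded by
#' default because it is usually completely resected).
#'
#' @param trajectories List of [TrajectorySet-class] (see
#'   [buildTrajectories()]).
#' @param compartments Compartment codes.
#' @return Row-bound `data.frame` of [transitionStats()] output.
#' @export
cohortTransitionStats <- function(trajectories,
                                  compartments = c("NCE_T2", "CET")) {
  rows <- lapply(trajectories, function(ts)
    do.call(rbind, lapply(compartments, function(comp)
      transitionStats(ts, comp))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(out)) .emptyTransitionStats() else out
}

.log10WithFloor <- function(vTo, vFrom, epsilon) {
  log10(pmax(vTo, epsilon) / pmax(vFrom, epsilon))
}

#' Detect slope-sign disagreements between rater pairs
#'
#' A disagreement is a transition on which one rater's slope sign is +1 and
#' the other's is -1 — the two raters' points lie on opposite sides of the
#' zero line of the disagreement plot. An exactly zero slope disagrees with
#' neither sign under the default `zeroSignPolicy = "neutral"` (only the
#' two strict signs are named by the definition); `"strict"` additionally
#' treats 0 vs a strict sign as a disagreement. The magnitude of a
#' disagreement is the absolute difference of the two raters' log10 volume
#' ratios. When a zero volume leaves a log undefined, the default
#' `zeroVolumePolicy = "epsilon"` floors both endpoint volumes at
#' `epsilon` (1 mm^3) before the ratio and flags the record;
#' `"exclude"` drops such records instead.
#'
#' @param stats Transition statistics from [transitionStats()] or
#'   [cohortTransitionStats()], covering identical transition lists for
#'   every rater (asserted).
#' @param raters Raters whose unordered pairs are compared (default all in
#'   `stats`).
#' @param zeroSignPolicy `"neutral"` (default) or `"strict"`.
#' @param zeroVolumePolicy `"epsilon"` (default) or `"exclude"`.
#' @param epsilon Volume floor in mm^3 for the epsilon policy.
#' @return `data.frame` with one row per disagreement: `patient`, `from`,
#'   `to`, `compartment`, `rater_a`, `rater_b`, `magnitude`, `flagged`
#'   (`TRUE` when the epsilon fallback was used).
#' @export
detectDisagreements <- function(stats, raters = sort(unique(stats$rater)),
                                zeroSignPolicy = c("neutral", "strict"),
                                zeroVolumePolicy = c("epsilon", "exclude"),
                                epsilon = 1) {
  zeroSignPolicy <- match.arg(zeroSignPolicy)
  zeroVolumePolicy <- match.arg(zeroVolumePolicy)
  out <- list()
  if (length(raters) >= 2) {
    for (i in seq_len(length(raters) - 1)) for (j in seq(i + 1, length(raters))) {
      a <- stats[stats$rater == raters[i], ]
      b <- stats[stats$rater == raters[j], ]
      ka <- paste(a$patient, a$from, a$to, a$compartment)
      kb <- paste(b$patient, b$from, b$to, b$compartment)
      if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb))
        stop("raters ", raters[i], " and ", raters[j],
             " do not cover identical transition lists")
      b <- b[match(ka, kb), ]
      dis <- if (zeroSignPolicy == "neutral")
        a$slope_sign * b$slope_sign == -1
      else
        a$slope_sign != b$slope_sign
      if (!any(dis)) next
      a <- a[dis, ]; b <- b[dis, ]
      logA <- a$log10_delta_rel
      logB <- b$log10_delta_rel
      flagged <- is.na(logA) | is.na(logB)
      if (zeroVolumePolicy == "epsilon") {
        logA[is.na(logA)] <- .log10WithFloor(a$v_to, a$v_from, epsilon)[is.na(logA)]
        logB[is.na(logB)] <- .log10WithFloor(b$v_to, b$v_from, epsilon)[is.na(logB)]
      }
      rec <- data.frame(patient = a$patient, from = a$from, to = a$to,
                        compartment = a$compartment,
                        rater_a = raters[i], rater_b = raters[j],
                        magnitude = abs(logA - logB), flagged = flagged,
                        stringsAsFactors = FALSE)
      if (zeroVolumePolicy == "exclude") rec <- rec[!flagged, ]
      out[[length(out) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(patient = character(), from = character(),
                      to = character(), compartment = character(),
                      rater_a = character(), rater_b = character(),
                      magnitude = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort-level disagreement matrix
#'
#' Sums disagreement magnitudes (and counts) over all patients and
#' transitions into a symmetric rater x rater grid with zero diagonal.
#' Each off-diagonal total is the sum of the absolute log10-ratio
#' differences of every disagreement between the two raters.
#'
#' @param records Disagreement records from [detectDisagreements()].
#' @param raters Ordered rater list defining the matrix dimensions.
#' @param compartment Compartment to restrict to (one code), or `NULL` to
#'   use all records.
#' @return A [DisagreementMatrix-class].
#' @export
disagreementMatrix <- function(records, raters, compartment = NULL) {
  if (!is.null(compartment))
    records <- records[records$compartment == compartment, ]
  totals <- counts <- matrix(0, length(raters), length(raters),
                             dimnames = list(raters, raters))
  if (nrow(records)) {
    for (k in seq_len(nrow(records))) {
      i <- records$rater_a[k]; j <- records$rater_b[k]
      totals[i, j] <- totals[i, j] + records$magnitude[k]
      totals[j, i] <- totals[i, j]
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[i, j]
    }
  }
  new("DisagreementMatrix",
      compartment = if (is.null(compartment)) "ALL" else compartment,
      totals = totals, counts = counts)
}

#' @rdname accessors
#' @export
setMethod("disagreementTotals", "DisagreementMatrix", function(x, ...) x@totals)

#' @rdname accessors
#' @export
setMethod("disagreementCounts", "DisagreementMatrix", function(x, ...) x@counts)

#' @rdname accessors
#' @export
setMethod("raters", "DisagreementMatrix", function(x, ...) rownames(x@totals))

#' @rdname accessors
#' @export
setMethod("compartments", "DisagreementMatrix", function(x, ...) x@compartment)

setMethod("show", "DisagreementMatrix", function(object) {
  cat(sprintf("DisagreementMatrix (%s): total summed magnitudes\n",
              object@compartment))
  print(round(object@totals, 3))
  cat("counts:\n")
  print(object@counts)
})

#' Per-pair disagreement counts and frequencies
#'
#' Counts disagreements per rater pair and compartment and expresses them
#' as a fraction of the cohort's transitions (e.g. 11 disagreements over 50
#' transitions is 22%).
#'
#' @param records Disagreement records from [detectDisagreements()].
#' @param nTransitions Total transition count of the cohort, e.g.
#'   `countAcquisitions(schedule)[["transitions"]]`. Zero transitions
#'   leaves the fraction undefined (`NA`).
#' @param raters Ordered rater list (default all in `records`).
#' @param compartments Compartments to report (default those in `records`).
#' @return `data.frame` with columns `compartment`, `rater_a`, `rater_b`,
#'   `count`, `fraction`, `percent`.
#' @export
disagreementFrequencies <- function(records, nTransitions,
                                    raters = sort(unique(c(records$rater_a, records$rater_b))),
                                    compartments = sort(unique(records$compartment))) {
  grid <- expand.grid(a = seq_along(raters), b = seq_along(raters),
                      compartment = compartments, stringsAsFactors = FALSE)
  grid <- grid[grid$a < grid$b, ]
  out <- data.frame(compartment = grid$compartment,
                    rater_a = raters[grid$a], rater_b = raters[grid$b],
                    stringsAsFactors = FALSE)
  out$count <- mapply(function(a, b, comp) {
    sum((records$rater_a == a & records$rater_b == b |
         records$rater_a == b & records$rater_b == a) &
        records$compartment == comp)
  }, out$rater_a, out$rater_b, out$compartment)
  out$fraction <- if (nTransitions > 0) out$count / nTransitions else NA_real_
  out$percent <- 100 * out$fraction
  rownames(out) <- NULL
  out
}

#' Transitions where an outlier rater disagrees with a consensus pair
#'
#' Counts, per compartment, the transitions on which two designated raters
#' agree with each other (no slope-sign disagreement between them) while a
#' third rater disagrees with both — e.g. two human raters agreeing on the
#' trend while an automatic method contradicts them.
#'
#' @param records Disagreement records from [detectDisagreements()] run
#'   over all three raters.
#' @param consensus Character vector of the two consensus raters.
#' @param outlier The third rater.
#' @return `data.frame` with columns `compartment` and `count`.
#' @export
consensusOutlierCount <- function(records, consensus, outlier) {
  stopifnot(length(consensus) == 2, length(outlier) == 1)
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  recKey <- paste(records$patient, records$from, records$to,
                  records$compartment)
  pk <- pairKey(records$rater_a, records$rater_b)
  ccKey <- pairKey(consensus[1], consensus[2])
  o1Key <- pairKey(outlier, consensus[1])
  o2Key <- pairKey(outlier, consensus[2])
  comps <- sort(unique(records$compartment))
  count <- vapply(comps, function(comp) {
    inComp <- records$compartment == comp
    both <- intersect(recKey[inComp & pk == o1Key], recKey[inComp & pk == o2Key])
    length(setdiff(both, recKey[inComp & pk == ccKey]))
  }, 0L)
  data.frame(compartment = comps, count = unname(count),
             stringsAsFactors = FALSE)
}

#' Long-format disagreement-plot data
#'
#' The per-patient scatter underlying the disagreement plot: one point per
#' rater per transition at the decimal logarithm of the volume ratio
#' between consecutive time points. The zero line corresponds to a stable
#' volume; raters on opposite sides of it disagree. Undefined logarithms
#' (a zero endpoint volume) are emitted as missing with a reason code.
#'
#' @param ts A [TrajectorySet-class].
#' @param compartment Compartment code.
#' @return `data.frame` with columns `patient`, `transition` (label
#'   "from->to"), `from`, `to`, `rater`, `compartment`, `log10_delta_rel`,
#'   `reason` (`"ok"`, `"zero_baseline"` or `"zero_followup"`).
#' @export
disagreementPlotData <- function(ts, compartment) {
  st <- transitionStats(ts, compartment)
  reason <- ifelse(!is.na(st$log10_delta_rel), "ok",
                   ifelse(st$v_from <= 0, "zero_baseline", "zero_followup"))
  data.frame(patient = st$patient,
             transition = paste0(st$from, "->", st$to),
             from = st$from, to = st$to, rater = st$rater,
             compartment = st$compartment,
             log10_delta_rel = st$log10_delta_rel,
             reason = reason, stringsAsFactors = FALSE)
}
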