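#' @include AllGenerics.R
NULL

.sameGrid <- function(a, b) {
  identical(dim(a@labels), dim(b@labels)) &&
    isTRUE(all.equal(a@spacing, b@spacing, tolerance = 1e-8))
}

#' Dice overlap between two raters' segmentations, with small-volume gating
#'
#' Computes the Dice coefficient `2|A\\&B| / (|A| + |B|)` on the voxel sets
#' of a compartment in two label maps sharing the same grid. Small volumes
#' make the coefficient unstable, so the comparison is excluded when a
#' rater's compartment volume falls below `minVolume` (90 mm^3 by
#' default): with `rule = "either"` one small volume suffices for
#' exclusion, with `"both"` both must be small. The gate compares physical
#' volume (mm^3), not voxel count, so mixed 1x1x1 and 1x1x3 mm grids are
#' treated consistently. When both volumes pass the gate the value is
#' computed even if the overlap is empty (Dice 0).
#'
#' @param a,b [LabelVolume-class] objects on an identical grid (asserted,
#'   not corrected).
#' @param compartment Compartment code.
#' @param minVolume Exclusion gate in mm^3 (default 90).
#' @param rule `"either"` (default) or `"both"`: whose volume below the
#'   gate triggers exclusion.
#' @return One-row `data.frame` with columns `patient`, `time_point`,
#'   `rater_a`, `rater_b`, `compartment`, `dice` (`NA` when excluded),
#'   `vol_a`, `vol_b`, `excluded`.
#' @examples
#' arr <- array(0L, c(10, 10, 10)); arr[3:7, 3:7, 3:7] <- 4L
#' lv <- LabelVolume(arr, rater = "R1")
#' diceCoefficient(lv, lv, "CET")$dice  # identical masks: 1
#' @export
diceCoefficient <- function(a, b, compartment, minVolume = 90,
                            rule = c("either", "both")) {
  stopifnot(is(a, "LabelVolume"), is(b, "LabelVolume"))
  rule <- match.arg(rule)
  if (!.sameGrid(a, b))
    stop("label maps are not on the same grid (shape and spacing must match)")
  labs <- compartmentLabels(compartment)
  inA <- a@labels %in% labs
  inB <- b@labels %in% labs
  vv <- prod(a@spacing)
  volA <- sum(inA) * vv
  volB <- sum(inB) * vv
  small <- c(volA, volB) < minVolume
  excluded <- if (rule == "either") any(small) else all(small)
  dice <- if (excluded) NA_real_ else if (volA + volB == 0) NA_real_ else
    2 * sum(inA & inB) / (sum(inA) + sum(inB))
  data.frame(patient = a@patient, time_point = a@timePoint,
             rater_a = a@rater, rater_b = b@rater,
             compartment = compartment, dice = dice,
             vol_a = volA, vol_b = volB, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Pairwise Dice over a set of label maps
#'
#' Applies [diceCoefficient()] to every unordered rater pair at every
#' (patient, time point) where both raters have a label map.
#'
#' @param labelVolumes List of [LabelVolume-class] with identifiers set.
#' @param compartments Compartment codes (default the two analysis
#'   compartments, contrast-enhancing tumor and merged non-enhancing
#'   T2-hyperintense tissue).
#' @inheritParams diceCoefficient
#' @return `data.frame` of [diceCoefficient()] rows.
#' @export
pairwiseDice <- function(labelVolumes, compartments = c("NCE_T2", "CET"),
                         minVolume = 90, rule = c("either", "both")) {
  rule <- match.arg(rule)
  key <- vapply(labelVolumes, function(lv) paste(lv@patient, lv@timePoint), "")
  rows <- list()
  for (k in unique(key)) {
    lvs <- labelVolumes[key == k]
    rs <- order(vapply(lvs, function(lv) lv@rater, ""))
    lvs <- lvs[rs]
    if (length(lvs) < 2) next
    for (i in seq_len(length(lvs) - 1)) for (j in seq(i + 1, length(lvs)))
      for (comp in compartments)
        rows[[length(rows) + 1L]] <-
          diceCoefficient(lvs[[i]], lvs[[j]], comp, minVolume, rule)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize Dice results as (median, range) tuples
#'
#' Groups Dice results by time point, rater pair and compartment and
#' reports the median and the range (max - min, a single number) over the
#' included patients. Excluded (gated) results are dropped from `n`; an
#' empty group keeps its row with `n = 0` and `NA` summaries.
#'
#' @param results `data.frame` from [pairwiseDice()]/[diceCoefficient()].
#' @return `data.frame` with columns `time_point`, `rater_a`, `rater_b`,
#'   `compartment`, `median`, `range`, `n`, `n_scheduled` (group size
#'   before gating).
#' @export
summarizeDice <- function(results) {
  g <- interaction(results$time_point, results$rater_a, results$rater_b,
                   results$compartment, drop = TRUE)
  rows <- lapply(split(results, g), function(d) {
    inc <- d$dice[!d$excluded & !is.na(d$dice)]
    data.frame(time_point = d$time_point[1], rater_a = d$rater_a[1],
               rater_b = d$rater_b[1], compartment = d$compartment[1],
               median = if (length(inc)) stats::median(inc) else NA_real_,
               range = if (length(inc)) max(inc) - min(inc) else NA_real_,
               n = length(inc), n_scheduled = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$time_point, timePointLevels()),
                   out$compartment, out$rater_a, out$rater_b), ]
  rownames(out) <- NULL
  out
}

.consecutiveDiffs <- function(records, rater, compartment) {
  sub <- records[records$rater == rater &
                 records$compartment == compartment, ]
  rows <- lapply(split(sub, sub$patient), function(d) {
    d <- d[order(match(d$time_point, timePointLevels())), ]
    if (nrow(d) < 2) return(NULL)
    data.frame(patient = d$patient[1],
               from = d$time_point[-nrow(d)], to = d$time_point[-1],
               compartment = compartment,
               diff = diff(d$volume_mm3), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation between two raters' volumes or volume differences
#'
#' In `"volume"` mode, pairs the two raters' absolute volumes at every
#' shared (patient, time point, compartment). In `"difference"` mode, pairs
#' the volume changes `V(t[i+1]) - V(t[i])` over each rater's own
#' consecutive available transitions. Compartments are pooled by default
#' (pass one compartment to restrict). The p-value uses the standard t
#' transform with n - 2 degrees of freedom, two-sided; it is reported,
#' never used for gating.
#'
#' @param records Volume record `data.frame`.
#' @param raterX,raterY The two raters.
#' @param compartments Compartments pooled into the scatter (default the
#'   two analysis compartments).
#' @param mode `"volume"` or `"difference"`.
#' @return List with `r`, `p`, `n`, `mode`, `compartments`. Fewer than 3
#'   pairs is an error; zero variance in either vector yields `r = NA`
#'   with `degenerate = TRUE`.
#' @export
volumeCorrelation <- function(records, raterX, raterY,
                              compartments = c("NCE_T2", "CET"),
                              mode = c("volume", "difference")) {
  mode <- match.arg(mode)
  records <- records[records$compartment %in% compartments, ]
  if (mode == "volume") {
    x <- records[records$rater == raterX, ]
    y <- records[records$rater == raterY, ]
    kx <- paste(x$patient, x$time_point, x$compartment)
    ky <- paste(y$patient, y$time_point, y$compartment)
    common <- intersect(kx, ky)
    xv <- x$volume_mm3[match(common, kx)]
    yv <- y$volume_mm3[match(common, ky)]
  } else {
    pair <- lapply(compartments, function(comp) {
      dx <- .consecutiveDiffs(records, raterX, comp)
      dy <- .consecutiveDiffs(records, raterY, comp)
      if (is.null(dx) || is.null(dy)) return(NULL)
      kx <- paste(dx$patient, dx$from, dx$to)
      ky <- paste(dy$patient, dy$from, dy$to)
      common <- intersect(kx, ky)
      cbind(dx$diff[match(common, kx)], dy$diff[match(common, ky)])
    })
    m <- do.call(rbind, pair)
    xv <- m[, 1]; yv <- m[, 2]
  }
  n <- length(xv)
  if (n < 3) stop("need at least 3 pairs, got ", n)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, mode = mode,
                compartments = compartments, degenerate = TRUE))
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, mode = mode,
       compartments = compartments, degenerate = FALSE)
}

#' Median relative over- or underestimation between two raters
#'
#' The median, over patients with the given acquisition, of the ratio of
#' one rater's volume to another's for one compartment at one time point.
#' A value above 1 means the numerator rater segments larger. Patients
#' whose denominator volume is zero cannot contribute a ratio and are
#' excluded, with the exclusion count reported.
#'
#' @param records Volume record `data.frame`.
#' @param raterNum,raterDen Numerator and denominator raters.
#' @param compartment Compartment code.
#' @param timePoint Time-point code.
#' @return List with `ratio` (median, `NA` if no patient has a positive
#'   denominator), `n` (patients included) and `nExcluded`.
#' @export
estimationRatio <- function(records, raterNum, raterDen, compartment,
                            timePoint) {
  sub <- records[records$compartment == compartment &
                 records$time_point == timePoint, ]
  num <- sub[sub$rater == raterNum, ]
  den <- sub[sub$rater == raterDen, ]
  common <- intersect(num$patient, den$patient)
  nv <- num$volume_mm3[match(common, num$patient)]
  dv <- den$volume_mm3[match(common, den$patient)]
  ok <- dv > 0
  list(ratio = if (any(ok)) stats::median(nv[ok] / dv[ok]) else NA_real_,
       n = sum(ok), nExcluded = sum(!ok))
}

#' Estimation-ratio table over pairs, compartments and time points
#'
#' Tabulates [estimationRatio()] for every ordered rater pair at every
#' time point with data.
#'
#' @param records Volume record `data.frame`.
#' @param raters Raters to compare (ordered pairs of distinct raters).
#' @param compartments Compartment codes.
#' @return `data.frame` with columns `rater_num`, `rater_den`,
#'   `compartment`, `time_point`, `ratio`, `n`, `n_excluded`.
#' @export
estimationRatioTable <- function(records, raters = sort(unique(records$rater)),
                                 compartments = c("NCE_T2", "CET")) {
  tps <- intersect(timePointLevels(), unique(records$time_point))
  grid <- expand.grid(rater_num = raters, rater_den = raters,
                      compartment = compartments, time_point = tps,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$rater_num != grid$rater_den, ]
  res <- Map(function(rn, rd, comp, tp) estimationRatio(records, rn, rd, comp, tp),
             grid$rater_num, grid$rater_den, grid$compartment, grid$time_point)
  grid$ratio <- vapply(res, `[[`, 0, "ratio")
  grid$n <- vapply(res, `[[`, 0, "n")
  grid$n_excluded <- vapply(res, `[[`, 0, "nExcluded")
  rownames(grid) <- NULL
  grid
}
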