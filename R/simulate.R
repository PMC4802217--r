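#' @include AllGenerics.R
NULL

# default generative parameters per base compartment, on the scale the
# model draws from: preoperative volume is lognormal (log10 mm^3), the
# immediate postoperative volume is PRE times a lognormal residual
# fraction (median `residualMedian`, natural-log sd `residualLogSd`), and
# each later transition multiplies by exp(N(0, growthLogSd)).
.defaultCompartmentModel <- function() {
  data.frame(
    compartment    = c("NECROSIS", "EDEMA", "NONENH", "CET"),
    log10PreMean   = c(3.9, 4.8, 4.0, 4.3),
    log10PreSd     = c(0.4, 0.35, 0.4, 0.4),
    residualMedian = c(0.05, 0.6, 0.5, 0.08),
    residualLogSd  = c(0.5, 0.3, 0.3, 0.6),
    growthLogSd    = c(0.25, 0.2, 0.25, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic glioblastoma cohort generator. The defaults
#' emulate the structure of the 14-patient study cohort: every patient has
#' a preoperative scan; each follow-up is present with the marginal
#' frequency of the printed schedule (or `schedule = "table1"` reproduces
#' that exact presence pattern); preoperative volumes are lognormal on a
#' scale typical of newly diagnosed glioblastoma; surgery drops each
#' compartment to a lognormal residual fraction of its preoperative volume
#' at the immediate postoperative scan; later follow-ups evolve by
#' multiplicative lognormal drift.
#'
#' @param nPatients Number of patients (>= 1). Ignored for
#'   `schedule = "table1"` (fixed at 14).
#' @param schedule `"table1"` (the printed 14-patient pattern) or
#'   `"random"` (presence drawn per follow-up from `followupProb`).
#' @param followupProb Named probabilities in \[0, 1\] that each follow-up
#'   acquisition is present; `PRE` is always present. Defaults are the
#'   printed schedule's marginal frequencies (12/14, 9/14, 13/14, 8/14,
#'   4/14, 4/14).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   cohorts.
#' @param compartmentModel `data.frame` of per-compartment generative
#'   parameters (columns `compartment`, `log10PreMean`, `log10PreSd`,
#'   `residualMedian`, `residualLogSd`, `growthLogSd`).
#' @return Object of class `CohortConfig` (a validated list).
#' @seealso [simulateCohort()], [raterPreset()]
#' @export
cohortConfig <- function(nPatients = 14,
                         schedule = c("table1", "random"),
                         followupProb = c(POST = 12 / 14, M1 = 9 / 14,
                                          M3 = 13 / 14, M6 = 8 / 14,
                                          M9 = 4 / 14, M12 = 4 / 14),
                         seed = 1L,
                         compartmentModel = .defaultCompartmentModel()) {
  schedule <- match.arg(schedule)
  stopifnot(nPatients >= 1, all(followupProb >= 0), all(followupProb <= 1),
            setequal(names(followupProb), setdiff(timePointLevels(), "PRE")),
            all(compartmentModel$log10PreSd >= 0),
            all(compartmentModel$residualLogSd >= 0),
            all(compartmentModel$growthLogSd >= 0),
            all(compartmentModel$residualMedian > 0))
  structure(list(nPatients = as.integer(nPatients), schedule = schedule,
                 followupProb = followupProb, seed = as.integer(seed),
                 compartmentModel = compartmentModel),
            class = "CohortConfig")
}

#' Rater observation model
#'
#' How a rater (human or automatic) observes a latent tumor volume: the
#' observation is `V * bias * exp(N(0, noiseLogSd))`, floored to 0 when it
#' falls below the rater's detection threshold. Bias can be a single
#' factor, a per-compartment named vector, or a compartment x time-point
#' matrix (rows named by compartment, columns by time point) for tendencies
#' such as a systematic postoperative overestimation.
#'
#' @param name Rater identifier.
#' @param bias Multiplicative bias (> 0): scalar, named vector, or matrix.
#' @param noiseLogSd Natural-log sd of the lognormal measurement noise
#'   (>= 0).
#' @param detectionThreshold Volume in mm^3 below which the rater reports 0
#'   (>= 0).
#' @return Object of class `RaterModel` (a validated list).
#' @export
raterModel <- function(name, bias = 1, noiseLogSd = 0, detectionThreshold = 0) {
  stopifnot(is.character(name), length(name) == 1,
            all(bias > 0), noiseLogSd >= 0, detectionThreshold >= 0)
  structure(list(name = name, bias = bias, noiseLogSd = noiseLogSd,
                 detectionThreshold = detectionThreshold),
            class = "RaterModel")
}

.biasFactor <- function(model, compartment, timePoint) {
  b <- model$bias
  if (is.matrix(b)) {
    out <- 1
    if (compartment %in% rownames(b) && timePoint %in% colnames(b))
      out <- b[compartment, timePoint]
    out
  } else if (!is.null(names(b))) {
    if (compartment %in% names(b)) unname(b[compartment]) else 1
  } else b
}

#' Preset rater models
#'
#' Three observation models mirroring the tendency structure of the study
#' raters:
#' `"R1"` — an unbiased experienced rater; `"R2"` — a rater segmenting
#' contrast-enhancing tumor more aggressively (CET bias above 1); `"B"` —
#' an automatic method that overestimates the non-enhancing
#' T2-hyperintense components at every postoperative time point, grossly
#' overestimates residual contrast-enhancing tumor on the immediate
#' postoperative scan, and has no detection floor (it rarely reports a
#' volume of exactly zero, unlike the human raters).
#'
#' @param which `"R1"`, `"R2"` or `"B"`.
#' @param noiseLogSd Measurement noise shared by the presets (default
#'   0.15).
#' @return A [raterModel()].
#' @export
raterPreset <- function(which = c("R1", "R2", "B"), noiseLogSd = 0.15) {
  which <- match.arg(which)
  tps <- timePointLevels()
  post <- setdiff(tps, "PRE")
  switch(which,
    R1 = raterModel("R1", bias = 1, noiseLogSd = noiseLogSd,
                    detectionThreshold = 50),
    R2 = raterModel("R2", bias = c(CET = 1.4), noiseLogSd = noiseLogSd,
                    detectionThreshold = 50),
    B = {
      b <- matrix(1, nrow = 4, ncol = length(tps),
                  dimnames = list(c("NECROSIS", "EDEMA", "NONENH", "CET"), tps))
      b[c("EDEMA", "NONENH"), post] <- 1.4
      b["CET", "PRE"] <- 1.3
      b["CET", "POST"] <- 6
      b["CET", setdiff(post, "POST")] <- 1.2
      raterModel("B", bias = b, noiseLogSd = noiseLogSd,
                 detectionThreshold = 0)
    })
}

.simulateSchedule <- function(cfg) {
  if (cfg$schedule == "table1") return(table1Schedule())
  tps <- timePointLevels()
  m <- matrix(FALSE, cfg$nPatients, length(tps),
              dimnames = list(sprintf("p%02d", seq_len(cfg$nPatients)), tps))
  m[, "PRE"] <- TRUE
  for (tp in setdiff(tps, "PRE"))
    m[, tp] <- stats::runif(cfg$nPatients) < cfg$followupProb[[tp]]
  AcquisitionSchedule(m)
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates an acquisition schedule, a latent (true) volume trajectory per
#' patient and base compartment, and each rater's observed volume records.
#' The latent trajectory is generated over the full seven-point grid
#' (surgery happens whether or not the immediate postoperative scan is
#' acquired) and then subset to the present acquisitions. Edema and
#' non-enhancing tumor are generated separately and the merged `NCE_T2`
#' record is their sum, so its additivity holds by construction for both
#' the latent and every observed table. Deterministic given the seed.
#'
#' @param cfg A [cohortConfig()].
#' @param raterModels List of [raterModel()] objects (default the three
#'   presets).
#' @param seed Overrides `cfg$seed` when given.
#' @return List with elements `schedule` ([AcquisitionSchedule-class]),
#'   `records` (observed volume record `data.frame` over all raters) and
#'   `latent` (the true trajectories, rater `".latent"`).
#' @examples
#' sim <- simulateCohort(cohortConfig(seed = 7))
#' countAcquisitions(sim$schedule)
#' @export
simulateCohort <- function(cfg = cohortConfig(),
                           raterModels = list(raterPreset("B"),
                                              raterPreset("R1"),
                                              raterPreset("R2")),
                           seed = NULL) {
  stopifnot(inherits(cfg, "CohortConfig"),
            all(vapply(raterModels, inherits, TRUE, "RaterModel")))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  schedule <- .simulateSchedule(cfg)
  tps <- timePointLevels()
  cm <- cfg$compartmentModel
  latentRows <- list()
  obsRows <- list()
  for (p in patients(schedule)) {
    for (k in seq_len(nrow(cm))) {
      comp <- cm$compartment[k]
      v <- numeric(length(tps))
      v[1] <- 10^stats::rnorm(1, cm$log10PreMean[k], cm$log10PreSd[k])
      v[2] <- v[1] * cm$residualMedian[k] *
        exp(stats::rnorm(1, 0, cm$residualLogSd[k]))
      for (t in 3:length(tps))
        v[t] <- v[t - 1] * exp(stats::rnorm(1, 0, cm$growthLogSd[k]))
      present <- presentMap(schedule)[p, ]
      latentRows[[length(latentRows) + 1L]] <-
        data.frame(patient = p, time_point = tps[present], rater = ".latent",
                   compartment = comp, volume_mm3 = v[present],
                   stringsAsFactors = FALSE)
      for (rm in raterModels) {
        noise <- exp(stats::rnorm(length(tps), 0, rm$noiseLogSd))
        bias <- vapply(tps, function(tp) .biasFactor(rm, comp, tp), 0)
        obs <- v * bias * noise
        obs[obs < rm$detectionThreshold] <- 0
        obsRows[[length(obsRows) + 1L]] <-
          data.frame(patient = p, time_point = tps[present], rater = rm$name,
                     compartment = comp, volume_mm3 = obs[present],
                     stringsAsFactors = FALSE)
      }
    }
  }
  latent <- addMergedCompartment(do.call(rbind, latentRows))
  records <- addMergedCompartment(do.call(rbind, obsRows))
  rownames(latent) <- rownames(records) <- NULL
  list(schedule = schedule, records = records, latent = latent)
}

#' Simulate per-rater phantom label maps for one acquisition
#'
#' Builds a nested spherical phantom — necrosis core, contrast-enhancing
#' rim, non-enhancing band, edema halo — whose per-compartment voxel counts
#' times the voxel volume approximate the requested volumes to within the
#' discretized boundary shell. Shell radii are derived from the cumulative
#' requested volumes, so a requested volume of 0 yields an empty shell.
#' Per-rater variants perturb the shell radii multiplicatively by
#' `exp(N(0, jitter))`, so the Dice overlap between raters is controllable:
#' zero jitter gives identical maps (Dice 1 for every compartment).
#'
#' @param volumes Named numeric, requested volumes in mm^3 for
#'   `NECROSIS`, `CET`, `NONENH`, `EDEMA` (missing names default to 0).
#' @param gridDim Integer length-3 array dimensions.
#' @param spacing Voxel edge lengths in mm.
#' @param raterJitter Named numeric of per-rater radial jitter sds (natural
#'   log scale); names become the rater identifiers.
#' @param patient,timePoint Identifiers attached to the maps.
#' @param seed Optional integer seed for the jitter draws.
#' @return Named list of [LabelVolume-class], one per rater.
#' @examples
#' maps <- simulateLabelMaps(c(CET = 4000, EDEMA = 20000),
#'                           raterJitter = c(R1 = 0, R2 = 0))
#' diceCoefficient(maps$R1, maps$R2, "CET")$dice  # identical: 1
#' @export
simulateLabelMaps <- function(volumes, gridDim = c(48, 48, 48),
                              spacing = c(1, 1, 1),
                              raterJitter = c(R1 = 0),
                              patient = NA_character_,
                              timePoint = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  want <- c(NECROSIS = 0, CET = 0, NONENH = 0, EDEMA = 0)
  stopifnot(all(names(volumes) %in% names(want)), all(volumes >= 0))
  want[names(volumes)] <- volumes
  # inside-out shell order and their label codes
  shellOrder <- c("NECROSIS", "CET", "NONENH", "EDEMA")
  shellLabel <- c(1L, 4L, 3L, 2L)
  radii <- (3 * cumsum(want[shellOrder]) / (4 * pi))^(1 / 3)
  extent <- gridDim * spacing
  if (max(radii) > min(extent) / 2)
    stop("requested volumes too large for the grid (outer radius ",
         round(max(radii), 1), " mm exceeds half the smallest extent)")
  center <- extent / 2
  ax <- lapply(1:3, function(i) ((seq_len(gridDim[i]) - 0.5) * spacing[i] -
                                   center[i])^2)
  d <- sqrt(outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`))
  out <- lapply(names(raterJitter), function(r) {
    rr <- radii * exp(stats::rnorm(length(radii), 0, raterJitter[[r]]))
    rr <- cummax(rr)  # keep shells nested after jitter
    labs <- array(0L, dim = gridDim)
    for (k in seq_along(rr)) {  # equal radii give an empty shell
      sel <- if (k == 1) d <= rr[k] else d > rr[k - 1] & d <= rr[k]
      labs[sel] <- shellLabel[k]
    }
    LabelVolume(labs, spacing = spacing, patient = patient,
                timePoint = timePoint, rater = r)
  })
  names(out) <- names(raterJitter)
  out
}
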