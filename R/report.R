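#' @include AllGenerics.R
NULL

.writeTable <- function(df, dir, name, digits = 6) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.matrixToDf <- function(m) {
  data.frame(rater = rownames(m), m, check.names = FALSE)
}

#' Assemble the full analysis report for a cohort
#'
#' Runs the downstream analysis surfaces over one cohort and writes them as
#' a deterministic set of CSV tables: preoperative-normalized trend curves,
#' disagreement-plot data, per-compartment disagreement matrices (totals
#' and counts), per-pair disagreement frequencies, the consensus-outlier
#' count when three raters are present, estimation-ratio tables, Pearson
#' correlations of volumes and volume differences, and — when label maps
#' are supplied — gated Dice results and their (median, range) summaries.
#' Numbers are rounded only at serialization (6 significant digits);
#' internal computation keeps full precision.
#'
#' @param records Volume record `data.frame` covering the schedule.
#' @param schedule An [AcquisitionSchedule-class].
#' @param outDir Output directory (created if needed).
#' @param raters Raters to analyse (default all in `records`).
#' @param compartments Analysis compartments (default contrast-enhancing
#'   tumor and merged non-enhancing T2-hyperintense tissue).
#' @param labelVolumes Optional list of [LabelVolume-class] for Dice
#'   analysis.
#' @param consensus,outlier Optional rater names for the consensus-outlier
#'   count (defaults: first two raters as consensus when exactly three are
#'   analysed).
#' @param zeroVolumePolicy,epsilon Passed to [detectDisagreements()].
#' @param diceMinVolume Dice exclusion gate in mm^3.
#' @param metadata Named list merged into `run_metadata.csv` (e.g. seed,
#'   config hash).
#' @param plots Also render PDF figures (trend curves, disagreement plot,
#'   matrix heatmaps). Plots are side-effects of the tables; the CSVs are
#'   the product.
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory tables (`class "ReportBundle"`).
#' @export
buildReport <- function(records, schedule, outDir,
                        raters = sort(unique(records$rater)),
                        compartments = c("NCE_T2", "CET"),
                        labelVolumes = NULL,
                        consensus = NULL, outlier = NULL,
                        zeroVolumePolicy = c("epsilon", "exclude"),
                        epsilon = 1, diceMinVolume = 90,
                        metadata = list(), plots = FALSE) {
  zeroVolumePolicy <- match.arg(zeroVolumePolicy)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  records <- .validateRecords(records)
  records <- records[records$rater %in% raters, ]
  trajectories <- buildTrajectories(records, schedule, raters = raters,
                                    compartments = compartments)
  counts <- countAcquisitions(schedule)

  # relative trend curves (zero-PRE series refused, recorded with a reason)
  trendRows <- list()
  for (ts in trajectories) for (r in raters) for (comp in compartments) {
    rel <- withCallingHandlers(relativeTrajectory(ts, r, comp),
                               warning = function(w) invokeRestart("muffleWarning"))
    trendRows[[length(trendRows) + 1L]] <- if (is.null(rel)) {
      data.frame(patient = ts@patient, rater = r, compartment = comp,
                 timePoint = NA_character_, ratio = NA_real_,
                 note = "zero preoperative volume", stringsAsFactors = FALSE)
    } else {
      cbind(patient = ts@patient, rater = r, compartment = comp, rel,
            note = "", stringsAsFactors = FALSE)
    }
  }
  trends <- do.call(rbind, trendRows)

  plotData <- do.call(rbind, lapply(trajectories, function(ts)
    do.call(rbind, lapply(compartments, function(comp)
      disagreementPlotData(ts, comp)))))
  rownames(plotData) <- NULL

  stats <- cohortTransitionStats(trajectories, compartments)
  disRecords <- detectDisagreements(stats, raters = raters,
                                    zeroVolumePolicy = zeroVolumePolicy,
                                    epsilon = epsilon)
  freqs <- disagreementFrequencies(disRecords, counts[["transitions"]],
                                   raters = raters,
                                   compartments = compartments)
  matrices <- lapply(compartments, function(comp)
    disagreementMatrix(disRecords, raters, comp))
  names(matrices) <- compartments

  if (is.null(consensus) && is.null(outlier) && length(raters) == 3) {
    consensus <- raters[2:3]
    outlier <- raters[1]
  }
  outlierCounts <- if (!is.null(consensus) && !is.null(outlier))
    consensusOutlierCount(disRecords, consensus, outlier) else NULL

  ratios <- estimationRatioTable(records, raters, compartments)

  corrRows <- list()
  for (i in seq_len(length(raters) - 1)) for (j in seq(i + 1, length(raters)))
    for (mode in c("volume", "difference"))
      for (scope in c(list(compartments), as.list(compartments))) {
        cc <- tryCatch(volumeCorrelation(records, raters[i], raters[j],
                                         compartments = scope, mode = mode),
                       error = function(e) NULL)
        if (is.null(cc)) next  # fewer than 3 pairs in this scope
        corrRows[[length(corrRows) + 1L]] <-
          data.frame(rater_x = raters[i], rater_y = raters[j], mode = mode,
                     compartments = paste(scope, collapse = "+"),
                     r = cc$r, p = cc$p, n = cc$n, stringsAsFactors = FALSE)
      }
  corr <- do.call(rbind, corrRows)

  files <- list(
    trends_relative = .writeTable(trends, outDir, "trends_relative.csv"),
    disagreement_plot = .writeTable(plotData, outDir, "disagreement_plot.csv"),
    disagreement_records = .writeTable(disRecords, outDir, "disagreement_records.csv"),
    disagreement_frequencies = .writeTable(freqs, outDir, "disagreement_frequencies.csv"),
    ratio_summary = .writeTable(ratios, outDir, "ratio_summary.csv"),
    correlations = .writeTable(corr, outDir, "correlations.csv")
  )
  for (comp in compartments) {
    files[[paste0("disagreement_matrix_", comp)]] <-
      .writeTable(.matrixToDf(disagreementTotals(matrices[[comp]])), outDir,
                  paste0("disagreement_matrix_", comp, ".csv"))
    files[[paste0("disagreement_counts_", comp)]] <-
      .writeTable(.matrixToDf(disagreementCounts(matrices[[comp]])), outDir,
                  paste0("disagreement_counts_", comp, ".csv"))
  }
  if (!is.null(outlierCounts))
    files$consensus_outlier <- .writeTable(outlierCounts, outDir,
                                           "consensus_outlier.csv")

  diceResults <- diceSummary <- NULL
  if (!is.null(labelVolumes)) {
    diceResults <- pairwiseDice(labelVolumes, compartments,
                                minVolume = diceMinVolume)
    diceSummary <- summarizeDice(diceResults)
    files$dice <- .writeTable(diceResults, outDir, "dice.csv")
    files$dice_summary <- .writeTable(diceSummary, outDir, "dice_summary.csv")
  }

  meta <- c(list(package = "LongiVol",
                 version = as.character(utils::packageVersion("LongiVol")),
                 n_patients = length(patients(schedule)),
                 n_acquisitions = unname(counts[["acquisitions"]]),
                 n_transitions = unname(counts[["transitions"]]),
                 raters = paste(raters, collapse = ","),
                 compartments = paste(compartments, collapse = ","),
                 zero_volume_policy = zeroVolumePolicy,
                 epsilon_mm3 = epsilon,
                 dice_min_volume_mm3 = diceMinVolume),
            metadata)
  metaDf <- data.frame(key = names(meta),
                       value = vapply(meta, function(x) paste(format(x), collapse = ","), ""),
                       stringsAsFactors = FALSE)
  files$run_metadata <- .writeTable(metaDf, outDir, "run_metadata.csv")

  bundle <- structure(list(files = files, trends = trends,
                           plot_data = plotData, records = disRecords,
                           frequencies = freqs, matrices = matrices,
                           consensus_outlier = outlierCounts,
                           ratios = ratios, correlations = corr,
                           dice = diceResults, dice_summary = diceSummary),
                      class = "ReportBundle")
  if (plots) .renderPlots(bundle, trajectories, outDir, compartments)
  invisible(bundle)
}

# optional PDF figures mirroring the analysis surfaces; the CSV tables are
# the authoritative output
.renderPlots <- function(bundle, trajectories, outDir, compartments) {
  grDevices::pdf(file.path(outDir, "trends_relative.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  tr <- bundle$trends[!is.na(bundle$trends$ratio), ]
  for (p in unique(tr$patient)) {
    d <- tr[tr$patient == p, ]
    ord <- match(d$timePoint, timePointLevels())
    graphics::plot(range(ord), range(d$ratio), type = "n",
                   xaxt = "n", xlab = "time point",
                   ylab = "volume relative to preoperative",
                   main = paste("patient", p))
    graphics::axis(1, at = sort(unique(ord)),
                   labels = timePointLevels()[sort(unique(ord))])
    graphics::abline(h = 1, lty = 3)
    keys <- unique(d[, c("rater", "compartment")])
    for (k in seq_len(nrow(keys))) {
      dd <- d[d$rater == keys$rater[k] & d$compartment == keys$compartment[k], ]
      o <- order(match(dd$timePoint, timePointLevels()))
      graphics::lines(match(dd$timePoint, timePointLevels())[o], dd$ratio[o],
                      col = k, lty = match(keys$compartment[k], compartments))
      graphics::points(match(dd$timePoint, timePointLevels())[o], dd$ratio[o],
                       col = k, pch = 16)
    }
  }

  grDevices::pdf(file.path(outDir, "disagreement_plot.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  pd <- bundle$plot_data[!is.na(bundle$plot_data$log10_delta_rel), ]
  for (p in unique(pd$patient)) {
    d <- pd[pd$patient == p, ]
    x <- match(d$to, timePointLevels())
    graphics::plot(range(x), range(d$log10_delta_rel), type = "n", xaxt = "n",
                   xlab = "transition (labelled by endpoint)",
                   ylab = expression(log[10] ~ Delta[rel]),
                   main = paste("patient", p))
    graphics::axis(1, at = sort(unique(x)),
                   labels = timePointLevels()[sort(unique(x))])
    graphics::abline(h = 0, lty = 3)
    rs <- unique(d$rater)
    for (r in rs) {
      dd <- d[d$rater == r, ]
      graphics::points(match(dd$to, timePointLevels()), dd$log10_delta_rel,
                       col = match(r, rs),
                       pch = c(1, 4)[match(dd$compartment, compartments)])
    }
  }

  grDevices::pdf(file.path(outDir, "disagreement_matrices.pdf"),
                 width = 5, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (comp in names(bundle$matrices)) {
    m <- disagreementTotals(bundle$matrices[[comp]])
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m, axes = FALSE,
                    xlab = "", ylab = "", main = paste("disagreement totals,", comp))
    graphics::axis(1, seq_len(nrow(m)), rownames(m))
    graphics::axis(2, seq_len(ncol(m)), colnames(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      graphics::text(i, j, round(m[i, j], 2))
  }
  invisible(NULL)
}
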