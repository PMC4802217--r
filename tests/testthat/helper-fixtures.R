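# small in-code fixtures shared across test files

# random schedule: PRE always present, follow-ups coin-flipped
randomSchedule <- function(nPatients, seed) {
  set.seed(seed)
  tps <- timePointLevels()
  m <- matrix(stats::runif(nPatients * length(tps)) < 0.6, nPatients,
              length(tps), dimnames = list(sprintf("q%02d", seq_len(nPatients)), tps))
  m[, "PRE"] <- TRUE
  AcquisitionSchedule(m)
}

# cuboid label map: one block of a single label in a zero background
blockVolume <- function(label, dims = c(12, 12, 12), block = 1:6,
                        spacing = c(1, 1, 1), rater = "R1",
                        patient = "p1", timePoint = "PRE") {
  arr <- array(0L, dim = dims)
  arr[block, block, block] <- as.integer(label)
  LabelVolume(arr, spacing = spacing, patient = patient,
              timePoint = timePoint, rater = rater)
}

# records for one patient, one compartment, several raters: volumes is a
# named list of numeric vectors over timePoints
seriesRecords <- function(volumes, timePoints, patient = "p1",
                          compartment = "CET") {
  do.call(rbind, lapply(names(volumes), function(r)
    data.frame(patient = patient, time_point = timePoints, rater = r,
               compartment = compartment, volume_mm3 = volumes[[r]],
               stringsAsFactors = FALSE)))
}

scheduleFor <- function(timePoints, patient = "p1") {
  m <- matrix(timePointLevels() %in% timePoints, 1,
              length(timePointLevels()),
              dimnames = list(patient, timePointLevels()))
  AcquisitionSchedule(m)
}

# trajectory set straight from a named list of per-rater volume vectors
trajectoryOf <- function(volumes, timePoints, patient = "p1",
                         compartment = "CET") {
  recs <- seriesRecords(volumes, timePoints, patient, compartment)
  buildTrajectories(recs, scheduleFor(timePoints, patient))[[patient]]
}
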