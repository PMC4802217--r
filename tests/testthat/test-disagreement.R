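test_that("transition statistics measure slope sign, volume ratio and its decimal log", {
  ts <- trajectoryOf(list(R1 = c(100, 200, 200, 0, 50, 80, 20)),
                     timePointLevels())
  st <- transitionStats(ts, "CET")
  expect_equal(st$slope_sign, c(1, 0, -1, 1, 1, -1))
  expect_equal(st$delta_rel, c(2, 1, 0, NA, 8 / 5, 1 / 4))
  expect_equal(st$log10_delta_rel,
               c(log10(2), 0, NA, NA, log10(1.6), log10(0.25)))
  # worked values: doubling is ~0.30103, quartering ~ -0.60206
  expect_equal(st$log10_delta_rel[1], 0.30103, tolerance = 1e-5)
  expect_equal(st$log10_delta_rel[6], -0.60206, tolerance = 1e-5)

  single <- trajectoryOf(list(R1 = 100), "PRE")
  expect_equal(nrow(transitionStats(single, "CET")), 0)
})

test_that("only opposite strict slope signs count as disagreement, at |log10 A - log10 B| magnitude", {
  tps <- c("PRE", "POST")
  mk <- function(vA, vB) {
    ts <- trajectoryOf(list(A = vA, B = vB), tps)
    detectDisagreements(transitionStats(ts, "CET"))
  }
  d <- mk(c(100, 200), c(100, 50))  # A doubles, B halves
  expect_equal(nrow(d), 1)
  expect_equal(d$magnitude, abs(log10(2) - log10(0.5)))
  expect_equal(d$magnitude, 0.60206, tolerance = 1e-5)
  expect_false(d$flagged)

  expect_equal(nrow(mk(c(100, 200), c(50, 80))), 0)   # both grow
  expect_equal(nrow(mk(c(100, 100), c(100, 50))), 0)  # zero sign is neutral
  # strict policy counts 0 vs a strict sign
  ts <- trajectoryOf(list(A = c(100, 100), B = c(100, 50)), tps)
  expect_equal(nrow(detectDisagreements(transitionStats(ts, "CET"),
                                        zeroSignPolicy = "strict")), 1)
})

test_that("zero-volume endpoints follow the epsilon or exclude policy", {
  tps <- c("PRE", "POST")
  ts <- trajectoryOf(list(A = c(100, 200), B = c(100, 0)), tps)
  st <- transitionStats(ts, "CET")
  d <- detectDisagreements(st)  # default epsilon = 1 mm^3 floor
  expect_equal(nrow(d), 1)
  expect_true(d$flagged)
  expect_equal(d$magnitude, abs(log10(2) - log10(1 / 100)))
  d2 <- detectDisagreements(st, zeroVolumePolicy = "exclude")
  expect_equal(nrow(d2), 0)

  # mismatched transition coverage is an error
  st_b <- st[!(st$rater == "B" & st$to == "POST"), ]
  expect_error(detectDisagreements(st_b, raters = c("A", "B")),
               "identical transition")
})

test_that("disagreement matrices sum magnitudes symmetrically with zero diagonal", {
  recs <- data.frame(patient = c("p1", "p2"), from = "PRE", to = "POST",
                     compartment = "CET", rater_a = "R1", rater_b = "R2",
                     magnitude = c(0.3, 0.4), flagged = FALSE)
  m <- disagreementMatrix(recs, c("B", "R1", "R2"), "CET")
  expect_equal(disagreementTotals(m)["R1", "R2"], 0.7)
  expect_equal(disagreementTotals(m)["R2", "R1"], 0.7)
  expect_equal(disagreementCounts(m)["R1", "R2"], 2)
  expect_equal(sum(disagreementTotals(m)), 1.4)  # only that pair

  empty <- disagreementMatrix(recs[0, ], c("B", "R1", "R2"), "CET")
  expect_true(all(disagreementTotals(empty) == 0))
  expect_true(all(disagreementCounts(empty) == 0))
})

test_that("cohort matrices equal an exhaustive pair/transition enumeration and stay symmetric", {
  for (seed in c(3, 17, 31)) {
    sim <- simulateCohort(cohortConfig(nPatients = 8, schedule = "random",
                                       seed = seed))
    tr <- buildTrajectories(sim$records, sim$schedule,
                            compartments = c("NCE_T2", "CET"))
    st <- cohortTransitionStats(tr)
    d <- detectDisagreements(st)
    raters <- c("B", "R1", "R2")
    m <- disagreementMatrix(d, raters, "CET")

    # brute force: double loop over every pair and transition
    tot <- matrix(0, 3, 3, dimnames = list(raters, raters))
    cnt <- tot
    cet <- st[st$compartment == "CET", ]
    keys <- unique(cet[, c("patient", "from", "to")])
    for (k in seq_len(nrow(keys))) {
      tk <- cet[cet$patient == keys$patient[k] & cet$from == keys$from[k] &
                cet$to == keys$to[k], ]
      for (i in 1:2) for (j in (i + 1):3) {
        a <- tk[tk$rater == raters[i], ]; b <- tk[tk$rater == raters[j], ]
        if (a$slope_sign * b$slope_sign == -1) {
          la <- if (is.na(a$log10_delta_rel))
            log10(max(a$v_to, 1) / max(a$v_from, 1)) else a$log10_delta_rel
          lb <- if (is.na(b$log10_delta_rel))
            log10(max(b$v_to, 1) / max(b$v_from, 1)) else b$log10_delta_rel
          tot[i, j] <- tot[j, i] <- tot[i, j] + abs(la - lb)
          cnt[i, j] <- cnt[j, i] <- cnt[i, j] + 1
        }
      }
    }
    expect_equal(disagreementTotals(m), tot)
    expect_equal(disagreementCounts(m), cnt)
    expect_equal(disagreementTotals(m), t(disagreementTotals(m)))
    expect_true(all(diag(disagreementTotals(m)) == 0))
  }
})

test_that("trend decisions are invariant to a constant positive bias on one rater", {
  sim <- simulateCohort(cohortConfig(nPatients = 10, schedule = "random",
                                     seed = 9))
  tr <- buildTrajectories(sim$records, sim$schedule,
                          compartments = c("NCE_T2", "CET"))
  d0 <- detectDisagreements(cohortTransitionStats(tr))

  scaled <- sim$records
  sel <- scaled$rater == "R2"
  scaled$volume_mm3[sel] <- scaled$volume_mm3[sel] * 3.7
  tr2 <- buildTrajectories(scaled, sim$schedule,
                           compartments = c("NCE_T2", "CET"))
  d1 <- detectDisagreements(cohortTransitionStats(tr2))
  # the same transitions disagree: slope signs and ratios of consecutive
  # volumes are scale-free
  key <- function(d) paste(d$patient, d$from, d$to, d$compartment,
                           d$rater_a, d$rater_b)
  expect_identical(sort(key(d1)), sort(key(d0)))
  # and magnitudes agree wherever no zero-volume fallback was involved
  o0 <- d0[!d0$flagged, ]; o1 <- d1[!d1$flagged, ]
  expect_equal(o1$magnitude[order(key(o1))], o0$magnitude[order(key(o0))],
               tolerance = 1e-12)
})

test_that("identical trajectories give zero disagreements", {
  ts <- trajectoryOf(list(A = c(100, 40, 70, 30), B = c(100, 40, 70, 30)),
                     c("PRE", "POST", "M1", "M3"))
  expect_equal(nrow(detectDisagreements(transitionStats(ts, "CET"))), 0)
})

test_that("disagreement frequencies and the consensus-outlier count match enumeration", {
  # 11 disagreements of 50 transitions is 22%
  recs <- data.frame(patient = sprintf("p%02d", 1:11), from = "PRE",
                     to = "POST", compartment = "NCE_T2", rater_a = "B",
                     rater_b = "R1", magnitude = 0.1, flagged = FALSE)
  f <- disagreementFrequencies(recs, 50, raters = c("B", "R1", "R2"),
                               compartments = "NCE_T2")
  expect_equal(f$count[f$rater_a == "B" & f$rater_b == "R1"], 11)
  expect_equal(f$percent[f$rater_a == "B" & f$rater_b == "R1"], 22)
  expect_equal(f$count[f$rater_a == "R1" & f$rater_b == "R2"], 0)
  expect_equal(f$percent[f$rater_a == "R1" & f$rater_b == "R2"], 0)
  expect_true(all(is.na(disagreementFrequencies(recs, 0)$fraction)))

  # consensus-outlier: enumerate sign triples on a synthetic cohort
  sim <- simulateCohort(cohortConfig(nPatients = 12, schedule = "random",
                                     seed = 23))
  tr <- buildTrajectories(sim$records, sim$schedule,
                          compartments = c("NCE_T2", "CET"))
  st <- cohortTransitionStats(tr)
  d <- detectDisagreements(st)
  got <- consensusOutlierCount(d, consensus = c("R1", "R2"), outlier = "B")
  for (comp in c("CET", "NCE_T2")) {
    cc <- st[st$compartment == comp, ]
    keys <- unique(cc[, c("patient", "from", "to")])
    n <- 0
    for (k in seq_len(nrow(keys))) {
      tk <- cc[cc$patient == keys$patient[k] & cc$from == keys$from[k] &
               cc$to == keys$to[k], ]
      s <- setNames(tk$slope_sign, tk$rater)
      opp <- function(a, b) s[[a]] * s[[b]] == -1
      if (opp("B", "R1") && opp("B", "R2") && !opp("R1", "R2")) n <- n + 1
    }
    expect_equal(got$count[got$compartment == comp], n)
  }
})

test_that("disagreement-plot data carries log ratios and reason codes for missing points", {
  ts <- trajectoryOf(list(R1 = c(50, 100, 50, 0, 10)),
                     c("PRE", "POST", "M1", "M3", "M6"))
  pd <- disagreementPlotData(ts, "CET")
  expect_equal(pd$transition,
               c("PRE->POST", "POST->M1", "M1->M3", "M3->M6"))
  # doubling then halving: +0.30103 then -0.30103
  expect_equal(pd$log10_delta_rel[1:2], c(log10(2), -log10(2)))
  expect_equal(pd$reason, c("ok", "ok", "zero_followup", "zero_baseline"))

  stable <- trajectoryOf(list(R1 = c(80, 80, 80)), c("PRE", "M1", "M3"))
  expect_true(all(disagreementPlotData(stable, "CET")$log10_delta_rel == 0))
})
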