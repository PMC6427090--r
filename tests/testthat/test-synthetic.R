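test_that("generation is reproducible and honors group sizes and shapes", {
  sp <- smallSpec(seed = 7L)
  co1 <- generateCohort(sp)
  co2 <- generateCohort(sp)
  expect_identical(lapply(cohortSubjects(co1), tsValues),
                   lapply(cohortSubjects(co2), tsValues))
  expect_equal(length(cohortSubjects(co1)), 16L)
  expect_equal(sum(subjectLabels(cohortManifest(co1)) == "patient"), 8L)
  s <- cohortSubjects(co1)[[1L]]
  expect_equal(dim(tsValues(s)), c(80L, 10L))

  # patient-free spec produces controls only
  cp <- defaultCouplings(); cp$group <- "both"
  onlyC <- generateCohort(smallSpec(nPatients = 0L, nControls = 5L,
                                    couplings = cp))
  expect_true(all(subjectLabels(cohortManifest(onlyC)) == "control"))

  # pure AR(1) noise when couplings are absent: no activations added
  quiet <- SyntheticSpec(nPatients = 1L, nControls = 1L, nRegions = 4L,
                         nTimepoints = 50L, eventRate = 1e-12,
                         couplings = defaultCouplings()[0, ], seed = 3L)
  s1 <- generateSubject(quiet, "control", seed = 11L)
  s2 <- generateSubject(quiet, "control", seed = 11L)
  expect_identical(tsValues(s1), tsValues(s2))
})

test_that("deterministic couplings are visible in the binarized co-activations", {
  # strength 1, no AR noise, huge amplitude: every in-range source event must
  # be followed at exactly `lag` by a target activation
  cp <- data.frame(src = 1L, dst = 2L, lag = 2L, strength = 1,
                   group = "patient")
  sp <- SyntheticSpec(nPatients = 1L, nControls = 1L, nRegions = 3L,
                      nTimepoints = 100L, eventRate = 0.1, amplitude = 10,
                      noiseAR = 0, couplings = cp, seed = 2L)
  sim <- mscalefc:::simulateSubject(sp, "patient", seed = 5L)
  srcEvents <- which(sim$events[, 1L])
  inRange <- srcEvents[srcEvents + 2L <= 100L]
  expect_true(all(sim$induced[inRange + 2L, 2L]))
  bam <- binarize(RoiTimeSeries(sim$values, "p"))
  cnt <- coactivationCount(states(bam)[, 1L], states(bam)[, 2L], c(2L, 2L))
  expect_gte(cnt, length(inRange))
  # the coupling is absent for a control generated from the same draws
  simC <- mscalefc:::simulateSubject(sp, "control", seed = 5L)
  expect_false(any(simC$induced))
})

test_that("coupled cells carry more probability mass, increasing with strength", {
  gap <- vapply(c(0.2, 0.5, 0.8), function(s) {
    co <- generateCohort(smallSpec(seed = 17L, nPatients = 10L, nControls = 0L,
                                   couplings = defaultCouplings(strength = s)))
    cp <- defaultCouplings()
    lagIdx <- c(`1` = 2L, `2` = 3L, `3` = 4L)  # interval index for lag l
    diffs <- vapply(cohortSubjects(co), function(subj) {
      pt <- probs(normalizeTensor(coactivationTensor(binarize(subj))))
      coupled <- mean(vapply(seq_len(nrow(cp)), function(i)
        pt[cp$src[[i]], cp$dst[[i]], lagIdx[[as.character(cp$lag[[i]])]]], 0))
      # matched uncoupled cells: same lags, reversed direction
      uncoupled <- mean(vapply(seq_len(nrow(cp)), function(i)
        pt[cp$dst[[i]], cp$src[[i]], lagIdx[[as.character(cp$lag[[i]])]]], 0))
      coupled - uncoupled
    }, 0)
    mean(diffs)
  }, 0)
  expect_true(all(gap > 0))
  expect_true(all(diff(gap) > 0))  # monotone in coupling strength
})

test_that("swapping which group carries the couplings swaps the signal symmetrically", {
  accFor <- function(group, seed) {
    cp <- defaultCouplings()
    cp$group <- group
    co <- generateCohort(smallSpec(seed = seed, nPatients = 10L,
                                   nControls = 10L, couplings = cp))
    fm <- extractFeatures(co, "multiscale_fc")
    metrics(loocvEvaluate(fm, cohortManifest(co)))[["accuracy"]]
  }
  aPat <- vapply(1:3, function(s) accFor("patient", s), 0)
  aCtl <- vapply(1:3, function(s) accFor("control", s), 0)
  expect_gt(mean(aPat), 0.7)
  expect_gt(mean(aCtl), 0.7)
  expect_lt(abs(mean(aPat) - mean(aCtl)), 0.2)
})

test_that("a written cohort round-trips through the manifest reader", {
  co <- generateCohort(smallSpec(nPatients = 2L, nControls = 2L,
                                 nTimepoints = 30L))
  d <- withr::local_tempdir()
  writeCohort(co, d)
  mf <- readManifest(file.path(d, "manifest.csv"))
  expect_equal(subjectIDs(mf), subjectIDs(cohortManifest(co)))
  ts <- readSubjectTimeSeries(manifestEntries(mf)$path[[1L]])
  expect_equal(unname(tsValues(ts)),
               unname(tsValues(cohortSubjects(co)[[1L]])))
})
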