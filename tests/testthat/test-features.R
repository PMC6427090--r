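test_that("multi-scale feature vector has N*N*T entries in the documented order", {
  set.seed(3)
  ts <- makeTs(matrix(rnorm(30 * 5), 30, 5))
  v <- multiscaleFCVector(ts)
  expect_length(v, 5 * 5 * 4)
  expect_equal(names(v)[1:4],
               c("ROI_1|ROI_1|0-0", "ROI_1|ROI_1|1-1", "ROI_1|ROI_1|2-2",
                 "ROI_1|ROI_1|3-12"))
  expect_equal(names(v)[5], "ROI_1|ROI_2|0-0")   # interval inner, dst middle
  expect_equal(sum(v), 1, tolerance = 1e-9)
  # the vector is the flattened probability tensor, cell by cell
  pt <- probs(normalizeTensor(coactivationTensor(binarize(ts))))
  expect_equal(unname(v[["ROI_2|ROI_4|1-1"]]), pt[2, 4, 2])
})

test_that("excluding the diagonal drops i = j cells and renormalizes", {
  set.seed(4)
  ts <- makeTs(matrix(rnorm(40 * 4), 40, 4))
  v <- multiscaleFCVector(ts, excludeDiagonal = TRUE)
  expect_length(v, 4 * 3 * 4)
  expect_false(any(grepl("ROI_1\\|ROI_1\\|", names(v))))
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("degenerate subjects give an all-zero vector with a warning", {
  # strictly increasing series: no value reaches mean + sd until the last
  # points; construct a matrix whose binarization is all zeros via constant
  # plus one dominating outlier per region placed so no co-activation occurs
  m <- cbind(c(10, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
             c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 10))
  iv <- LagIntervalSet(list(c(1L, 1L)))  # the two spikes are 13 apart
  expect_warning(v <- multiscaleFCVector(makeTs(m), intervalSet = iv),
                 "degenerate")
  expect_true(all(v == 0))
})

test_that("permuting region order permutes features consistently with names", {
  set.seed(12)
  m <- matrix(rnorm(50 * 6), 50, 6)
  colnames(m) <- paste0("R", 1:6)
  ts <- RoiTimeSeries(m, "orig")
  perm <- sample(6)
  tsp <- RoiTimeSeries(m[, perm], "perm")
  v1 <- multiscaleFCVector(ts)
  v2 <- multiscaleFCVector(tsp)
  expect_equal(v2[names(v1)], v1)
  p1 <- pccVector(ts)
  p2 <- pccVector(tsp)
  # unordered pairs: align by canonical pair key
  key <- function(x) {
    parts <- strsplit(names(x), "|", fixed = TRUE)
    vapply(parts, function(p) paste(sort(p), collapse = "|"), "")
  }
  expect_equal(unname(p2[match(key(p1), key(p2))]), unname(p1))
})

test_that("PCC features hit the textbook endpoints and are affine-invariant", {
  x <- rnorm(20)
  ts <- makeTs(cbind(a = x, b = -x + 3, c = 2 * x + 1))
  p <- pccVector(ts)
  expect_equal(unname(p[["a|b"]]), -1)
  expect_equal(unname(p[["a|c"]]), 1)
  expect_true(all(p >= -1 & p <= 1))
  # positive per-column affine maps leave every correlation unchanged
  ts2 <- makeTs(cbind(a = 5 * x - 2, b = 0.1 * (-x + 3) + 7,
                      c = 3 * (2 * x + 1)))
  expect_equal(unname(pccVector(ts2)), unname(p))
  expect_error(pccVector(makeTs(cbind(a = rep(1, 5), b = rnorm(5)))),
               "zero-variance.*a")
})

test_that("feature kinds concatenate with additive dimension and strict alignment", {
  co <- generateCohort(smallSpec(nPatients = 3L, nControls = 3L,
                                 nTimepoints = 40L))
  a <- extractFeatures(co, "multiscale_fc")
  b <- extractFeatures(co, "pcc")
  ab <- combineFeatures(a, b)
  expect_equal(ncol(featureValues(ab)),
               ncol(featureValues(a)) + ncol(featureValues(b)))
  expect_equal(featureKind(ab), "combined")
  expect_identical(featureValues(extractFeatures(co, "combined")),
                   featureValues(ab))
  # empty second operand is the identity
  empty <- FeatureMatrix(matrix(numeric(0), 6, 0,
                                dimnames = list(subjectIDs(a), NULL)), "pcc")
  expect_identical(combineFeatures(a, empty), a)
  # subject mismatch is an alignment error
  bad <- FeatureMatrix(featureValues(b)[6:1, , drop = FALSE], "pcc")
  expect_error(combineFeatures(a, bad), "different subjects")
})

test_that("extraction from a written cohort matches in-memory extraction", {
  co <- generateCohort(smallSpec(nPatients = 3L, nControls = 3L,
                                 nTimepoints = 40L))
  d <- withr::local_tempdir()
  writeCohort(co, d)
  mf <- readManifest(file.path(d, "manifest.csv"))
  onDisk <- extractFeatures(mf, "multiscale_fc")
  inMem <- extractFeatures(co, "multiscale_fc")
  expect_equal(featureValues(onDisk), featureValues(inMem))
})
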