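test_that("scene validation enforces ordered intensities and sane geometry", {
  expect_error(sceneSpec(intensities = c(background = 0.5, cell = 0.3,
                                         nucleus = 0.8, puncta = 0.9)),
               "background < cell")
  expect_error(sceneSpec(nCells = -1L), "nCells")
  expect_error(sceneSpec(nucleusAxes = c(40, 60)), "too large")
})

test_that("an empty scene renders background only", {
  s <- generateSample(sceneSpec(nCells = 0L, seed = 1))
  expect_true(all(!sampleMasks(s, "nucleus")))
  expect_true(all(!sampleMasks(s, "cell")))
  expect_true(all(!sampleMasks(s, "puncta")))
  expect_true(all(sampleImage(s) >= 0 & sampleImage(s) <= 1))
})

test_that("per-class component counts match the placed objects", {
  s <- generateSample(sceneSpec(nCells = 5L, seed = 13))
  expect_equal(max(segbo:::labelComponents(sampleMasks(s, "nucleus"))), 5)
  expect_equal(max(segbo:::labelComponents(sampleMasks(s, "cell"))), 5)
  nPuncta <- length(s@metadata$puncta)
  expect_equal(max(segbo:::labelComponents(sampleMasks(s, "puncta"))), nPuncta)
})

test_that("generation is seed-reproducible and masks are nested", {
  a <- generateSample(defaultSceneSpec(seed = 7))
  b <- generateSample(defaultSceneSpec(seed = 7))
  expect_identical(sampleImage(a), sampleImage(b))
  expect_identical(sampleMasks(a), sampleMasks(b))
  for (seed in c(1, 5, 9)) {
    s <- generateSample(defaultSceneSpec(seed = seed))
    expect_true(all(sampleMasks(s, "cell")[sampleMasks(s, "nucleus")]))
  }
})

test_that("datasets use consecutive seeds, distinct images, and a complete manifest", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(defaultSceneSpec(), 3, baseSeed = 21, dir = dir)
  expect_length(ds$samples, 3)
  expect_equal(sum(ds$manifest$class == "image"), 3)
  expect_true(all(file.exists(ds$manifest$path)))
  hashes <- vapply(ds$samples, function(s)
    paste(range(sampleImage(s)), sum(sampleImage(s)), collapse = "/"),
    character(1))
  expect_equal(length(unique(hashes)), 3)
  expect_error(generateDataset(defaultSceneSpec(), 0), ">= 1")
})

test_that("the oracle rating maps IoU onto the 1-10 scale with half-up rounding", {
  m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
  expect_equal(oracleRating(m, m), 10L)
  n <- matrix(FALSE, 4, 4); n[4, 4] <- TRUE
  expect_equal(oracleRating(n, m), 1L)
  # IoU exactly 0.5: 1 + round-half-away(4.5) = 6
  a <- matrix(FALSE, 2, 2); a[1, 1:2] <- TRUE
  b <- matrix(FALSE, 2, 2); b[1, 1] <- TRUE
  expect_equal(maskIoU(b, a), 0.5)
  expect_equal(oracleRating(b, a), 6L)
  expect_error(oracleRating(matrix(FALSE, 2, 2), matrix(FALSE, 3, 3)),
               "shape")
})

test_that("the noise-free rating is monotone in IoU and noise stays on scale", {
  truth <- matrix(FALSE, 10, 10); truth[1:10, 1:5] <- TRUE
  ratings <- vapply(0:5, function(k) {
    pred <- truth
    if (k > 0) pred[1:10, 5 + seq_len(k)] <- TRUE   # grow false positives
    oracleRating(pred, truth)
  }, integer(1))
  expect_true(all(diff(ratings) <= 0))
  withr::with_seed(31, {
    noisy <- replicate(50, oracleRating(truth, truth, noiseProb = 0.5))
    expect_true(all(noisy >= 1 & noisy <= 10))
    expect_true(any(noisy < 10))   # flips do occur
  })
})

test_that("the recorded oracle configuration segments its own scenes well", {
  s <- generateSample(defaultSceneSpec(seed = 17))
  cfg <- s@metadata$oracleConfig
  expect_equal(cfg, oracleConfiguration())
  res <- runPipeline(sampleImage(s), cfg)
  expect_gt(maskIoU(res@primary > 0, sampleMasks(s, "nucleus")), 0.8)
})

test_that("the simulated rater scores pipeline results like the oracle rating", {
  s <- generateSample(defaultSceneSpec(seed = 19))
  rater <- makeSimulatedRater(s, "nucleus")
  res <- runPipeline(sampleImage(s), oracleConfiguration())
  expect_equal(rater(res),
               oracleRating(res@primary > 0, sampleMasks(s, "nucleus")))
  expect_gte(rater(res), 9)
})
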