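test_that("automated QS aggregates per-criterion pass fractions onto the 1-10 scale", {
  m <- data.frame(area = c(100, 150, 200, 250), solidity = c(0.95, 0.9, 0.97, 0.99))
  allPass <- automatedCriteria(measurementCriterion("solidity", lower = 0.5))
  expect_equal(automatedQS(m, allPass), 10)
  nonePass <- automatedCriteria(measurementCriterion("solidity", lower = 0.999))
  expect_equal(automatedQS(m, nonePass), 1)
  # pass fractions 1.0 and 0.5 -> 1 + 9 * 0.75
  two <- automatedCriteria(
    measurementCriterion("solidity", lower = 0.5),
    measurementCriterion("area", lower = 180))
  expect_equal(automatedQS(m, two), 7.75)
  expect_error(
    automatedQS(m, automatedCriteria(measurementCriterion("perimeter", lower = 1))),
    "'perimeter' not found")
})

test_that("zero-object segmentations score worst with a warning, not an error", {
  crit <- automatedCriteria(measurementCriterion("area", lower = 1))
  expect_warning(qs <- automatedQS(data.frame(area = numeric(0)), crit),
                 "no objects")
  expect_equal(qs, 1)
})

test_that("at most four criteria are accepted and each needs a usable bound", {
  mk <- function(n) lapply(seq_len(n), function(i)
    measurementCriterion("area", lower = i))
  expect_error(automatedCriteria(mk(5)), "at most 4")
  expect_silent(automatedCriteria(mk(4)))
  expect_error(automatedCriteria(list()), "at least one")
  expect_error(measurementCriterion("area"), "at least one bound")
  expect_error(measurementCriterion("area", lower = 5, upper = 2), "lower bound")
})

test_that("automated QS is monotone in adding passing/failing objects", {
  crit <- automatedCriteria(measurementCriterion("solidity", lower = 0.9))
  base <- data.frame(solidity = c(0.95, 0.5, 0.92))
  qs0 <- automatedQS(base, crit)
  expect_gte(automatedQS(rbind(base, data.frame(solidity = 0.99)), crit), qs0)
  expect_lte(automatedQS(rbind(base, data.frame(solidity = 0.1)), crit), qs0)
})

test_that("manual QS validates integer ratings and re-queries before aborting", {
  expect_equal(manualQS(function(p) 7L), 7L)
  # the payload reaches the provider
  seen <- NULL
  manualQS(function(p) { seen <<- p; 3L }, payload = "overlay.png")
  expect_equal(seen, "overlay.png")
  # out-of-scale ratings are re-queried
  tries <- 0
  qs <- suppressWarnings(
    manualQS(function(p) { tries <<- tries + 1; if (tries < 3) 0L else 8L }))
  expect_equal(qs, 8L)
  expect_equal(tries, 3)
  expect_error(suppressWarnings(manualQS(function(p) 11L)), "no valid rating")
  expect_error(suppressWarnings(manualQS(function(p) 6.5)), "no valid rating")
})

test_that("composite QS is a normalised weighted mean bounded by its inputs", {
  expect_equal(compositeQS(c(4, 9), c(1, 0)), 4)
  expect_equal(compositeQS(c(4, 8), c(1, 1)), 6)
  expect_equal(compositeQS(c(3, 9), c(2, 2)), compositeQS(c(3, 9), c(0.5, 0.5)))
  withr::with_seed(91, {
    for (i in 1:20) {
      s <- runif(3, 1, 10); w <- runif(3)
      q <- compositeQS(s, w)
      expect_gte(q, min(s)); expect_lte(q, max(s))
    }
  })
  expect_error(compositeQS(c(4, 8), c(1, 1, 1)), "same length")
  expect_error(compositeQS(c(4, 8), c(0, 0)), "not all be zero")
})

test_that("quality gap is the clamped target shortfall", {
  expect_equal(qualityGap(8, 8), 0)
  expect_equal(qualityGap(8, 5), 3)
  expect_equal(qualityGap(8, 9.5), 0)
  expect_error(qualityGap(11, 5), "\\[1, 10\\]")
  withr::with_seed(92, {
    for (i in 1:20) {
      tg <- runif(1, 1, 10); cur <- runif(1, 1, 10)
      g <- qualityGap(tg, cur)
      expect_gte(g, 0)
      expect_identical(g == 0, cur >= tg)
    }
  })
})
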