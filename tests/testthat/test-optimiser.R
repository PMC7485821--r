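# Cheap analytic task: the "pipeline" hands the configuration straight to
# the evaluator, which scores closeness to a known optimum on the 1-10
# scale. Exercises the loop without image processing.
analyticSpace <- function() {
  searchSpace(parameterSpec("a", "float", 0, 1, 0.1),
              parameterSpec("b", "float", 0, 1, 0.1))
}
analyticEvaluator <- function(opt = c(0.3, 0.7)) {
  function(cfg) {
    d <- sqrt(sum((unlist(cfg) - opt)^2))
    max(1, min(10, round(10 - 9 * d)))
  }
}

test_that("settings are validated", {
  expect_error(boSettings(targetQS = 11), "\\[1, 10\\]")
  expect_error(boSettings(bootstrapCount = 1), ">= 2")
  expect_error(boSettings(maxIterations = 0), ">= 1")
  expect_equal(boSettings()$bootstrapCount, 2L)
})

test_that("an achievable target terminates with quality gap zero", {
  res <- runBO(analyticSpace(), identity, analyticEvaluator(),
               boSettings(targetQS = 9, maxIterations = 25, seed = 3))
  expect_equal(terminatedReason(res), "target_met")
  trace <- boTrace(res)
  expect_equal(trace$gap[nrow(trace)], 0)
  expect_gte(bestQS(res), 9)
})

test_that("an unachievable target exhausts exactly the iteration budget", {
  res <- runBO(analyticSpace(), identity, function(cfg) 5,
               boSettings(targetQS = 10, maxIterations = 7, seed = 4))
  expect_equal(terminatedReason(res), "budget_exhausted")
  expect_equal(nrow(boTrace(res)), 2 + 7)   # bootstrap + budget
})

test_that("best-so-far QS is non-decreasing in every seeded run", {
  for (seed in 1:5) {
    res <- runBO(analyticSpace(), identity, analyticEvaluator(),
                 boSettings(targetQS = 10, maxIterations = 10, seed = seed))
    expect_true(all(diff(boTrace(res)$best_qs) >= 0))
    expect_true(all(diff(boTrace(res)$best_gap) <= 0))
  }
})

test_that("a fixed master seed reproduces the whole trace bit for bit", {
  st <- boSettings(targetQS = 10, maxIterations = 8, seed = 12)
  r1 <- runBO(analyticSpace(), identity, analyticEvaluator(), st)
  r2 <- runBO(analyticSpace(), identity, analyticEvaluator(), st)
  expect_identical(boTrace(r1), boTrace(r2))
  expect_identical(bestConfiguration(r1), bestConfiguration(r2))
})

test_that("crashing configurations score 1 and are flagged, not fatal", {
  crashy <- function(cfg) {
    if (cfg[["a"]] > 0.55) stop("boom")
    cfg
  }
  cappedAt9 <- function(cfg) min(analyticEvaluator()(cfg), 9)
  res <- runBO(analyticSpace(), crashy, cappedAt9,
               boSettings(targetQS = 10, maxIterations = 10, seed = 5))
  trace <- boTrace(res)
  expect_true(any(trace$crashed))
  expect_true(all(trace$qs[trace$crashed] == 1))
  expect_equal(terminatedReason(res), "budget_exhausted")
})

test_that("an evaluator failure aborts the run and persists the partial trace", {
  dir <- withr::local_tempdir()
  n <- 0
  failing <- function(cfg) {
    n <<- n + 1
    if (n >= 3) stop("rater walked away")
    5
  }
  expect_error(
    runBO(analyticSpace(), identity, failing,
          boSettings(targetQS = 10, maxIterations = 5, seed = 6),
          traceDir = dir),
    "evaluator failed")
  expect_true(file.exists(file.path(dir, "trace_partial.csv")))
  expect_equal(nrow(read.csv(file.path(dir, "trace_partial.csv"))), 2)
})

test_that("the iteration report pairs best, previous and proposed values", {
  res <- runBO(analyticSpace(), identity, analyticEvaluator(),
               boSettings(targetQS = 10, maxIterations = 5, seed = 7))
  trace <- boTrace(res)
  rep3 <- iterationReport(res, evaluation = 3)   # first post-bootstrap
  expect_equal(rep3$setting, c("a", "b"))
  # "old value" is the second bootstrap configuration
  expect_equal(rep3$old_value, c(trace$a[2], trace$b[2]))
  bestRow <- which.max(trace$qs[1:2])
  expect_equal(rep3$best_so_far, c(trace$a[bestRow], trace$b[bestRow]))
  expect_equal(rep3$new_value,
               c(trace[["a (proposed)"]][3], trace[["b (proposed)"]][3]))
  expect_error(iterationReport(res, evaluation = 99), "no such")
})

test_that("persisted traces round-trip the training set exactly", {
  dir <- withr::local_tempdir()
  res <- runBO(analyticSpace(), identity, analyticEvaluator(),
               boSettings(targetQS = 10, maxIterations = 6, seed = 8))
  paths <- persistTrace(res, file.path(dir, "out"))
  expect_true(all(file.exists(paths)))
  trace <- boTrace(res)
  back <- readEvaluations(paths[["evaluations"]])
  expect_equal(nrow(back), nrow(trace))   # one line per evaluation
  expect_identical(back$a, trace$a)
  expect_identical(back$b, trace$b)
  expect_equal(as.numeric(back$qs), trace$qs)
  expect_true(all(back$gap >= 0))

  f <- file.path(dir, "plainfile")
  writeLines("x", f)
  expect_error(suppressWarnings(persistTrace(res, file.path(f, "sub"))),
               "cannot create")
})

test_that("the optimiser recovers a working configuration on the reference task", {
  s <- generateSample(defaultSceneSpec(seed = 5))
  pipe <- function(cfg) runPipeline(sampleImage(s), cfg)
  res <- runBO(defaultSearchSpace(), pipe, makeSimulatedRater(s, "nucleus"),
               boSettings(targetQS = 8, maxIterations = 30, seed = 5))
  expect_equal(terminatedReason(res), "target_met")
  final <- runPipeline(sampleImage(s), bestConfiguration(res))
  expect_gt(maskIoU(final@primary > 0, sampleMasks(s, "nucleus")), 0.7)
})
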