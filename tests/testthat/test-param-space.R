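test_that("search-space validation accepts valid spaces and names offenders", {
  sp <- searchSpace(parameterSpec("f", "float", 0.6, 1.5, 0.1))
  expect_s4_class(validateSearchSpace(sp), "SearchSpace")

  expect_error(searchSpace(list()), "at least one parameter")
  expect_error(parameterSpec("bad", "float", 5, 5, 1), "'bad'.*minimum")
  expect_error(parameterSpec("neg", "float", 0, 1, -0.1), "'neg'")
  expect_error(parameterSpec("wide", "float", 0, 10, 20), "'wide'.*range")
  expect_error(parameterSpec("frac", "integer", 1, 5, 0.5), "whole-valued")
  expect_error(
    searchSpace(parameterSpec("a", "float", 0, 1, 0.5),
                parameterSpec("a", "float", 0, 2, 1)),
    "duplicate.*'a'")
})

test_that("gridValues enumerates the interval grid and always includes both bounds", {
  expect_equal(gridValues(parameterSpec("i", "integer", 1, 3, 1)), c(1, 2, 3))
  # max appended when the last step falls short of it
  expect_equal(gridValues(parameterSpec("f", "float", 0.6, 1.5, 0.4)),
               c(0.6, 1.0, 1.4, 1.5))
  for (sp in list(parameterSpec("a", "float", 0.3, 2.2, 0.7),
                  parameterSpec("b", "integer", 10, 97, 8),
                  parameterSpec("c", "float", -1, 1, 0.3))) {
    g <- gridValues(sp)
    expect_equal(g[1], sp@minimum)
    expect_equal(g[length(g)], sp@maximum)
    expect_true(all(diff(g) > 0))
  }
})

test_that("encode maps bounds to 0/1 and decode(encode(.)) is the identity on the grid", {
  space <- twoSpecSpace()
  lo <- c(window = 1, factor = 0.6)
  hi <- c(window = 3, factor = 1.5)
  expect_equal(unname(encodeConfiguration(lo, space)), c(0, 0))
  expect_equal(unname(encodeConfiguration(hi, space)), c(1, 1))

  # brute force over the full cartesian grid
  grids <- lapply(space@specs, gridValues)
  for (w in grids[[1]]) for (f in grids[[2]]) {
    cfg <- c(window = w, factor = f)
    expect_equal(decodeConfiguration(encodeConfiguration(cfg, space), space),
                 cfg, tolerance = 1e-12)
  }

  expect_error(encodeConfiguration(c(window = 1), space), "missing")
  expect_error(encodeConfiguration(c(window = 1, factor = 1, x = 2), space),
               "unknown")
})

test_that("decode snaps into the grid with ties breaking low", {
  space <- twoSpecSpace()
  expect_equal(decodeConfiguration(c(0, 0), space),
               c(window = 1, factor = 0.6))
  # exact midpoint between window grid values 1 and 2 -> lower value
  expect_equal(decodeConfiguration(c(0.25, 0), space)[["window"]], 1)
  expect_error(decodeConfiguration(c(-0.2, 0.5), space), "\\[0, 1\\]")

  # random points always land in the enumerated grid of a 3-setting space
  sp3 <- searchSpace(parameterSpec("a", "integer", 0, 4, 2),
                     parameterSpec("b", "float", 0, 1, 0.25),
                     parameterSpec("c", "float", 2, 3, 0.4))
  grids <- lapply(sp3@specs, gridValues)
  full <- expand.grid(grids[[1]], grids[[2]], grids[[3]])
  keys <- apply(full, 1, paste, collapse = "/")
  withr::with_seed(99, {
    for (i in 1:1000) {
      v <- decodeConfiguration(runif(3), sp3)
      expect_true(paste(v, collapse = "/") %in% keys)
    }
  })
})

test_that("random configuration sampling is seeded and uniform over the grid", {
  space <- twoSpecSpace()
  expect_error(sampleConfigurations(space, 0), ">= 1")
  a <- sampleConfigurations(space, 2, seed = 5)
  b <- sampleConfigurations(space, 2, seed = 5)
  expect_identical(a, b)
  grids <- lapply(space@specs, gridValues)
  for (cfg in a) {
    expect_true(cfg[["window"]] %in% grids[[1]])
    expect_true(cfg[["factor"]] %in% grids[[2]])
  }

  # frequencies over a 3-value grid: within 3 binomial SE of 1/3, and a
  # chi-square goodness-of-fit not rejected at alpha = 0.01
  sp1 <- searchSpace(parameterSpec("i", "integer", 1, 3, 1))
  draws <- vapply(sampleConfigurations(sp1, 10000, seed = 11), `[[`, numeric(1), "i")
  counts <- table(factor(draws, levels = 1:3))
  se <- sqrt(10000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 10000 / 3) <= 3 * se))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})
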