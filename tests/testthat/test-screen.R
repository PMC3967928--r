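test_that("right-censored log-rank matches the hand-computed O-E and variance sums", {
  toy <- data.frame(
    duration = c(2, 5, 7, 9, 1, 3, 6, 8),
    event = c(1, 1, 0, 0, 1, 1, 0, 0),
    group = rep(c("mutant", "control"), each = 4))
  res <- logrankRightCensored(toy)
  oracle <- handLogrank(toy$duration, toy$event, toy$group)
  expect_equal(res$statistic, oracle$chisq, tolerance = 1e-10)
  expect_equal(res$p, pchisq(oracle$chisq, 1, lower.tail = FALSE))
  # mutant deaths later than expected => direction +1 (longer survival)
  expect_equal(res$direction, as.integer(sign(-oracle$OminusE)))
})

test_that("log-rank degenerate and error cases behave", {
  same <- data.frame(duration = rep(c(1, 2, 3), 2),
                     event = 1,
                     group = rep(c("control", "mutant"), each = 3))
  res <- logrankRightCensored(same)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)
  expect_equal(res$direction, 0L)
  nocens <- data.frame(duration = c(1, 2), event = 0,
                       group = c("control", "mutant"))
  expect_error(logrankRightCensored(nocens), "no events")
  expect_error(logrankRightCensored(
    data.frame(duration = 1, event = 1, group = "control")), "non-empty")
})

test_that("interval log-rank approaches the exact-time log-rank as the grid refines", {
  tr <- simulateIntervalTrials(0.5, inspection_spacing = 0.002,
                               n_per_group = 60, n_trials = 1,
                               n_inspections = 5000, seed = 11)
  latent <- attr(tr, "truth")$latent
  exact <- data.frame(duration = latent, event = 1, group = tr$group)
  ri <- logrankIntervalCensored(tr)
  re <- logrankRightCensored(exact)
  expect_equal(ri$statistic, re$statistic, tolerance = 0.02)
  expect_equal(ri$direction, re$direction)
})

test_that("interval log-rank validates the shared inspection grid", {
  bad <- data.frame(L = c(0, 0.5), R = c(1, 1.2),
                    group = c("control", "mutant"))
  expect_error(logrankIntervalCensored(bad), "grid")
  flat <- data.frame(L = rep(c(0, 1), 4), R = rep(c(1, 2), 4),
                     group = rep(c("control", "mutant"), each = 4))
  expect_equal(logrankIntervalCensored(flat)$p, 1, tolerance = 1e-9)
})

test_that("hypergeometric count test enumerates the exact two-sided tail", {
  res <- hypergeomCountTest(3, 3, 0, 3)
  expect_equal(res$p, 0.10, tolerance = 1e-12)
  expect_equal(res$direction, 1L)
  # agrees with fisher.test's minimum-likelihood rule on random tables
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    a <- rbinom(1, n1, 0.4); b <- rbinom(1, n2, 0.4)
    ours <- hypergeomCountTest(a, n1, b, n2)$p
    ft <- stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2))$p.value
    expect_equal(ours, ft, tolerance = 1e-7)
  }
  # label swap keeps p, flips direction
  x <- hypergeomCountTest(10, 20, 3, 20)
  y <- hypergeomCountTest(3, 20, 10, 20)
  expect_equal(x$p, y$p)
  expect_equal(x$direction, -y$direction)
  # equal proportions sit at the modal table
  expect_equal(hypergeomCountTest(5, 10, 5, 10)$p, 1, tolerance = 1e-12)
  expect_error(hypergeomCountTest(0, 0, 1, 5), "totals")
  # doubling rule never exceeds 1 and differs predictably
  expect_lte(hypergeomCountTest(3, 3, 0, 3, "doubling")$p, 1)
})

test_that("chi-square sum combination follows the stated df rule", {
  one <- list(trialTestResult(2.5, 1L, pchisq(2.5, 1, lower.tail = FALSE), 1L, "a"))
  expect_equal(combineTrials(one), pchisq(2.5, 1, lower.tail = FALSE))
  two <- rep(list(trialTestResult(1, 1L, pchisq(1, 1, lower.tail = FALSE), 1L, "a")), 2)
  expect_equal(combineTrials(two), exp(-1), tolerance = 1e-12)
  mixed <- list(trialTestResult(1, 1L, 0.3, 1L, "a"),
                trialTestResult(1, 1L, 0.3, 1L, "b"))
  expect_error(combineTrials(mixed), "mixed")
})

test_that("binomial-GLM combination is null on identical proportions and detects shifts", {
  cnt <- data.frame(trial = rep(1:3, each = 2),
                    group = rep(c("control", "mutant"), 3),
                    dauers = rep(c(5, 5), 3), total = 50)
  expect_gt(combineTrials(NULL, method = "count_glm", counts = cnt), 0.99)
  shifted <- simulateDauerTrials(0.05, 0.5, n_trials = 3, seed = 2)
  expect_lt(combineTrials(NULL, method = "count_glm", counts = shifted), 1e-6)
})

test_that("confidence classification implements the three criteria and the variable override", {
  res3 <- rep(list(trialTestResult(11, 1L, 0.001, 1L, "a")), 3)
  cp <- combineTrials(res3)
  expect_lt(cp, 0.01)
  expect_equal(classifyConfidence(res3, cp, rep("lab1", 3))$level, "high")
  # combined significance without per-trial majority: low confidence
  res4 <- c(list(trialTestResult(14, 1L, 2e-4, 1L, "a")),
            rep(list(trialTestResult(0.5, 1L, 0.48, 1L, "a")), 3))
  cp4 <- combineTrials(res4)
  expect_lt(cp4, 0.01)
  expect_equal(classifyConfidence(res4, cp4, rep("lab1", 4))$level, "low")
  # significant trials in both directions: variable regardless
  resv <- list(trialTestResult(11, 1L, 0.001, 1L, "a"),
               trialTestResult(11, 1L, 0.001, -1L, "a"),
               trialTestResult(11, 1L, 0.001, 1L, "a"))
  expect_equal(classifyConfidence(resv, combineTrials(resv),
                                  rep("lab1", 3))$level, "variable")
  # two-lab rule: majority needed in both labs
  res22 <- list(trialTestResult(11, 1L, 0.001, 1L, "a"),
                trialTestResult(11, 1L, 0.001, 1L, "a"),
                trialTestResult(0.1, 1L, 0.75, 1L, "a"),
                trialTestResult(0.2, 1L, 0.65, 1L, "a"))
  call22 <- classifyConfidence(res22, combineTrials(res22),
                               c("lab1", "lab1", "lab2", "lab2"))
  expect_equal(call22$level, "low")
  # one significant trial only in a single lab fails criterion 3 (>= 2 trials)
  res1 <- list(trialTestResult(11, 1L, 0.001, 1L, "a"),
               trialTestResult(12, 1L, 5e-4, 1L, "a"))
  expect_equal(classifyConfidence(res1, combineTrials(res1),
                                  rep("lab1", 2))$level, "high")
  expect_error(classifyConfidence(list(), 0.5, character()), "empty")
})

test_that("confidence classification is invariant to trial order", {
  set.seed(9)
  res <- lapply(1:5, function(i) {
    p <- runif(1)
    trialTestResult(qchisq(p, 1, lower.tail = FALSE), 1L, p,
                    sample(c(-1L, 1L), 1), "a")
  })
  labs <- c("lab1", "lab1", "lab2", "lab2", "lab2")
  cp <- combineTrials(res)
  base <- classifyConfidence(res, cp, labs)
  for (i in 1:10) {
    perm <- sample(5)
    shuffled <- classifyConfidence(res[perm], cp, labs[perm])
    expect_equal(shuffled$level, base$level)
    expect_equal(shuffled$direction, base$direction)
  }
})

test_that("phenotype matrix aggregation and low-confidence toggling behave", {
  calls <- data.frame(
    ilp = c("a", "a", "b", "c"),
    assay = c("dauer_entry_daf2", "dauer_entry_daf28", "lifespan", "dauer_exit"),
    level = c("high", "high", "low", "none"))
  m <- buildPhenotypeMatrix(calls, aggregate_dauer_entry = TRUE)
  expect_equal(unname(m["a", "dauer_entry"]), 1L)   # OR of the three screens
  expect_equal(sum(m["a", ]), 1)
  expect_equal(sum(m["b", ]), 0)                    # low excluded by default
  ml <- buildPhenotypeMatrix(calls, include_low = TRUE)
  expect_true(all(ml >= m))                         # monotone in include_low
  expect_equal(unname(ml["b", "lifespan"]), 1L)
  zero <- buildPhenotypeMatrix(data.frame(ilp = "a", assay = "lifespan",
                                          level = "none"))
  expect_true(all(zero == 0))
  expect_error(buildPhenotypeMatrix(data.frame(ilp = "a", assay = "weird",
                                               level = "high")), "assay")
})

test_that("pleiotropy is the row percentage of processes", {
  m <- rbind(full = c(1L, 1L, 1L), empty = c(0L, 0L, 0L), one = c(1L, 0L, 0L))
  expect_equal(unname(pleiotropy(m)), c(100, 0, 100 / 3))
})
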