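test_that("newborn class distribution mixes crosses by class frequency", {
  expect_equal(newbornClassDistribution(populationState(ZZ = 100, WZ = 100), 0),
               c(ZZ_MALE = 0.5, IS = 0, WZ_FEMALE = 0.5, WW_FEMALE = 0))
  # the pure intersex x female cross
  expect_equal(newbornClassDistribution(populationState(IS = 100, WZ = 100), 0),
               c(ZZ_MALE = 0.25, IS = 0, WZ_FEMALE = 0.5, WW_FEMALE = 0.25))
  # half ZZ / half IS sires: hand mixture of the two cross tables
  expect_equal(
    newbornClassDistribution(populationState(ZZ = 50, IS = 50, WZ = 100), 0),
    c(ZZ_MALE = 0.375, IS = 0, WZ_FEMALE = 0.5, WW_FEMALE = 0.125))
  # single-sex populations cannot recruit
  expect_equal(sum(newbornClassDistribution(populationState(ZZ = 10), 0.04)), 0)
  expect_equal(sum(newbornClassDistribution(populationState(WZ = 10), 0.04)), 0)
})

test_that("projection step adds survivors and recruits", {
  p <- DemographicParams(alpha = 0, sigma0 = 1, sigmaA = 0, phi = 2)
  st <- projectStep(populationState(ZZ = 100, WZ = 100), p)
  expect_equal(st, populationState(ZZ = 100, WZ = 100))  # lambda = 1
  # all-female population: survivors only
  p2 <- DemographicParams(sigmaA = 0.6)
  st2 <- projectStep(populationState(WZ = 50, WW = 10), p2)
  expect_equal(sum(st2), 0.6 * 60)
  # the stable structure is a fixed point of the step in fractions
  f <- classFractions(stableDistribution(0.04, method = "solve"))
  nxt <- projectStep(f, DemographicParams(alpha = 0.04))
  expect_equal(nxt / sum(nxt), f, tolerance = 1e-10)
})

test_that("constant-size variant conserves N and shares the fixed point", {
  p <- DemographicParams(alpha = 0.04, sigmaA = 0.6)
  set.seed(11)
  for (i in 1:20) {
    st <- populationState(ZZ = runif(1, 1, 100), IS = runif(1, 0, 20),
                          WZ = runif(1, 1, 100), WW = runif(1, 0, 20))
    nxt <- constantPopulationStep(st, p)
    expect_equal(sum(nxt), sum(st), tolerance = 1e-12)
  }
  # sigmaA = 1: no deaths, no recruits
  st <- populationState(ZZ = 30, IS = 2, WZ = 30, WW = 1)
  expect_equal(constantPopulationStep(st, DemographicParams(sigmaA = 1)), st)
  # iterating from 50/50 reaches the same structure as the growing model
  st <- populationState(ZZ = 50, WZ = 50)
  for (i in 1:2000) st <- constantPopulationStep(st, p)
  expect_equal(st / sum(st),
               classFractions(stableDistribution(0.04, method = "solve")),
               tolerance = 1e-8)
})

test_that("stable distribution reproduces the published fractions", {
  sd1 <- stableDistribution(0.04)
  expect_equal(round(100 * classFractions(sd1), 2), ltsdExpected)
  expect_equal(classFractions(stableDistribution(0)),
               c(ZZ = 0.5, IS = 0, WZ = 0.5, WW = 0), tolerance = 1e-9)
})

test_that("LTSD depends on alpha only, not survival or fecundity", {
  ref <- classFractions(stableDistribution(0.04))
  for (sa in c(0, 0.3, 0.9)) for (sp in c(0.5, 3.0)) {
    f <- classFractions(stableDistribution(
      0.04, DemographicParams(sigmaA = sa, sigma0 = 1, phi = sp)))
    expect_equal(f, ref, tolerance = 1e-6)
  }
})

test_that("iterative LTSD equals the direct fixed-point solve", {
  for (a in c(0.005, 0.01, 0.04, 0.1, 0.3, 0.8)) {
    expect_equal(classFractions(stableDistribution(a, tol = 1e-12)),
                 classFractions(stableDistribution(a, method = "solve")),
                 tolerance = 1e-8)
  }
  expect_error(stableDistribution(0.04, tol = 1e-14, maxIter = 3L),
               "did not converge")
})

test_that("LTSD balances functional males and females at 1:1", {
  for (a in c(0, 0.05, 0.1, 0.2)) {
    f <- classFractions(stableDistribution(a, method = "solve"))
    expect_lt(abs((f[["ZZ"]] + f[["IS"]]) - (f[["WZ"]] + f[["WW"]])),
              1e-4)  # 0.01 percentage points
  }
})

test_that("long-run growth rate is the same with and without intersex", {
  p0 <- DemographicParams(alpha = 0)
  p4 <- DemographicParams(alpha = 0.04)
  tr0 <- simulateTrajectory(populationState(ZZ = 100, WZ = 100), p0, 120)
  tr4 <- simulateTrajectory(populationState(ZZ = 100, WZ = 100), p4, 120)
  l0 <- growthRates(tr0); l4 <- growthRates(tr4)
  expect_equal(l0[length(l0)], l4[length(l4)], tolerance = 1e-8)
})

test_that("abundances stay nonnegative under both step operators", {
  set.seed(7)
  for (i in 1:20) {
    p <- DemographicParams(alpha = runif(1), sigma0 = runif(1),
                           sigmaA = runif(1, 0, 0.99), phi = runif(1, 0, 4))
    st <- populationState(ZZ = runif(1, 0, 50), IS = runif(1, 0, 50),
                          WZ = runif(1, 0, 50), WW = runif(1, 0, 50))
    expect_true(all(projectStep(st, p) >= 0))
    if (sum(st) > 0)
      expect_true(all(constantPopulationStep(st, p) >= 0))
  }
})

test_that("generations to convergence behaves and meets the 30-step bound", {
  p <- DemographicParams(alpha = 0.04, sigmaA = 0.6, sigma0 = 1, phi = 1.2)
  ltsd <- classFractions(stableDistribution(0.04, method = "solve"))
  expect_equal(generationsToConvergence(ltsd, p)$generations, 0)
  res <- generationsToConvergence(populationState(ZZ = 0.5, WZ = 0.5), p,
                                  tolPP = 0.1)
  expect_lte(res$generations, 30)
  expect_equal(res$years, res$generations / 2)  # 6-month steps
  # smaller tolerance never converges earlier
  gens <- vapply(c(1, 0.1, 0.01, 0.001), function(tp)
    generationsToConvergence(populationState(ZZ = 0.5, WZ = 0.5), p,
                             tolPP = tp)$generations, numeric(1))
  expect_true(all(diff(gens) >= 0))
})

test_that("threshold times order by founder composition", {
  p <- DemographicParams(alpha = 0.04, sigmaA = 0.6, sigma0 = 1, phi = 1.2)
  expect_equal(timeToThreshold(populationState(ZZ = 600, WZ = 600), p, 1000), 0)
  tIS <- timeToThreshold(populationState(IS = 100, WZ = 100), p, 1000)
  tZZ <- timeToThreshold(populationState(ZZ = 100, WZ = 100), p, 1000)
  expect_lt(tIS, tZZ)
  # doubling recruitment never slows the population down
  p2 <- DemographicParams(alpha = 0.04, sigmaA = 0.6, sigma0 = 1, phi = 2.4)
  expect_lte(timeToThreshold(populationState(ZZ = 100, WZ = 100), p2, 1000),
             tZZ)
  expect_error(
    timeToThreshold(populationState(ZZ = 100, WZ = 100),
                    DemographicParams(sigmaA = 0.3, phi = 0.5), 1000),
    "not growing")
})

test_that("stochastic simulation tracks the deterministic mean", {
  p <- DemographicParams(alpha = 0.04, sigmaA = 0.6, sigma0 = 1, phi = 1.2)
  init <- populationState(ZZ = 500, IS = 20, WZ = 500, WW = 10)
  det <- simulateTrajectory(init, p, nSteps = 5)
  nrep <- 200
  finals <- matrix(NA_real_, nrep, 4)
  set.seed(99)
  for (r in seq_len(nrep))
    finals[r, ] <- finalState(simulateTrajectory(init, p, nSteps = 5,
                                                 mode = "stochastic"))
  mn <- colMeans(finals)
  se <- apply(finals, 2, stats::sd) / sqrt(nrep)
  expect_true(all(abs(mn - finalState(det)) < 3.5 * se + 1e-9))
})

test_that("stochastic runs are seed-reproducible and flag extinction", {
  p <- DemographicParams(alpha = 0.04, sigmaA = 0.6, sigma0 = 1, phi = 1.2)
  init <- populationState(ZZ = 50, WZ = 50)
  a <- simulateTrajectory(init, p, 10, mode = "stochastic", seed = 42)
  b <- simulateTrajectory(init, p, 10, mode = "stochastic", seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  tiny <- simulateTrajectory(populationState(ZZ = 1, WZ = 1),
                             DemographicParams(sigmaA = 0.01, sigma0 = 0.01,
                                               phi = 0.5),
                             nSteps = 50, mode = "stochastic", seed = 3)
  expect_true(isExtinct(tiny))
  expect_lt(nrow(as.data.frame(tiny)), 51)
})

test_that("alpha is recovered as twice the intersex fraction", {
  expect_equal(estimateAlphaFromCohort(0.0204), 0.0408)
  expect_equal(estimateAlphaFromCohort(0), 0)
  expect_error(estimateAlphaFromCohort(0.6), "0.5")
})
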