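test_that("expected counts follow the null ratio", {
  expect_equal(expectedCounts(83, c(3, 1)), c(62.25, 20.75))
  expect_equal(expectedCounts(0, c(3, 1)), c(0, 0))
  expect_equal(expectedCounts(61, c(3, 1)), c(45.75, 15.25))
  expect_error(expectedCounts(10, numeric(0)), "positive")
  expect_error(expectedCounts(10, c(3, 0)), "positive")
})

test_that("uncorrected chi-square reproduces the published progeny p-values", {
  ps <- vapply(table1Counts, function(o) pValue(chiSquareGof(o, c(3, 1))),
               numeric(1))
  expect_equal(round(ps, 2), table1P)
  expect_equal(chisqStatistic(chiSquareGof(c(66, 17), c(3, 1))),
               0.9036145, tolerance = 1e-6)
})

test_that("chi-square GOF agrees with the stats::chisq.test oracle", {
  cases <- list(list(o = c(66, 17), r = c(3, 1)),
                list(o = c(42, 19), r = c(3, 1)),
                list(o = c(10, 25, 12), r = c(1, 2, 1)),
                list(o = c(5, 5), r = c(1, 1)))
  for (cs in cases) {
    ref <- suppressWarnings(stats::chisq.test(cs$o, p = cs$r / sum(cs$r),
                                              correct = FALSE))
    res <- chiSquareGof(cs$o, cs$r)
    expect_equal(chisqStatistic(res), unname(ref$statistic))
    expect_equal(pValue(res), unname(ref$p.value))
  }
})

test_that("chi-square statistic and p behave as required", {
  # O = E exactly
  res <- chiSquareGof(c(60, 20), c(3, 1))
  expect_equal(chisqStatistic(res), 0)
  expect_equal(pValue(res), 1)
  # invariant to scaling the ratio weights
  expect_equal(chisqStatistic(chiSquareGof(c(66, 17), c(3, 1))),
               chisqStatistic(chiSquareGof(c(66, 17), c(30, 10))))
  expect_equal(pValue(chiSquareGof(c(66, 17), c(3, 1))),
               pValue(chiSquareGof(c(66, 17), c(30, 10))))
  # p strictly decreasing in the statistic at fixed df
  stats <- c(0.1, 0.5, 1, 2, 5)
  ps <- stats::pchisq(stats, 1, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  expect_error(chiSquareGof(c(5), c(1)), "2 categories")
})

test_that("statistic matches brute-force enumeration on small totals", {
  # enumerate every 2-category outcome of n = 28 under a 3:1 null
  n <- 28
  enumStat <- vapply(0:n, function(k) {
    E <- n * c(3, 1) / 4
    sum((c(k, n - k) - E)^2 / E)  # independent hand formula
  }, numeric(1))
  for (k in c(0, 10, 17, 21, 28))
    expect_equal(chisqStatistic(chiSquareGof(c(k, n - k), c(3, 1))),
                 enumStat[k + 1])
  # the exact multinomial tail is asymptotically tracked by pchisq
  obs <- 17
  pExact <- sum(stats::dbinom(0:n, n, 0.75)[enumStat >= enumStat[obs + 1] - 1e-12])
  expect_lt(abs(pExact - pValue(chiSquareGof(c(obs, n - obs), c(3, 1)))),
            0.06)
})

test_that("cohort tallies reproduce the native-population WW percentages", {
  for (loc in names(table3Females)) {
    cnt <- table3Females[[loc]]
    tal <- tallyCohort(makeCohort(nMale = 5, nWZ = cnt[1], nWW = cnt[2]))
    expect_equal(tal@wwPercent, unname(table3WWpct[loc]))
  }
})

test_that("ratio labels use nearest-integer k:1 style", {
  tal <- tallyCohort(makeCohort(nMale = 5, nWZ = 33, nWW = 15))
  expect_equal(tal@wzWwRatioLabel, "2:1")  # pond table: 33 WZ + 15 WW
  expect_equal(tal@wzWwRatio, 33 / 15)
  tal2 <- tallyCohort(makeCohort(nMale = 412, nWZ = 700, nWW = 104))
  expect_equal(tal2@fmRatioLabel, "2:1")
  # all-male cohort: F:M undefined, flagged
  tal3 <- tallyCohort(makeCohort(nMale = 10))
  expect_true(is.na(tal3@fmRatio))
  expect_equal(tal3@fmRatioLabel, "-")
})

test_that("tallies exclude undetermined genotypes but keep phenotypes", {
  tal <- tallyCohort(makeCohort(nMale = 3, nIntersex = 2, nWZ = 10,
                                nWW = 2, nFemaleNA = 4))
  expect_equal(tal@phenotypeCounts[["female"]], 16)
  expect_equal(tal@phenotypeCounts[["intersex"]], 2)
  expect_equal(unname(tal@genotypeCounts), c(10L, 2L))
  expect_equal(tal@nExcluded, 4L)
  expect_error(tallyCohort(makeCohort(nMale = 2), site = "nowhere"),
               "no 'site' column|empty cohort")
})

test_that("progeny report recovers the published table per progeny", {
  rec <- do.call(rbind, lapply(seq_along(table1Counts), function(i) {
    o <- table1Counts[[i]]
    data.frame(site = paste0("progeny", i),
               genotype = c(rep("WZ", o[1]), rep("WW", o[2])))
  }))
  rep <- progenyRatioReport(rec)
  expect_equal(nrow(rep), 3)
  expect_equal(round(rep$p, 2), table1P)
  expect_equal(rep$n, c(83, 68, 61))
  expect_equal(rep$obs_WW, c(17, 12, 19))
})

test_that("progeny report warns and skips ungenotyped progenies", {
  rec <- rbind(data.frame(site = "a", genotype = c("WZ", "WZ", "WW")),
               data.frame(site = "b", genotype = NA_character_))
  expect_warning(rep <- progenyRatioReport(rec), "skipped")
  expect_equal(rep$progeny, "a")
})

test_that("the 3:1 test holds its nominal size and rejects a 1:1 truth", {
  set.seed(101)
  rej <- replicate(500, {
    o <- as.integer(rmultinom(1, 80, c(3, 1) / 4))
    pValue(chiSquareGof(o, c(3, 1))) < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  rejPower <- replicate(100, {
    o <- as.integer(rmultinom(1, 200, c(1, 1) / 2))
    pValue(chiSquareGof(o, c(3, 1))) < 0.05
  })
  expect_gt(mean(rejPower), 0.9)
})

test_that("the three-category 1:2:1 test is available", {
  rec <- data.frame(site = "p",
                    genotype = c(rep("ZZ", 22), rep("WZ", 40), rep("WW", 18)))
  rep <- progenyRatioReport(rec, categories = "three")
  expect_equal(rep$df, 2L)
  expect_gt(rep$p, 0.05)
})
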