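sched21 <- mortalitySchedule(c(0.5, 0))
P21 <- assembleP(buildAgeU(sched21), buildM(sched21))

test_that("accumulated moments match hand enumeration on the two-class chain", {
  # moment_consistent, v = 1, credit 1/2: reward is 0.5 w.p. 1/2 (die
  # first year) or 1.5 w.p. 1/2 (survive one year, then die)
  R <- binaryRewards(c(1, 1), P21, mode = "moment_consistent")
  rho <- accumulateMoments(P21, R)
  expect_equal(momentVector(rho, 1)[1], 1.0, tolerance = 1e-14)
  expect_equal(momentVector(rho, 2)[1], 1.25, tolerance = 1e-14)
  expect_equal(momentVector(rho, 3)[1], 1.75, tolerance = 1e-14)
  # all-zero rewards give all-zero moments
  R0 <- binaryRewards(c(0, 0), P21)
  rho0 <- accumulateMoments(P21, R0)
  for (k in 1:3) expect_equal(momentVector(rho0, k), c(0, 0))
  expect_error(accumulateMoments(P21, R, maxOrder = 4), "order")
})

test_that("the general recursion reproduces the order-1..3 special-case formulas", {
  set.seed(5)
  for (rep in 1:20) {
    ch <- randomChain()
    R <- binaryRewards(runif(ch$omega), ch$P,
                       mode = sample(c("paper_literal", "moment_consistent"), 1),
                       deathCredit = runif(1))
    rho <- accumulateMoments(ch$P, R)
    oracle <- specialCaseMoments(ch$P, R)
    for (k in 1:3)
      expect_equal(momentVector(rho, k), oracle[[k]], tolerance = 1e-13)
  }
})

test_that("unit reward on every transition recovers the longevity moments", {
  set.seed(9)
  for (rep in 1:10) {
    ch <- if (rep %% 2) randomChain() else randomOpenChain()
    eta <- longevityMoments(fundamentalMatrix(ch$U))
    R <- binaryRewards(rep(1, ch$omega), ch$P, deathCredit = 1)
    rho <- accumulateMoments(ch$P, R)
    expect_equal(momentVector(rho, 1), eta@eta1, tolerance = 1e-10)
    expect_equal(momentVector(rho, 2), eta@eta2, tolerance = 1e-10)
    expect_equal(momentVector(rho, 3), eta@eta3, tolerance = 1e-10)
    # survival-only unit reward counts lifetime minus the final step
    Rs <- binaryRewards(rep(1, ch$omega), ch$P, deathCredit = 0)
    expect_equal(momentVector(accumulateMoments(ch$P, Rs), 1),
                 eta@eta1 - 1, tolerance = 1e-10)
  }
})

test_that("scaling rewards by c scales moment k by c^k, mean by c, skewness not at all", {
  set.seed(13)
  ch <- randomChain(omega = 3, alpha = 2)
  v <- runif(3)
  R <- binaryRewards(v, ch$P, mode = "moment_consistent")
  cval <- 2.7
  Rs <- rewardMomentSet(lapply(1:3, function(k) cval^k * rewardMoment(R, k)),
                        R@omega, R@alpha)
  rho <- accumulateMoments(ch$P, R)
  rhoS <- accumulateMoments(ch$P, Rs)
  for (k in 1:3)
    expect_equal(momentVector(rhoS, k), cval^k * momentVector(rho, k),
                 tolerance = 1e-12)
  st <- lifetimeStatistics(rho)
  stS <- lifetimeStatistics(rhoS)
  expect_equal(stS@mean, cval * st@mean, tolerance = 1e-12)
  expect_equal(stS@variance, cval^2 * st@variance, tolerance = 1e-12)
  expect_equal(stS@skewness, st@skewness, tolerance = 1e-9)
})

test_that("mean healthy longevity is monotone in prevalence", {
  set.seed(17)
  for (rep in 1:10) {
    ch <- randomChain()
    v <- runif(ch$omega, 0, 0.9)
    bump <- v + runif(ch$omega, 0, 1 - max(v))
    r1 <- momentVector(accumulateMoments(ch$P, binaryRewards(v, ch$P)), 1)
    r1b <- momentVector(accumulateMoments(ch$P, binaryRewards(bump, ch$P)), 1)
    expect_true(all(r1b - r1 > -1e-12))
  }
})

test_that("lifetimeStatistics computes the summary statistics and missing rules", {
  rho <- new("MomentVectorSet", rho = list(2, 6), ages = numeric())
  st <- lifetimeStatistics(rho)
  expect_equal(st@variance, 2)
  expect_equal(st@sd, sqrt(2))
  expect_equal(st@cv, sqrt(2) / 2)
  expect_true(is.na(st@skewness))  # order 3 not supplied
  # symmetric case has zero skewness
  st2 <- lifetimeStatistics(new("MomentVectorSet",
                                rho = list(1, 2, 4), ages = numeric()))
  expect_equal(st2@skewness, 0)
  # degenerate reward: variance 0, skewness missing, cv missing at mean 0
  st3 <- lifetimeStatistics(new("MomentVectorSet",
                                rho = list(c(0, 2), c(0, 4), c(0, 8)),
                                ages = numeric()))
  expect_equal(st3@variance, c(0, 0))
  expect_true(is.na(st3@cv[1]))
  expect_true(all(is.na(st3@skewness)))
  # inconsistent moments beyond tolerance raise an error
  expect_error(lifetimeStatistics(new("MomentVectorSet",
                                      rho = list(2, 1), ages = numeric())),
               "inconsistent")
  # tiny negative variance is clamped with a warning
  expect_warning(stc <- lifetimeStatistics(new("MomentVectorSet",
                                               rho = list(1, 1 - 1e-12),
                                               ages = numeric())),
                 "clamped")
  expect_equal(stc@variance, 0)
})

test_that("variance decomposes into among- plus within-trajectory parts", {
  set.seed(19)
  for (rep in 1:10) {
    ch <- randomChain()
    R <- binaryRewards(runif(ch$omega), ch$P,
                       mode = sample(c("paper_literal", "moment_consistent"), 1))
    d <- decomposeVariance(ch$P, R)
    expect_equal(d$among + d$within, d$total, tolerance = 1e-12)
    expect_true(all(d$within > -1e-12))
    expect_true(all(d$among > -1e-12))
    # feeding the mean-fixed version of the rewards leaves no within part
    dFixed <- decomposeVariance(ch$P, fixedRewards(R))
    expect_equal(dFixed$within, rep(0, ch$omega))
  }
})

test_that("single open-ended state with deterministic per-step reward has only among-trajectory variance", {
  p <- 0.5
  sched <- mortalitySchedule(p, openEnded = TRUE)
  P <- assembleP(buildAgeU(sched), buildM(sched))
  R <- binaryRewards(1, P, deathCredit = 0)
  d <- decomposeVariance(P, R)
  expect_equal(d$within, 0)
  expect_equal(d$among, p / (1 - p)^2, tolerance = 1e-12)  # geometric variance
})

test_that("deterministic lifetime leaves only within-trajectory variance", {
  # all survive until the forced terminal death: exactly one trajectory
  sched <- mortalitySchedule(c(1, 1, 0))
  P <- assembleP(buildAgeU(sched), buildM(sched))
  R <- binaryRewards(c(0.3, 0.6, 0.2), P, mode = "moment_consistent")
  d <- decomposeVariance(P, R)
  expect_equal(d$among, rep(0, 3), tolerance = 1e-14)
  expect_equal(d$within, d$total, tolerance = 1e-14)
  expect_true(d$total[1] > 0)
})

test_that("sullivan expectancy sums prevalence-weighted person-years from a starting class", {
  expect_equal(sullivanExpectancy(c(1, 0.5), c(1, 1), 1), 1.5)
  expect_equal(sullivanExpectancy(c(1, 0.5), c(0, 0), 1), 0)
  expect_equal(sullivanExpectancy(c(1, 0.5), c(1, 0.4), 2), 0.2)
  expect_error(sullivanExpectancy(c(1, 0.5), c(1, 1), 3), "out of range")
  expect_error(sullivanExpectancy(c(1, -0.5), c(1, 1), 1), "nonnegative")
})

test_that("chain occupancy person-years reproduce the mean healthy longevity", {
  set.seed(23)
  for (rep in 1:10) {
    ch <- randomChain(ageOnly = TRUE)
    v <- runif(ch$omega)
    N <- fundamentalMatrix(ch$U)
    rho1 <- momentVector(accumulateMoments(ch$P, binaryRewards(v, ch$P)), 1)
    for (x in seq_len(ch$omega)) {
      L <- occupancyPersonYears(N, ch$sched, deathCredit = 0.5, start = x)
      expect_equal(sullivanExpectancy(L, v, x), rho1[x], tolerance = 1e-12)
    }
  }
})

test_that("healthyLongevity wrapper runs the full binary and interval pipelines", {
  sched <- mortalitySchedule(c(0.9, 0.8, 0), ages = 70:72)
  st <- healthyLongevity(sched, prevalence = c(0.8, 0.7, 0.6))
  expect_s4_class(st, "HealthStatistics")
  expect_equal(st@ages, 70:72)
  expect_equal(st@meta$mode, "paper_literal")
  expect_equal(st@meta$truncationAge, 72)
  # total longevity via v = 1 matches the longevity moments
  tot <- healthyLongevity(sched, prevalence = rep(1, 3), deathCredit = 1)
  eta <- longevityMoments(fundamentalMatrix(buildAgeU(sched)))
  expect_equal(tot@mean, eta@eta1, tolerance = 1e-12)
  expect_error(healthyLongevity(sched), "exactly one")
  expect_error(healthyLongevity(sched, prevalence = c(1, 1)), "one entry per")
})
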