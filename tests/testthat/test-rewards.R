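sched21 <- mortalitySchedule(c(0.5, 0))
P21 <- assembleP(buildAgeU(sched21), buildM(sched21))

test_that("binary rewards credit v on living and v * credit on dying transitions", {
  sched <- mortalitySchedule(0.5, openEnded = TRUE)
  P <- assembleP(buildAgeU(sched), buildM(sched))
  R <- binaryRewards(0.3, P)
  expect_equal(rewardMoment(R, 1)[1, 1], 0.3)    # survival self-transition
  expect_equal(rewardMoment(R, 1)[2, 1], 0.15)   # half-period death credit
  expect_equal(rewardMoment(R, 2), rewardMoment(R, 1))  # paper_literal
  expect_equal(rewardMoment(R, 3), rewardMoment(R, 1))
  # moment_consistent: death entries scale as credit^k, living stay v
  Rm <- binaryRewards(0.3, P, mode = "moment_consistent")
  expect_equal(rewardMoment(Rm, 1)[2, 1], 0.15)
  expect_equal(rewardMoment(Rm, 2)[2, 1], 0.3 * 0.25)
  expect_equal(rewardMoment(Rm, 3)[2, 1], 0.3 * 0.125)
  expect_equal(rewardMoment(Rm, 2)[1, 1], 0.3)
})

test_that("binary reward edge cases: full health, zero prevalence, bad input", {
  R1 <- rewardMoment(binaryRewards(c(1, 1), P21), 1)
  expect_equal(R1[2, 1], 1)          # survive class 1
  expect_equal(R1[3, 1], 0.5)        # die from class 1
  expect_equal(R1[3, 2], 0.5)        # die from class 2 (forced)
  expect_true(all(rewardMoment(binaryRewards(c(0, 0), P21), 1) == 0))
  expect_true(all(rewardMoment(binaryRewards(c(0, 0), P21), 3) == 0))
  expect_error(binaryRewards(c(0.5, 1.2), P21), "\\[0, 1\\]")
})

test_that("rewards vanish on impossible transitions and absorbing-origin columns", {
  set.seed(3)
  for (rep in 1:10) {
    ch <- randomChain()
    R <- binaryRewards(runif(ch$omega), ch$P,
                       mode = sample(c("paper_literal", "moment_consistent"), 1))
    for (k in 1:3) {
      Rk <- rewardMoment(R, k)
      expect_true(all(Rk[ch$P == 0] == 0))
      expect_true(all(Rk[, (ch$omega + 1):(ch$omega + ch$alpha)] == 0))
    }
  }
})

test_that("per-transition reward variances are nonnegative in both modes", {
  v <- c(0.25, 0.8)
  for (mode in c("paper_literal", "moment_consistent")) {
    R <- binaryRewards(v, P21, mode = mode)
    varMat <- rewardMoment(R, 2) - rewardMoment(R, 1)^2
    expect_true(all(varMat > -1e-15))
    # living transition variance is exactly v(1-v)
    expect_equal(varMat[2, 1], v[1] * (1 - v[1]))
  }
  # moment_consistent death-transition variance is v(1-v) * credit^2
  Rm <- binaryRewards(v, P21, mode = "moment_consistent")
  varMat <- rewardMoment(Rm, 2) - rewardMoment(Rm, 1)^2
  expect_equal(varMat[3, 1], v[1] * (1 - v[1]) * 0.25)
})

test_that("combinePrevalence sums component prevalences of a proper subset", {
  prev <- list(H = 0.5, C = 0.3, I = 0.2)
  expect_equal(combinePrevalence(prev, c("H", "C")), 0.8)
  expect_equal(combinePrevalence(prev, "H"), 0.5)  # identity on singletons
  expect_error(combinePrevalence(prev, c("H", "C", "I")), "degenerate")
  expect_error(combinePrevalence(prev, integer(0)), "degenerate")
  expect_error(combinePrevalence(list(A = 0.7, B = 0.6), "A"), "more than 1")
  # additivity over disjoint subsets
  p4 <- list(a = c(0.1, 0.2), b = c(0.2, 0.1), c = c(0.3, 0.3), d = c(0.1, 0.05))
  expect_equal(combinePrevalence(p4, c("a", "b")) + combinePrevalence(p4, "c"),
               combinePrevalence(p4, c("a", "b", "c")))
})

test_that("countGroupings equals the number of nonempty proper subsets", {
  expect_equal(countGroupings(2), 2)
  # oracle: enumerate all nonempty proper subsets of 3 outcomes
  subsets <- unlist(lapply(1:2, function(k) utils::combn(3, k, simplify = FALSE)),
                    recursive = FALSE)
  expect_equal(countGroupings(3), length(subsets))
  expect_equal(countGroupings(5), 2^5 - 2)
  expect_error(countGroupings(1), ">= 2")
})

test_that("ordinalBinarySplits returns the n-1 order-preserving cuts", {
  splits <- ordinalBinarySplits(c("L", "M", "H"))
  expect_length(splits, 2)
  expect_equal(splits[[1]], list(low = "L", high = c("M", "H")))
  expect_equal(splits[[2]], list(low = c("L", "M"), high = "H"))
  expect_length(ordinalBinarySplits(2), 1)
  expect_length(ordinalBinarySplits(4), 3)
  expect_error(ordinalBinarySplits(1), "at least 2")
})

test_that("interval rewards carry empirical raw moments with the death credit", {
  # age-class sample {2, 4}: m1 = 3, m2 = 10, m3 = 36
  R <- intervalRewards(c(3, 3), c(10, 10), c(36, 36), P21)
  expect_equal(rewardMoment(R, 1)[2, 1], 3)
  expect_equal(rewardMoment(R, 2)[2, 1], 10)
  expect_equal(rewardMoment(R, 3)[2, 1], 36)
  expect_equal(rewardMoment(R, 1)[3, 1], 1.5)   # half credit at death
  expect_equal(rewardMoment(R, 2)[3, 1], 5)     # paper_literal: m_k * credit
  Rm <- intervalRewards(c(3, 3), c(10, 10), c(36, 36), P21,
                        mode = "moment_consistent")
  expect_equal(rewardMoment(Rm, 2)[3, 1], 10 * 0.25)
  expect_error(intervalRewards(c(1, 1), c(0.5, 0.5), c(1, 1), P21),
               "negative variance|inconsistent")
})

test_that("a constant outcome c reduces to c times the full-health binary case", {
  cval <- 7
  Rc <- intervalRewards(rep(cval, 2), rep(cval^2, 2), rep(cval^3, 2), P21,
                        mode = "moment_consistent")
  Rb <- binaryRewards(c(1, 1), P21, mode = "moment_consistent")
  rhoC <- accumulateMoments(P21, Rc)
  rhoB <- accumulateMoments(P21, Rb)
  for (k in 1:3)
    expect_equal(momentVector(rhoC, k), cval^k * momentVector(rhoB, k),
                 tolerance = 1e-12)
})

test_that("fixedRewards keeps R1 and takes elementwise powers for higher moments", {
  R <- binaryRewards(c(0.3, 0.3), P21)
  Rf <- fixedRewards(R)
  expect_equal(rewardMoment(Rf, 1), rewardMoment(R, 1))
  expect_equal(rewardMoment(Rf, 2), rewardMoment(R, 1)^2)
  expect_equal(rewardMoment(Rf, 3), rewardMoment(R, 1)^3)
  expect_equal(rewardMoment(Rf, 2)[2, 1], 0.09)
  expect_equal(rewardMoment(Rf, 3)[2, 1], 0.027)
  # per-transition variance collapses to zero
  expect_true(all(abs(rewardMoment(Rf, 2) - rewardMoment(Rf, 1)^2) < 1e-15))
  # all-ones and all-zero fixed points
  R1s <- binaryRewards(c(1, 1), P21, deathCredit = 1)
  expect_equal(rewardMoment(fixedRewards(R1s), 2), rewardMoment(R1s, 1))
  expect_true(all(rewardMoment(fixedRewards(binaryRewards(c(0, 0), P21)), 3) == 0))
})
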