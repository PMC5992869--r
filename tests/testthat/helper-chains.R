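# Shared fixtures: random absorbing chains and reward samplers built in code.

# A random absorbing chain that dies out in at most omega steps (no
# open-ended class): either an age-classified chain (subdiagonal U) or a
# general acyclic stage chain (strictly lower-triangular U).
randomChain <- function(omega = sample(1:3, 1), alpha = sample(1:2, 1),
                        ageOnly = FALSE) {
  if (ageOnly || stats::runif(1) < 0.5) {
    p <- c(if (omega > 1) stats::runif(omega - 1, 0.05, 0.95), 0)
    sched <- mortalitySchedule(p)
    U <- buildAgeU(sched)
  } else {
    sched <- NULL
    U <- matrix(0, omega, omega)
    if (omega > 1) {
      for (j in seq_len(omega - 1)) {
        w <- stats::runif(omega - j)
        U[(j + 1):omega, j] <- w / sum(w) * stats::runif(1, 0.1, 0.9)
      }
    }
  }
  q <- 1 - colSums(U)
  M <- if (alpha == 1L) matrix(q, nrow = 1) else {
    f <- stats::runif(omega)
    rbind(f * q, (1 - f) * q)
  }
  list(U = U, M = M, P = assembleP(U, M), omega = omega, alpha = alpha,
       sched = sched)
}

# A random open-ended age chain (geometric tail).
randomOpenChain <- function(omega = sample(1:3, 1)) {
  p <- stats::runif(omega, 0.05, 0.9)
  sched <- mortalitySchedule(p, openEnded = TRUE)
  U <- buildAgeU(sched)
  M <- buildM(sched)
  list(U = U, M = M, P = assembleP(U, M), omega = omega, alpha = 1L,
       sched = sched)
}

# Independent special-case implementations of the order-1..3 moment
# formulas (used as oracles for the general recursion).
specialCaseMoments <- function(P, R) {
  omega <- R@omega
  s <- nrow(P)
  tidx <- seq_len(omega)
  Z <- cbind(diag(omega), matrix(0, omega, s - omega))
  U <- P[tidx, tidx, drop = FALSE]
  N <- solve(diag(omega) - U)
  Nt <- t(N)
  ones <- rep(1, s)
  Rt <- lapply(R@moments, function(Rk) Z %*% Rk %*% t(Z))
  Rm <- R@moments
  r1 <- Nt %*% (Z %*% t(P * Rm[[1]]) %*% ones)
  r2 <- Nt %*% (Z %*% t(P * Rm[[2]]) %*% ones + 2 * t(U * Rt[[1]]) %*% r1)
  r3 <- Nt %*% (Z %*% t(P * Rm[[3]]) %*% ones +
                  3 * t(U * Rt[[2]]) %*% r1 + 3 * t(U * Rt[[1]]) %*% r2)
  list(as.numeric(r1), as.numeric(r2), as.numeric(r3))
}

# The default synthetic cohort with its chain and binary reward set.
syntheticBinaryCase <- function(mode = "paper_literal", seed = 1L) {
  cohort <- generateSyntheticCohort(syntheticCohortSpec(seed = seed))
  sched <- cohort$mortality
  P <- assembleP(buildAgeU(sched), buildM(sched))
  v <- unname(cohort$prevalence)
  list(cohort = cohort, sched = sched, P = P, v = v,
       R = binaryRewards(v, P, mode = mode),
       sampler = binaryRewardSampler(v, P, mode = mode))
}
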