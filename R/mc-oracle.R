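#' Per-transition reward samplers
#'
#' A reward sampler realises the random per-transition rewards as explicit
#' discrete distributions, one per transition of the chain, for use by the
#' simulation and exhaustive-enumeration reference implementations. A
#' sampler is a list-matrix: entry `(i, j)` is `list(values, probs)` for
#' the reward collected on the transition from state `j` to state `i`
#' (`NULL` means a fixed reward of 0). Samplers are meant to be
#' moment-compatible with the [RewardMomentSet] they mirror; use
#' [samplerMoments()] to verify.
#'
#' @param s total number of states (`omega + alpha`).
#' @return an empty `RewardSampler` (all rewards fixed at 0).
#' @seealso [setSamplerReward()], [binaryRewardSampler()],
#'   [fixedRewardSampler()], [dalyRewardSampler()]
#' @export
rewardSampler <- function(s) {
  dist <- vector("list", s * s)
  dim(dist) <- c(s, s)
  structure(list(dist = dist, s = as.integer(s)), class = "RewardSampler")
}

#' @rdname rewardSampler
#' @param sampler a `RewardSampler`.
#' @param i,j destination and origin state of the transition.
#' @param values,probs support and probabilities of the discrete reward
#'   distribution (probs must sum to 1). Scalars define a fixed reward.
#' @export
setSamplerReward <- function(sampler, i, j, values, probs = rep(1 / length(values), length(values))) {
  stopifnot(inherits(sampler, "RewardSampler"))
  if (length(values) != length(probs))
    stop("values and probs must have the same length")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probs must sum to 1")
  sampler$dist[[i, j]] <- list(values = as.numeric(values),
                               probs = as.numeric(probs))
  sampler
}

#' Raw moments implied by a reward sampler
#'
#' @param sampler a `RewardSampler`.
#' @param k moment order.
#' @return `s x s` matrix of kth raw moments `E[r_ij^k]`.
#' @export
samplerMoments <- function(sampler, k) {
  stopifnot(inherits(sampler, "RewardSampler"))
  s <- sampler$s
  out <- matrix(0, s, s)
  for (idx in seq_len(s * s)) {
    d <- sampler$dist[[idx]]
    if (!is.null(d)) out[idx] <- sum(d$probs * d$values^k)
  }
  out
}

#' Sampler realising binary prevalence rewards
#'
#' Living transitions out of class `j` grant one year with probability
#' `v_j`. The death transition grants, under `"moment_consistent"`, a
#' reward of `deathCredit` with probability `v_j`; under
#' `"paper_literal"`, a full year with probability `v_j * deathCredit`
#' (the discrete distribution whose kth raw moment is `v_j * deathCredit`
#' for every `k`, matching that convention's moment matrices exactly).
#'
#' @inheritParams binaryRewards
#' @return a `RewardSampler` moment-compatible with
#'   `binaryRewards(v, P, mode, deathCredit)`.
#' @export
binaryRewardSampler <- function(v, P,
                                mode = c("paper_literal", "moment_consistent"),
                                deathCredit = 0.5) {
  mode <- match.arg(mode)
  s <- nrow(P)
  omega <- length(v)
  smp <- rewardSampler(s)
  for (j in seq_len(omega)) {
    for (i in which(P[, j] > 0)) {
      if (i <= omega) {
        smp <- setSamplerReward(smp, i, j, c(1, 0), c(v[j], 1 - v[j]))
      } else if (mode == "paper_literal") {
        pr <- v[j] * deathCredit
        smp <- setSamplerReward(smp, i, j, c(1, 0), c(pr, 1 - pr))
      } else {
        smp <- setSamplerReward(smp, i, j, c(deathCredit, 0), c(v[j], 1 - v[j]))
      }
    }
  }
  smp
}

#' Sampler with every reward fixed at its mean
#'
#' @param R1 first-moment reward matrix (`s x s`).
#' @param P full transition matrix.
#' @param omega number of transient states.
#' @return a `RewardSampler` granting `R1[i, j]` deterministically on each
#'   possible transition out of a transient state.
#' @export
fixedRewardSampler <- function(R1, P, omega) {
  s <- nrow(P)
  smp <- rewardSampler(s)
  for (j in seq_len(omega))
    for (i in which(P[, j] > 0))
      smp <- setSamplerReward(smp, i, j, R1[i, j], 1)
  smp
}

#' Exact distribution of remaining longevity
#'
#' The distribution of the time to absorption, starting from a given
#' transient state, computed by propagating the state distribution through
#' `U`: the probability of dying at step `t` is the transient mass lost
#' between steps `t - 1` and `t`.
#'
#' @param U transient matrix.
#' @param start starting state index.
#' @param tol stop once the remaining transient mass falls below this.
#' @param maxT hard cap on the support.
#' @return list with `values` (steps `1, 2, ...`) and `probs`.
#' @export
lifetimeDistribution <- function(U, start, tol = 1e-14, maxT = 100000L) {
  omega <- nrow(U)
  u <- numeric(omega)
  u[start] <- 1
  probs <- numeric(0)
  t <- 0L
  while (sum(u) > tol && t < maxT) {
    t <- t + 1L
    u1 <- as.numeric(U %*% u)
    probs[t] <- sum(u) - sum(u1)
    u <- u1
  }
  if (sum(u) > tol)
    stop("longevity distribution did not converge within ", maxT, " steps")
  list(values = seq_len(t), probs = probs)
}

#' Sampler realising the DALY rewards
#'
#' Survival transitions carry the Bernoulli disability reward
#' (severity with probability prevalence); cause-1 death transitions carry
#' the exact distribution of remaining longevity under the standard
#' schedule at the age of death; cause-2 death transitions carry nothing.
#' The standard schedule must absorb in bounded steps (no open-ended
#' class) so that the years-of-life-lost distribution has finite support.
#'
#' @param spec a [DalySpec].
#' @return a `RewardSampler` on `omega + 2` states, moment-compatible with
#'   [dalyRewards()].
#' @export
dalyRewardSampler <- function(spec) {
  stopifnot(is(spec, "DalySpec"))
  if (spec@standard@openEnded)
    stop("exact DALY sampler needs a standard schedule without an open-ended class")
  omega <- length(spec@mortality@surv)
  chain <- .dalyChain(spec)
  Us <- buildAgeU(spec@standard)
  smp <- rewardSampler(omega + 2L)
  for (j in seq_len(omega)) {
    for (i in which(chain$P[, j] > 0)) {
      if (i <= omega) {
        smp <- setSamplerReward(smp, i, j, c(spec@severity[j], 0),
                                c(spec@prevalence[j], 1 - spec@prevalence[j]))
      } else if (i == omega + 1L) {
        d <- lifetimeDistribution(Us, j)
        smp <- setSamplerReward(smp, i, j, d$values, d$probs)
      }
      ## cause-2 death: reward stays fixed 0
    }
  }
  smp
}

#' Monte Carlo simulation of lifetime accumulated reward
#'
#' Simulates `n` independent individuals moving through the chain from a
#' common starting state, sampling a reward on every transition (including
#' the transition into death) and accumulating until absorption. Absorbing
#' states collect nothing. Fully reproducible for a fixed seed.
#'
#' @param P full transition matrix (column-stochastic).
#' @param sampler a `RewardSampler` covering every possible transition.
#' @param start starting (transient) state index.
#' @param n number of replicates.
#' @param seed integer seed for the run.
#' @param maxSteps cap on the number of steps (default: ten times the
#'   largest expected lifetime, a guard against non-absorbing chains).
#' @return a [SimulationResult].
#' @export
simulateRewards <- function(P, sampler, start, n, seed,
                            maxSteps = NULL) {
  stopifnot(inherits(sampler, "RewardSampler"))
  s <- nrow(P)
  if (any(abs(colSums(P) - 1) > 1e-9))
    stop("P must be column-stochastic")
  ## transient states are those not mapping to themselves w.p. 1
  absorbing <- vapply(seq_len(s), function(j)
    P[j, j] == 1 && all(P[-j, j] == 0), logical(1))
  omega <- sum(!absorbing)
  if (any(which(absorbing) <= omega))
    stop("absorbing states must come after the transient states")
  if (is.null(maxSteps)) {
    N <- fundamentalMatrix(P[seq_len(omega), seq_len(omega), drop = FALSE])
    maxSteps <- max(100L, ceiling(10 * max(colSums(N))))
  }
  set.seed(as.integer(seed))
  state <- rep.int(as.integer(start), n)
  total <- numeric(n)
  alive <- rep.int(TRUE, n)
  step <- 0L
  while (any(alive)) {
    step <- step + 1L
    if (step > maxSteps)
      stop("simulation exceeded ", maxSteps,
           " steps; chain may not be absorbing")
    for (j in unique(state[alive])) {
      idx <- which(alive & state == j)
      nxt <- sample.int(s, length(idx), replace = TRUE, prob = P[, j])
      for (i in unique(nxt)) {
        ii <- idx[nxt == i]
        d <- sampler$dist[[i, j]]
        if (!is.null(d)) {
          total[ii] <- total[ii] +
            if (length(d$values) == 1L) d$values else
              sample(d$values, length(ii), replace = TRUE, prob = d$probs)
        }
      }
      state[idx] <- nxt
    }
    alive <- state <= omega
  }
  m <- vapply(1:3, function(k) mean(total^k), numeric(1))
  se <- vapply(1:3, function(k) stats::sd(total^k) / sqrt(n), numeric(1))
  new("SimulationResult", rewards = total, start = as.integer(start),
      seed = as.integer(seed), moments = m, se = se)
}

#' Exact moments of lifetime accumulated reward by exhaustive enumeration
#'
#' Enumerates every (life-course trajectory x reward realisation)
#' combination with its exact probability and returns the raw moments of
#' the accumulated reward. Requires a chain that absorbs in a bounded
#' number of steps (no open-ended class) and finite reward supports. This
#' is an independent reference implementation against which the analytic
#' moment recursion is validated.
#'
#' @param P full transition matrix.
#' @param sampler a `RewardSampler`.
#' @param start starting state index.
#' @param maxOrder highest moment order (default 3).
#' @param maxOutcomes cap on the size of any intermediate reward support.
#' @return numeric vector of raw moments `1..maxOrder`.
#' @export
enumerateExact <- function(P, sampler, start, maxOrder = 3L,
                           maxOutcomes = 1e6) {
  stopifnot(inherits(sampler, "RewardSampler"))
  s <- nrow(P)
  absorbing <- vapply(seq_len(s), function(j)
    P[j, j] == 1 && all(P[-j, j] == 0), logical(1))
  omega <- sum(!absorbing)
  momacc <- numeric(maxOrder)
  recurse <- function(j, pathProb, values, probs, depth) {
    if (j > omega) {
      for (k in seq_len(maxOrder))
        momacc[k] <<- momacc[k] + pathProb * sum(probs * values^k)
      return(invisible(NULL))
    }
    if (depth > omega)
      stop("infeasible: chain does not absorb within ", omega,
           " steps (open-ended class or cycle)")
    for (i in which(P[, j] > 0)) {
      d <- sampler$dist[[i, j]]
      if (is.null(d)) {
        nv <- values; np <- probs
      } else if (length(d$values) == 1L) {
        nv <- values + d$values; np <- probs
      } else {
        nv <- as.vector(outer(values, d$values, `+`))
        np <- as.vector(outer(probs, d$probs, `*`))
      }
      if (length(nv) > maxOutcomes)
        stop("infeasible: reward outcome space exceeds ", maxOutcomes)
      recurse(i, pathProb * P[i, j], nv, np, depth + 1L)
    }
    invisible(NULL)
  }
  recurse(as.integer(start), 1, 0, 1, 0L)
  momacc
}
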