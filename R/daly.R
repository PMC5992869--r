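#' Construct a DALY specification
#'
#' @param mortality [MortalitySchedule] of the focal population.
#' @param cause1Fraction per-age fraction of deaths due to the focal cause
#'   (cause 1), in `[0, 1]`; a scalar is recycled. The complement goes to
#'   all other causes (cause 2).
#' @param prevalence per-age prevalence of disability due to the focal
#'   cause, in `[0, 1]`; a scalar is recycled.
#' @param severity per-age disability weight in `[0, 1]` (1 = a year with
#'   the condition is equivalent to a year lost to death); scalar recycled.
#' @param standard [MortalitySchedule] of the reference population used to
#'   score years of life lost; must share the focal age grid. Defaults to
#'   the focal population's own schedule.
#' @return a [DalySpec].
#' @export
dalySpec <- function(mortality, cause1Fraction, prevalence, severity,
                     standard = mortality) {
  stopifnot(is(mortality, "MortalitySchedule"))
  if (!is(standard, "MortalitySchedule"))
    stop("a standard (reference) mortality schedule is required")
  omega <- length(mortality@surv)
  rec <- function(x) if (length(x) == 1L) rep(as.numeric(x), omega) else as.numeric(x)
  new("DalySpec", mortality = mortality,
      cause1Fraction = rec(cause1Fraction),
      prevalence = rec(prevalence), severity = rec(severity),
      standard = standard)
}

#' Moments of remaining longevity under a standard schedule
#'
#' Builds the reference chain `U_s` from the standard mortality schedule
#' and returns the first three raw moments of remaining longevity from its
#' fundamental matrix `N_s = (I - U_s)^{-1}`. These moments score the years
#' of life lost by an individual dying from the focal cause at each age.
#' The choice of reference schedule is the investigator's; using the focal
#' population's own schedule gives an internally consistent baseline.
#'
#' @param standard a [MortalitySchedule].
#' @return a [LongevityMoments].
#' @export
standardLongevity <- function(standard) {
  stopifnot(is(standard, "MortalitySchedule"))
  N <- fundamentalMatrix(buildAgeU(standard))
  longevityMoments(N, ages = standard@ages)
}

## chain pieces shared by dalyRewards and computeDaly
.dalyChain <- function(spec) {
  U <- buildAgeU(spec@mortality)
  split <- rbind(spec@cause1Fraction, 1 - spec@cause1Fraction)
  M <- buildM(spec@mortality, causeSplit = split)
  list(U = U, M = M, P = assembleP(U, M))
}

#' Reward moment matrices for disability-adjusted life years
#'
#' Builds the combined DALY reward structure on the two-cause chain
#' (absorbing state 1 = death from the focal cause, state 2 = death from
#' all other causes):
#' \itemize{
#'   \item Years lived with disability (YLD): each survival transition out
#'     of age class `j` carries a Bernoulli reward equal to the severity
#'     `s_j` with probability `v_j` (kth raw moment `s_j^k v_j`).
#'   \item Years of life lost (YLL): the transition from age class `j`
#'     into absorbing state 1 carries the remaining longevity under the
#'     standard schedule at the age of death, with raw moments
#'     `eta_k[j]`.
#'   \item Transitions into absorbing state 2 carry no reward, and no
#'     rewards accumulate after absorption.
#' }
#' Each transition carries exactly one reward type, so no cross-moments
#' arise. Optionally (`disabilityCreditAtDeath = TRUE`), the year of death
#' also carries a half-period disability credit; the cause-1 death reward
#' is then the sum of the independent YLL and credit rewards, whose raw
#' moments follow from the binomial expansion. The default is off: the
#' plain construction attaches disability to survival transitions only.
#'
#' @param spec a [DalySpec].
#' @param eta optional [LongevityMoments] under the standard schedule
#'   (computed from `spec@standard` if missing).
#' @param maxOrder number of moment matrices (up to 3).
#' @param disabilityCreditAtDeath logical, see above.
#' @param deathCredit fraction of the death period credited when
#'   `disabilityCreditAtDeath` is `TRUE`.
#' @return a [RewardMomentSet] on `omega + 2` states.
#' @export
dalyRewards <- function(spec, eta = NULL, maxOrder = 3L,
                        disabilityCreditAtDeath = FALSE, deathCredit = 0.5) {
  stopifnot(is(spec, "DalySpec"))
  validObject(spec)
  maxOrder <- as.integer(maxOrder)
  if (maxOrder < 1L || maxOrder > 3L)
    stop("maxOrder must be between 1 and 3 (standard longevity moments go to order 3)")
  if (is.null(eta)) eta <- standardLongevity(spec@standard)
  omega <- length(spec@mortality@surv)
  if (length(eta@eta1) != omega)
    stop("standard-longevity moments must be on the focal age grid (",
         omega, " classes)")
  chain <- .dalyChain(spec)
  s <- omega + 2L
  etak <- list(eta@eta1, eta@eta2, eta@eta3)
  v <- spec@prevalence
  sev <- spec@severity
  moments <- vector("list", maxOrder)
  for (k in seq_len(maxOrder)) {
    Rk <- matrix(0, s, s)
    ## YLD on survival transitions: Bernoulli(severity_j, prob v_j)
    live <- which(chain$U > 0, arr.ind = TRUE)
    if (nrow(live))
      Rk[cbind(live[, 1L], live[, 2L])] <- sev[live[, 2L]]^k * v[live[, 2L]]
    ## YLL on cause-1 death transitions
    j1 <- which(chain$M[1L, ] > 0)
    if (disabilityCreditAtDeath) {
      ## death reward = YLL + credit * disability, independent components:
      ## E[(A+B)^k] = sum_i C(k,i) E[A^i] E[B^{k-i}]
      dmom <- function(j, i) {
        if (i == 0L) 1 else deathCredit^i * sev[j]^i * v[j]
      }
      amom <- function(j, i) if (i == 0L) 1 else etak[[i]][j]
      for (j in j1)
        Rk[omega + 1L, j] <- sum(vapply(0:k, function(i)
          choose(k, i) * amom(j, i) * dmom(j, k - i), numeric(1)))
      j2 <- which(chain$M[2L, ] > 0)
      for (j in j2)
        Rk[omega + 2L, j] <- dmom(j, k)
    } else {
      if (length(j1)) Rk[omega + 1L, j1] <- etak[[k]][j1]
    }
    moments[[k]] <- Rk
  }
  rewardMomentSet(moments, omega, 2L, mode = "daly",
                  deathCredit = if (disabilityCreditAtDeath) deathCredit else 0)
}

#' Statistics of disability-adjusted life years
#'
#' Full DALY pipeline: assemble the two-cause chain, build the combined
#' YLL + YLD reward matrices, run the moment recursion, and summarise. A
#' larger mean indicates poorer health and a greater burden from the focal
#' cause. The metadata record the YLL and YLD component means (the first
#' moment is additive across the two reward types).
#'
#' @param spec a [DalySpec].
#' @param maxOrder highest moment order (default 3).
#' @param disabilityCreditAtDeath,deathCredit passed to [dalyRewards()].
#' @return a [HealthStatistics] with `meta$yllMean` and `meta$yldMean`.
#' @export
computeDaly <- function(spec, maxOrder = 3L,
                        disabilityCreditAtDeath = FALSE, deathCredit = 0.5) {
  stopifnot(is(spec, "DalySpec"))
  validObject(spec)
  chain <- .dalyChain(spec)
  eta <- standardLongevity(spec@standard)
  R <- dalyRewards(spec, eta, maxOrder = maxOrder,
                   disabilityCreditAtDeath = disabilityCreditAtDeath,
                   deathCredit = deathCredit)
  rho <- accumulateMoments(chain$P, R, maxOrder = maxOrder,
                           ages = spec@mortality@ages)
  ## component means: zero out one reward type at a time (rho_1 is linear
  ## in R_1)
  omega <- length(spec@mortality@surv)
  specYll <- spec; specYll@severity <- rep(0, omega)
  specYld <- spec; specYld@cause1Fraction <- rep(0, omega)
  Ryll <- dalyRewards(specYll, eta, maxOrder = 1L,
                      disabilityCreditAtDeath = disabilityCreditAtDeath,
                      deathCredit = deathCredit)
  Ryld <- dalyRewards(specYld, eta, maxOrder = 1L,
                      disabilityCreditAtDeath = disabilityCreditAtDeath,
                      deathCredit = deathCredit)
  yll <- momentVector(accumulateMoments(chain$P, Ryll, maxOrder = 1L), 1L)
  yld <- momentVector(accumulateMoments(chain$P, Ryld, maxOrder = 1L), 1L)
  lifetimeStatistics(rho, meta = list(
    outcome = "daly", mode = "daly",
    disabilityCreditAtDeath = disabilityCreditAtDeath,
    yllMean = yll, yldMean = yld))
}
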