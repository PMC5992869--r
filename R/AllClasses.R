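#' @import methods
NULL

#' MortalitySchedule: per-age survival probabilities of the life course
#'
#' An age- (or stage-) classified mortality schedule. `surv[j]` is the
#' probability `p_j` of surviving age class `j` and entering class `j + 1`
#' (or, for the last class of an open-ended schedule, of remaining in that
#' class). Death probability is `1 - p_j`. The time step is the class width
#' (one year for single-year-of-age data), and all longevity and reward
#' units follow it.
#'
#' @slot ages numeric vector of class labels (starting ages), strictly
#'   ascending, length `omega`.
#' @slot surv numeric vector of survival probabilities in `[0, 1]`,
#'   length `omega`.
#' @slot openEnded logical flag; if `TRUE` the last class retains its
#'   age-invariant survival probability `p_omega` (a geometric tail), which
#'   must then be `< 1` so that absorption (death) is certain.
#'
#' @seealso [mortalitySchedule()], [buildAgeU()], [readMortality()]
#' @export
setClass("MortalitySchedule",
  representation(ages = "numeric", surv = "numeric", openEnded = "logical"))

setValidity("MortalitySchedule", function(object) {
  msgs <- character()
  n <- length(object@surv)
  if (n < 1L) msgs <- c(msgs, "schedule must contain at least one age class")
  if (length(object@ages) != n)
    msgs <- c(msgs, "ages and surv must have the same length")
  if (any(!is.finite(object@surv)) ||
      any(object@surv < 0) || any(object@surv > 1))
    msgs <- c(msgs, "survival probabilities must lie in [0, 1]")
  if (n > 1L && any(diff(object@ages) <= 0))
    msgs <- c(msgs, "ages must be strictly ascending")
  if (length(object@openEnded) != 1L || is.na(object@openEnded))
    msgs <- c(msgs, "openEnded must be TRUE or FALSE")
  else if (object@openEnded && n >= 1L && object@surv[n] >= 1)
    msgs <- c(msgs,
      "open-ended last class must have survival < 1 (otherwise the chain never absorbs)")
  if (length(msgs)) msgs else TRUE
})

#' LongevityMoments: raw moments of remaining longevity by starting class
#'
#' The first three raw moments of the time to absorption (death), in time
#' steps, for an individual starting in each transient class.
#'
#' @slot eta1,eta2,eta3 numeric vectors of length `omega`: first, second and
#'   third raw moments of remaining longevity.
#' @slot ages numeric vector of class labels (may be empty).
#'
#' @seealso [longevityMoments()], [standardLongevity()]
#' @export
setClass("LongevityMoments",
  representation(eta1 = "numeric", eta2 = "numeric", eta3 = "numeric",
                 ages = "numeric"))

setValidity("LongevityMoments", function(object) {
  msgs <- character()
  n <- length(object@eta1)
  if (length(object@eta2) != n || length(object@eta3) != n)
    msgs <- c(msgs, "eta1, eta2, eta3 must have equal length")
  if (length(object@ages) && length(object@ages) != n)
    msgs <- c(msgs, "ages must be empty or match eta length")
  if (any(object@eta1 < 1 - 1e-9))
    msgs <- c(msgs, "eta1 must be >= 1 (every individual lives at least one step)")
  if (any(object@eta2 - object@eta1^2 < -1e-9))
    msgs <- c(msgs, "implied variance eta2 - eta1^2 must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' RewardMomentSet: per-transition raw moment matrices R_1..R_m
#'
#' The matrices `R_k` hold the kth raw moments of the random reward collected
#' on each transition of the chain: entry `(i, j)` of `R_k` is `E[r_ij^k]`
#' for the transition from state `j` to state `i` (column-to-row
#' orientation, matching the column-stochastic transition matrix). Rewards
#' never accrue after absorption, so all columns whose origin is an
#' absorbing state are zero, and entries on transitions with zero
#' probability are set to zero.
#'
#' @slot moments list of `(omega+alpha) x (omega+alpha)` numeric matrices,
#'   element `k` holding the kth raw moments.
#' @slot omega integer, number of transient (living) states.
#' @slot alpha integer, number of absorbing (dead) states.
#' @slot mode character; how higher moments were constructed:
#'   `"paper_literal"` (R_2 = R_3 = R_1 for binary outcomes, with the
#'   death-credit entry repeated verbatim in every order), `"moment_consistent"`
#'   (death-credit entries scaled as `credit^k`), `"fixed"` (rewards fixed at
#'   their means, `R_k = R_1^{o k}`), or `"custom"`.
#' @slot deathCredit numeric scalar in `[0, 1]`: fraction of a period's
#'   reward credited on the transition into death (default convention: 1/2,
#'   the half-year credit).
#'
#' @seealso [binaryRewards()], [intervalRewards()], [fixedRewards()],
#'   [rewardMomentSet()]
#' @export
setClass("RewardMomentSet",
  representation(moments = "list", omega = "integer", alpha = "integer",
                 mode = "character", deathCredit = "numeric"))

setValidity("RewardMomentSet", function(object) {
  msgs <- character()
  s <- object@omega + object@alpha
  if (object@omega < 1L) msgs <- c(msgs, "omega must be >= 1")
  if (object@alpha < 1L) msgs <- c(msgs, "alpha must be >= 1")
  if (!length(object@moments)) msgs <- c(msgs, "at least one moment matrix required")
  for (k in seq_along(object@moments)) {
    Rk <- object@moments[[k]]
    if (!is.matrix(Rk) || !identical(dim(Rk), c(s, s))) {
      msgs <- c(msgs, sprintf("moment matrix %d must be %d x %d", k, s, s))
      next
    }
    if (any(!is.finite(Rk)))
      msgs <- c(msgs, sprintf("moment matrix %d has non-finite entries", k))
    if (object@alpha > 0L &&
        any(abs(Rk[, (object@omega + 1L):s, drop = FALSE]) > 0))
      msgs <- c(msgs, sprintf(
        "moment matrix %d has rewards on absorbing-origin columns (the dead collect nothing)", k))
  }
  if (length(object@mode) != 1L)
    msgs <- c(msgs, "mode must be a single string")
  if (length(object@deathCredit) != 1L || is.na(object@deathCredit) ||
      object@deathCredit < 0 || object@deathCredit > 1)
    msgs <- c(msgs, "deathCredit must be a single value in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' MomentVectorSet: raw moments of lifetime accumulated reward
#'
#' Element `k` of `rho` is the vector whose jth entry is the kth raw moment
#' of the remaining lifetime accumulated reward for an individual starting
#' in transient state `j`.
#'
#' @slot rho list of numeric vectors of length `omega` (orders `1..m`).
#' @slot ages numeric vector of class labels (may be empty).
#'
#' @seealso [accumulateMoments()], [lifetimeStatistics()]
#' @export
setClass("MomentVectorSet",
  representation(rho = "list", ages = "numeric"))

setValidity("MomentVectorSet", function(object) {
  msgs <- character()
  if (!length(object@rho)) msgs <- c(msgs, "at least one moment vector required")
  n <- length(object@rho[[1L]])
  for (k in seq_along(object@rho)) {
    if (!is.numeric(object@rho[[k]]) || length(object@rho[[k]]) != n)
      msgs <- c(msgs, sprintf("moment vector %d must be numeric of length %d", k, n))
  }
  if (length(object@ages) && length(object@ages) != n)
    msgs <- c(msgs, "ages must be empty or match vector length")
  if (length(msgs)) msgs else TRUE
})

#' HealthStatistics: summary statistics of healthy longevity by starting class
#'
#' Mean, variance, standard deviation, coefficient of variation, and
#' skewness of remaining lifetime accumulated reward for every transient
#' starting class. Mean and SD are in reward units (years, grip-years, ...),
#' variance in squared units; CV and skewness are dimensionless. CV is `NA`
#' where the mean is zero and skewness is `NA` where the variance is
#' (numerically) zero.
#'
#' @slot ages numeric vector of class labels.
#' @slot mean,variance,sd,cv,skewness numeric vectors, one entry per
#'   starting class.
#' @slot meta list of provenance fields (reward mode, death credit, ...)
#'   recorded so that outputs are self-describing.
#'
#' @seealso [lifetimeStatistics()], [writeStatistics()]
#' @export
setClass("HealthStatistics",
  representation(ages = "numeric", mean = "numeric", variance = "numeric",
                 sd = "numeric", cv = "numeric", skewness = "numeric",
                 meta = "list"))

setValidity("HealthStatistics", function(object) {
  msgs <- character()
  n <- length(object@mean)
  for (sl in c("ages", "variance", "sd", "cv", "skewness"))
    if (length(slot(object, sl)) != n)
      msgs <- c(msgs, sprintf("slot %s must have length %d", sl, n))
  if (any(object@variance < 0, na.rm = TRUE))
    msgs <- c(msgs, "variance must be nonnegative")
  ok <- !is.na(object@variance)
  if (any(abs(object@sd[ok] - sqrt(object@variance[ok])) > 1e-8))
    msgs <- c(msgs, "sd must equal sqrt(variance)")
  if (length(msgs)) msgs else TRUE
})

#' DalySpec: inputs for a disability-adjusted life-year analysis
#'
#' Bundles the four ingredients of the DALY model for one focal cause:
#' the focal population's mortality schedule with its per-age split of
#' deaths between the focal cause (cause 1) and all other causes (cause 2);
#' the prevalence of disability due to the focal cause; the severity
#' (disability weight) of that disability; and the standard (reference)
#' mortality schedule from which years of life lost at each age of death
#' are scored.
#'
#' @slot mortality [MortalitySchedule] of the focal population.
#' @slot cause1Fraction numeric vector, length `omega`: fraction of deaths
#'   in each age class attributable to the focal cause (in `[0, 1]`).
#' @slot prevalence numeric vector, length `omega`: prevalence of
#'   disability due to the focal cause (in `[0, 1]`).
#' @slot severity numeric vector, length `omega`: disability weight in
#'   `[0, 1]` (1 means a year with the condition is equivalent to a year
#'   lost to death).
#' @slot standard [MortalitySchedule] of the reference population, on the
#'   same age grid as `mortality`.
#'
#' @seealso [dalySpec()], [computeDaly()], [dalyRewards()]
#' @export
setClass("DalySpec",
  representation(mortality = "MortalitySchedule", cause1Fraction = "numeric",
                 prevalence = "numeric", severity = "numeric",
                 standard = "MortalitySchedule"))

setValidity("DalySpec", function(object) {
  msgs <- character()
  omega <- length(object@mortality@surv)
  for (sl in c("cause1Fraction", "prevalence", "severity")) {
    v <- slot(object, sl)
    if (length(v) != omega)
      msgs <- c(msgs, sprintf("%s must have length %d (one entry per age class)", sl, omega))
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      msgs <- c(msgs, sprintf("%s must lie in [0, 1]", sl))
  }
  if (length(object@standard@surv) != omega)
    msgs <- c(msgs, "standard schedule must be on the same age grid as the focal mortality")
  if (length(msgs)) msgs else TRUE
})

#' SimulationResult: Monte Carlo replicates of lifetime accumulated reward
#'
#' @slot rewards numeric vector of accumulated rewards, one per replicate.
#' @slot start integer starting state.
#' @slot seed integer seed used.
#' @slot moments numeric vector: empirical raw moments 1..3.
#' @slot se numeric vector: standard errors of the empirical raw moments.
#'
#' @seealso [simulateRewards()]
#' @export
setClass("SimulationResult",
  representation(rewards = "numeric", start = "integer", seed = "integer",
                 moments = "numeric", se = "numeric"))

setValidity("SimulationResult", function(object) {
  msgs <- character()
  if (!length(object@rewards)) msgs <- c(msgs, "no replicates")
  if (any(!is.finite(object@rewards))) msgs <- c(msgs, "non-finite replicate rewards")
  if (length(msgs)) msgs else TRUE
})
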