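#' Moments of lifetime accumulated reward
#'
#' Computes the raw moment vectors of the remaining lifetime accumulated
#' reward, by starting state, for an absorbing Markov chain with rewards.
#' The single implementation is the general recursion
#' \deqn{\tilde\rho_m = N^T Z (P \circ R_m)^T 1
#'   + \sum_{k=1}^{m-1} \binom{m}{k} N^T (U \circ \tilde R_{m-k})^T
#'     \tilde\rho_k,}
#' where `Z = [I | 0]` selects the transient states,
#' `tilde R_k = Z R_k Z^T` is the transient submatrix of the kth reward
#' moment matrix, and `N` is the fundamental matrix. The first-, second-
#' and third-order formulas are the `m = 1, 2, 3` special cases.
#'
#' @param P full transition matrix from [assembleP()] (column-stochastic,
#'   transient states first).
#' @param R a [RewardMomentSet] providing moments up to `maxOrder`.
#' @param maxOrder highest moment order to compute (default 3; arbitrary
#'   orders are supported given enough reward moments).
#' @param ages optional class labels carried through to the result.
#' @return a [MomentVectorSet] with vectors `rho_1..rho_maxOrder`.
#' @examples
#' sched <- mortalitySchedule(c(0.5, 0))
#' P <- assembleP(buildAgeU(sched), buildM(sched))
#' R <- binaryRewards(c(1, 1), P)
#' momentVector(accumulateMoments(P, R), 1)  # healthy life expectancy
#' @export
accumulateMoments <- function(P, R, maxOrder = 3L, ages = numeric()) {
  stopifnot(is(R, "RewardMomentSet"))
  maxOrder <- as.integer(maxOrder)
  if (maxOrder < 1L) stop("maxOrder must be >= 1")
  if (maxOrder > momentOrder(R))
    stop("R provides moments up to order ", momentOrder(R),
         " but order ", maxOrder, " was requested")
  omega <- R@omega
  s <- nrow(P)
  if (ncol(P) != s || s != omega + R@alpha)
    stop("dimensions of P do not conform with the reward set (expected ",
         omega + R@alpha, " states)")
  tidx <- seq_len(omega)
  U <- P[tidx, tidx, drop = FALSE]
  N <- fundamentalMatrix(U)
  Nt <- t(N)
  Rt <- lapply(R@moments, function(Rk) Rk[tidx, tidx, drop = FALSE])
  rho <- vector("list", maxOrder)
  for (m in seq_len(maxOrder)) {
    ## Z (P o R_m)^T 1: per-origin expected kth-moment flux out of each
    ## transient state
    zterm <- colSums(P * R@moments[[m]])[tidx]
    acc <- zterm
    if (m >= 2L) {
      for (k in seq_len(m - 1L)) {
        acc <- acc + choose(m, k) *
          as.numeric(t(U * Rt[[m - k]]) %*% rho[[k]])
      }
    }
    rho[[m]] <- as.numeric(Nt %*% acc)
  }
  new("MomentVectorSet", rho = rho, ages = as.numeric(ages))
}

#' Summary statistics of healthy longevity from its moment vectors
#'
#' Converts raw moment vectors into the mean, variance, standard deviation,
#' coefficient of variation, and skewness of lifetime accumulated reward,
#' per starting class:
#' \deqn{V = \rho_2 - \rho_1 \circ \rho_1, \quad SD = \sqrt V, \quad
#'   CV = SD / \rho_1, \quad
#'   Sk = (\rho_3 - 3 \rho_1 \circ \rho_2 + 2 \rho_1^{\circ 3}) / V^{3/2}.}
#'
#' Tiny negative variances from floating-point cancellation (in
#' `(-negTol, 0)`) are clamped to zero with a warning; anything below
#' `-negTol` raises an error. CV is reported as `NA` where the mean is
#' zero; skewness is `NA` where the variance is numerically zero (below
#' `degTol`), including near-degenerate open-ended tail classes.
#'
#' @param rho a [MomentVectorSet] with orders 1-2 (1-3 for skewness).
#' @param ages optional class labels (default: those stored in `rho`).
#' @param meta named list of provenance fields to record (reward mode,
#'   death credit, ...).
#' @param negTol tolerance below which a negative variance is an error.
#' @param degTol variance threshold under which skewness is `NA`.
#' @return a [HealthStatistics].
#' @export
lifetimeStatistics <- function(rho, ages = NULL, meta = list(),
                               negTol = 1e-9, degTol = 1e-12) {
  stopifnot(is(rho, "MomentVectorSet"))
  if (momentOrder(rho) < 2L)
    stop("moment vectors of orders 1 and 2 are required")
  r1 <- rho@rho[[1L]]
  r2 <- rho@rho[[2L]]
  n <- length(r1)
  if (is.null(ages)) ages <- rho@ages
  if (!length(ages)) ages <- seq_len(n)
  v <- r2 - r1^2
  bad <- v < -negTol
  if (any(bad))
    stop("inconsistent moments: variance ", signif(min(v), 6),
         " below -", negTol, " in starting class ", which(bad)[1L])
  clamp <- v < 0
  if (any(clamp)) {
    warning(sum(clamp), " variance value(s) in (-", negTol,
            ", 0) clamped to 0 (floating-point cancellation)")
    v[clamp] <- 0
  }
  sdv <- sqrt(v)
  cv <- ifelse(r1 != 0, sdv / r1, NA_real_)
  if (momentOrder(rho) >= 3L) {
    r3 <- rho@rho[[3L]]
    sk <- ifelse(v > degTol,
                 (r3 - 3 * r1 * r2 + 2 * r1^3) / v^1.5,
                 NA_real_)
  } else {
    sk <- rep(NA_real_, n)
  }
  new("HealthStatistics", ages = as.numeric(ages), mean = r1, variance = v,
      sd = sdv, cv = cv, skewness = sk, meta = meta)
}

#' Decompose the variance of lifetime accumulated reward
#'
#' Variance among individuals arises from two sources: the random pathway
#' through the life course (among-trajectory) and the random health reward
#' collected at each age within a trajectory (within-trajectory). The
#' among-trajectory component is the variance obtained after fixing every
#' reward at its mean ([fixedRewards()]); the within-trajectory component
#' is obtained by subtraction, so the two always add up to the total.
#'
#' @param P full transition matrix.
#' @param R a [RewardMomentSet] with moments of orders 1-2 (the stochastic
#'   rewards).
#' @param tol tolerance below which a negative within-component is an
#'   error rather than rounding noise.
#' @return list with numeric vectors `total`, `among`, `within` (one entry
#'   per starting class).
#' @export
decomposeVariance <- function(P, R, tol = 1e-9) {
  stopifnot(is(R, "RewardMomentSet"))
  rhoS <- accumulateMoments(P, R, maxOrder = 2L)
  rhoF <- accumulateMoments(P, fixedRewards(R), maxOrder = 2L)
  total <- rhoS@rho[[2L]] - rhoS@rho[[1L]]^2
  among <- rhoF@rho[[2L]] - rhoF@rho[[1L]]^2
  within <- total - among
  if (any(within < -tol))
    stop("numerical inconsistency: within-trajectory variance ",
         signif(min(within), 6), " below -", tol)
  list(total = total, among = among, within = within)
}

#' Sullivan health expectancy
#'
#' The classical prevalence-based health expectancy: with `L_j` person-years
#' lived in age class `j` and `v_j` the prevalence of the healthy state,
#' \deqn{HE(x) = \sum_{j \ge x} L_j v_j.}
#' The chain-based mean healthy longevity reproduces this exactly when
#' `L_j` is taken as the chain's expected occupancy with the matched
#' death-period credit; see [occupancyPersonYears()].
#'
#' @param L numeric vector of person-years per age class.
#' @param v numeric prevalence vector, same length.
#' @param x starting class index (1-based; the sum runs from `x` onward).
#' @return scalar health expectancy.
#' @examples
#' sullivanExpectancy(c(1, 0.5), c(1, 1), 1)  # 1.5
#' @export
sullivanExpectancy <- function(L, v, x = 1L) {
  if (length(L) != length(v))
    stop("L and v must have the same length")
  if (any(L < 0)) stop("person-years L must be nonnegative")
  x <- as.integer(x)
  if (x < 1L || x > length(L))
    stop("starting class ", x, " out of range 1..", length(L))
  sum(L[x:length(L)] * v[x:length(L)])
}

#' Person-years of occupancy implied by the chain
#'
#' Expected person-years lived in each age class by an individual starting
#' in class `start`, crediting a fraction `deathCredit` of the period in
#' which death occurs: `L_j = N[j, start] * (p_j + (1 - p_j) * credit)`.
#' With the default half-period credit this is the familiar life-table
#' convention `L_j = (l_j + l_{j+1}) / 2` (averaging survivors at the start
#' and end of the interval), and [sullivanExpectancy()] applied to it
#' reproduces the chain's mean healthy longevity exactly.
#'
#' @param N fundamental matrix.
#' @param schedule the [MortalitySchedule] the chain was built from.
#' @param deathCredit fraction of the death period credited (default 1/2).
#' @param start starting class index.
#' @return numeric vector `L` of person-years per age class.
#' @export
occupancyPersonYears <- function(N, schedule, deathCredit = 0.5, start = 1L) {
  stopifnot(is(schedule, "MortalitySchedule"))
  p <- schedule@surv
  if (nrow(N) != length(p))
    stop("N and schedule dimensions do not match")
  start <- as.integer(start)
  if (start < 1L || start > length(p))
    stop("starting class out of range")
  N[, start] * (p + (1 - p) * deathCredit)
}

#' One-call healthy longevity analysis
#'
#' Convenience wrapper for the full pipeline: build the age-classified
#' chain from a mortality schedule, attach binary (prevalence) or
#' interval-scale (moment) rewards, run the moment recursion, and return
#' summary statistics for every starting age class.
#'
#' @param schedule a [MortalitySchedule].
#' @param prevalence numeric prevalence vector (binary outcome), length
#'   `omega`; use `rep(1, omega)` for total longevity. Exactly one of
#'   `prevalence` and `outcomeMoments` must be given.
#' @param outcomeMoments data.frame with columns `m1, m2, m3` (per-age raw
#'   moments of a quantitative outcome).
#' @param mode death-credit moment convention (see [binaryRewards()]).
#' @param deathCredit fraction of the death period credited.
#' @param maxOrder highest moment order (default 3).
#' @return a [HealthStatistics] with provenance metadata.
#' @examples
#' sched <- mortalitySchedule(c(0.9, 0.8, 0), ages = 70:72)
#' healthyLongevity(sched, prevalence = c(0.8, 0.7, 0.6))
#' @export
healthyLongevity <- function(schedule, prevalence = NULL,
                             outcomeMoments = NULL,
                             mode = c("paper_literal", "moment_consistent"),
                             deathCredit = 0.5, maxOrder = 3L) {
  mode <- match.arg(mode)
  stopifnot(is(schedule, "MortalitySchedule"))
  if (is.null(prevalence) == is.null(outcomeMoments))
    stop("supply exactly one of prevalence and outcomeMoments")
  U <- buildAgeU(schedule)
  M <- buildM(schedule)
  P <- assembleP(U, M)
  R <- if (!is.null(prevalence)) {
    if (length(prevalence) != length(schedule@surv))
      stop("prevalence must have one entry per age class")
    binaryRewards(prevalence, P, mode = mode, deathCredit = deathCredit,
                  maxOrder = max(3L, maxOrder))
  } else {
    if (nrow(outcomeMoments) != length(schedule@surv))
      stop("outcomeMoments must have one row per age class")
    intervalRewards(outcomeMoments, P = P, mode = mode,
                    deathCredit = deathCredit)
  }
  rho <- accumulateMoments(P, R, maxOrder = maxOrder, ages = schedule@ages)
  lifetimeStatistics(rho, meta = list(
    outcome = if (!is.null(prevalence)) "binary" else "interval",
    mode = mode, deathCredit = deathCredit,
    openEnded = schedule@openEnded,
    truncationAge = if (!schedule@openEnded)
      schedule@ages[length(schedule@ages)] else NA_real_))
}
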