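#' Construct a custom reward moment set
#'
#' Low-level constructor: wraps a list of `(omega+alpha) x (omega+alpha)`
#' moment matrices. Entries on absorbing-origin columns must be zero
#' (no rewards accumulate after death).
#'
#' @param moments list of moment matrices, element `k` holding the kth raw
#'   moments.
#' @param omega number of transient states.
#' @param alpha number of absorbing states.
#' @param mode construction label recorded for provenance.
#' @param deathCredit death-credit fraction recorded for provenance.
#' @return a [RewardMomentSet].
#' @export
rewardMomentSet <- function(moments, omega, alpha, mode = "custom",
                            deathCredit = NA_real_) {
  if (is.na(deathCredit)) deathCredit <- 0
  new("RewardMomentSet", moments = moments, omega = as.integer(omega),
      alpha = as.integer(alpha), mode = mode,
      deathCredit = as.numeric(deathCredit))
}

## mask of structurally possible transitions, split into living and dying rows
.transitionMasks <- function(P, omega) {
  s <- nrow(P)
  live <- matrix(FALSE, s, s)
  dead <- matrix(FALSE, s, s)
  live[seq_len(omega), seq_len(omega)] <- P[seq_len(omega), seq_len(omega)] > 0
  dead[(omega + 1L):s, seq_len(omega)] <- P[(omega + 1L):s, seq_len(omega)] > 0
  list(live = live, dead = dead)
}

#' Reward moments for a binary health outcome (prevalence data)
#'
#' The reward collected during a year lived in age class `j` is a Bernoulli
#' random variable: one year of the health condition with probability
#' `v_j`, zero with probability `1 - v_j`. Individuals who die during the
#' step are credited a fraction `deathCredit` (default one half) of a year
#' of the condition. Rewards are attached to the origin class `j` for all
#' transitions out of `j`; the open-ended class's self-transition uses its
#' own prevalence.
#'
#' Two conventions for the higher moments of the death-transition credit
#' are provided. `"paper_literal"` sets `R_3 = R_2 = R_1`, i.e. the death
#' entry is `v_j * credit` in every order; this is realisable as a reward
#' of one full year granted with probability `v_j * credit`.
#' `"moment_consistent"` treats the death reward as `credit` with
#' probability `v_j`, whose kth raw moment is `v_j * credit^k`. Living
#' transitions have kth moment `v_j` under both (Bernoulli raw moments are
#' all `v_j`). The choice is recorded on the returned object and in all
#' downstream output.
#'
#' Setting `v = 1` everywhere yields the total-longevity reward
#' specification (a full year credited for every year lived).
#'
#' @param v numeric vector of prevalences in `[0, 1]`, length `omega`.
#' @param P full transition matrix from [assembleP()] (used to place
#'   rewards only on transitions that can occur).
#' @param mode `"paper_literal"` (default) or `"moment_consistent"`.
#' @param deathCredit fraction of a period credited at death, in `[0, 1]`.
#' @param maxOrder number of moment matrices to build (default 3).
#' @return a [RewardMomentSet] with moments `R_1..R_maxOrder`.
#' @examples
#' sched <- mortalitySchedule(c(0.5, 0))
#' P <- assembleP(buildAgeU(sched), buildM(sched))
#' binaryRewards(c(0.3, 0.3), P)
#' @export
binaryRewards <- function(v, P,
                          mode = c("paper_literal", "moment_consistent"),
                          deathCredit = 0.5, maxOrder = 3L) {
  mode <- match.arg(mode)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("prevalences must lie in [0, 1]")
  if (deathCredit < 0 || deathCredit > 1)
    stop("deathCredit must lie in [0, 1]")
  omega <- length(v)
  s <- nrow(P)
  alpha <- s - omega
  if (alpha < 1L)
    stop("P (", s, " states) must include at least one absorbing state ",
         "beyond the ", omega, " age classes of v")
  masks <- .transitionMasks(P, omega)
  Vmat <- matrix(c(v, rep(0, alpha)), nrow = s, ncol = s, byrow = TRUE)
  moments <- vector("list", maxOrder)
  for (k in seq_len(maxOrder)) {
    credit_k <- if (mode == "paper_literal") deathCredit else deathCredit^k
    Rk <- matrix(0, s, s)
    Rk[masks$live] <- Vmat[masks$live]
    Rk[masks$dead] <- Vmat[masks$dead] * credit_k
    moments[[k]] <- Rk
  }
  rewardMomentSet(moments, omega, alpha, mode = mode,
                  deathCredit = deathCredit)
}

#' Combine prevalences of grouped categorical outcomes
#'
#' Polychotomous (nominal) or ordinal health outcomes can be grouped into a
#' binary condition; the prevalence of the grouped condition is the sum of
#' the component prevalences. The subset must be a nonempty proper subset
#' of the outcomes (grouping all of them leaves an empty complement and no
#' contrast).
#'
#' @param prevalences named list of numeric prevalence vectors, one per
#'   outcome, all the same length; per age the prevalences may sum to at
#'   most 1.
#' @param subset indices or names of the outcomes to group.
#' @param tol tolerance on the per-age total prevalence check.
#' @return numeric prevalence vector of the grouped condition.
#' @examples
#' combinePrevalence(list(H = 0.5, C = 0.3, I = 0.2), c("H", "C"))  # 0.8
#' @export
combinePrevalence <- function(prevalences, subset, tol = 1e-9) {
  if (!is.list(prevalences) || length(prevalences) < 2L)
    stop("prevalences must be a list of at least two outcome schedules")
  lens <- lengths(prevalences)
  if (length(unique(lens)) != 1L)
    stop("all outcome schedules must have the same length")
  total <- Reduce(`+`, prevalences)
  if (any(total > 1 + tol))
    stop("outcome prevalences sum to more than 1 in some age class (max ",
         signif(max(total), 6), ")")
  if (is.character(subset)) subset <- match(subset, names(prevalences))
  if (any(is.na(subset)))
    stop("subset names not found among the outcomes")
  subset <- unique(as.integer(subset))
  if (length(subset) == 0L || length(subset) >= length(prevalences))
    stop("degenerate grouping: subset must be a nonempty proper subset of the outcomes")
  v <- Reduce(`+`, prevalences[subset])
  pmin(pmax(v, 0), 1)
}

#' Number of binary groupings of n categorical outcomes
#'
#' With `n` outcomes, every nonempty proper subset defines a grouped binary
#' condition; there are `sum_{k=1}^{n-1} choose(n, k) = 2^n - 2` of them.
#'
#' @param n number of outcomes (`>= 2`).
#' @return integer count of groupings.
#' @examples
#' countGroupings(3)  # 6
#' @export
countGroupings <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop("n must be an integer >= 2")
  sum(choose(n, seq_len(n - 1L)))
}

#' Order-preserving binary splits of an ordinal outcome
#'
#' An ordinal outcome with `n` ordered levels can be dichotomised in
#' `n - 1` ways that preserve the order: each cut point separates the
#' lowest `k` levels from the rest (e.g. for low/medium/high: L vs M+H and
#' L+M vs H).
#'
#' @param levels integer number of ordered levels, or a character vector of
#'   level names in increasing order.
#' @return list of `n - 1` elements, each `list(low = ..., high = ...)`.
#' @examples
#' ordinalBinarySplits(c("L", "M", "H"))
#' @export
ordinalBinarySplits <- function(levels) {
  if (is.numeric(levels) && length(levels) == 1L)
    levels <- paste0("level", seq_len(as.integer(levels)))
  n <- length(levels)
  if (n < 2L)
    stop("an ordinal outcome needs at least 2 levels")
  lapply(seq_len(n - 1L), function(k)
    list(low = levels[seq_len(k)], high = levels[(k + 1L):n]))
}

#' Reward moments for an interval-scale (quantitative) health outcome
#'
#' For a quantitative outcome (e.g. grip strength in kg), prevalence data
#' do not determine the higher moments; instead the first three empirical
#' raw moments of the outcome in each age class are supplied (all moments
#' are about zero). A year lived in class `j` then contributes a reward
#' with kth raw moment `m_k[j]`; the transition into death is credited a
#' fraction `deathCredit` of the period, following the same convention as
#' [binaryRewards()] (`"paper_literal"`: kth death moment
#' `m_k[j] * credit`; `"moment_consistent"`: `m_k[j] * credit^k`, the
#' moments of `credit` times the outcome).
#'
#' @param m1,m2,m3 numeric vectors of length `omega`: per-class raw moments
#'   of the outcome (units outcome^k). Alternatively pass a data.frame with
#'   columns `m1, m2, m3` as `m1`.
#' @param P full transition matrix from [assembleP()].
#' @param mode moment convention for the death credit (see above).
#' @param deathCredit fraction of a period credited at death.
#' @return a [RewardMomentSet] with moments `R_1..R_3`.
#' @examples
#' sched <- mortalitySchedule(c(0.5, 0))
#' P <- assembleP(buildAgeU(sched), buildM(sched))
#' intervalRewards(c(3, 3), c(10, 10), c(36, 36), P)  # sample {2, 4}
#' @export
intervalRewards <- function(m1, m2 = NULL, m3 = NULL, P,
                            mode = c("paper_literal", "moment_consistent"),
                            deathCredit = 0.5) {
  mode <- match.arg(mode)
  if (is.data.frame(m1)) {
    stopifnot(all(c("m1", "m2", "m3") %in% names(m1)))
    df <- m1; m1 <- df$m1; m2 <- df$m2; m3 <- df$m3
  }
  if (is.null(m2) || is.null(m3))
    stop("raw moments m1, m2, m3 are all required")
  omega <- length(m1)
  if (length(m2) != omega || length(m3) != omega)
    stop("m1, m2, m3 must have equal length")
  if (any(m2 < 0))
    stop("second raw moments must be nonnegative")
  if (any(m2 - m1^2 < -1e-9))
    stop("inconsistent moments: m2 < m1^2 (negative variance) in age class ",
         which(m2 - m1^2 < -1e-9)[1L])
  s <- nrow(P)
  alpha <- s - omega
  if (alpha < 1L)
    stop("P must include at least one absorbing state")
  masks <- .transitionMasks(P, omega)
  mk <- list(m1, m2, m3)
  moments <- vector("list", 3L)
  for (k in 1:3) {
    credit_k <- if (mode == "paper_literal") deathCredit else deathCredit^k
    Mk <- matrix(c(mk[[k]], rep(0, alpha)), nrow = s, ncol = s, byrow = TRUE)
    Rk <- matrix(0, s, s)
    Rk[masks$live] <- Mk[masks$live]
    Rk[masks$dead] <- Mk[masks$dead] * credit_k
    moments[[k]] <- Rk
  }
  rewardMomentSet(moments, omega, alpha, mode = mode,
                  deathCredit = deathCredit)
}

#' Fix rewards at their mean values
#'
#' Replaces the random per-transition rewards by their means: `R_1` is kept
#' and the higher moments become elementwise powers, `R_k = R_1` Hadamard
#' power `k`. The per-transition reward variance is then zero, so the only
#' remaining source of variance in lifetime accumulated reward is the
#' life-course trajectory itself. Used for the among-trajectory component
#' of the variance decomposition (see [decomposeVariance()]).
#'
#' @param R a [RewardMomentSet].
#' @param maxOrder number of moment matrices to build (default: as many as
#'   `R` holds, at least 3).
#' @return a [RewardMomentSet] with `mode = "fixed"`.
#' @export
fixedRewards <- function(R, maxOrder = max(3L, momentOrder(R))) {
  stopifnot(is(R, "RewardMomentSet"))
  R1 <- R@moments[[1L]]
  moments <- lapply(seq_len(maxOrder), function(k) R1^k)
  rewardMomentSet(moments, R@omega, R@alpha, mode = "fixed",
                  deathCredit = R@deathCredit)
}
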