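#' Construct a mortality schedule
#'
#' @param surv numeric vector of per-class survival probabilities `p_j` in
#'   `[0, 1]`.
#' @param ages numeric vector of class labels (starting ages); defaults to
#'   `1:length(surv)`.
#' @param openEnded logical; if `TRUE`, the last class is open-ended: an
#'   individual reaching it survives each further step with probability
#'   `p_omega` (which must be `< 1`). To truncate an analysis at some age
#'   (e.g. report statistics "up to age 90"), build the schedule with the
#'   final survival probability set to 0 and `openEnded = FALSE`.
#'
#' @return a [MortalitySchedule].
#' @examples
#' mortalitySchedule(c(0.9, 0.8, 0), ages = c(70, 71, 72))
#' @export
mortalitySchedule <- function(surv, ages = seq_along(surv), openEnded = FALSE) {
  new("MortalitySchedule", ages = as.numeric(ages), surv = as.numeric(surv),
      openEnded = isTRUE(openEnded))
}

#' Build the transient (survival) matrix U of an age-classified chain
#'
#' For an age-classified life course the transient matrix `U` has the
#' survival probabilities `p_1, ..., p_{omega-1}` on the subdiagonal and
#' zeros elsewhere; for an open-ended schedule the `(omega, omega)` corner
#' additionally holds the age-invariant survival probability `p_omega`.
#' `U` is column-to-row oriented: column `j` describes transitions out of
#' class `j`.
#'
#' Stage-classified (non-age) life cycles are supported by supplying an
#' arbitrary column-substochastic `U` directly to the downstream functions
#' ([fundamentalMatrix()], [assembleP()], [accumulateMoments()]); this
#' builder only covers the age-classified special case.
#'
#' @param schedule a [MortalitySchedule].
#' @return `omega x omega` numeric matrix `U`.
#' @examples
#' buildAgeU(mortalitySchedule(c(0.5, 0)))
#' @export
buildAgeU <- function(schedule) {
  stopifnot(is(schedule, "MortalitySchedule"))
  validObject(schedule)
  p <- schedule@surv
  omega <- length(p)
  U <- matrix(0, omega, omega)
  if (omega > 1L)
    U[cbind(2:omega, 1:(omega - 1L))] <- p[1:(omega - 1L)]
  if (schedule@openEnded)
    U[omega, omega] <- p[omega]
  U
}

#' Build the mortality matrix M
#'
#' `M` is `alpha x omega`; entry `(c, j)` is the probability that an
#' individual in age class `j` dies into absorbing state `c` during the
#' step. Without a cause split there is a single absorbing state and
#' `M = [1 - p_j]`. With a split, each column's death probability
#' `1 - p_j` is partitioned across causes by the supplied fractions.
#'
#' @param schedule a [MortalitySchedule].
#' @param causeSplit optional `alpha x omega` matrix (or a vector of
#'   length `alpha`, recycled across ages) of per-age cause fractions;
#'   each column must sum to 1.
#' @param tol tolerance for the column-sum check on `causeSplit`.
#' @return `alpha x omega` numeric matrix; `rbind(U, M)` has unit column
#'   sums.
#' @examples
#' sched <- mortalitySchedule(c(0.5, 0))
#' buildM(sched)                              # one cause
#' buildM(sched, causeSplit = c(0.2, 0.8))    # two causes
#' @export
buildM <- function(schedule, causeSplit = NULL, tol = 1e-9) {
  stopifnot(is(schedule, "MortalitySchedule"))
  validObject(schedule)
  q <- 1 - schedule@surv
  omega <- length(q)
  if (is.null(causeSplit))
    return(matrix(q, nrow = 1L))
  if (is.vector(causeSplit))
    causeSplit <- matrix(causeSplit, nrow = length(causeSplit), ncol = omega)
  if (!is.matrix(causeSplit) || ncol(causeSplit) != omega)
    stop("causeSplit must be an alpha x omega matrix (or a length-alpha vector)")
  if (any(causeSplit < 0))
    stop("cause fractions must be nonnegative")
  cs <- colSums(causeSplit)
  if (any(abs(cs - 1) > tol))
    stop("cause fractions must sum to 1 in every age class (column ",
         which(abs(cs - 1) > tol)[1L], " sums to ", cs[which.max(abs(cs - 1))], ")")
  sweep(causeSplit, 2L, q, `*`)
}

#' Assemble the full transition matrix P of the absorbing chain
#'
#' Stacks the transient block `U`, the mortality block `M`, and the
#' identity on the absorbing states into the column-stochastic transition
#' matrix
#' \deqn{P = \begin{pmatrix} U & 0 \\ M & I_\alpha \end{pmatrix}.}
#' Absorbing states map to themselves; every column sums to one.
#'
#' @param U `omega x omega` transient matrix.
#' @param M `alpha x omega` mortality matrix.
#' @param tol tolerance for the conservation (column sum) check.
#' @return `(omega+alpha) x (omega+alpha)` column-stochastic matrix.
#' @examples
#' sched <- mortalitySchedule(c(0.5, 0))
#' assembleP(buildAgeU(sched), buildM(sched))
#' @export
assembleP <- function(U, M, tol = 1e-12) {
  if (!is.matrix(U) || nrow(U) != ncol(U))
    stop("U must be a square matrix")
  if (!is.matrix(M) || ncol(M) != ncol(U))
    stop("M must have the same number of columns as U (mismatched omega)")
  omega <- ncol(U)
  alpha <- nrow(M)
  cs <- colSums(U) + colSums(M)
  if (any(abs(cs - 1) > tol))
    stop("probability not conserved: column(s) of [U; M] sum to ",
         paste(signif(cs[abs(cs - 1) > tol], 12), collapse = ", "),
         " instead of 1")
  P <- rbind(cbind(U, matrix(0, omega, alpha)),
             cbind(M, diag(alpha)))
  unname(P)
}

#' Fundamental matrix of the absorbing chain
#'
#' Solves `(I - U) N = I` for the fundamental matrix `N`; entry `(i, j)` is
#' the expected number of time steps spent in transient state `i` by an
#' individual starting in state `j` before absorption. A linear solve is
#' used rather than explicit inversion; the contract is on the relative
#' residual of the solution.
#'
#' @param U `omega x omega` transient matrix with spectral radius `< 1`.
#' @param tol maximum allowed relative residual `||(I-U)N - I|| / ||I||`.
#' @return `omega x omega` matrix `N` with nonnegative entries and unit or
#'   larger diagonal.
#' @examples
#' fundamentalMatrix(matrix(0.5, 1, 1))  # geometric: N = 2
#' @export
fundamentalMatrix <- function(U, tol = 1e-10) {
  if (!is.matrix(U) || nrow(U) != ncol(U))
    stop("U must be a square matrix")
  if (any(U < 0) || any(U > 1))
    stop("entries of U must lie in [0, 1]")
  omega <- nrow(U)
  sr <- max(Mod(eigen(U, only.values = TRUE)$values))
  if (sr >= 1 - 1e-12)
    stop("chain is not absorbing: spectral radius of U is ", signif(sr, 6),
         " (must be < 1 so that death is certain)")
  A <- diag(omega) - U
  N <- tryCatch(solve(A, diag(omega)),
                error = function(e) stop("I - U is singular or near-singular: ",
                                         conditionMessage(e)))
  resid <- max(abs(A %*% N - diag(omega)))
  if (resid > tol)
    stop("fundamental matrix solve did not meet the residual contract (",
         signif(resid, 3), " > ", tol, ")")
  unname(N)
}

#' Raw moments of remaining longevity
#'
#' The first three raw moments of the time to absorption (remaining
#' longevity, in time steps), per starting class, from the fundamental
#' matrix:
#' \deqn{\eta_1^T = 1^T N, \quad
#'       \eta_2^T = \eta_1^T (2N - I), \quad
#'       \eta_3^T = \eta_1^T (6N^2 - 6N + I).}
#'
#' @param N fundamental matrix from [fundamentalMatrix()].
#' @param ages optional numeric vector of class labels.
#' @return a [LongevityMoments].
#' @examples
#' N <- fundamentalMatrix(matrix(0.5, 1, 1))
#' longevityMoments(N)  # geometric lifetime: 2, 6, 26
#' @export
longevityMoments <- function(N, ages = numeric()) {
  if (!is.matrix(N) || nrow(N) != ncol(N))
    stop("N must be a square matrix")
  omega <- nrow(N)
  I <- diag(omega)
  eta1 <- colSums(N)
  eta2 <- as.numeric(eta1 %*% (2 * N - I))
  eta3 <- as.numeric(eta1 %*% (6 * (N %*% N) - 6 * N + I))
  new("LongevityMoments", eta1 = eta1, eta2 = eta2, eta3 = eta3,
      ages = as.numeric(ages))
}
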