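#' Specification of a synthetic SHARE/HMD-like cohort
#'
#' Parameters of the synthetic fixture generator, which emulates the shape
#' of the inputs used in survey-based healthy-longevity analyses: ages 50
#' to 90 (calculations truncated at 90), Gompertz mortality, a logistic
#' age decline in the prevalence of being free of limitations in
#' activities of daily living (ADL), and an age-declining grip-strength
#' distribution with constant coefficient of variation and mild negative
#' skew.
#'
#' Default parameter values are chosen to resemble a contemporary European
#' male population aged 50+: a Gompertz hazard of `a * exp(b (x - 50))`
#' with `a = 0.004` per year and doubling time around 8 years
#' (`b = 0.09`), ADL-free prevalence declining from about 0.93 at age 50
#' towards 0.42 at 90, and mean grip strength declining linearly from
#' 45 kg at age 50 by 0.45 kg per year with CV 0.2 and skewness -0.3.
#'
#' @param ageMin,ageMax age range (default 50-90; the last class has
#'   survival 0, truncating the analysis at `ageMax`).
#' @param gompertzA baseline hazard at `ageMin` (per year).
#' @param gompertzB hazard slope (per year).
#' @param prevMax,prevMid,prevScale logistic parameters of the healthy
#'   (ADL-free) prevalence: `prevMax / (1 + exp((age - prevMid) / prevScale))`.
#' @param gripMean0 mean outcome (kg) at `ageMin`.
#' @param gripSlope decline of the mean per year of age (kg/year).
#' @param gripCV coefficient of variation of the outcome at every age.
#' @param gripSkew skewness of the outcome at every age.
#' @param nPerAge microdata sample size per age class.
#' @param sex label recorded with the fixture.
#' @param seed integer seed for the microdata draws.
#' @return list of class `SyntheticCohortSpec`.
#' @export
syntheticCohortSpec <- function(ageMin = 50, ageMax = 90,
                                gompertzA = 0.004, gompertzB = 0.09,
                                prevMax = 0.95, prevMid = 88, prevScale = 9,
                                gripMean0 = 45, gripSlope = 0.45,
                                gripCV = 0.2, gripSkew = -0.3,
                                nPerAge = 60L, sex = "male", seed = 1L) {
  spec <- list(ageMin = ageMin, ageMax = ageMax, gompertzA = gompertzA,
               gompertzB = gompertzB, prevMax = prevMax, prevMid = prevMid,
               prevScale = prevScale, gripMean0 = gripMean0,
               gripSlope = gripSlope, gripCV = gripCV, gripSkew = gripSkew,
               nPerAge = as.integer(nPerAge), sex = sex,
               seed = as.integer(seed))
  if (ageMax <= ageMin) stop("ageMax must exceed ageMin")
  if (gompertzA < 0 || gompertzB < 0) stop("Gompertz parameters must be >= 0")
  if (prevMax < 0 || prevMax > 1) stop("prevMax must lie in [0, 1]")
  if (gripCV <= 0 || spec$nPerAge < 2L)
    stop("gripCV must be positive and nPerAge >= 2")
  structure(spec, class = "SyntheticCohortSpec")
}

#' Generate a synthetic SHARE/HMD-like cohort fixture
#'
#' Builds, deterministically for a given seed, the full input bundle of a
#' healthy-longevity analysis: a Gompertz mortality schedule truncated at
#' `ageMax` (survival 0 in the last class), an ADL-free prevalence
#' schedule, grip-strength-like microdata (negative-skew draws via a
#' reflected standardised gamma), and the per-age raw moments computed
#' from those microdata.
#'
#' @param spec a [syntheticCohortSpec()].
#' @return list with elements `mortality` ([MortalitySchedule]),
#'   `prevalence` (named numeric vector), `microdata` (data.frame
#'   `age, value`), `outcomeMoments` (data.frame `age, m1, m2, m3`), and
#'   `spec`.
#' @export
generateSyntheticCohort <- function(spec = syntheticCohortSpec()) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  ages <- seq(spec$ageMin, spec$ageMax)
  omega <- length(ages)
  ## Gompertz hazard integrated over each one-year class
  haz <- spec$gompertzA * exp(spec$gompertzB * (ages - spec$ageMin))
  qx <- 1 - exp(-haz)
  p <- 1 - qx
  p[omega] <- 0  # truncate the analysis at ageMax
  if (any(p < 0) || any(p[-omega] <= 0) || any(p >= 1))
    stop("Gompertz parameters yield survival probabilities outside (0, 1)")
  mortality <- mortalitySchedule(p, ages = ages, openEnded = FALSE)
  v <- spec$prevMax / (1 + exp((ages - spec$prevMid) / spec$prevScale))
  if (any(v < 0) || any(v > 1))
    stop("prevalence parameters yield values outside [0, 1]")
  prevalence <- stats::setNames(v, ages)
  ## grip-strength-like microdata: mean declines linearly, CV constant,
  ## negative skew via a reflected standardised gamma
  mu <- spec$gripMean0 - spec$gripSlope * (ages - spec$ageMin)
  if (any(mu <= 0)) stop("grip mean becomes nonpositive within the age range")
  shape <- (2 / abs(spec$gripSkew))^2
  set.seed(spec$seed)
  micro <- do.call(rbind, lapply(seq_along(ages), function(i) {
    g <- stats::rgamma(spec$nPerAge, shape = shape, rate = 1)
    z <- (g - shape) / sqrt(shape)          # mean 0, sd 1, skew 2/sqrt(shape)
    if (spec$gripSkew < 0) z <- -z
    data.frame(age = ages[i], value = mu[i] * (1 + spec$gripCV * z))
  }))
  list(mortality = mortality, prevalence = prevalence, microdata = micro,
       outcomeMoments = momentsFromMicrodata(micro), spec = spec)
}

#' Write a synthetic cohort fixture to CSV files
#'
#' @param cohort result of [generateSyntheticCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the written paths
#'   (`mortality`, `prevalence`, `microdata`, `moments`).
#' @export
writeSyntheticFixture <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mortality = file.path(dir, "mortality.csv"),
             prevalence = file.path(dir, "prevalence.csv"),
             microdata = file.path(dir, "microdata.csv"),
             moments = file.path(dir, "outcome_moments.csv"))
  sched <- cohort$mortality
  utils::write.csv(data.frame(age = sched@ages, qx = 1 - sched@surv),
                   paths["mortality"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(age = as.numeric(names(cohort$prevalence)),
                              prevalence = unname(cohort$prevalence)),
                   paths["prevalence"], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$microdata, paths["microdata"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$outcomeMoments, paths["moments"],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
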