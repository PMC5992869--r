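#' @rdname accessors
#' @aliases ageClasses,MortalitySchedule-method
setMethod("ageClasses", "MortalitySchedule", function(x) x@ages)

#' @rdname accessors
setMethod("ageClasses", "LongevityMoments", function(x) x@ages)

#' @rdname accessors
setMethod("ageClasses", "MomentVectorSet", function(x) x@ages)

#' @rdname accessors
setMethod("ageClasses", "HealthStatistics", function(x) x@ages)

#' @rdname accessors
setMethod("survProb", "MortalitySchedule", function(x) x@surv)

#' @rdname accessors
setMethod("deathProb", "MortalitySchedule", function(x) 1 - x@surv)

#' @rdname accessors
setMethod("isOpenEnded", "MortalitySchedule", function(x) x@openEnded)

#' @rdname accessors
setMethod("rewardMoment", "RewardMomentSet", function(x, k) {
  k <- as.integer(k)
  if (k < 1L || k > length(x@moments))
    stop("moment order ", k, " not available (set holds orders 1..",
         length(x@moments), ")")
  x@moments[[k]]
})

#' @rdname accessors
setMethod("momentOrder", "RewardMomentSet", function(x) length(x@moments))

#' @rdname accessors
setMethod("momentOrder", "MomentVectorSet", function(x) length(x@rho))

#' @rdname accessors
setMethod("momentVector", "MomentVectorSet", function(x, k) {
  k <- as.integer(k)
  if (k < 1L || k > length(x@rho))
    stop("moment order ", k, " not available (set holds orders 1..",
         length(x@rho), ")")
  x@rho[[k]]
})

#' @rdname accessors
setMethod("statsTable", "HealthStatistics", function(x) {
  data.frame(age = x@ages, mean = x@mean, variance = x@variance,
             sd = x@sd, cv = x@cv, skewness = x@skewness)
})

#' @rdname accessors
setMethod("statsTable", "LongevityMoments", function(x) {
  data.frame(age = if (length(x@ages)) x@ages else seq_along(x@eta1),
             eta1 = x@eta1, eta2 = x@eta2, eta3 = x@eta3)
})

setMethod("show", "MortalitySchedule", function(object) {
  n <- length(object@surv)
  cat("MortalitySchedule with", n, "age class(es):",
      object@ages[1L], "..", object@ages[n],
      if (object@openEnded) "(open-ended)\n" else "(closed)\n")
  cat("  survival p_j: ", paste(signif(utils::head(object@surv, 5), 4),
                                collapse = ", "),
      if (n > 5) ", ...\n" else "\n", sep = "")
})

setMethod("show", "RewardMomentSet", function(object) {
  cat("RewardMomentSet: orders 1..", length(object@moments),
      ", omega = ", object@omega, ", alpha = ", object@alpha,
      "\n  mode = ", object@mode,
      ", death credit = ", object@deathCredit, "\n", sep = "")
})

setMethod("show", "MomentVectorSet", function(object) {
  cat("MomentVectorSet: orders 1..", length(object@rho),
      " over ", length(object@rho[[1L]]), " starting class(es)\n", sep = "")
  cat("  rho_1[1] =", signif(object@rho[[1L]][1L], 6), "\n")
})

setMethod("show", "LongevityMoments", function(object) {
  cat("LongevityMoments over", length(object@eta1), "class(es); eta1[1] =",
      signif(object@eta1[1L], 6), "\n")
})

setMethod("show", "HealthStatistics", function(object) {
  cat("HealthStatistics over", length(object@mean), "starting class(es)\n")
  if (length(object@meta)) {
    keys <- names(object@meta)
    cat("  meta:", paste(keys, unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  print(utils::head(statsTable(object), 4))
  if (length(object@mean) > 4) cat("  ...\n")
})

setMethod("show", "DalySpec", function(object) {
  cat("DalySpec over", length(object@mortality@surv), "age class(es)\n")
  cat("  mean cause-1 death fraction:",
      signif(mean(object@cause1Fraction), 4), "\n")
  cat("  mean prevalence:", signif(mean(object@prevalence), 4),
      " mean severity:", signif(mean(object@severity), 4), "\n")
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", length(object@rewards), "replicates from state",
      object@start, "(seed", paste0(object@seed, ")"), "\n")
  cat("  empirical mean =", signif(object@moments[1L], 6),
      "+/-", signif(object@se[1L], 3), "\n")
})
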