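#' Accessor generics
#'
#' Small accessor family for the package's S4 classes: `ageClasses()`
#' returns the age (or stage) labels; `survProb()` and `deathProb()` the
#' per-class survival and death probabilities; `isOpenEnded()` whether the
#' last class is open-ended; `rewardMoment(x, k)` the kth reward moment
#' matrix; `momentVector(x, k)` the kth moment vector of lifetime
#' accumulated reward; `momentOrder()` the highest moment order available;
#' `statsTable()` a plain `data.frame` rendering of a result object.
#'
#' @param x an object of the appropriate class.
#' @param k moment order (integer).
#' @return `ageClasses`, `survProb`, `deathProb`, `momentVector`: numeric
#'   vectors; `isOpenEnded`: logical; `rewardMoment`: a matrix;
#'   `momentOrder`: integer; `statsTable`: a `data.frame`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ageClasses", function(x) standardGeneric("ageClasses"))

#' @rdname accessors
#' @export
setGeneric("survProb", function(x) standardGeneric("survProb"))

#' @rdname accessors
#' @export
setGeneric("deathProb", function(x) standardGeneric("deathProb"))

#' @rdname accessors
#' @export
setGeneric("isOpenEnded", function(x) standardGeneric("isOpenEnded"))

#' @rdname accessors
#' @export
setGeneric("rewardMoment", function(x, k) standardGeneric("rewardMoment"))

#' @rdname accessors
#' @export
setGeneric("momentVector", function(x, k) standardGeneric("momentVector"))

#' @rdname accessors
#' @export
setGeneric("momentOrder", function(x) standardGeneric("momentOrder"))

#' @rdname accessors
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
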