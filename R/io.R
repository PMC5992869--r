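#' Read a mortality schedule from a delimited file
#'
#' The plain dialect is a CSV with a header and columns `age` plus either
#' `qx` (death probability) or `px` (survival probability), one row per
#' age class in ascending order. The `hmd` dialect accepts period
#' life-table extracts with columns `Age` and `qx`, either comma- or
#' whitespace-delimited, and tolerates the open-age label (e.g. `110+`),
#' which marks the schedule as open-ended.
#'
#' @param path file path.
#' @param dialect `"plain"` (default) or `"hmd"`.
#' @return a [MortalitySchedule].
#' @export
readMortality <- function(path, dialect = c("plain", "hmd")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("mortality file not found: ", path)
  df <- if (dialect == "plain") {
    utils::read.csv(path, strip.white = TRUE, check.names = FALSE)
  } else {
    first <- readLines(path, n = 1L)
    if (grepl(",", first, fixed = TRUE))
      utils::read.csv(path, strip.white = TRUE, check.names = FALSE)
    else
      utils::read.table(path, header = TRUE, check.names = FALSE)
  }
  names(df) <- tolower(names(df))
  if (!"age" %in% names(df))
    stop("missing 'age'/'Age' column in ", path)
  ageRaw <- trimws(as.character(df$age))
  open <- grepl("\\+$", ageRaw)
  if (any(open) && which(open) != length(ageRaw))
    stop("open-age label must be the last row (line ",
         which(open)[1L] + 1L, ")")
  ages <- suppressWarnings(as.numeric(sub("\\+$", "", ageRaw)))
  if (any(is.na(ages)))
    stop("unparseable age at line ", which(is.na(ages))[1L] + 1L,
         " of ", path)
  if (any(duplicated(ages)))
    stop("duplicate age ", ages[duplicated(ages)][1L], " in ", path)
  if (is.unsorted(ages, strictly = TRUE))
    stop("ages must be strictly ascending in ", path)
  if ("qx" %in% names(df)) {
    qx <- as.numeric(df$qx)
    bad <- !is.finite(qx) | qx < 0 | qx > 1
    if (any(bad))
      stop("qx outside [0, 1] at line ", which(bad)[1L] + 1L, " of ", path)
    p <- 1 - qx
  } else if ("px" %in% names(df)) {
    p <- as.numeric(df$px)
    bad <- !is.finite(p) | p < 0 | p > 1
    if (any(bad))
      stop("px outside [0, 1] at line ", which(bad)[1L] + 1L, " of ", path)
  } else {
    stop("missing 'qx' or 'px' column in ", path)
  }
  mortalitySchedule(p, ages = ages, openEnded = any(open))
}

#' Read a prevalence schedule
#'
#' Reads a CSV with columns `age` and `prevalence` (or several outcome
#' columns for polychotomous data). Returns a named numeric vector (names
#' are ages) for a single outcome, or a named list of such vectors for
#' multiple outcomes.
#'
#' @param path file path.
#' @return named numeric vector, or named list of them.
#' @export
readPrevalence <- function(path) {
  if (!file.exists(path)) stop("prevalence file not found: ", path)
  df <- utils::read.csv(path, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!"age" %in% names(df)) stop("missing 'age' column in ", path)
  cols <- setdiff(names(df), "age")
  if (!length(cols)) stop("no outcome columns in ", path)
  out <- lapply(cols, function(cn) {
    v <- as.numeric(df[[cn]])
    bad <- !is.finite(v) | v < 0 | v > 1
    if (any(bad))
      stop("prevalence '", cn, "' outside [0, 1] at line ",
           which(bad)[1L] + 1L, " of ", path)
    stats::setNames(v, df$age)
  })
  names(out) <- cols
  if (length(out) == 1L) out[[1L]] else out
}

#' Per-age raw moments of a quantitative outcome from microdata
#'
#' @param df data.frame with columns `age` and `value` (one row per
#'   individual observation).
#' @return data.frame with columns `age, m1, m2, m3` (raw moments about
#'   zero per age class).
#' @export
momentsFromMicrodata <- function(df) {
  stopifnot(all(c("age", "value") %in% names(df)))
  if (!nrow(df)) stop("no observations in any age class")
  if (any(!is.finite(df$value))) stop("non-finite outcome values")
  ages <- sort(unique(df$age))
  n <- vapply(ages, function(a) sum(df$age == a), numeric(1))
  if (any(n < 1))
    stop("no observations in age class ", ages[which(n < 1)[1L]])
  mom <- function(k) vapply(ages, function(a)
    mean(df$value[df$age == a]^k), numeric(1))
  data.frame(age = ages, m1 = mom(1), m2 = mom(2), m3 = mom(3))
}

#' Read a quantitative outcome schedule
#'
#' Accepts either microdata (columns `age, value`; per-age raw moments are
#' computed internally) or pre-aggregated moments (columns
#' `age, m1, m2, m3`).
#'
#' @param path file path.
#' @return data.frame with columns `age, m1, m2, m3`.
#' @export
readOutcome <- function(path) {
  if (!file.exists(path)) stop("outcome file not found: ", path)
  df <- utils::read.csv(path, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (all(c("age", "value") %in% names(df))) {
    momentsFromMicrodata(df)
  } else if (all(c("age", "m1", "m2", "m3") %in% names(df))) {
    if (any(df$m2 - df$m1^2 < -1e-9))
      stop("inconsistent moments (m2 < m1^2) at line ",
           which(df$m2 - df$m1^2 < -1e-9)[1L] + 1L, " of ", path)
    df[c("age", "m1", "m2", "m3")]
  } else {
    stop("expected columns 'age,value' (microdata) or 'age,m1,m2,m3' in ", path)
  }
}

#' Align an age-indexed schedule to a mortality schedule
#'
#' Inner-joins on age, warning if classes had to be dropped from either
#' side.
#'
#' @param x named numeric vector (names are ages) or data.frame with an
#'   `age` column.
#' @param schedule a [MortalitySchedule].
#' @return `x` restricted and ordered to the schedule's age grid, plus the
#'   (possibly truncated) schedule, as `list(x, schedule)`.
#' @export
alignToAges <- function(x, schedule) {
  stopifnot(is(schedule, "MortalitySchedule"))
  xa <- if (is.data.frame(x)) as.numeric(x$age) else as.numeric(names(x))
  if (!length(xa) || any(is.na(xa)))
    stop("x must be age-indexed (named vector or data.frame with 'age')")
  common <- intersect(schedule@ages, xa)
  if (!length(common)) stop("no ages in common with the mortality schedule")
  if (length(common) < length(schedule@ages) || length(common) < length(xa))
    warning("age grids differ; using the ", length(common),
            " common age class(es)")
  keep <- schedule@ages %in% common
  sched2 <- mortalitySchedule(schedule@surv[keep],
                              ages = schedule@ages[keep],
                              openEnded = schedule@openEnded && keep[length(keep)])
  x2 <- if (is.data.frame(x)) x[match(common, xa), , drop = FALSE]
        else x[match(common, xa)]
  list(x = x2, schedule = sched2)
}

#' Write healthy-longevity statistics to CSV
#'
#' Writes a CSV with columns `age, mean, variance, sd, cv, skewness`,
#' preceded by `#`-prefixed metadata header lines recording the reward
#' mode, death credit, and any other provenance fields stored on the
#' object, so that outputs are self-describing. Missing CV/skewness values
#' are encoded as empty fields.
#'
#' @param stats a [HealthStatistics].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeStatistics <- function(stats, path) {
  stopifnot(is(stats, "HealthStatistics"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  meta <- stats@meta
  meta <- meta[vapply(meta, function(x) length(x) == 1L, logical(1))]
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, format(meta[[key]])), con)
  df <- statsTable(stats)
  num <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
  writeLines("age,mean,variance,sd,cv,skewness", con)
  writeLines(paste(num(df$age), num(df$mean), num(df$variance), num(df$sd),
                   num(df$cv), num(df$skewness), sep = ","), con)
  invisible(path)
}

#' Read back a statistics CSV written by [writeStatistics()]
#'
#' @param path file path.
#' @return list with `stats` (data.frame) and `meta` (named character).
#' @export
readStatistics <- function(path) {
  if (!file.exists(path)) stop("statistics file not found: ", path)
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- character(0)
  if (length(metaLines)) {
    kv <- regmatches(metaLines, regexec("^# *([^:]+): *(.*)$", metaLines))
    meta <- stats::setNames(vapply(kv, `[`, "", 3L),
                            vapply(kv, `[`, "", 2L))
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"))
  list(stats = df, meta = meta)
}
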