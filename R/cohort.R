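# Cohort data model ------------------------------------------------------
#
# A cohort is a tibble with one row per individual and one column per
# analyte.  Non-detects (the "ND" cells of the source table) are stored as
# NA in the numeric analyte columns: a value is present XOR the measurement
# is censored, and every stored value is strictly positive.  Quantification
# limits and the canonical outlier id set travel as attributes.

XENO_SEX <- c("M", "F", "Indet")
XENO_AGE <- c("0-15", "15-30", "30-50", ">50", "unknown")
XENO_PIPE <- c("none", "simple", "special", "imported")
XENO_ANTHRACOSIS <- c("yes", "yes_with_emphysema", "no", "unassessed")
XENO_OUTLIERS <- c(14L, 29L, 31L, 41L)

XENO_SCHEMA <- c("sample_id", "name", "dating_start", "dating_end", "sex",
                 "age_class", "pipe", "shaman", "anthracosis", XENO_ANALYTES)

#' Detection and quantification limits of the analytical method
#'
#' Limits are stored as published for the validated LC-MS/MS assay:
#' 0.01/0.02 ng/mg (LOD/LLOQ) for nicotine and cotinine and 0.05/0.01 ng/mg
#' for the three methylxanthines.  The methylxanthine pair is internally
#' inconsistent (an LOD above its LLOQ); it is kept verbatim and flagged in
#' the `consistent` column rather than silently "corrected".
#'
#' @return A tibble with columns `analyte`, `lod_ng_mg`, `lloq_ng_mg`,
#'   `consistent`.
#' @export
default_limits <- function() {
  tibble::tibble(
    analyte = XENO_ANALYTES,
    lod_ng_mg  = c(0.05, 0.05, 0.05, 0.01, 0.01),
    lloq_ng_mg = c(0.01, 0.01, 0.01, 0.02, 0.02),
    consistent = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

#' Load a hair-xenobiotic cohort table
#'
#' Reads a cohort CSV with the fixed column schema
#' `sample_id,name,dating_start,dating_end,sex,age_class,pipe,shaman,`
#' `anthracosis,theobromine,caffeine,theophylline,nicotine,cotinine`,
#' where concentration cells hold either a positive number (pg/mg) or the
#' literal token `ND` for a non-detect.  `path = "builtin"` returns the
#' packaged 47-individual Yakutia reference cohort.
#'
#' @param path Path to a cohort CSV, or `"builtin"`.
#' @return A tibble of class `xeno_cohort`; ND cells become `NA`, and the
#'   quantification limits ([default_limits()]) and canonical outlier ids
#'   (`14, 29, 31, 41`) are attached as attributes `limits` and
#'   `outlier_ids`.
#' @export
#' @examples
#' ch <- load_cohort()
#' nrow(ch)
load_cohort <- function(path = "builtin") {
  if (identical(path, "builtin")) {
    path <- system.file("extdata", "yakutia_hair_cohort.csv",
                        package = "paleoxeno", mustWork = TRUE)
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  if (!identical(names(raw), XENO_SCHEMA)) {
    stop("cohort CSV header must be exactly: ",
         paste(XENO_SCHEMA, collapse = ","), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) return(new_cohort(empty_cohort_df()))

  bad_token <- function(field, allowed) {
    bad <- which(!(raw[[field]] %in% allowed))
    if (length(bad)) {
      stop(sprintf("row %d: unknown %s token '%s'",
                   bad[1], field, raw[[field]][bad[1]]), call. = FALSE)
    }
  }
  bad_token("sex", XENO_SEX)
  bad_token("age_class", XENO_AGE)
  bad_token("pipe", XENO_PIPE)
  bad_token("shaman", c("TRUE", "FALSE"))
  bad_token("anthracosis", XENO_ANTHRACOSIS)

  sample_id <- suppressWarnings(as.integer(raw$sample_id))
  if (anyNA(sample_id)) {
    stop(sprintf("row %d: non-integer sample_id '%s'",
                 which(is.na(sample_id))[1],
                 raw$sample_id[which(is.na(sample_id))[1]]), call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  dating_start <- suppressWarnings(as.integer(raw$dating_start))
  dating_end <- suppressWarnings(as.integer(raw$dating_end))
  if (anyNA(dating_start) || anyNA(dating_end)) {
    stop("non-numeric dating bound", call. = FALSE)
  }
  if (any(dating_start > dating_end)) {
    stop(sprintf("row %d: dating interval start exceeds end",
                 which(dating_start > dating_end)[1]), call. = FALSE)
  }

  conc <- lapply(XENO_ANALYTES, function(a) parse_conc(raw[[a]], a))
  names(conc) <- XENO_ANALYTES

  out <- tibble::tibble(
    sample_id = sample_id,
    name = raw$name,
    dating_start = dating_start,
    dating_end = dating_end,
    sex = factor(raw$sex, levels = XENO_SEX),
    age_class = factor(raw$age_class, levels = XENO_AGE),
    pipe = factor(raw$pipe, levels = XENO_PIPE),
    shaman = as.logical(raw$shaman),
    anthracosis = factor(raw$anthracosis, levels = XENO_ANTHRACOSIS)
  )
  for (a in XENO_ANALYTES) out[[a]] <- conc[[a]]
  new_cohort(out)
}

parse_conc <- function(x, analyte) {
  x <- trimws(x)
  val <- rep(NA_real_, length(x))
  num <- x != "ND"
  parsed <- suppressWarnings(as.numeric(x[num]))
  if (anyNA(parsed)) {
    stop(sprintf("row %d: %s cell '%s' is neither a number nor ND",
                 which(num)[which(is.na(parsed))[1]], analyte,
                 x[num][which(is.na(parsed))[1]]), call. = FALSE)
  }
  if (any(parsed <= 0)) {
    stop(sprintf("row %d: %s concentration must be > 0 (got %s)",
                 which(num)[which(parsed <= 0)[1]], analyte,
                 parsed[which(parsed <= 0)[1]]), call. = FALSE)
  }
  val[num] <- parsed
  val
}

empty_cohort_df <- function() {
  out <- tibble::tibble(
    sample_id = integer(), name = character(),
    dating_start = integer(), dating_end = integer(),
    sex = factor(character(), levels = XENO_SEX),
    age_class = factor(character(), levels = XENO_AGE),
    pipe = factor(character(), levels = XENO_PIPE),
    shaman = logical(),
    anthracosis = factor(character(), levels = XENO_ANTHRACOSIS)
  )
  for (a in XENO_ANALYTES) out[[a]] <- numeric()
  out
}

new_cohort <- function(df) {
  attr(df, "limits") <- default_limits()
  attr(df, "outlier_ids") <- XENO_OUTLIERS
  class(df) <- unique(c("xeno_cohort", class(df)))
  df
}

#' Write a cohort back to CSV
#'
#' Inverse of [load_cohort()]: non-detects are emitted as the literal token
#' `ND`, so `load_cohort(write_cohort(x, f))` round-trips field for field.
#'
#' @param cohort An `xeno_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, XENO_SCHEMA]
  for (a in XENO_ANALYTES) {
    v <- out[[a]]
    out[[a]] <- ifelse(is.na(v), "ND",
                       vapply(v, format, "", scientific = FALSE))
  }
  out$shaman <- ifelse(out$shaman, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Era of each individual relative to the 1800 AD split
#'
#' The cohort is periodized at 1800 AD (pre-assimilation vs assimilation
#' into Russian society).  An individual whose dating interval ends at or
#' before 1800 is `before_1800`; one whose interval starts at or after 1800
#' is `after_1800`.  Intervals straddling 1800 are rejected rather than
#' guessed (none exist in the reference cohort).
#'
#' @param cohort An `xeno_cohort`, or a vector of interval starts.
#' @param dating_end Interval ends, when `cohort` is a vector of starts.
#' @return Factor with levels `before_1800`, `after_1800`.
#' @export
#' @examples
#' era_of(1750, 1800)   # before_1800
#' era_of(1800, 1850)   # after_1800
era_of <- function(cohort, dating_end = NULL) {
  if (inherits(cohort, "xeno_cohort")) {
    start <- cohort$dating_start
    end <- cohort$dating_end
  } else {
    start <- cohort
    end <- dating_end
  }
  straddle <- start < 1800 & end > 1800
  if (any(straddle)) {
    stop("dating interval straddles 1800 AD for row(s) ",
         paste(which(straddle), collapse = ", "),
         "; era is undefined", call. = FALSE)
  }
  factor(ifelse(end <= 1800, "before_1800", "after_1800"),
         levels = c("before_1800", "after_1800"))
}

#' Detection status of censored concentrations
#'
#' The source table stores only quantified values, so any stored value
#' counts as detected and `ND` cells do not.
#'
#' @param x Numeric vector with `NA` for non-detects (e.g. an analyte
#'   column of an `xeno_cohort`).
#' @return Logical vector.
#' @export
detected <- function(x) !is.na(x)

#' Numeric analyte panel of one individual
#'
#' @param ind One-row `xeno_cohort` (or any list with the five analyte
#'   fields).
#' @param nd_policy `"zero"` replaces non-detects by 0; `"drop"` omits
#'   them (used for detected-only summaries).
#' @return Named numeric vector in canonical analyte order (possibly
#'   shorter under `"drop"`).
#' @export
numeric_panel <- function(ind, nd_policy = c("zero", "drop")) {
  nd_policy <- match.arg(nd_policy)
  v <- vapply(XENO_ANALYTES, function(a) as.numeric(ind[[a]][1]), 0.0)
  if (nd_policy == "zero") {
    v[is.na(v)] <- 0
    v
  } else {
    v[!is.na(v)]
  }
}

#' Analyte concentration matrix of a cohort
#'
#' @param cohort An `xeno_cohort`.
#' @param which Analyte names (default all five).
#' @param nd_policy `"zero"` (non-detects as 0) or `"na"` (keep censoring).
#' @return Numeric matrix, one row per individual, rownames = sample ids.
#' @export
analyte_matrix <- function(cohort, which = XENO_ANALYTES,
                           nd_policy = c("zero", "na")) {
  nd_policy <- match.arg(nd_policy)
  stopifnot(all(which %in% XENO_ANALYTES))
  m <- as.matrix(as.data.frame(cohort)[, which, drop = FALSE])
  if (nd_policy == "zero") m[is.na(m)] <- 0
  rownames(m) <- cohort$sample_id
  m
}

#' Canonical outlier ids of a cohort
#' @param cohort An `xeno_cohort`.
#' @return Integer vector of sample ids flagged as PCA outliers.
#' @export
outlier_ids <- function(cohort) attr(cohort, "outlier_ids")

#' Validate a cohort file and summarise its strata
#'
#' Loads `path` through the full schema validation and prints stratum
#' counts (era, sex, age class, per-analyte detections).  Errors from
#' malformed files propagate with their row numbers.
#'
#' @param path Cohort CSV path or `"builtin"`.
#' @return The validated cohort, invisibly.
#' @export
validate_cohort <- function(path = "builtin") {
  ch <- load_cohort(path)
  cat(sprintf("cohort: %d individuals\n", nrow(ch)))
  if (nrow(ch)) {
    cat("era:  ", paste(sprintf("%s=%d", levels(era_of(ch)),
                                table(era_of(ch))), collapse = "  "), "\n")
    cat("sex:  ", paste(sprintf("%s=%d", levels(ch$sex), table(ch$sex)),
                        collapse = "  "), "\n")
    cat("age:  ", paste(sprintf("%s=%d", levels(ch$age_class),
                                table(ch$age_class)), collapse = "  "), "\n")
    det <- vapply(XENO_ANALYTES, function(a) sum(detected(ch[[a]])), 0L)
    cat("detected:", paste(sprintf("%s=%d", names(det), det),
                           collapse = "  "), "\n")
  }
  invisible(ch)
}
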