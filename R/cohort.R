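.status_levels <- c("alive", "dead_cancer", "dead_other")

.case_columns <- c("id", "sex", "age_dx", "year_dx", "futime", "status", "morph", "site")

#' Registry cohort
#'
#' A `cohort` is a data frame of case records with one row per case and
#' columns `id` (unique), `sex`, `age_dx` (years at diagnosis), `year_dx`
#' (real calendar year of diagnosis), `futime` (years from diagnosis to death
#' or censoring, `> 0`), `status` (one of `alive`, `dead_cancer`,
#' `dead_other`), `morph` (ICD-O-3 morphology code) and `site` (ICD-O-3
#' topography, e.g. `"C69.3"`), plus a `study_end` attribute giving the
#' administrative censoring date as a real calendar year.
#'
#' `alive` means right-censored at `futime`; `dead_cancer` means the recorded
#' cause of death is the cancer of interest.
#'
#' @param cases data frame with the columns above.
#' @param study_end real calendar year of administrative censoring.
#' @return The validated `cohort` object.
#' @export
new_cohort <- function(cases, study_end) {
  stopifnot(is.data.frame(cases), is.numeric(study_end), length(study_end) == 1L)
  missing_cols <- setdiff(.case_columns, names(cases))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  cases <- as.data.frame(cases)[, .case_columns]
  if (anyDuplicated(cases$id)) stop("case ids must be unique")
  if (any(cases$futime <= 0)) stop("all futime must be > 0")
  if (any(cases$age_dx < 0)) stop("all age_dx must be >= 0")
  if (any(cases$age_dx + cases$futime > 125))
    stop("age_dx + futime exceeds 125 years for some cases")
  if (!all(cases$status %in% .status_levels))
    stop("status must be one of: ", paste(.status_levels, collapse = ", "))
  structure(cases, study_end = as.numeric(study_end),
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  st <- table(factor(x$status, levels = .status_levels))
  cat("Registry cohort: ", nrow(x), " cases, study end ", attr(x, "study_end"), "\n",
      "  alive ", st[["alive"]], ", dead of cancer ", st[["dead_cancer"]],
      ", dead of other causes ", st[["dead_other"]], "\n",
      "  age at dx ", round(min(x$age_dx), 1), "-", round(max(x$age_dx), 1),
      " (median ", round(stats::median(x$age_dx), 1), "), diagnosis years ",
      floor(min(x$year_dx)), "-", floor(max(x$year_dx)), "\n", sep = "")
  invisible(x)
}

#' Select uveal melanoma cases by ICD-O-3 codes
#'
#' Retains cases with melanoma morphology (8720-8790) at uveal sites:
#' C69.2 (retina), C69.3 (choroid), C69.4 (ciliary body and iris).
#' Input order is preserved; the retained/dropped counts are recorded in the
#' `"filter_log"` attribute and reported via `message()`.
#'
#' @param cases data frame of case records (see [new_cohort()]); may already
#'   be a `cohort`.
#' @param study_end administrative censoring year; defaults to the input's
#'   `study_end` attribute, or the latest observed `year_dx + futime`.
#' @return A `cohort` of the retained cases.
#' @export
filter_uveal_melanoma <- function(cases, study_end = NULL) {
  keep <- cases$morph >= 8720 & cases$morph <= 8790 &
    cases$site %in% c("C69.2", "C69.3", "C69.4")
  keep[is.na(keep)] <- FALSE
  log <- c(retained = sum(keep), dropped = sum(!keep))
  message("filter_uveal_melanoma: retained ", log[["retained"]],
          ", dropped ", log[["dropped"]])
  if (is.null(study_end)) {
    study_end <- attr(cases, "study_end")
    if (is.null(study_end))
      study_end <- if (any(keep)) max(cases$year_dx[keep] + cases$futime[keep]) else NA_real_
  }
  out <- cases[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- if (nrow(out)) new_cohort(out, study_end) else
    structure(out, study_end = study_end, class = c("cohort", "data.frame"))
  attr(out, "filter_log") <- log
  out
}

#' Default column mapping for delimited case listings
#'
#' Names the input columns holding each case-record field. Survival time is
#' expected in whole months (`srv_time_mon`) and is converted to years.
#'
#' @param ... named overrides, e.g. `status = "vital_recode"`.
#' @return Named list of column names.
#' @export
case_column_mapping <- function(...) {
  m <- list(id = "id", sex = "sex", age_dx = "age_dx", year_dx = "year_dx",
            srv_time_mon = "srv_time_mon", status = "status",
            morph = "morph", site = "site")
  utils::modifyList(m, list(...))
}

#' Read case records from delimited text
#'
#' Reads a CSV (or TSV, by file extension) case listing with a header row.
#' Survival time in months is converted to years (/12). Records with zero or
#' negative survival time are set to half a month (0.5/12 years) — registries
#' record whole months and zero-length follow-up breaks product-limit
#' estimators — and their ids are recorded in the `"zero_time_ids"`
#' attribute. Rows with missing status are dropped with a logged count; rows
#' with unparseable numerics are dropped and reported in the `"bad_rows"`
#' attribute, and the run continues.
#'
#' @param path delimited text file with header.
#' @param mapping a [case_column_mapping()].
#' @param sep field separator; default inferred from the file extension
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @return Data frame of case records (columns as in [new_cohort()]).
#' @export
read_cases <- function(path, mapping = case_column_mapping(), sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(unlist(mapping), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  num <- function(col) suppressWarnings(as.numeric(raw[[mapping[[col]]]]))
  out <- data.frame(id = raw[[mapping$id]],
                    sex = raw[[mapping$sex]],
                    age_dx = num("age_dx"),
                    year_dx = num("year_dx"),
                    futime = num("srv_time_mon") / 12,
                    status = raw[[mapping$status]],
                    morph = num("morph"),
                    site = raw[[mapping$site]],
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$age_dx) | is.na(out$year_dx) | is.na(out$futime) |
                 is.na(out$morph))
  if (length(bad)) {
    warning(length(bad), " row(s) with unparseable numerics dropped: rows ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "")
  }
  no_status <- which(!(out$status %in% .status_levels))
  if (length(setdiff(no_status, bad)))
    message("read_cases: dropped ", length(setdiff(no_status, bad)),
            " row(s) with missing/unknown status")
  drop <- union(bad, no_status)
  if (length(drop)) out <- out[-drop, , drop = FALSE]
  zero <- out$futime <= 0
  if (any(zero)) {
    message("read_cases: ", sum(zero),
            " record(s) with zero survival time set to half a month")
    out$futime[zero] <- 0.5 / 12
  }
  rownames(out) <- NULL
  attr(out, "zero_time_ids") <- out$id[zero]
  attr(out, "bad_rows") <- bad
  out
}

#' Write case records as CSV
#'
#' Inverse of [read_cases()] under the default mapping: survival time is
#' written in months (`futime * 12`).
#'
#' @param cases a `cohort` or case-record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  out <- data.frame(id = cases$id, sex = cases$sex, age_dx = cases$age_dx,
                    year_dx = cases$year_dx, srv_time_mon = cases$futime * 12,
                    status = cases$status, morph = cases$morph, site = cases$site)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a cohort at an age-at-diagnosis cutoff
#'
#' @param cohort a `cohort`.
#' @param cut age in years; cases with `age_dx < cut` go to the first group,
#'   `age_dx >= cut` to the second.
#' @return Named list `young`/`old` of two cohorts forming an exact partition
#'   of the input.
#' @export
split_by_age <- function(cohort, cut = 50) {
  stopifnot(inherits(cohort, "cohort"), cut > 0)
  se <- attr(cohort, "study_end")
  mk <- function(df) {
    rownames(df) <- NULL
    if (nrow(df)) new_cohort(df, se) else
      structure(df, study_end = se, class = c("cohort", "data.frame"))
  }
  young <- cohort$age_dx < cut
  list(young = mk(as.data.frame(cohort)[young, , drop = FALSE]),
       old = mk(as.data.frame(cohort)[!young, , drop = FALSE]))
}
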