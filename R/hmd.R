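#' Read a Human Mortality Database Mx_1x1 file
#'
#' Parses the HMD period death-rate text dialect: an arbitrary leading header
#' block, then whitespace-delimited columns `Year Age Female Male Total`, one
#' row per (year, age). Age `"110+"` maps to age 110 (the table's open
#' terminal cell). Missing rates (`"."`) are filled by carrying the last
#' finite rate at a lower age forward for that sex and year; if no lower age
#' has a finite rate, 0 is used.
#'
#' @param path path to an Mx_1x1 text file.
#' @return A [new_lifetable()] object covering all parsed years and ages.
#' @export
read_hmd_mx <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "\\s+")
  is_data <- vapply(toks, function(tk) {
    length(tk) >= 2L && grepl("^[0-9]{4}$", tk[[1]]) &&
      grepl("^([0-9]+\\+?)$", tk[[2]])
  }, logical(1))
  if (!any(is_data)) stop("no data rows found in HMD file: ", path)
  first <- which(is_data)[1]
  for (i in seq(first, length(lines))) {
    if (!nzchar(trimws(lines[i]))) next
    if (length(toks[[i]]) != 5L)
      stop("malformed HMD row (expected 5 columns) at line ", i, ": ", lines[i])
  }
  keep <- is_data & nzchar(trimws(lines))
  tk <- toks[keep]
  year <- as.integer(vapply(tk, `[[`, "", 1L))
  age_str <- vapply(tk, `[[`, "", 2L)
  age <- as.integer(sub("\\+$", "", age_str))
  parse_rate <- function(j) {
    v <- vapply(tk, `[[`, "", j)
    out <- suppressWarnings(as.numeric(v))
    out[v == "."] <- NA_real_
    out
  }
  female <- parse_rate(3L); male <- parse_rate(4L)

  for (y in unique(year)) {
    a <- age[year == y]
    if (is.unsorted(a, strictly = TRUE))
      stop("non-monotone ages within year ", y, " in HMD file")
  }

  age_min <- min(age); age_max <- max(age)
  year_min <- min(year); year_max <- max(year)
  rates <- array(0, dim = c(age_max - age_min + 1L, year_max - year_min + 1L, 2L))
  ai <- age - age_min + 1L; yi <- year - year_min + 1L
  rates[cbind(ai, yi, 1L)] <- female
  rates[cbind(ai, yi, 2L)] <- male
  # carry-forward fill in age, per sex and year; leading NAs become 0
  for (s in 1:2) for (y in seq_len(dim(rates)[2])) {
    col <- rates[, y, s]
    if (anyNA(col)) {
      last <- 0
      for (a in seq_along(col)) {
        if (is.na(col[a])) col[a] <- last else last <- col[a]
      }
      rates[, y, s] <- col
    }
  }
  new_lifetable(rates, age_min, age_max, year_min, year_max)
}

#' Write a life table in the HMD Mx_1x1 dialect
#'
#' Inverse of [read_hmd_mx()]: writes a header line, the standard column
#' header, and one `Year Age Female Male Total` row per cell. The terminal
#' age is written as `"110+"` style (`<age_max>+`). `Total` is written as the
#' mean of the two sex rates (it is ignored on re-read).
#'
#' @param table a [new_lifetable()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hmd_mx <- function(table, path) {
  stopifnot(inherits(table, "lifetable"))
  ages <- table$age_min:table$age_max
  years <- table$year_min:table$year_max
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Synthetic period death rates (Mx_1x1 dialect)", "",
               sprintf("%6s %6s %12s %12s %12s", "Year", "Age", "Female", "Male", "Total")),
             con)
  for (y in seq_along(years)) {
    a_lab <- c(as.character(ages[-length(ages)]), paste0(ages[length(ages)], "+"))
    f <- table$rates[, y, 1L]; m <- table$rates[, y, 2L]
    writeLines(sprintf("%6d %6s %15.8e %15.8e %15.8e", years[y], a_lab, f, m, (f + m) / 2), con)
  }
  invisible(path)
}
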