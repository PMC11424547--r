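#' Parse FAERS-style compact dates
#'
#' FAERS quarterly files carry dates as digit strings of three precisions:
#' `YYYYMMDD` (day), `YYYYMM` (month) and `YYYY` (year). All three are
#' accepted; finer precision is retained where present. Each value is mapped
#' to a sortable integer key obtained by zero-padding to eight digits
#' (`2023` becomes `20230000`), so partial dates order before complete dates
#' of the same year or year-month. Only day-precision values are converted
#' to [Date] and take part in day-resolution arithmetic such as
#' time-to-onset.
#'
#' @param x Character or numeric vector of compact dates; `""`/`NA` are
#'   treated as missing.
#' @return A tibble with one row per input: `key` (integer sort key, `NA`
#'   when missing), `precision` (`"day"`, `"month"`, `"year"` or `NA`) and
#'   `date` (a [Date], `NA` unless day precision).
#' @examples
#' parse_faers_date(c("20230301", "202303", "2023", ""))
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringr::str_trim(x)
  nc <- nchar(x)
  ok <- stringr::str_detect(x, "^[0-9]*$")

  precision <- dplyr::case_when(
    x == "" | !ok ~ NA_character_,
    nc == 8L ~ "day",
    nc == 6L ~ "month",
    nc == 4L ~ "year",
    TRUE ~ NA_character_
  )
  key <- rep(NA_real_, length(x))
  valid <- !is.na(precision)
  key[valid] <- as.numeric(
    stringr::str_pad(x[valid], 8L, side = "right", pad = "0")
  )
  date <- rep(as.Date(NA), length(x))
  day <- !is.na(precision) & precision == "day"
  if (any(day)) {
    d <- as.Date(x[day], format = "%Y%m%d")
    key[day][is.na(d)] <- NA_real_
    precision[day][is.na(d)] <- NA_character_
    date[day] <- d
  }
  tibble::tibble(key = as.integer(key), precision = precision, date = date)
}

# Format a Date (or NA) back to YYYYMMDD text, "" when missing.
format_faers_date <- function(x) {
  out <- format(x, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}
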