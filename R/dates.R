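#' Parse FAERS-style numeric date strings
#'
#' FAERS date fields are plain digit strings: 8 digits are a full
#' `yyyymmdd` date, 6 digits a year-month, 4 digits a year only.  Anything
#' else (including calendar-invalid combinations such as month 13) is
#' treated as missing.  The function is total: no input raises an error.
#'
#' @param x character vector of raw date fields (may contain `NA` or "").
#' @return A data.frame with one row per input and columns
#'   \describe{
#'     \item{date}{`Date`; the full date when `precision == "day"`, the
#'       first day of the period for month/year precision, `NA` otherwise.}
#'     \item{precision}{one of `"day"`, `"month"`, `"year"`, `"missing"`.}
#'   }
#' @examples
#' faers_parse_date(c("20230215", "202302", "2023", "20231315", ""))
#' @export
faers_parse_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  n <- length(x)
  date <- rep(as.Date(NA), n)
  precision <- rep("missing", n)

  digits <- grepl("^[0-9]+$", x)

  is8 <- digits & nchar(x) == 8L
  if (any(is8)) {
    d <- as.Date(x[is8], format = "%Y%m%d")
    # as.Date() yields NA for invalid calendar combinations, but also
    # accepts e.g. day 00 on some platforms; re-format to confirm.
    ok <- !is.na(d) & format(d, "%Y%m%d") == x[is8]
    date[is8][ok] <- d[ok]
    precision[is8][ok] <- "day"
  }

  is6 <- digits & nchar(x) == 6L
  if (any(is6)) {
    mm <- as.integer(substr(x[is6], 5, 6))
    ok <- mm >= 1L & mm <= 12L
    date[is6][ok] <- as.Date(paste0(x[is6][ok], "01"), format = "%Y%m%d")
    precision[is6][ok] <- "month"
  }

  is4 <- digits & nchar(x) == 4L
  if (any(is4)) {
    yy <- as.integer(x[is4])
    ok <- yy >= 1000L & yy <= 9999L
    date[is4][ok] <- as.Date(paste0(x[is4][ok], "0101"), format = "%Y%m%d")
    precision[is4][ok] <- "year"
  }

  data.frame(date = date, precision = precision, stringsAsFactors = FALSE)
}
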