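#' @import data.table
#' @importFrom stats rbinom rexp rgeom rnorm rpois runif setNames
#' @importFrom utils head tail
NULL

# Sentinels for the two kinds of missingness. Plain missing is NA (empty cell
# in CSV); missing-by-design (e.g. a survey wave a dead participant could not
# complete) is ".D" in CSV, NaN in numeric columns in memory and the literal
# ".D" string in character columns.
CF_MBD_TOKEN <- ".D"

#' Missing-by-design sentinel helpers
#'
#' Missing-by-design values (data absent for a structural reason, such as a
#' follow-up survey a participant had died before) are distinct from plain
#' missing values. In memory they are `NaN` in numeric columns and the string
#' `".D"` in character columns; in CSV files both serialize as `".D"`, while
#' plain missing serializes as an empty cell.
#'
#' @param x a vector.
#' @param n length of the sentinel vector to create.
#' @return `is_missing_by_design()` returns a logical vector; `mbd_numeric()`
#'   and `mbd_character()` return sentinel-filled vectors of length `n`.
#' @examples
#' is_missing_by_design(c(1, NaN, NA))
#' @export
is_missing_by_design <- function(x) {
  if (is.numeric(x)) return(is.nan(x))
  if (is.character(x)) return(!is.na(x) & x == CF_MBD_TOKEN)
  rep(FALSE, length(x))
}

#' @rdname is_missing_by_design
#' @export
mbd_numeric <- function(n) rep(NaN, n)

#' @rdname is_missing_by_design
#' @export
mbd_character <- function(n) rep(CF_MBD_TOKEN, n)

#' Parse a user-entered date
#'
#' User-facing inputs accept the MM/DD/YYYY convention in addition to
#' ISO-8601; everything is normalized to `Date` on entry and all files use
#' ISO-8601.
#'
#' @param x character vector of dates, `MM/DD/YYYY` or `YYYY-MM-DD`.
#' @return a `Date` vector.
#' @examples
#' parse_user_date("01/01/2005")
#' parse_user_date("2005-01-01")
#' @export
parse_user_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  us <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[us] <- as.Date(x[us], format = "%m/%d/%Y")
  out[iso] <- as.Date(x[iso])
  bad <- !is.na(x) & x != "" & !us & !iso
  if (any(bad)) {
    stop("unparseable date(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected MM/DD/YYYY or YYYY-MM-DD)", call. = FALSE)
  }
  out
}

# days between two Dates as integer
days_between <- function(from, to) as.integer(as.numeric(to) - as.numeric(from))

`%||%` <- function(a, b) if (is.null(a)) b else a

# path to a bundled reference table
cf_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cohortforge")
  if (!nzchar(path)) stop("bundled table not found: ", file, call. = FALSE)
  path
}

# owner-write permission bit; file.access() is useless for privileged users
cf_is_readonly <- function(path) {
  info <- file.info(path)
  !is.na(info$mode) & bitwAnd(as.integer(info$mode), strtoi("200", 8L)) == 0L
}

cf_stop <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "cohortforge_error")))
}
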