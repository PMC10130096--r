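# Internal utilities: calendar-month arithmetic on Date vectors and a pure
# 32-bit string hash used for deterministic fold assignment.

#' @importFrom data.table data.table as.data.table rbindlist := .N .SD
NULL

.datatable.aware <- TRUE

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  d[month == 2L & leap] <- 29L
  d
}

#' Shift dates by whole calendar months
#'
#' Month arithmetic used throughout the ascertainment windows: the year/month
#' field is shifted and the day-of-month is clamped to the length of the
#' target month (e.g. 31 Jan minus 2 months is 30 Nov).
#'
#' @param dates a `Date` vector (or anything coercible).
#' @param k integer number of months to add (negative to subtract).
#' @return a `Date` vector of the same length.
#' @export
add_months <- function(dates, k) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  mon <- lt$year * 12L + lt$mon + as.integer(k)
  y <- mon %/% 12L + 1900L
  m <- mon %% 12L + 1L
  day <- pmin(lt$mday, days_in_month(y, m))
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, day))
  out[is.na(dates)] <- as.Date(NA)
  out
}

#' Round half away from zero
#'
#' The convention of printed percentage tables (base `round()` is
#' half-to-even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## ---- exact 32-bit arithmetic on doubles (values in [0, 2^32)) ----

.MOD32 <- 2^32

xor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

mul32 <- function(a, b) {
  # (a * b) mod 2^32 without exceeding 2^53: split a into 16-bit halves
  ah <- a %/% 65536; al <- a %% 65536
  (((ah * b) %% 65536) * 65536 + al * b) %% .MOD32
}

fmix32 <- function(h) {
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2246822507)
  h <- xor32(h, h %/% 8192)
  h <- mul32(h, 3266489909)
  xor32(h, h %/% 65536)
}

#' Deterministic hash of identifiers to the unit interval
#'
#' Pure function of (id, seed): the same id and seed always map to the same
#' value, independent of the set of ids hashed alongside it. This is what
#' makes nested fold assignments compatible across arbitrary cohort subsets.
#'
#' @param ids character (or coercible) identifiers; ASCII.
#' @param seed a single integer.
#' @return numeric vector in `[0, 1)`.
#' @export
hash_unit <- function(ids, seed) {
  ids <- as.character(ids)
  stopifnot(length(seed) == 1, is.finite(seed))
  if (length(ids) == 0) return(numeric(0))
  w <- max(nchar(ids, type = "bytes"))
  padded <- formatC(ids, width = w, flag = " ")
  codes <- matrix(utf8ToInt(paste(padded, collapse = "")), nrow = w)
  h <- rep(mul32((as.numeric(seed) %% .MOD32) + 2654435769, 2654435761),
           length(ids))
  for (j in seq_len(w)) {
    h <- (mul32(h, 31) + codes[j, ]) %% .MOD32
  }
  fmix32(h) / .MOD32
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_levels <- function() c("localized", "regional", "distant", "others")
site_levels <- function() c("breast", "colorectal", "liver", "lung", "oral")
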