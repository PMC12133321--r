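# Shared internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed integer percentages in
#' radiology QC reports conventionally round half up, so the package routes
#' every displayed percentage through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 94.7))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Trim whitespace; "" and all-blank collapse to NA.
str_or_na <- function(x) {
  if (is.null(x) || length(x) == 0 || all(is.na(x))) return(NA_character_)
  x <- trimws(x)
  if (!nzchar(x)) NA_character_ else x
}

# Drop NULL elements of a list (so jsonlite never sees them).
compact <- function(x) x[!vapply(x, is.null, logical(1))]

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == trunc(x)

#' Apportion a total into integer counts by largest remainder
#'
#' Splits `total` into integer counts proportional to `shares` (which must sum
#' to 1) using the largest-remainder (Hamilton) method: each category first
#' receives the floor of its exact quota, then the leftover units go to the
#' categories with the largest fractional remainders. Ties on the remainder are
#' broken in favour of the earlier-listed category, making the result fully
#' deterministic.
#'
#' @param shares numeric vector of non-negative fractions summing to 1
#'   (within 1e-9); names are preserved.
#' @param total integer total to distribute.
#' @return integer vector of counts summing exactly to `total`.
#' @export
#' @examples
#' apportion_largest_remainder(c(a = 0.5, b = 0.3, c = 0.2), 7)
apportion_largest_remainder <- function(shares, total) {
  stopifnot(is.numeric(shares), length(shares) >= 1, all(shares >= -1e-12))
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("shares must sum to 1 (got ", format(sum(shares), digits = 12), ")")
  }
  if (!is_count(total)) stop("total must be a non-negative integer")
  quota <- shares * total
  base <- floor(quota + 1e-9)          # guard exact quotas against FP dust
  rem <- quota - base
  left <- total - sum(base)
  if (left > 0) {
    # order by remainder desc, then original position asc
    idx <- order(-rem, seq_along(rem))[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(shares)
  stopifnot(sum(counts) == total)
  counts
}
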