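#' Genomic length under the 1-based inclusive convention
#'
#' All coordinates in this package are 1-based and inclusive of both end
#' bases, so a segment spanning positions `start..end` covers
#' `end - start + 1` bp.
#'
#' @param start,end Integer coordinates, `end > start`.
#' @return Length in bp.
#' @export
cnv_length <- function(start, end) {
  if (any(end <= start)) stop("end must be greater than start")
  end - start + 1
}

#' Format a size in kb the way CNV reports print it
#'
#' Below 100 kb sizes are rounded to one decimal; at or above 100 kb to
#' the nearest integer (15,761 bp -> 15.8, 133,901 bp -> 134).
#'
#' @param bp Length in base pairs.
#' @return Numeric kb value under the rounding convention.
#' @export
format_kb <- function(bp) {
  ifelse(bp < 1e5, round(bp / 1000, 1), round(bp / 1000))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix and no call banner
.fail <- function(...) stop(..., call. = FALSE)

.assert_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
    .fail(name, " must be a single non-negative integer")
  as.integer(x)
}

# split a character vector of data lines on tabs (runs of blanks also
# accepted, so hand-written fixtures do not need literal tabs)
.split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")
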