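# Interval algebra on 1-based inclusive residue coordinates.
#
# Intervals travel as data frames with integer columns `start` and `end`
# (both inclusive, UniProt convention). IRanges does the set algebra;
# half-open or 0-based coordinates never appear in the interface.

as_iranges <- function(x) {
  IRanges::IRanges(start = as.integer(x$start), end = as.integer(x$end))
}

iranges_to_df <- function(ir) {
  data.frame(start = as.integer(IRanges::start(ir)),
             end = as.integer(IRanges::end(ir)))
}

#' Validate an interval data frame
#'
#' Checks that `start`/`end` are present, integral, and satisfy
#' 1 <= start <= end. Used by every consumer of interval input; errors
#' name the offending context (e.g. an accession or feature id).
#'
#' @param x data frame with columns `start`, `end`.
#' @param context character scalar naming the object being validated,
#'   used in error messages.
#' @param max_end optional upper bound (protein length).
#' @return `x`, invisibly, with integer coordinates.
#' @keywords internal
check_intervals <- function(x, context = "interval set", max_end = NULL) {
  if (!is.data.frame(x) || !all(c("start", "end") %in% names(x))) {
    stop(context, ": intervals must be a data frame with columns start, end")
  }
  s <- x$start
  e <- x$end
  if (anyNA(s) || anyNA(e)) {
    stop(context, ": interval endpoints must not be missing")
  }
  if (any(s != as.integer(s)) || any(e != as.integer(e))) {
    stop(context, ": interval endpoints must be integers")
  }
  if (any(s < 1L)) {
    stop(context, ": interval start below residue 1")
  }
  if (any(e < s)) {
    stop(context, ": interval end precedes start")
  }
  if (!is.null(max_end) && any(e > max_end)) {
    stop(context, ": interval end ", max(e), " exceeds protein length ",
         max_end)
  }
  x$start <- as.integer(s)
  x$end <- as.integer(e)
  invisible(x)
}

#' Normalize a set of residue intervals
#'
#' Sorts intervals by start and merges overlapping and adjacent ones, so
#' that the result is the minimal sorted, pairwise disjoint,
#' non-adjacent representation of the same residue set. Normalization is
#' idempotent and independent of input order.
#'
#' @param x data frame with 1-based inclusive columns `start`, `end`.
#' @return data frame with columns `start`, `end`, normalized.
#' @examples
#' normalize_intervals(data.frame(start = c(6, 1), end = c(9, 5)))
#' @export
normalize_intervals <- function(x) {
  check_intervals(x)
  iranges_to_df(IRanges::reduce(as_iranges(x)))
}

#' Total residue count of an interval set
#'
#' Length of the union of the residues covered, i.e. the non-redundant
#' residue count. Overlapping or duplicated intervals are counted once.
#'
#' @param x data frame with columns `start`, `end`.
#' @return integer scalar.
#' @examples
#' interval_total_length(data.frame(start = c(360, 360), end = c(365, 362)))
#' @export
interval_total_length <- function(x) {
  check_intervals(x)
  sum(IRanges::width(IRanges::reduce(as_iranges(x))))
}

#' Non-redundant residue count over a collection of interval sets
#'
#' Counts every residue covered by at least one interval exactly once.
#' With annotations at 360--365 and 360--362 on the same protein the
#' union holds six residues, which is the accounting rule used for pProS
#' residue totals.
#'
#' @param interval_sets a single interval data frame, or a list of them,
#'   all on the same protein.
#' @return integer scalar: the cardinality of the union of residue sets.
#' @examples
#' union_residue_count(list(data.frame(start = 360, end = 365),
#'                          data.frame(start = 360, end = 362)))
#' @export
union_residue_count <- function(interval_sets) {
  if (is.data.frame(interval_sets)) interval_sets <- list(interval_sets)
  if (length(interval_sets) == 0L) return(0L)
  combined <- do.call(rbind, lapply(interval_sets, function(x) {
    check_intervals(x)
    x[, c("start", "end"), drop = FALSE]
  }))
  interval_total_length(combined)
}

#' Convert a per-residue call vector to intervals
#'
#' @param calls logical vector, one element per residue.
#' @return data frame with columns `start`, `end` covering the TRUE runs.
#' @export
calls_to_intervals <- function(calls) {
  stopifnot(is.logical(calls))
  if (anyNA(calls)) stop("per-residue calls must not be missing")
  if (!any(calls)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(calls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = as.integer(starts[r$values]),
             end = as.integer(ends[r$values]))
}

#' Convert intervals to a per-residue call vector
#'
#' Inverse of [calls_to_intervals()]; the two interconvert losslessly for
#' normalized interval sets.
#'
#' @param x data frame with columns `start`, `end`.
#' @param length protein length (number of residues).
#' @return logical vector of the given length.
#' @export
intervals_to_calls <- function(x, length) {
  stopifnot(length >= 1L)
  check_intervals(x, max_end = length)
  calls <- logical(length)
  for (i in seq_len(nrow(x))) {
    calls[x$start[i]:x$end[i]] <- TRUE
  }
  calls
}
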