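#' Closed subintervals of the unit interval
#'
#' Constructs intervals `[lower, upper]` with `0 <= lower <= upper <= 1`,
#' the carrier set on which the ensemble's class scores live. An `interval`
#' object is a two-column numeric matrix (columns `lower`, `upper`); a single
#' interval is a one-row matrix, and most operations are vectorised over rows.
#'
#' Out-of-range or inverted bounds are an error, never clipped: scores are
#' brought into the unit interval upstream (see [soft_labels()]), so an
#' invalid interval here always indicates a bug in the caller.
#'
#' @param lower,upper numeric vectors of equal length with
#'   `0 <= lower <= upper <= 1`.
#' @return An `interval` object: an `n x 2` numeric matrix.
#' @examples
#' interval(0.2, 0.4)
#' interval(c(0, 0.1), c(0.5, 0.1))
#' @export
interval <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != length(upper))
    stop("'lower' and 'upper' must be numeric vectors of equal length")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("interval bounds must be finite")
  bad <- lower < 0 | upper > 1 | lower > upper
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("invalid interval: [%g, %g] is not a subinterval of [0, 1]",
                 lower[i], upper[i]))
  }
  structure(cbind(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "interval")
}

as_interval <- function(x) {
  if (inherits(x, "interval")) return(x)
  x <- rbind(x)
  interval(x[, 1L], x[, 2L])
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("<interval[%d]>\n", nrow(x)))
  cat(sprintf("  [%g, %g]\n", x[, 1L], x[, 2L]), sep = "")
  invisible(x)
}

#' @export
`[.interval` <- function(x, i, j, ...) {
  m <- unclass(x)
  if (missing(j)) structure(m[i, , drop = FALSE], class = "interval")
  else m[i, j, ...]
}

#' Interval width and bound sum
#'
#' `iv_width()` returns `upper - lower`; `iv_sum()` returns `lower + upper`.
#' These are the tie-break and primary keys of the Xu-Yager order.
#'
#' @param x an [interval()] object.
#' @return Numeric vector, one value per interval.
#' @export
iv_width <- function(x) {
  x <- as_interval(x)
  unname(x[, 2L] - x[, 1L])
}

#' @rdname iv_width
#' @export
iv_sum <- function(x) {
  x <- as_interval(x)
  unname(x[, 1L] + x[, 2L])
}

#' Componentwise partial order on intervals
#'
#' The classical partial order: `[x1,x2] <= [y1,y2]` iff `x1 <= y1` and
#' `x2 <= y2`. It is not linear; e.g. `[0.3, 0.5]` and `[0.1, 0.7]` are
#' incomparable.
#'
#' @param x,y [interval()] objects (recycled rowwise if one has a single row).
#' @return Logical vector: `TRUE`, `FALSE`, or `NA` when the pair is
#'   incomparable in either direction.
#' @examples
#' iv_partial_leq(interval(0.1, 0.3), interval(0.2, 0.5)) # TRUE
#' iv_partial_leq(interval(0.3, 0.5), interval(0.1, 0.7)) # NA (incomparable)
#' @export
iv_partial_leq <- function(x, y) {
  x <- as_interval(x); y <- as_interval(y)
  fwd <- x[, 1L] <= y[, 1L] & x[, 2L] <= y[, 2L]
  bwd <- y[, 1L] <= x[, 1L] & y[, 2L] <= x[, 2L]
  out <- rep(NA, length(fwd))
  out[fwd] <- TRUE
  out[!fwd & bwd] <- FALSE
  out
}

#' Lattice join and meet
#'
#' Componentwise maximum (`iv_join`) and minimum (`iv_meet`): the supremum
#' and infimum under the componentwise partial order.
#'
#' @param x,y [interval()] objects of matching (or recyclable) length.
#' @return An [interval()] object.
#' @export
iv_join <- function(x, y) {
  x <- as_interval(x); y <- as_interval(y)
  interval(pmax(x[, 1L], y[, 1L]), pmax(x[, 2L], y[, 2L]))
}

#' @rdname iv_join
#' @export
iv_meet <- function(x, y) {
  x <- as_interval(x); y <- as_interval(y)
  interval(pmin(x[, 1L], y[, 1L]), pmin(x[, 2L], y[, 2L]))
}

iv_orders <- c("xy", "lex1", "lex2")

# Sort-key columns of each admissible linear order, compared left to right.
# The Xu-Yager sum and width keys are derived quantities whose binary
# rounding would misorder decimal-valued bounds (0.2 + 0.4 > 0.1 + 0.5 in
# doubles), so they are rounded to 12 decimals; the raw bounds are appended
# as final tie-breakers, keeping the order total and antisymmetric even if
# two distinct intervals collide on the rounded keys. The lexicographical
# orders involve no arithmetic and use the exact bounds directly.
iv_order_keys <- function(x, order) {
  x <- as_interval(x)
  switch(order,
         xy   = cbind(round(x[, 1L] + x[, 2L], 12L),
                      round(x[, 2L] - x[, 1L], 12L),
                      x[, 1L], x[, 2L]),
         lex1 = cbind(x[, 1L], x[, 2L]),
         lex2 = cbind(x[, 2L], x[, 1L]),
         stop(sprintf("unknown interval order '%s'; available: %s",
                      order, paste(iv_orders, collapse = ", "))))
}

# Rowwise lexicographic comparison of key matrices: -1, 0, or 1.
compare_keys <- function(kx, ky) {
  cmp <- integer(nrow(kx))
  for (cc in seq_len(ncol(kx))) {
    open <- cmp == 0L
    if (!any(open)) break
    cmp[open] <- sign(kx[open, cc] - ky[open, cc])
  }
  as.integer(cmp)
}

#' Compare intervals under an admissible linear order
#'
#' Three total orders on intervals are supported, each refining the
#' componentwise partial order:
#' \describe{
#'   \item{`"xy"`}{Xu-Yager: compare the bound sums `lower + upper`; on a
#'     tie the narrower interval precedes.}
#'   \item{`"lex1"`}{lexicographical by lower bound, then upper bound.}
#'   \item{`"lex2"`}{lexicographical by upper bound, then lower bound.}
#' }
#' Equality (`0`) means identical bounds. No fuzzy equality is involved — a
#' tolerance would destroy antisymmetry. The Xu-Yager sum and width keys are
#' rounded to 12 decimals so that decimal-valued bounds order as in exact
#' decimal arithmetic (`[0.2, 0.4]` ties `[0.1, 0.5]` on the sum key although
#' the binary sums differ in the 17th digit), with the raw bounds as final
#' tie-breakers so the order stays total.
#'
#' @param x,y [interval()] objects, compared rowwise.
#' @param order one of `"xy"` (default), `"lex1"`, `"lex2"`.
#' @return Integer vector in `{-1, 0, 1}`: `-1` when `x` strictly precedes
#'   `y`, `1` when `y` strictly precedes `x`.
#' @examples
#' x <- interval(0.2, 0.4); y <- interval(0.1, 0.5)
#' iv_compare(x, y, "xy")   # -1: equal sums 0.6, width 0.2 < 0.4
#' iv_compare(x, y, "lex1") # +1: y's lower bound is smaller
#' iv_compare(x, y, "lex2") # -1: x's upper bound is smaller
#' @export
iv_compare <- function(x, y, order = c("xy", "lex1", "lex2")) {
  order <- match.arg(order)
  compare_keys(iv_order_keys(x, order), iv_order_keys(y, order))
}

#' Index of the greatest interval under a linear order
#'
#' Used by the ensemble's decision rule: the predicted class is the one whose
#' aggregated interval is greatest. Ties on identical intervals resolve to the
#' smallest index, so class order (sorted training labels) breaks exact ties
#' deterministically.
#'
#' @param x an [interval()] object with at least one row.
#' @param order passed to [iv_compare()].
#' @return Integer index of the greatest row.
#' @export
iv_which_max <- function(x, order = c("xy", "lex1", "lex2")) {
  order <- match.arg(order)
  x <- as_interval(x)
  if (nrow(x) == 0L) stop("cannot take the maximum of zero intervals")
  keys <- iv_order_keys(x, order)
  best <- 1L
  for (i in seq_len(nrow(x))[-1L]) {
    if (compare_keys(keys[i, , drop = FALSE],
                     keys[best, , drop = FALSE]) > 0L)
      best <- i
  }
  best
}
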