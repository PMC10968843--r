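#' The ten interval-valued aggregation functions
#'
#' Combines `n >= 1` intervals into one. Writing `L`/`U` for the vectors of
#' lower/upper bounds, `AM` for the arithmetic mean, `GM` for the geometric
#' mean, `M_p` for the power mean `((1/n) sum x^p)^(1/p)` and `LM_p` for the
#' Lehmer-type ratio `sum(x^p) / sum(x^(p-1))` (with the convention
#' `0/0 := 0`), the family is:
#'
#' \tabular{ll}{
#'   A1 \tab `[AM(L), AM(U)]` \cr
#'   A2 \tab `[AM(L), max_i AM(U with the i-th entry replaced by L_i)]` \cr
#'   A3 \tab `[AM(L), LM_2(U)]` \cr
#'   A4 \tab `[AM(L), LM_3(U)]` \cr
#'   A5 \tab `[M_2(L), M_3(U)]` \cr
#'   A6 \tab `[M_3(L), M_4(U)]` \cr
#'   A7 \tab `[min_i AM(L with the i-th entry replaced by U_i), AM(U)]` \cr
#'   A8 \tab `[GM(L), LM_2(U)]` \cr
#'   A9 \tab `[M_2(L), LM_3(U)]` \cr
#'   A10 \tab `[M_2(L), M_2(U)]`
#' }
#'
#' All ten map valid intervals to a valid interval, satisfy the boundary
#' conditions (all-`[0,0]` maps to `[0,0]`, all-`[1,1]` to `[1,1]`) and keep
#' the result inside the hull `[min L, max U]`. All except A2 and A7 are
#' idempotent. The `0/0 := 0` convention applies to the Lehmer-ratio uppers
#' of A3, A4, A8 and A9 and is only reachable when every upper bound is 0.
#'
#' In the ensemble, one aggregation is applied per class across the surviving
#' groups' intervals; its arity is the number of groups, which may shrink to
#' one after group pruning, so `n = 1` is allowed (every formula then reduces
#' to an identity-like map).
#'
#' @param x an [interval()] object: the `n` intervals to combine (rows).
#' @param method one of `"A1"` .. `"A10"` (default `"A1"`, the componentwise
#'   arithmetic mean).
#' @return A single [interval()].
#' @examples
#' xs <- interval(c(0.2, 0.1), c(0.4, 0.5))
#' iv_aggregate(xs, "A1") # [0.15, 0.45]
#' iv_aggregate(xs, "A3")
#' @export
iv_aggregate <- function(x, method = "A1") {
  x <- as_interval(x)
  if (nrow(x) == 0L) stop("cannot aggregate zero intervals")
  if (length(method) != 1L || !method %in% iv_aggregations())
    stop(sprintf("unknown aggregation '%s'; available: %s",
                 paste(method, collapse = ","),
                 paste(iv_aggregations(), collapse = ", ")))
  L <- x[, 1L]; U <- x[, 2L]; n <- length(L)
  pm <- function(v, p) (sum(v^p) / n)^(1 / p)
  lm <- function(v, p) {
    den <- sum(v^(p - 1))
    if (den == 0) 0 else sum(v^p) / den
  }
  res <- switch(method,
    A1  = c(mean(L), mean(U)),
    A2  = c(mean(L), max((sum(U) - U + L) / n)),
    A3  = c(mean(L), lm(U, 2)),
    A4  = c(mean(L), lm(U, 3)),
    A5  = c(pm(L, 2), pm(U, 3)),
    A6  = c(pm(L, 3), pm(U, 4)),
    A7  = c(min((sum(L) - L + U) / n), mean(U)),
    A8  = c(prod(L)^(1 / n), lm(U, 2)),
    A9  = c(pm(L, 2), lm(U, 3)),
    A10 = c(pm(L, 2), pm(U, 2))
  )
  # guard against anything worse than round-off; then snap round-off back
  tol <- 1e-9
  if (any(res < -tol) || any(res > 1 + tol) || res[1L] > res[2L] + tol)
    stop(sprintf("internal error: aggregation %s produced [%.17g, %.17g]",
                 method, res[1L], res[2L]))
  res <- pmin(pmax(res, 0), 1)
  interval(min(res), res[2L])
}

#' Names of the available interval-valued aggregations
#'
#' @return Character vector `c("A1", ..., "A10")`, in order.
#' @export
iv_aggregations <- function() paste0("A", 1:10)
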