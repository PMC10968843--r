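#' Fit an interval-valued heterogeneous ensemble classifier
#'
#' Trains groups of heterogeneous base classifiers and combines them through
#' interval modeling: at prediction time each group contributes, per class,
#' the interval spanned by its members' soft labels; the per-group intervals
#' of each class are merged with an interval-valued aggregation function
#' ([iv_aggregate()]); and the predicted class is the one whose aggregated
#' interval is greatest under an admissible linear interval order
#' ([iv_compare()]).
#'
#' Three variants are available:
#' \describe{
#'   \item{`"plain"`}{every member of every group is fitted; no selection.}
#'   \item{`"entropy"`}{within each group, members are ranked by mean
#'     cross-entropy loss estimated with repeated stratified two-fold
#'     cross-validation on the training data ([model_losses()]); the two
#'     best members plus everything at or below the group average are kept
#'     ([select_members()]) and refitted on the full training data.}
#'   \item{`"entropy_groups"`}{additionally applies the same keep rule to
#'     whole groups using their mean losses ([select_groups()]), so a group
#'     that drags the ensemble down is removed (at least two groups always
#'     survive).}
#' }
#'
#' Survivors of the selection step are refitted on the full training data:
#' the cross-validated fits exist only to estimate losses, and discarding
#' half the training signal in the final members would waste it.
#'
#' @param x feature matrix (samples x features), or a formula.
#' @param y class labels (any atomic type; coerced to factor). At least two
#'   classes are required.
#' @param variant `"plain"`, `"entropy"`, or `"entropy_groups"`.
#' @param groups list of [model_group()]s; defaults to [default_groups()].
#' @param aggregation one of `"A1"` .. `"A10"` (default `"A1"`).
#' @param order interval order for the decision: `"xy"` (default), `"lex1"`,
#'   or `"lex2"`.
#' @param n_splits,n_repeats nested cross-validation geometry for the
#'   entropy variants (default: 10 repeats of stratified two-fold).
#' @param seed single integer; every source of randomness (forest growth,
#'   network initialisation, CV splits) is derived from it.
#' @param data,formula for the formula method: `formula` names the class
#'   column (e.g. `label ~ .`), `data` is a data frame.
#' @param ... passed between methods.
#' @return An object of class `ivens` with components `variant`, `groups`
#'   (surviving groups with fitted members), `class_ids`, `aggregation`,
#'   `order`, `selection` (a selection report for the entropy variants,
#'   `NULL` otherwise), and `seed`.
#' @seealso [predict.ivens()], [class_intervals()], [run_experiment()]
#' @examples
#' sim <- generate_dataset(microarray_spec(n_samples = 60, n_features = 40,
#'                                         class_probs = c(0.5, 0.5),
#'                                         n_informative = 10, seed = 1))
#' groups <- list(model_group("RF", list(rf_learner(10), rf_learner(25))),
#'                model_group("KNN", list(knn_learner(1), knn_learner(3))))
#' fit <- ivens(sim$x, sim$y, variant = "plain", groups = groups, seed = 1)
#' table(predict(fit, sim$x), sim$y)
#' @export
ivens <- function(x, ...) UseMethod("ivens")

#' @rdname ivens
#' @export
ivens.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- as_feature_matrix(mf[, -1L, drop = FALSE])
  obj <- ivens.default(x, y, ...)
  obj$call <- match.call()
  obj
}

#' @rdname ivens
#' @export
ivens.default <- function(x, y,
                          variant = c("plain", "entropy", "entropy_groups"),
                          groups = default_groups(),
                          aggregation = "A1",
                          order = c("xy", "lex1", "lex2"),
                          n_splits = 2L, n_repeats = 10L, seed = 1L, ...) {
  variant <- match.arg(variant)
  order <- match.arg(order)
  if (!aggregation %in% iv_aggregations())
    stop(sprintf("unknown aggregation '%s'; available: %s", aggregation,
                 paste(iv_aggregations(), collapse = ", ")))
  groups <- check_groups(groups)
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  class_ids <- levels(y)

  # remember original positions: a surviving member's fit seed must not
  # depend on how many colleagues were pruned before it
  for (g in seq_along(groups))
    for (j in seq_along(groups[[g]]$members)) {
      groups[[g]]$members[[j]]$orig_group <- g
      groups[[g]]$members[[j]]$orig_index <- j
    }

  selection <- NULL
  if (variant != "plain") {
    selection <- run_selection(groups, x, y, n_splits = n_splits,
                               n_repeats = n_repeats, seed = seed,
                               select_whole_groups =
                                 variant == "entropy_groups")
    groups <- lapply(seq_along(groups), function(g) {
      grp <- groups[[g]]
      grp$members <- grp$members[selection$kept_models[[g]]]
      grp
    })
    groups <- groups[selection$kept_groups]
  }

  for (g in seq_along(groups)) {
    for (j in seq_along(groups[[g]]$members)) {
      mb <- groups[[g]]$members[[j]]
      groups[[g]]$members[[j]] <- fit_member(
        mb, x, y, seed = derive_seed(seed, 888, mb$orig_group, mb$orig_index))
    }
  }

  structure(list(variant = variant, groups = groups, class_ids = class_ids,
                 aggregation = aggregation, order = order,
                 selection = selection, seed = seed,
                 n_features = ncol(x), feature_names = colnames(x),
                 call = match.call()),
            class = "ivens")
}

#' Per-sample, per-class, per-group score intervals
#'
#' For each group, the members' soft-label matrices are collected (see
#' [soft_labels()] for the softmax rule) and condensed, per sample and class,
#' into the interval from the smallest to the largest member score.
#'
#' @param object a fitted [ivens()] model.
#' @param x feature matrix.
#' @return A 4-d array `[sample, class, group, bound]` where the last margin
#'   is `c("lower", "upper")`.
#' @export
class_intervals <- function(object, x) {
  stopifnot(inherits(object, "ivens"))
  x <- as_feature_matrix(x)
  n <- nrow(x); K <- length(object$class_ids); G <- length(object$groups)
  out <- array(NA_real_, c(n, K, G, 2L),
               dimnames = list(NULL, object$class_ids,
                               vapply(object$groups, `[[`, "", "label"),
                               c("lower", "upper")))
  for (g in seq_len(G)) {
    members <- object$groups[[g]]$members
    sl <- lapply(members, soft_labels, x = x, class_ids = object$class_ids)
    lo <- sl[[1L]]; hi <- sl[[1L]]
    for (s in sl[-1L]) {
      lo <- pmin(lo, s); hi <- pmax(hi, s)
    }
    out[, , g, 1L] <- lo
    out[, , g, 2L] <- hi
  }
  out
}

# Aggregate the per-group intervals of every (sample, class) cell; returns
# list(lower, upper), each samples x classes.
aggregate_intervals <- function(ivs, method) {
  n <- dim(ivs)[1L]; K <- dim(ivs)[2L]
  lower <- matrix(NA_real_, n, K, dimnames = dimnames(ivs)[1:2])
  upper <- lower
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      agg <- iv_aggregate(interval(ivs[i, k, , 1L], ivs[i, k, , 2L]), method)
      lower[i, k] <- agg[1L, 1L]
      upper[i, k] <- agg[1L, 2L]
    }
  }
  list(lower = lower, upper = upper)
}

#' Predict classes or membership degrees
#'
#' `type = "class"` returns, per sample, the class whose aggregated interval
#' is greatest under the model's interval order (exact ties resolve to the
#' first class in sorted label order). `type = "membership"` returns graded
#' class memberships: the midpoint `(lower + upper) / 2` of each class's
#' aggregated interval, renormalised to sum to one per sample (an all-zero
#' row falls back to the uniform distribution).
#'
#' `type = "interval"` exposes the aggregated intervals themselves as a
#' list of `lower` and `upper` matrices, for inspection or custom decision
#' rules.
#'
#' @param object a fitted [ivens()] model.
#' @param newdata feature matrix.
#' @param type `"class"`, `"membership"`, or `"interval"`.
#' @param ... ignored.
#' @return A factor (class), a samples-by-classes matrix of membership
#'   degrees, or a list of two matrices.
#' @export
predict.ivens <- function(object, newdata,
                          type = c("class", "membership", "interval"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) stop("'newdata' is required")
  ivs <- class_intervals(object, newdata)
  agg <- aggregate_intervals(ivs, object$aggregation)
  if (type == "interval") return(agg)
  if (type == "membership") {
    mid <- (agg$lower + agg$upper) / 2
    sums <- rowSums(mid)
    zero <- sums == 0
    mid[zero, ] <- 1 / ncol(mid)
    mid[!zero, ] <- mid[!zero, , drop = FALSE] / sums[!zero]
    return(mid)
  }
  idx <- vapply(seq_len(nrow(agg$lower)), function(i)
    iv_which_max(interval(agg$lower[i, ], agg$upper[i, ]), object$order), 0L)
  factor(object$class_ids[idx], levels = object$class_ids)
}

#' @export
print.ivens <- function(x, ...) {
  cat(sprintf("Interval-valued ensemble classifier (variant: %s)\n", x$variant))
  cat(sprintf("  aggregation %s, order %s, %d classes, %d features\n",
              x$aggregation, x$order, length(x$class_ids), x$n_features))
  for (g in x$groups)
    cat(sprintf("  group %-4s: %s\n", g$label,
                paste(vapply(g$members, `[[`, "", "label"), collapse = ", ")))
  invisible(x)
}

#' @export
summary.ivens <- function(object, ...) {
  structure(list(model = object), class = "summary.ivens")
}

#' @export
print.summary.ivens <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$selection)) {
    cat("\n")
    print(x$model$selection)
  }
  invisible(x)
}

#' Plot aggregated class intervals for selected samples
#'
#' Draws, for each requested sample, one horizontal segment per class: the
#' aggregated interval on the unit line, with the predicted class marked.
#' A quick visual check of how decisively the ensemble separates classes.
#'
#' @param x a fitted [ivens()] model.
#' @param newdata feature matrix.
#' @param samples indices of samples to draw (default: the first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ivens <- function(x, newdata, samples = 1L, ...) {
  agg <- predict(x, newdata[samples, , drop = FALSE], type = "interval")
  cls <- predict(x, newdata[samples, , drop = FALSE], type = "class")
  K <- length(x$class_ids); S <- length(samples)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0.5, S * (K + 1) + 0.5),
                 xlab = "aggregated class interval", ylab = "",
                 yaxt = "n", ...)
  at <- c(); lab <- c()
  for (s in seq_len(S)) {
    base <- (s - 1L) * (K + 1L)
    for (k in seq_len(K)) {
      yy <- base + k
      pred <- x$class_ids[k] == as.character(cls[s])
      graphics::segments(agg$lower[s, k], yy, agg$upper[s, k], yy,
                         lwd = if (pred) 3 else 1.5,
                         col = if (pred) "firebrick" else "grey30")
      graphics::points((agg$lower[s, k] + agg$upper[s, k]) / 2, yy, pch = 16,
                       col = if (pred) "firebrick" else "grey30")
      at <- c(at, yy)
      lab <- c(lab, sprintf("s%d: %s", samples[s], x$class_ids[k]))
    }
  }
  graphics::axis(2, at = at, labels = lab, las = 1, cex.axis = 0.7)
  invisible(x)
}
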