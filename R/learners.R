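#' Base learner specifications
#'
#' A base learner is an unfitted member of a [model_group()]: a family tag, a
#' human-readable label, and hyperparameters. The default zoo covers four
#' heterogeneous families:
#'
#' * `rf_learner(num_trees)` — random forest ([ranger::ranger()]); soft
#'   labels are out-of-bag-free vote fractions (probability forests).
#' * `mlp_learner(hidden)` — multilayer perceptron (ReLU hidden layers,
#'   softmax output, full-batch Adam); soft labels are the output layer.
#' * `svm_learner(kernel)` — support vector machine ([e1071::svm()],
#'   `scale = FALSE`); soft labels come from raw one-vs-one decision values
#'   folded into per-class signed sums, which lie outside `[0, 1]` and
#'   therefore pass through the softmax rule of [soft_labels()].
#' * `knn_learner(k)` — k-nearest neighbours under the Manhattan (L1)
#'   metric; soft labels are neighbour vote fractions.
#'
#' Custom learners can be registered with `base_learner()`: supply a `fit`
#' function `(x, y, seed) -> fitted` and a `score` function
#' `(fitted, x) -> samples x classes matrix` with the fitted model's class
#' labels as column names.
#'
#' @param num_trees number of trees in the forest.
#' @param hidden integer vector of hidden layer sizes.
#' @param kernel one of `"linear"`, `"polynomial"`, `"radial"`; the
#'   polynomial kernel uses the conventional degree 3.
#' @param k neighbourhood size.
#' @param family short family tag (e.g. `"RF"`).
#' @param label unique human-readable member label.
#' @param fit,score fitting and scoring closures, see above.
#' @param params list of hyperparameters (recorded, shown by `summary`).
#' @param ... passed to the family's fitting routine.
#' @return An object of class `ivens_learner`.
#' @examples
#' rf_learner(50)
#' knn_learner(3)
#' @export
base_learner <- function(family, label, fit, score, params = list()) {
  stopifnot(is.character(family), is.character(label),
            is.function(fit), is.function(score))
  structure(list(family = family, label = label, fit = fit, score = score,
                 params = params),
            class = "ivens_learner")
}

#' @export
print.ivens_learner <- function(x, ...) {
  p <- paste(names(x$params), vapply(x$params, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = ", ")
  cat(sprintf("<learner %s (%s)%s>\n", x$label, x$family,
              if (nzchar(p)) paste0(": ", p) else ""))
  invisible(x)
}

#' @rdname base_learner
#' @export
rf_learner <- function(num_trees, ...) {
  force(num_trees)
  base_learner(
    family = "RF", label = sprintf("rf_%d", num_trees),
    params = list(num_trees = num_trees),
    fit = function(x, y, seed) {
      x <- as_feature_matrix(x)
      ranger::ranger(x = x, y = as.factor(y), num.trees = num_trees,
                     probability = TRUE, num.threads = 1L, seed = seed,
                     oob.error = FALSE, verbose = FALSE, ...)
    },
    score = function(fitted, x) {
      x <- as_feature_matrix(x)
      predict(fitted, data = x, num.threads = 1L, verbose = FALSE)$predictions
    })
}

#' @rdname base_learner
#' @export
mlp_learner <- function(hidden, ...) {
  force(hidden)
  base_learner(
    family = "MLP",
    label = sprintf("mlp_%s", paste(hidden, collapse = "-")),
    params = list(hidden = hidden),
    fit = function(x, y, seed) mlp_train(x, y, hidden = hidden, seed = seed, ...),
    score = function(fitted, x) mlp_probs(fitted, x))
}

#' @rdname base_learner
#' @export
svm_learner <- function(kernel = c("linear", "polynomial", "radial"), ...) {
  kernel <- match.arg(kernel)
  base_learner(
    family = "SVM", label = sprintf("svm_%s", kernel),
    params = list(kernel = kernel),
    fit = function(x, y, seed) {
      x <- as_feature_matrix(x)
      e1071::svm(x, as.factor(y), kernel = kernel, degree = 3,
                 scale = FALSE, fitted = FALSE, ...)
    },
    score = function(fitted, x) {
      x <- as_feature_matrix(x)
      dv <- attr(predict(fitted, x, decision.values = TRUE),
                 "decision.values")
      ovo_to_class_scores(dv, fitted$levels)
    })
}

#' @rdname base_learner
#' @export
knn_learner <- function(k, ...) {
  force(k)
  base_learner(
    family = "KNN", label = sprintf("knn_%d", k),
    params = list(k = k, metric = "manhattan"),
    fit = function(x, y, seed) {
      y <- as.factor(y)
      list(x = as_feature_matrix(x), y = y, classes = levels(y))
    },
    score = function(fitted, x) {
      knn_vote_fractions(fitted$x, fitted$y, as_feature_matrix(x), k)
    })
}

#' Label-shuffling wrapper for robustness probes
#'
#' Returns a learner identical to `learner` except that it is fitted on a
#' seeded random permutation of the labels, destroying any label signal
#' while keeping the feature distribution. Useful for checking that the
#' entropy-based selection drops uninformative members and groups — see
#' [robustness_benchmark()].
#'
#' @param learner a [base_learner()].
#' @return A `base_learner()` whose label carries a `_shuffled` suffix.
#' @export
shuffled_learner <- function(learner) {
  stopifnot(inherits(learner, "ivens_learner"))
  base_learner(
    family = learner$family,
    label = paste0(learner$label, "_shuffled"),
    params = learner$params,
    fit = function(x, y, seed) {
      rng <- local_rng(derive_seed(seed, 424243))
      on.exit(rng())
      learner$fit(x, y[sample.int(length(y))], seed)
    },
    score = learner$score)
}

# Per-class signed sums of one-vs-one decision values ("i/j" columns add the
# value to class i and subtract it from class j), giving a samples x classes
# margin matrix for the softmax rule.
ovo_to_class_scores <- function(dv, classes) {
  dv <- rbind(dv)
  out <- matrix(0, nrow(dv), length(classes),
                dimnames = list(NULL, classes))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (j in seq_along(pairs)) {
    out[, pairs[[j]][1L]] <- out[, pairs[[j]][1L]] + dv[, j]
    out[, pairs[[j]][2L]] <- out[, pairs[[j]][2L]] - dv[, j]
  }
  out
}

# Manhattan-metric kNN vote fractions; distance ties beyond the k-th
# neighbour are broken by training-set order (deterministic).
knn_vote_fractions <- function(train_x, train_y, test_x, k) {
  classes <- levels(train_y)
  n_test <- nrow(test_x)
  out <- matrix(0, n_test, length(classes),
                dimnames = list(NULL, classes))
  k <- min(k, nrow(train_x))
  dmat <- .l1_cross_dist(test_x, train_x)
  for (i in seq_len(n_test)) {
    nb <- order(dmat[i, ])[seq_len(k)]
    tab <- tabulate(as.integer(train_y[nb]), nbins = length(classes))
    out[i, ] <- tab / k
  }
  out
}

# Fit one learner; returns the learner with its fitted model attached.
fit_member <- function(learner, x, y, seed) {
  fitted <- learner$fit(x, y, seed)
  learner$fitted <- fitted
  learner$seed <- seed
  learner
}

#' Normalised per-class soft labels of a fitted member
#'
#' Extracts the member's samples-by-classes score matrix and applies the
#' normalisation rule: scores already inside `[0, 1]` (native probabilities,
#' vote fractions) pass through unchanged; if any score falls outside the
#' unit interval (e.g. SVM margins) the whole matrix is mapped row-wise
#' through the softmax. The check is per matrix, not per row — mixing
#' calibrated and softmaxed rows in one matrix would be incoherent.
#'
#' @param member a fitted learner (as stored inside a fitted [ivens()] model).
#' @param x feature matrix.
#' @param class_ids ordered class labels; columns of the result follow this
#'   order, and a mismatch with the member's training classes is an error.
#' @return A numeric matrix in `[0, 1]` with `length(class_ids)` columns.
#' @export
soft_labels <- function(member, x, class_ids) {
  if (is.null(member$fitted)) stop("member has not been fitted")
  s <- member$score(member$fitted, x)
  s <- rbind(s)
  if (is.null(colnames(s)))
    stop("learner scores must carry class labels as column names")
  if (!setequal(colnames(s), class_ids))
    stop(sprintf("class mismatch: model knows {%s}, expected {%s}",
                 paste(sort(colnames(s)), collapse = ","),
                 paste(sort(class_ids), collapse = ",")))
  s <- s[, class_ids, drop = FALSE]
  if (any(s < 0 | s > 1)) s <- softmax_rows(s)
  s
}
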