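#' Groups of base classifiers
#'
#' The ensemble's input is a collection of at least two model groups, each
#' holding at least two member classifiers of (typically) one family. Each
#' group later contributes one interval per class per sample — the span of
#' its members' soft labels — so members of a group should be variations of
#' a theme (e.g. forests of different sizes), making the interval width a
#' measure of within-family disagreement.
#'
#' @param label group label (unique within a collection).
#' @param members list of at least two [base_learner()] objects.
#' @return An object of class `ivens_group`.
#' @examples
#' model_group("RF", list(rf_learner(10), rf_learner(50)))
#' @export
model_group <- function(label, members) {
  if (!is.character(label) || length(label) != 1L)
    stop("'label' must be a single string")
  if (!is.list(members) || length(members) < 2L ||
      !all(vapply(members, inherits, TRUE, "ivens_learner")))
    stop("a model group needs a list of at least 2 base learners")
  labs <- vapply(members, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("member labels within a group must be unique")
  structure(list(label = label, members = members), class = "ivens_group")
}

#' @export
print.ivens_group <- function(x, ...) {
  cat(sprintf("<model group %s: %s>\n", x$label,
              paste(vapply(x$members, `[[`, "", "label"), collapse = ", ")))
  invisible(x)
}

#' The default heterogeneous model zoo
#'
#' Four groups of three members each: random forests with 10, 50 and 100
#' trees; multilayer perceptrons with hidden layers `100`, `50-50` and
#' `100-50-25`; SVMs with linear, polynomial and radial kernels; and k-nearest
#' neighbours with `k` of 1, 3 and 5 under the Manhattan metric. Group
#' configurations are deterministic; all stochastic fitting is seeded from
#' the single seed given to [ivens()].
#'
#' @return A list of four [model_group()] objects.
#' @export
default_groups <- function() {
  list(
    model_group("RF",  lapply(c(10L, 50L, 100L), rf_learner)),
    model_group("MLP", lapply(list(100L, c(50L, 50L), c(100L, 50L, 25L)),
                              mlp_learner)),
    model_group("SVM", lapply(c("linear", "polynomial", "radial"), svm_learner)),
    model_group("KNN", lapply(c(1L, 3L, 5L), knn_learner))
  )
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      !all(vapply(groups, inherits, TRUE, "ivens_group")))
    stop("'groups' must be a list of at least 2 model groups")
  labs <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("group labels must be unique")
  groups
}
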