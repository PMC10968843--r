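#' Mean cross-entropy (log) loss
#'
#' `-(1/N) sum_i sum_k y_ik log p_ik` with one-hot true labels.
#' Probabilities are clipped to `[1e-15, 1 - 1e-15]` before the logarithm —
#' without clipping a single confident miss (1-NN members emit exact 0/1
#' scores) would make the loss infinite and selection ill-defined.
#'
#' @param y true labels (length `N`).
#' @param probs `N x K` matrix of class scores; columns must be named with
#'   the class labels unless `class_ids` is given.
#' @param class_ids ordered class labels matching the columns of `probs`.
#' @return A non-negative scalar; 0 exactly when every true class has
#'   (clipped) probability 1.
#' @examples
#' cross_entropy(c("a", "b"), rbind(c(0.9, 0.1), c(0.2, 0.8)),
#'               class_ids = c("a", "b")) # 0.1643
#' @export
cross_entropy <- function(y, probs, class_ids = colnames(probs)) {
  probs <- rbind(probs)
  if (is.null(class_ids))
    stop("'probs' must have class labels as column names, or give 'class_ids'")
  if (length(class_ids) != ncol(probs))
    stop("'class_ids' length must match ncol(probs)")
  if (nrow(probs) != length(y))
    stop("'y' length must match nrow(probs)")
  col <- match(as.character(y), as.character(class_ids))
  if (anyNA(col)) {
    bad <- unique(as.character(y)[is.na(col)])
    stop(sprintf("label(s) outside the class set: %s",
                 paste(bad, collapse = ", ")))
  }
  p <- pmin(pmax(probs[cbind(seq_along(y), col)], 1e-15), 1 - 1e-15)
  -mean(log(p))
}

#' Per-member cross-validated loss estimates for one group
#'
#' Runs repeated stratified two-fold cross-validation (10 repeats by default,
#' i.e. 20 folds) on the supplied data — in the full procedure this is the
#' outer training partition only. Every member is fitted on each fold's
#' training half and scored by [cross_entropy()] on the held-out half. The
#' per-repeat random streams are derived from `(seed, repeat index)`, so each
#' repeat has an independent, reproducible split.
#'
#' @param group a [model_group()].
#' @param x,y training features and labels.
#' @param n_splits folds per repeat (2 in the reference procedure).
#' @param n_repeats number of repeats.
#' @param seed integer seed.
#' @return A list with `fold_losses` (members x folds matrix, member labels
#'   as row names), `member_means`, and `group_mean` (the average of
#'   `member_means` over all original members).
#' @export
model_losses <- function(group, x, y, n_splits = 2L, n_repeats = 10L,
                         seed = 1L) {
  stopifnot(inherits(group, "ivens_group"))
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  class_ids <- levels(y)
  m <- length(group$members)
  losses <- matrix(NA_real_, m, n_splits * n_repeats,
                   dimnames = list(vapply(group$members, `[[`, "", "label"),
                                   NULL))
  col <- 0L
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(y, n_splits, derive_seed(seed, r))
    for (f in seq_len(n_splits)) {
      col <- col + 1L
      tr <- folds != f
      for (j in seq_len(m)) {
        fit <- fit_member(group$members[[j]], x[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, r, f, j))
        p <- soft_labels(fit, x[!tr, , drop = FALSE], class_ids)
        losses[j, col] <- cross_entropy(y[!tr], p, class_ids)
      }
    }
  }
  list(fold_losses = losses,
       member_means = rowMeans(losses),
       group_mean = mean(rowMeans(losses)))
}

#' Entropy-based selection of members and groups
#'
#' Given mean cross-entropy losses, `select_members()` keeps the two members
#' with the lowest mean loss plus every member whose mean is at most the
#' group's average of member means. `select_groups()` applies the same rule
#' to group means: the kept set is the union of the top two and everything
#' at or below the average, so at least two groups always survive. Ties on
#' equal means resolve to the smallest index.
#'
#' Both rules depend only on ranks and the relation to the average, so they
#' are invariant to adding a constant to all losses.
#'
#' @param means numeric vector (length >= 2) of mean losses per member
#'   (or per group).
#' @return Sorted integer indices of the kept members (groups).
#' @examples
#' select_members(c(0.2, 0.5, 0.9))        # 1 2
#' select_groups(c(0.1, 0.8, 0.9, 1.0))    # 1 2 (fallback to the top two)
#' @export
select_members <- function(means) {
  if (length(means) < 2L) stop("selection needs at least 2 mean losses")
  if (any(!is.finite(means))) stop("mean losses must be finite")
  top2 <- order(means)[1:2]          # order() is stable: ties keep low index
  sort(union(top2, which(means <= mean(means))))
}

#' @rdname select_members
#' @export
select_groups <- function(means) select_members(means)

# Nested-CV selection across all groups; returns the audit report.
run_selection <- function(groups, x, y, n_splits, n_repeats, seed,
                          select_whole_groups = FALSE) {
  reports <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    reports[[g]] <- model_losses(groups[[g]], x, y, n_splits = n_splits,
                                 n_repeats = n_repeats,
                                 seed = derive_seed(seed, 555, g))
  }
  group_means <- vapply(reports, `[[`, 0, "group_mean")
  kept_models <- lapply(reports, function(r) select_members(r$member_means))
  kept_groups <- if (select_whole_groups) select_groups(group_means)
                 else seq_along(groups)
  structure(list(
    per_model_fold_losses = lapply(reports, `[[`, "fold_losses"),
    per_model_mean = lapply(reports, `[[`, "member_means"),
    per_group_mean = group_means,
    kept_models = kept_models,
    kept_groups = kept_groups,
    thresholds = list(group_averages = vapply(reports, function(r)
                        mean(r$member_means), 0),
                      global_group_average = mean(group_means)),
    provenance = list(seed = seed, n_splits = n_splits,
                      n_repeats = n_repeats)),
    class = "ivens_selection")
}

#' @export
print.ivens_selection <- function(x, ...) {
  cat("Entropy-based selection report\n")
  for (g in seq_along(x$per_model_mean)) {
    mm <- x$per_model_mean[[g]]
    kept <- x$kept_models[[g]]
    tag <- if (g %in% x$kept_groups) "" else " [group dropped]"
    cat(sprintf("  group %d (mean loss %.4f)%s\n", g, x$per_group_mean[g], tag))
    for (j in seq_along(mm))
      cat(sprintf("    %-14s %.4f %s\n", names(mm)[j], mm[j],
                  if (j %in% kept) "kept" else "dropped"))
  }
  invisible(x)
}
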