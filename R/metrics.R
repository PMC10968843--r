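#' Multi-class evaluation metrics
#'
#' `accuracy()` is the fraction of correct predictions. `balanced_accuracy()`
#' is the unweighted mean of per-class recalls, robust to class imbalance;
#' every class present in `y_true` counts equally. `ovo_auc()` is the
#' macro one-vs-one ROC AUC: for every unordered pair of classes, the two
#' directional binary AUCs (each from the corresponding class's score column,
#' restricted to samples of the pair) are averaged, and the pair AUCs are
#' averaged over all pairs. Ties in scores count one half, so each
#' directional AUC equals the tie-adjusted pairwise concordance probability.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels (same length).
#' @param scores samples-by-classes matrix of membership degrees or
#'   probability-like scores; columns named by class unless `class_ids`
#'   is given.
#' @param class_ids ordered class labels matching the columns of `scores`.
#' @return A scalar in `[0, 1]`.
#' @examples
#' accuracy(c(0, 1, 2, 0), c(0, 1, 1, 1))                 # 0.5
#' balanced_accuracy(c(0, 0, 0, 1), c(0, 0, 0, 0))        # 0.5
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  mean(as.character(y_true) == as.character(y_pred))
}

#' @rdname accuracy
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  recalls <- vapply(classes, function(cl)
    mean(y_pred[y_true == cl] == cl), 0)
  mean(recalls)
}

# Binary AUC of `score` for positives vs negatives via the rank (Mann-Whitney)
# statistic; ties get 1/2.
binary_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname accuracy
#' @export
ovo_auc <- function(y_true, scores, class_ids = colnames(scores)) {
  scores <- rbind(scores)
  if (is.null(class_ids))
    stop("'scores' must have class labels as column names, or give 'class_ids'")
  y_true <- as.character(y_true)
  class_ids <- as.character(class_ids)
  present <- class_ids[class_ids %in% y_true]
  if (length(present) < 2L)
    stop("one-vs-one AUC needs at least 2 classes present in 'y_true'")
  if (length(present) < length(class_ids))
    warning(sprintf("class(es) absent from 'y_true' skipped: %s",
                    paste(setdiff(class_ids, present), collapse = ", ")))
  pair_aucs <- c()
  for (a in seq_len(length(present) - 1L)) {
    for (b in seq(a + 1L, length(present))) {
      ca <- present[a]; cb <- present[b]
      sub <- y_true %in% c(ca, cb)
      auc_a <- binary_auc(scores[sub, match(ca, class_ids)],
                          y_true[sub] == ca)
      auc_b <- binary_auc(scores[sub, match(cb, class_ids)],
                          y_true[sub] == cb)
      pair_aucs <- c(pair_aucs, (auc_a + auc_b) / 2)
    }
  }
  mean(pair_aucs)
}
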