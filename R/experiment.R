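#' Model specifications for the evaluation harness
#'
#' [run_experiment()] consumes lightweight specifications rather than fitted
#' models, since it refits everything on each train/test split.
#' `ivens_model()` wraps the interval-valued ensemble; `learner_model()`
#' wraps a single base learner as a comparison baseline (scored by its own
#' soft labels).
#'
#' @param variant,groups,aggregation,order passed to [ivens()].
#' @param learner a [base_learner()].
#' @param label row label in the results table; defaults to something
#'   descriptive.
#' @return An `ivens_model_spec` object.
#' @export
ivens_model <- function(variant = "plain", aggregation = "A1", order = "xy",
                        groups = NULL, label = NULL) {
  if (is.null(label)) label <- toupper(variant)
  structure(list(label = label, aggregation = aggregation,
                 fit = function(x, y, seed)
                   ivens(x, y, variant = variant,
                         groups = if (is.null(groups)) default_groups() else groups,
                         aggregation = aggregation, order = order, seed = seed),
                 predict_class = function(fit, x) predict(fit, x, type = "class"),
                 predict_score = function(fit, x)
                   predict(fit, x, type = "membership")),
            class = "ivens_model_spec")
}

#' @rdname ivens_model
#' @export
learner_model <- function(learner, label = NULL) {
  stopifnot(inherits(learner, "ivens_learner"))
  if (is.null(label)) label <- toupper(learner$label)
  structure(list(label = label, aggregation = "",
                 fit = function(x, y, seed) {
                   fm <- fit_member(learner, x, y, seed)
                   fm$class_ids <- levels(as.factor(y))
                   fm
                 },
                 predict_class = function(fit, x) {
                   s <- soft_labels(fit, x, fit$class_ids)
                   factor(fit$class_ids[max.col(s, ties.method = "first")],
                          levels = fit$class_ids)
                 },
                 predict_score = function(fit, x)
                   soft_labels(fit, x, fit$class_ids)),
            class = "ivens_model_spec")
}

#' Repeated stratified train/test evaluation harness
#'
#' For each repeat: a stratified 80/20 (by default) train/test split is
#' drawn; a min-max scaler is fitted on the training features only and
#' applied to both partitions; every model specification is fitted on the
#' scaled training data and scored on the scaled test data by one-vs-one
#' ROC AUC (from membership degrees), accuracy and balanced accuracy (from
#' hard predictions). Rows report mean and standard deviation over repeats
#' and are sorted by decreasing mean ROC AUC.
#'
#' @param x,y features and labels.
#' @param models list of [ivens_model()] / [learner_model()] specifications.
#' @param n_repeats number of independent splits (default 5).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed; split `r` and all fits inside it derive their
#'   randomness from `(seed, r)`.
#' @return A data frame of class `ivens_results` with columns `classifier`,
#'   `aggregation`, and `<metric>_mean` / `<metric>_sd` for `roc_auc`,
#'   `accuracy`, `balanced_accuracy`. The per-repeat raw scores are attached
#'   as `attr(, "raw")` (a data frame in long format) for downstream
#'   significance testing.
#' @export
run_experiment <- function(x, y, models, n_repeats = 5L, train_frac = 0.8,
                           seed = 1L) {
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  if (!is.list(models) || length(models) == 0L ||
      !all(vapply(models, inherits, TRUE, "ivens_model_spec")))
    stop("'models' must be a non-empty list of model specifications")
  raw <- data.frame()
  for (r in seq_len(n_repeats)) {
    tr <- stratified_split(y, train_frac, derive_seed(seed, 42, r))
    scaler <- minmax_fit(x[tr, , drop = FALSE])
    x_tr <- minmax_apply(scaler, x[tr, , drop = FALSE])
    x_te <- minmax_apply(scaler, x[-tr, , drop = FALSE])
    y_tr <- y[tr]; y_te <- y[-tr]
    for (m in seq_along(models)) {
      spec <- models[[m]]
      fit <- spec$fit(x_tr, y_tr, derive_seed(seed, 42, r, m))
      cls <- spec$predict_class(fit, x_te)
      sc <- spec$predict_score(fit, x_te)
      raw <- rbind(raw, data.frame(
        classifier = spec$label, aggregation = spec$aggregation, repeat_id = r,
        roc_auc = ovo_auc(y_te, sc, class_ids = levels(y)),
        accuracy = accuracy(y_te, cls),
        balanced_accuracy = balanced_accuracy(y_te, cls)))
    }
  }
  agg <- do.call(rbind, lapply(split(raw, paste(raw$classifier, raw$aggregation)),
    function(d) data.frame(
      classifier = d$classifier[1L], aggregation = d$aggregation[1L],
      roc_auc_mean = mean(d$roc_auc), roc_auc_sd = stats::sd(d$roc_auc),
      accuracy_mean = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
      balanced_accuracy_mean = mean(d$balanced_accuracy),
      balanced_accuracy_sd = stats::sd(d$balanced_accuracy))))
  agg <- agg[order(-agg$roc_auc_mean, agg$classifier), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "raw") <- raw
  attr(agg, "n_repeats") <- n_repeats
  attr(agg, "seed") <- seed
  class(agg) <- c("ivens_results", "data.frame")
  agg
}

#' Corrupted-group robustness benchmark
#'
#' Measures how reliably group-level entropy selection removes an
#' uninformative group, and what that is worth in test performance. Each
#' trial draws a fresh synthetic dataset from `spec` (seeded from
#' `(seed, trial)`), corrupts one group of the default zoo by wrapping its
#' members in [shuffled_learner()], performs a stratified train/test split
#' with train-fitted min-max scaling, and fits both the plain variant (no
#' selection, the corrupted group votes) and the entropy-groups variant on
#' the training partition. Per trial it records whether the corrupted group
#' was dropped and both variants' one-vs-one test ROC AUC from membership
#' degrees.
#'
#' @param spec a [microarray_spec()]; the default matches the generator's
#'   study conditions (200 samples, 2000 features, 4 imbalanced classes,
#'   unit effect size).
#' @param corrupt_group label of the default-zoo group to corrupt
#'   (`"RF"`, `"MLP"`, `"SVM"`, or `"KNN"`).
#' @param n_trials number of seeded trials.
#' @param train_frac training fraction of each split.
#' @param aggregation,order passed to [ivens()].
#' @param seed integer seed.
#' @return A data frame with one row per trial: `trial`, `dropped`
#'   (corrupted group absent from the fitted entropy-groups ensemble),
#'   `auc_plain`, `auc_entropy_groups`.
#' @export
robustness_benchmark <- function(spec = microarray_spec(),
                                 corrupt_group = "KNN", n_trials = 50L,
                                 train_frac = 0.8, aggregation = "A1",
                                 order = "xy", seed = 1L) {
  stopifnot(inherits(spec, "microarray_spec"))
  groups <- default_groups()
  labels <- vapply(groups, `[[`, "", "label")
  gi <- match(corrupt_group, labels)
  if (is.na(gi))
    stop(sprintf("unknown group '%s'; default zoo has: %s", corrupt_group,
                 paste(labels, collapse = ", ")))
  groups[[gi]]$members <- lapply(groups[[gi]]$members, shuffled_learner)

  out <- data.frame(trial = seq_len(n_trials), dropped = NA,
                    auc_plain = NA_real_, auc_entropy_groups = NA_real_)
  for (t in seq_len(n_trials)) {
    spec$seed <- derive_seed(seed, 31, t)
    sim <- generate_dataset(spec)
    tr <- stratified_split(sim$y, train_frac, derive_seed(seed, 32, t))
    scaler <- minmax_fit(sim$x[tr, , drop = FALSE])
    x_tr <- minmax_apply(scaler, sim$x[tr, , drop = FALSE])
    x_te <- minmax_apply(scaler, sim$x[-tr, , drop = FALSE])
    y_tr <- sim$y[tr]; y_te <- sim$y[-tr]
    fit_seed <- derive_seed(seed, 33, t)
    plain <- ivens(x_tr, y_tr, "plain", groups = groups,
                   aggregation = aggregation, order = order, seed = fit_seed)
    egrp <- ivens(x_tr, y_tr, "entropy_groups", groups = groups,
                  aggregation = aggregation, order = order, seed = fit_seed)
    out$dropped[t] <- !corrupt_group %in%
      vapply(egrp$groups, `[[`, "", "label")
    out$auc_plain[t] <-
      ovo_auc(y_te, predict(plain, x_te, type = "membership"),
              class_ids = plain$class_ids)
    out$auc_entropy_groups[t] <-
      ovo_auc(y_te, predict(egrp, x_te, type = "membership"),
              class_ids = egrp$class_ids)
  }
  out
}

#' @export
print.ivens_results <- function(x, ...) {
  cat(sprintf("Evaluation over %d stratified splits (seed %s)\n",
              attr(x, "n_repeats"), format(attr(x, "seed"))))
  d <- data.frame(
    Classifier = x$classifier, Aggregation = x$aggregation,
    `ROC AUC` = sprintf("%.3f±%.3f", x$roc_auc_mean, x$roc_auc_sd),
    Accuracy = sprintf("%.3f±%.3f", x$accuracy_mean, x$accuracy_sd),
    `Balanced Accuracy` = sprintf("%.3f±%.3f", x$balanced_accuracy_mean,
                                  x$balanced_accuracy_sd),
    check.names = FALSE)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write a results table to disk
#'
#' Writes `results.csv` (the summary table, one row per classifier and
#' aggregation, mean and sd formatted as `mean±sd`) and `raw_scores.json`
#' (per-repeat scores, suitable for downstream significance tests) into
#' `dir`. Output is byte-stable for a fixed input.
#'
#' @param results an `ivens_results` table from [run_experiment()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "ivens_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  tab <- data.frame(
    Classifier = results$classifier, Aggregation = results$aggregation,
    ROC_AUC = sprintf("%.3f±%.3f", results$roc_auc_mean, results$roc_auc_sd),
    Accuracy = sprintf("%.3f±%.3f", results$accuracy_mean,
                       results$accuracy_sd),
    Balanced_Accuracy = sprintf("%.3f±%.3f",
                                results$balanced_accuracy_mean,
                                results$balanced_accuracy_sd))
  utils::write.csv(tab, csv, row.names = FALSE)
  js <- file.path(dir, "raw_scores.json")
  jsonlite::write_json(attr(results, "raw"), js, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}
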