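test_that("accuracy is the fraction of correct predictions", {
  expect_equal(accuracy(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(accuracy(c(0, 1, 2, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(accuracy(0, 1), 0)
  expect_error(accuracy(integer(0), integer(0)), "empty")
  expect_error(accuracy(1:3, 1:2), "mismatch")
})

test_that("balanced accuracy averages per-class recalls", {
  expect_equal(balanced_accuracy(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(balanced_accuracy(c(0, 0, 0, 1), c(0, 0, 0, 0)), 0.5)
  # majority-class prediction on a 90/10 split
  y <- rep(c("maj", "min"), c(90, 10))
  expect_equal(balanced_accuracy(y, rep("maj", 100)), 0.5)
  # differs from accuracy under imbalance
  expect_equal(accuracy(y, rep("maj", 100)), 0.9)
  # equals accuracy when per-class recalls coincide
  yt <- rep(c("a", "b"), each = 4)
  yp <- c("a", "a", "a", "b", "b", "b", "b", "a")
  expect_equal(balanced_accuracy(yt, yp), accuracy(yt, yp))
})

test_that("one-vs-one AUC reproduces hand and boundary cases", {
  y <- c(0, 0, 1, 1)
  s1 <- c(0.1, 0.4, 0.35, 0.8)
  scores <- cbind(`0` = 1 - s1, `1` = s1)
  expect_equal(ovo_auc(y, scores), 0.75)
  # perfectly separating memberships
  sep <- cbind(a = c(0.9, 0.8, 0.1, 0.2), b = c(0.1, 0.2, 0.9, 0.8))
  expect_equal(ovo_auc(c("a", "a", "b", "b"), sep), 1)
  # label-independent scores sit at chance
  const <- cbind(a = rep(0.5, 4), b = rep(0.5, 4))
  expect_equal(ovo_auc(c("a", "a", "b", "b"), const), 0.5)
  # a class missing from y_true is skipped with a warning
  three <- cbind(a = c(0.9, 0.1), b = c(0.1, 0.9), c = c(0, 0))
  expect_warning(auc <- ovo_auc(c("a", "b"), three), "skipped: c")
  expect_equal(auc, 1)
  expect_error(ovo_auc(c("a", "a"), three), "at least 2 classes")
})

test_that("one-vs-one AUC equals brute-force pairwise concordance", {
  set.seed(31)
  for (rep in 1:25) {
    K <- sample(2:4, 1)
    n <- sample(10:50, 1)
    y <- factor(sample(paste0("k", 1:K), n, replace = TRUE))
    while (nlevels(droplevels(y)) < K)
      y <- factor(sample(paste0("k", 1:K), n, replace = TRUE))
    scores <- matrix(round(runif(n * K), 1), n,
                     dimnames = list(NULL, paste0("k", 1:K)))  # forces ties
    expect_equal(ovo_auc(y, scores), brute_force_ovo_auc(y, scores),
                 tolerance = 1e-12)
  }
})

test_that("the harness is deterministic and scores a constant model at chance", {
  sim <- tiny_dataset(seed = 37, n = 50, p = 20)
  dummy <- structure(list(
    label = "DUMMY", aggregation = "",
    fit = function(x, y, seed) levels(y),
    predict_class = function(fit, x) factor(rep(fit[1], nrow(x)), levels = fit),
    predict_score = function(fit, x)
      matrix(1 / length(fit), nrow(x), length(fit),
             dimnames = list(NULL, fit))),
    class = "ivens_model_spec")
  models <- list(dummy, learner_model(knn_learner(3)))
  r1 <- run_experiment(sim$x, sim$y, models, n_repeats = 3, seed = 5)
  r2 <- run_experiment(sim$x, sim$y, models, n_repeats = 3, seed = 5)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 2L)
  expect_true(all(diff(r1$roc_auc_mean) <= 0))   # sorted by ROC AUC
  drow <- r1[r1$classifier == "DUMMY", ]
  expect_equal(drow$roc_auc_mean, 0.5)
  expect_equal(drow$roc_auc_sd, 0)
  raw <- attr(r1, "raw")
  expect_identical(nrow(raw), 6L)                 # 2 models x 3 repeats
})

test_that("the scaler is fitted on the training partition only", {
  sim <- tiny_dataset(seed = 41, n = 50, p = 10)
  seen <- new.env()
  probe <- structure(list(
    label = "PROBE", aggregation = "",
    fit = function(x, y, seed) {
      seen$x_train <- rbind(seen$x_train, x)
      levels(y)
    },
    predict_class = function(fit, x) factor(rep(fit[1], nrow(x)), levels = fit),
    predict_score = function(fit, x)
      matrix(1 / length(fit), nrow(x), length(fit),
             dimnames = list(NULL, fit))),
    class = "ivens_model_spec")

  run_experiment(sim$x, sim$y, list(probe), n_repeats = 2, seed = 9)
  ref <- seen$x_train
  # perturb a row that is in the test partition of the first repeat
  tr <- ivens:::stratified_split(sim$y, 0.8,
                                 ivens:::derive_seed(9, 42, 1))
  te_row <- setdiff(seq_len(50), tr)[1]
  x2 <- sim$x
  x2[te_row, ] <- x2[te_row, ] * 100
  seen$x_train <- NULL
  run_experiment(x2, sim$y, list(probe), n_repeats = 1, seed = 9)
  expect_equal(seen$x_train, ref[seq_len(nrow(seen$x_train)), ])
  # train features are scaled into the unit hypercube
  expect_true(all(seen$x_train >= 0 & seen$x_train <= 1))
})

test_that("min-max scaling does not clip test features outside [0, 1]", {
  tr_x <- matrix(c(0, 1, 0.5, 2, 4, 3), 3)
  sc <- ivens:::minmax_fit(tr_x)
  out <- ivens:::minmax_apply(sc, matrix(c(2, -1, 6, 1), 2))
  expect_equal(out[1, 1], 2)    # beyond the train max, kept as is
  expect_equal(out[2, 1], -1)
  # constant training features map to zero
  cx <- matrix(c(1, 1, 1, 0, 1, 2), 3)
  scc <- ivens:::minmax_fit(cx)
  expect_equal(ivens:::minmax_apply(scc, cx)[, 1], rep(0, 3))
})

test_that("every default family separates an easy synthetic problem", {
  sim <- generate_dataset(microarray_spec(
    n_samples = 80, n_features = 100, class_probs = c(0.5, 0.3, 0.2),
    n_informative = 30, effect_size = 3, block_size = 10, block_rho = 0.3,
    seed = 43))
  models <- list(learner_model(rf_learner(100)),
                 learner_model(mlp_learner(100L)),
                 learner_model(svm_learner("radial")),
                 learner_model(knn_learner(3)))
  res <- run_experiment(sim$x, sim$y, models, n_repeats = 2, seed = 3)
  expect_true(all(res$roc_auc_mean > 0.9),
              label = paste(res$classifier, round(res$roc_auc_mean, 3),
                            collapse = "; "))
})

test_that("results tables serialise byte-stably", {
  sim <- tiny_dataset(seed = 47, n = 40, p = 10)
  res <- run_experiment(sim$x, sim$y, list(learner_model(knn_learner(3))),
                        n_repeats = 2, seed = 1)
  d1 <- file.path(tempdir(), "res1"); d2 <- file.path(tempdir(), "res2")
  write_results(res, d1); write_results(res, d2)
  for (f in c("results.csv", "raw_scores.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
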