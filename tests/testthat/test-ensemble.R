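test_that("class intervals span the group members' scores", {
  cls <- c("a", "b")
  g1 <- list(stub_member("m1", rbind(c(0.3, 0.1)), cls),
             stub_member("m2", rbind(c(0.7, 0.2)), cls))
  ens <- stub_ensemble(list(g1), cls)
  ivs <- class_intervals(ens, matrix(0, 1, 1))
  expect_equal(ivs[1, "a", 1, ], c(lower = 0.3, upper = 0.7))
  expect_equal(ivs[1, "b", 1, ], c(lower = 0.1, upper = 0.2))

  # full agreement gives degenerate intervals
  g2 <- list(stub_member("m1", rbind(c(0.5, 0.5)), cls),
             stub_member("m2", rbind(c(0.5, 0.5)), cls))
  ivs2 <- class_intervals(stub_ensemble(list(g2), cls), matrix(0, 1, 1))
  expect_equal(unname(ivs2[1, , 1, "lower"]), unname(ivs2[1, , 1, "upper"]))

  # single member (constructed below the usual floor): min = max
  g3 <- list(stub_member("only", rbind(c(0.4, 0.6)), cls))
  ivs3 <- class_intervals(stub_ensemble(list(g3), cls), matrix(0, 1, 1))
  expect_equal(ivs3[1, "a", 1, ], c(lower = 0.4, upper = 0.4))
})

test_that("prediction aggregates per class and takes the interval argmax", {
  cls <- c("c0", "c1")
  # group intervals: class c0 {[0.6,0.8],[0.5,0.7]}, c1 {[0.1,0.3],[0.2,0.4]}
  g1 <- list(stub_member("a1", rbind(c(0.6, 0.1)), cls),
             stub_member("a2", rbind(c(0.8, 0.3)), cls))
  g2 <- list(stub_member("b1", rbind(c(0.5, 0.2)), cls),
             stub_member("b2", rbind(c(0.7, 0.4)), cls))
  ens <- stub_ensemble(list(g1, g2), cls, aggregation = "A1", order = "xy")
  x <- matrix(0, 1, 1)
  agg <- predict(ens, x, type = "interval")
  expect_equal(unname(c(agg$lower[1, "c0"], agg$upper[1, "c0"])),
               c(0.55, 0.75))
  expect_equal(unname(c(agg$lower[1, "c1"], agg$upper[1, "c1"])),
               c(0.15, 0.35))
  expect_identical(as.character(predict(ens, x)), "c0")
  mem <- predict(ens, x, type = "membership")
  expect_equal(unname(mem[1, ]), c(0.65, 0.25) / 0.9, tolerance = 1e-12)
  expect_equal(round(unname(mem[1, ]), 4), c(0.7222, 0.2778))
})

test_that("ties and degenerate cases resolve deterministically", {
  cls <- c("x", "y", "z")
  same <- list(stub_member("s1", rbind(c(0.4, 0.4, 0.4)), cls),
               stub_member("s2", rbind(c(0.4, 0.4, 0.4)), cls))
  ens <- stub_ensemble(list(same), cls)
  expect_identical(as.character(predict(ens, matrix(0, 1, 1))), "x")
  # all-zero midpoints fall back to the uniform membership vector
  zero <- list(stub_member("z1", rbind(c(0, 0, 0)), cls),
               stub_member("z2", rbind(c(0, 0, 0)), cls))
  ensz <- stub_ensemble(list(zero), cls)
  expect_equal(unname(predict(ensz, matrix(0, 1, 1), type = "membership")[1, ]),
               rep(1 / 3, 3))
})

test_that("membership degrees are a normalised probability vector", {
  sim <- tiny_dataset(seed = 13)
  fit <- ivens(sim$x[1:40, ], sim$y[1:40], groups = tiny_groups(), seed = 1)
  mem <- predict(fit, sim$x[41:60, ], type = "membership")
  expect_equal(rowSums(mem), rep(1, 20), tolerance = 1e-9)
  expect_true(all(mem >= 0))
  # membership argmax agrees with the class decision under A1/xy
  # whenever the sum key decides (generic position)
  cls <- predict(fit, sim$x[41:60, ])
  agg <- predict(fit, sim$x[41:60, ], type = "interval")
  sums <- agg$lower + agg$upper
  decided <- apply(sums, 1, function(s) sum(s == max(s)) == 1)
  expect_identical(as.character(cls[decided]),
                   colnames(mem)[max.col(mem[decided, , drop = FALSE],
                                         ties.method = "first")])
})

test_that("predictions are invariant to member and group permutations", {
  cls <- c("a", "b", "c")
  set.seed(21)
  mk <- function(lab) stub_member(lab, rbind(runif(3), runif(3)), cls)
  g1 <- list(mk("p"), mk("q"), mk("r"))
  g2 <- list(mk("s"), mk("t"))
  x <- matrix(0, 2, 1)
  base <- predict(stub_ensemble(list(g1, g2), cls, "A3"), x)
  perm <- predict(stub_ensemble(list(g2, list(g1[[3]], g1[[1]], g1[[2]])),
                                cls, "A3"), x)
  expect_identical(base, perm)
})

test_that("identical members reduce the ensemble to the single model argmax", {
  sim <- tiny_dataset(seed = 17)
  tr <- 1:40
  clone <- function(lab) {
    m <- knn_learner(3)
    m$label <- lab   # unique labels, identical behaviour
    m
  }
  groups <- list(model_group("G1", list(clone("k_a"), clone("k_b"))),
                 model_group("G2", list(clone("k_c"), clone("k_d"))))
  fit <- ivens(sim$x[tr, ], sim$y[tr], groups = groups, seed = 1)
  single <- ivens:::fit_member(knn_learner(3), sim$x[tr, ], sim$y[tr], 1)
  s <- soft_labels(single, sim$x[-tr, ], levels(sim$y))
  expect_identical(as.character(predict(fit, sim$x[-tr, ])),
                   levels(sim$y)[max.col(s, ties.method = "first")])
})

test_that("the three variants fit with the contracted structure", {
  sim <- tiny_dataset(seed = 23, n = 60, p = 30)
  groups <- list(
    model_group("KNN", list(knn_learner(1), knn_learner(3), knn_learner(5))),
    model_group("RF", list(rf_learner(10), rf_learner(25), rf_learner(50))),
    model_group("BAD", lapply(list(knn_learner(1), knn_learner(3),
                                   knn_learner(5)), shuffled_learner)))
  plain <- ivens(sim$x, sim$y, "plain", groups = groups, seed = 2)
  expect_null(plain$selection)
  expect_identical(vapply(plain$groups, function(g) length(g$members), 0L),
                   rep(3L, 3))

  ent <- ivens(sim$x, sim$y, "entropy", groups = groups, seed = 2)
  expect_length(ent$groups, 3L)   # entropy variant never drops groups
  for (g in seq_along(ent$groups)) {
    expect_gte(length(ent$groups[[g]]$members), 2L)
    expect_identical(
      vapply(ent$groups[[g]]$members, `[[`, "", "label"),
      rownames(ent$selection$per_model_fold_losses[[g]])[
        ent$selection$kept_models[[g]]])
  }

  egrp <- ivens(sim$x, sim$y, "entropy_groups", groups = groups, seed = 2)
  expect_gte(length(egrp$groups), 2L)
  expect_identical(egrp$selection$kept_groups,
                   select_groups(egrp$selection$per_group_mean))

  expect_error(ivens(sim$x, factor(rep("a", 60)), groups = groups),
               "single class")
})

test_that("printed summaries expose the selection audit", {
  sim <- tiny_dataset(seed = 29, n = 50, p = 20)
  fit <- ivens(sim$x, sim$y, "entropy", groups = tiny_groups(), seed = 3)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("variant: entropy", out)))
  expect_true(any(grepl("kept|dropped", out)))
})
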