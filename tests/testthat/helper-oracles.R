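# Independent, deliberately naive re-implementations used as oracles.
# These follow the printed formulas term by term and share no code with the
# package internals.

naive_aggregate <- function(name, lo, up) {
  n <- length(lo)
  am <- function(v) sum(v) / n
  power_mean <- function(v, p) (sum(v^p) / n)^(1 / p)
  lehmer <- function(v, p) {
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      num <- num + v[i]^p
      den <- den + v[i]^(p - 1)
    }
    if (den == 0) 0 else num / den
  }
  swap_means_max <- function() {
    best <- -Inf
    for (i in seq_len(n)) {
      u <- up; u[i] <- lo[i]
      best <- max(best, am(u))
    }
    best
  }
  swap_means_min <- function() {
    best <- Inf
    for (i in seq_len(n)) {
      l <- lo; l[i] <- up[i]
      best <- min(best, am(l))
    }
    best
  }
  switch(name,
         A1  = c(am(lo), am(up)),
         A2  = c(am(lo), swap_means_max()),
         A3  = c(am(lo), lehmer(up, 2)),
         A4  = c(am(lo), lehmer(up, 3)),
         A5  = c(power_mean(lo, 2), power_mean(up, 3)),
         A6  = c(power_mean(lo, 3), power_mean(up, 4)),
         A7  = c(swap_means_min(), am(up)),
         A8  = c(prod(lo)^(1 / n), lehmer(up, 2)),
         A9  = c(power_mean(lo, 2), lehmer(up, 3)),
         A10 = c(power_mean(lo, 2), power_mean(up, 2)))
}

# Tie-aware pairwise concordance count: P(score_pos > score_neg) + P(=)/2.
brute_force_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

brute_force_ovo_auc <- function(y, scores) {
  y <- as.character(y)
  classes <- colnames(scores)[colnames(scores) %in% y]
  pair_vals <- c()
  for (a in seq_len(length(classes) - 1L)) {
    for (b in seq(a + 1L, length(classes))) {
      ca <- classes[a]; cb <- classes[b]
      sub <- y %in% c(ca, cb)
      auc_a <- brute_force_auc(scores[sub, ca], y[sub] == ca)
      auc_b <- brute_force_auc(scores[sub, cb], y[sub] == cb)
      pair_vals <- c(pair_vals, (auc_a + auc_b) / 2)
    }
  }
  mean(pair_vals)
}

# Random valid intervals for property tests.
random_intervals <- function(n, seed) {
  set.seed(seed)
  a <- runif(n); b <- runif(n)
  interval(pmin(a, b), pmax(a, b))
}

# A stub fitted member whose soft labels are a fixed matrix (recycled to the
# number of rows of x), for exercising the interval/aggregation path without
# real learners.
stub_member <- function(label, scores, class_ids) {
  m <- base_learner("STUB", label,
                    fit = function(x, y, seed) TRUE,
                    score = function(fitted, x) {
                      s <- matrix(rep(t(scores), length.out =
                                        nrow(x) * ncol(scores)),
                                  nrow = nrow(x), byrow = TRUE)
                      colnames(s) <- class_ids
                      s
                    })
  m$fitted <- TRUE
  m
}

# Assemble a fitted-looking ensemble from stub members: groups is a list of
# lists of stub members.
stub_ensemble <- function(groups, class_ids, aggregation = "A1",
                          order = "xy") {
  gs <- lapply(seq_along(groups), function(g)
    structure(list(label = paste0("G", g), members = groups[[g]]),
              class = "ivens_group"))
  structure(list(variant = "plain", groups = gs, class_ids = class_ids,
                 aggregation = aggregation, order = order, selection = NULL,
                 seed = 0L, n_features = NA_integer_),
            class = "ivens")
}

# Small quick group zoo for integration tests.
tiny_groups <- function() {
  list(model_group("RF", list(rf_learner(10), rf_learner(25))),
       model_group("KNN", list(knn_learner(1), knn_learner(3))))
}

tiny_dataset <- function(seed = 1, n = 60, p = 40, effect = 2) {
  generate_dataset(microarray_spec(
    n_samples = n, n_features = p, class_probs = c(0.4, 0.35, 0.25),
    n_informative = min(12, p), effect_size = effect, block_size = 5,
    block_rho = 0.4, seed = seed))
}
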