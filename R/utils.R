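# Deterministic sub-seed derivation: every stochastic step draws its own seed
# from the user's single integer seed plus structural indices, so components
# are reproducible independently of evaluation order. Arithmetic stays in
# doubles (exact below 2^53) and is reduced mod 2^31 - 1 to a valid R seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# Row-wise numerically stable softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Stratified k-fold assignment: within each class, a seeded shuffle is dealt
# round-robin over folds. Errors (naming the smallest class) when any class
# has fewer members than folds.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  counts <- table(y)
  if (any(counts < k)) {
    small <- names(counts)[which.min(counts)]
    stop(sprintf(
      "stratified %d-fold split infeasible: class '%s' has only %d sample(s)",
      k, small, min(counts)))
  }
  folds <- integer(length(y))
  rng <- local_rng(derive_seed(seed, 104729))
  on.exit(rng())
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Stratified train/test split; per class the train share is round(frac * n_c),
# clamped so both partitions keep at least one sample of every class.
stratified_split <- function(y, train_frac, seed) {
  y <- as.factor(y)
  rng <- local_rng(derive_seed(seed, 7919))
  on.exit(rng())
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_c <- length(idx)
    if (n_c < 2L)
      stop(sprintf("stratified split infeasible: class '%s' has %d sample(s)",
                   cl, n_c))
    k <- min(max(round(train_frac * n_c), 1L), n_c - 1L)
    train <- c(train, idx[sample.int(n_c)][seq_len(k)])
  }
  sort(train)
}

# Temporarily seed the global RNG; returns a restorer for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# Min-max scaler fitted on training features only. Constant features map to 0.
minmax_fit <- function(x) {
  mins <- apply(x, 2L, min)
  rngs <- apply(x, 2L, max) - mins
  rngs[rngs == 0] <- 1
  list(min = mins, range = rngs)
}

minmax_apply <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$min, "-"), 2L, scaler$range, "/")
}

as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}
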