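# Multilayer perceptron classifier (ReLU hidden layers, softmax output,
# full-batch Adam on the cross-entropy loss). Small-sample expression data
# makes full-batch training both feasible and the most stable choice.
# Weights are initialised here (He scheme, seeded); the training loop runs
# in compiled code (src/mlp.cpp) and stops at max_iter, when the loss falls
# below loss_floor, or when the relative loss improvement stays under tol
# for `patience` consecutive iterations.

mlp_train <- function(x, y, hidden = c(100L), max_iter = 200L, lr = 0.1,
                      tol = 1e-4, patience = 5L, loss_floor = 5e-3,
                      l2 = 1e-4, seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  classes <- levels(y)
  n <- nrow(x); K <- length(classes)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  sizes <- c(ncol(x), hidden, K)
  nlay <- length(sizes) - 1L
  rng <- local_rng(derive_seed(seed, 31337))
  on.exit(rng())
  W <- vector("list", nlay); b <- vector("list", nlay)
  for (l in seq_len(nlay)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }

  trained <- .mlp_train_cpp(x, Y, W, b, as.integer(max_iter), lr, tol,
                            as.integer(patience), loss_floor, l2)

  structure(list(W = trained$W, b = trained$b, classes = classes,
                 n_features = ncol(x), iterations = trained$iterations),
            class = "ivens_mlp")
}

mlp_probs <- function(fit, x) {
  x <- as_feature_matrix(x)
  A <- x
  nlay <- length(fit$W)
  for (l in seq_len(nlay)) {
    Z <- sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    A <- if (l < nlay) pmax(Z, 0) else softmax_rows(Z)
  }
  colnames(A) <- fit$classes
  A
}
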