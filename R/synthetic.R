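#' Specification of a synthetic microarray-like dataset
#'
#' Captures the three traits that make gene-expression matrices hard:
#' high dimensionality with few samples, blocks of co-regulated (correlated)
#' features, and noise. Class signal enters as mean shifts on disjoint
#' per-class subsets of the informative features, so every class is
#' separable in principle.
#'
#' Defaults are a desk-scale rendition of published microarray cohorts:
#' 200 samples, 2000 features, four imbalanced classes with distribution
#' `(0.45, 0.28, 0.14, 0.13)`; full-scale shapes (tens of thousands of
#' features, 3-7 classes) are reachable through the arguments.
#'
#' @param n_samples number of samples.
#' @param n_features number of features (genes).
#' @param class_probs class probability vector (must sum to 1); class sizes
#'   are the largest-remainder rounding of `n_samples * class_probs`.
#' @param n_informative number of label-carrying features
#'   (`<= n_features`), split round-robin across classes.
#' @param effect_size class-mean shift on informative features, in units of
#'   `noise_sd`.
#' @param block_size width of correlated feature blocks; features in a block
#'   share a latent factor.
#' @param block_rho within-block feature correlation, in `[0, 1)`.
#' @param noise_sd standard deviation of the feature noise.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return A validated `microarray_spec` object.
#' @seealso [generate_dataset()]
#' @export
microarray_spec <- function(n_samples = 200L, n_features = 2000L,
                            class_probs = c(0.45, 0.28, 0.14, 0.13),
                            n_informative = 100L, effect_size = 1,
                            block_size = 20L, block_rho = 0.6,
                            noise_sd = 1, seed = 1L) {
  problems <- c(
    if (n_samples < 4L) "n_samples must be at least 4",
    if (n_features < 1L) "n_features must be positive",
    if (length(class_probs) < 2L) "class_probs needs at least 2 classes",
    if (any(class_probs <= 0)) "class_probs must be positive",
    if (abs(sum(class_probs) - 1) > 1e-9) "class_probs must sum to 1",
    if (n_informative > n_features) "n_informative must not exceed n_features",
    if (n_informative < length(class_probs))
      "n_informative must be at least the number of classes",
    if (effect_size < 0) "effect_size must be non-negative",
    if (block_size < 1L) "block_size must be at least 1",
    if (block_rho < 0 || block_rho >= 1) "block_rho must lie in [0, 1)",
    if (noise_sd <= 0) "noise_sd must be positive")
  if (length(problems)) stop(paste(problems, collapse = "; "))
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 class_probs = as.numeric(class_probs),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 block_size = as.integer(block_size),
                 block_rho = block_rho, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "microarray_spec")
}

# Largest-remainder apportionment of n into round(n * probs) integer counts.
largest_remainder <- function(n, probs) {
  quota <- n * probs
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic microarray-like dataset
#'
#' Draws features as `sqrt(rho) * B + sqrt(1 - rho) * E` (a latent factor
#' `B` shared within each feature block plus independent noise `E`), scaled
#' by `noise_sd`, then adds `effect_size * noise_sd` to each class's own
#' subset of informative features for samples of that class. Labels are
#' assigned by largest-remainder rounding of the class distribution and
#' shuffled. Bit-identical output for identical specs.
#'
#' @param spec a [microarray_spec()].
#' @return A list with `x` (samples x features matrix, features named
#'   `g1..gp`), `y` (factor of class labels `c1..cK`), and `spec`.
#' @examples
#' sim <- generate_dataset(microarray_spec(n_samples = 210, n_features = 50,
#'                                         class_probs = c(0.51, 0.41, 0.08),
#'                                         n_informative = 12))
#' table(sim$y)   # 107 86 17
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "microarray_spec"))
  rng <- local_rng(derive_seed(spec$seed, 2718281))
  on.exit(rng())
  n <- spec$n_samples; p <- spec$n_features
  K <- length(spec$class_probs)

  counts <- largest_remainder(n, spec$class_probs)
  y <- factor(rep(paste0("c", seq_len(K)), counts),
              levels = paste0("c", seq_len(K)))
  y <- y[sample.int(n)]

  blocks <- rep(seq_len(ceiling(p / spec$block_size)),
                each = spec$block_size, length.out = p)
  B <- matrix(stats::rnorm(n * max(blocks)), n)
  E <- matrix(stats::rnorm(n * p), n)
  x <- (sqrt(spec$block_rho) * B[, blocks, drop = FALSE] +
        sqrt(1 - spec$block_rho) * E) * spec$noise_sd

  info <- seq_len(spec$n_informative)
  owner <- rep_len(seq_len(K), spec$n_informative)  # round-robin over classes
  for (k in seq_len(K)) {
    cols <- info[owner == k]
    rows <- which(as.integer(y) == k)
    x[rows, cols] <- x[rows, cols] + spec$effect_size * spec$noise_sd
  }
  colnames(x) <- paste0("g", seq_len(p))
  list(x = x, y = y, spec = spec)
}

#' Read and write delimited datasets
#'
#' `write_dataset()` stores features plus a label column as CSV (or TSV,
#' by file extension). `read_dataset()` loads such a file back into the
#' `(x, y)` pair used throughout the package; the label column is found by
#' name (default `"label"`, else the last column).
#'
#' @param x,y features and labels.
#' @param path file path; `.tsv`/`.txt` selects tab separation.
#' @param label name of the label column.
#' @return `read_dataset()`: a list with `x` and `y`.
#' @export
write_dataset <- function(x, y, path, label = "label") {
  d <- data.frame(as_feature_matrix(x), check.names = FALSE)
  d[[label]] <- as.character(y)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, label = "label") {
  if (!file.exists(path)) stop(sprintf("dataset file not found: %s", path))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!label %in% names(d)) label <- names(d)[ncol(d)]
  y <- factor(d[[label]])
  x <- as_feature_matrix(d[setdiff(names(d), label)])
  list(x = x, y = y)
}
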