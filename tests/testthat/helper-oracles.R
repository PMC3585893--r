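# Independent oracles and shared fixtures.

# Exhaustive grid-search minimizer of the L1-regularized squared-hinge
# objective over [-lim, lim]^d with the given step; independent of the
# coordinate-descent solver. Only for 1- and 2-feature problems.
grid_oracle <- function(X, y, C, step = 0.01, lim = 5) {
  stopifnot(ncol(X) %in% c(1, 2))
  w <- seq(-lim, lim, by = step)
  if (ncol(X) == 1) {
    obj <- abs(w)
    for (i in seq_len(nrow(X)))
      obj <- obj + C * pmax(0, 1 - y[i] * X[i, 1] * w)^2
    k <- which.min(obj)
    return(list(w = w[k], objective = obj[k]))
  }
  W1 <- rep(w, times = length(w))
  W2 <- rep(w, each = length(w))
  obj <- abs(W1) + abs(W2)
  for (i in seq_len(nrow(X)))
    obj <- obj + C * pmax(0, 1 - y[i] * (X[i, 1] * W1 + X[i, 2] * W2))^2
  k <- which.min(obj)
  list(w = c(W1[k], W2[k]), objective = obj[k])
}

# Small random binary-feature instance with both classes present.
make_toy <- function(seed, l = 8, n = 5, informative = TRUE) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = l)
  X <- matrix(rbinom(l * n, 1, 0.5), nrow = l,
              dimnames = list(sprintf("s%02d", seq_len(l)),
                              sprintf("f%02d", seq_len(n))))
  if (informative) # tilt the first feature toward the positive class
    X[, 1] <- ifelse(y == 1, rbinom(l, 1, 0.9), rbinom(l, 1, 0.1))
  storage.mode(X) <- "double"
  X
}

toy_feature_matrix <- function(seed, l = 8, n = 5,
                               encoding = "binary", informative = TRUE) {
  X <- make_toy(seed, l, n, informative)
  y <- rep(c(1, -1), length.out = l)
  if (encoding == "frequency") {
    X <- X + 0.5  # strictly positive counts-like values
    X <- X / rowSums(X)
  }
  feature_matrix(X, encoding, stats::setNames(y, rownames(X)))
}

# A perfectly separable 4-sample set: f01 marks the positives, f02 (its
# complement) the negatives, so every leave-one-out fold keeps the signal.
separable_fm <- function() {
  X <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1), ncol = 2,
              dimnames = list(c("a", "b", "c", "d"), c("f01", "f02")))
  feature_matrix(X, "binary", stats::setNames(c(1, 1, -1, -1), rownames(X)))
}

# The default synthetic study set and its trained committee, built once per
# test run and shared across files (the grid search over 13 penalties is the
# expensive step).
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(simulation_config())
      fm <- build_matrix(ds$profiles, "binary", ds$labels)
      ens <- build_ensemble(fm)
      cache <<- list(ds = ds, fm = fm, ensemble = ens,
                     selected = select_features(ens))
    }
    cache
  }
})

# Hand-crafted committee for testing the voting/selection rules in isolation.
fake_ensemble <- function(W, encoding = "binary", scaler = NULL) {
  # W: families x 5 matrix of weights, rownames = family ids
  members <- lapply(seq_len(ncol(W)), function(k)
    structure(list(w = stats::setNames(W[, k], rownames(W)), C = 0.1 * k,
                   family_ids = rownames(W), encoding = encoding),
              class = "sparse_linear_model"))
  structure(list(members = members, grid_ranking = NULL, scaler = scaler,
                 family_ids = rownames(W), encoding = encoding),
            class = "svm_ensemble")
}
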