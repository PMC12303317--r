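# Unsupervised two-layer graph-convolutional autoencoder. Node features
# are the z-scored patient-value vectors of each feature (nodes x
# patients); the model reconstructs them through the normalized adjacency
# operator, and the L2 norms of the hidden embeddings rank features by
# their connectivity importance in the correlation network.

#' Node feature matrix: thresholded correlation profiles
#'
#' Each node's feature vector is its signed row of the thresholded
#' correlation matrix (entries where `|r| >= threshold`, zero elsewhere,
#' unit diagonal) — in a correlation network, a node's observable
#' attribute is its correlation pattern. Reconstructing these profiles
#' through the graph operator makes the embedding L2 norms express
#' connectivity strength, which is what the importance ranking reads out.
#'
#' @param net A `feature_network` (or a [correlation_matrix()] plus
#'   explicit `threshold`).
#' @param threshold Correlation magnitude cut-off; taken from `net` when
#'   it is a `feature_network`.
#' @return Nodes x nodes numeric matrix (rows = node feature vectors).
#' @export
node_feature_profile <- function(net, threshold = NULL) {
  if (inherits(net, "feature_network")) {
    r <- net$correlation$r
    threshold <- threshold %||% net$threshold
  } else if (inherits(net, "correlation_matrix")) {
    r <- net$r
    if (is.null(threshold)) stop_invalid("threshold required with a correlation_matrix")
  } else {
    stop_invalid("net must be a feature_network or correlation_matrix")
  }
  X <- r
  X[is.na(X) | abs(X) < threshold] <- 0
  diag(X) <- 1
  X
}

#' Symmetrically normalized adjacency with self-loops
#'
#' `A_hat = D^(-1/2) (A + I) D^(-1/2)` where `A` is the (by default
#' unweighted) adjacency of the correlation graph and `D` the degree of
#' `A + I`. Isolated nodes get `A_hat[i, i] = 1`. The operator is
#' symmetric with spectral radius <= 1.
#'
#' @param g An `igraph` graph (from [build_graph()]) or square adjacency
#'   matrix.
#' @param weighted Use `|r|` edge weights instead of 0/1 adjacency.
#' @return Dense nodes x nodes matrix.
#' @export
normalize_adjacency <- function(g, weighted = FALSE) {
  A <- if (igraph::is_igraph(g)) {
    as.matrix(igraph::as_adjacency_matrix(
      g, attr = if (weighted) "r" else NULL, sparse = FALSE))
  } else {
    as.matrix(g)
  }
  if (nrow(A) != ncol(A)) stop_invalid("adjacency must be square")
  if (weighted) A <- abs(A)
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  dinv <- 1 / sqrt(d)
  Ah <- At * outer(dinv, dinv)
  dimnames(Ah) <- dimnames(A)
  Ah
}

#' Forward pass of the two-layer graph-convolutional autoencoder
#'
#' `H = relu(A_hat %*% X %*% W1)` (embedding), `X_hat = A_hat %*% H %*% W2`
#' (reconstruction). The training loss is the mean squared error between
#' `X_hat` and `X` over (a mask of) entries.
#'
#' @param X Nodes x d node-feature matrix.
#' @param A_hat Normalized adjacency from [normalize_adjacency()].
#' @param W1 d x hidden weight matrix.
#' @param W2 hidden x d weight matrix.
#' @return List `H`, `X_hat`, `loss` (MSE over all entries).
#' @export
gcn_forward <- function(X, A_hat, W1, W2) {
  if (ncol(X) != nrow(W1) || ncol(W1) != nrow(W2) || ncol(W2) != ncol(X) ||
      nrow(X) != nrow(A_hat)) {
    stop_invalid("incompatible shapes for GCN forward pass")
  }
  H <- pmax(A_hat %*% X %*% W1, 0)
  X_hat <- A_hat %*% H %*% W2
  list(H = H, X_hat = X_hat, loss = mean((X_hat - X)^2))
}

#' Fit the graph-convolutional autoencoder
#'
#' Full-batch training with Adam (`beta1 = 0.9`, `beta2 = 0.999`,
#' `eps = 1e-8`); weights initialized from seeded `N(0, 0.1^2)` draws.
#' When a validation mask is supplied, the masked entries of `X` are
#' excluded from the training loss and scored separately as validation
#' MSE. Training is deterministic given the seed. A non-finite loss
#' raises a `hrvnet_training_failure` error.
#'
#' @param X Nodes x d node-feature matrix (z-scored patient values).
#' @param A_hat Normalized adjacency.
#' @param hidden Hidden (embedding) dimension.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param seed Integer seed for weight initialization.
#' @param val_mask Optional logical matrix, `TRUE` = held-out entry.
#' @return Object of class `gcn_fit`: `W1`, `W2`, `H` (embedding),
#'   `X_hat`, `loss_trace` (training MSE per epoch), `train_mse`,
#'   `val_mse` (`NA` without a mask), `hidden`, `lr`, `epochs`, `seed`,
#'   `node_names`, `X`.
#' @export
gcn_fit <- function(X, A_hat, hidden = 64L, lr = 0.01, epochs = 1000L,
                    seed = 1L, val_mask = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (epochs < 1L) stop_invalid("epochs must be positive")
  if (!is.null(val_mask)) {
    val_mask <- as.matrix(val_mask)
    if (!identical(dim(val_mask), dim(X))) stop_invalid("val_mask must match dim(X)")
  }
  train_mask <- if (is.null(val_mask)) matrix(TRUE, n, d) else !val_mask
  n_train <- sum(train_mask)
  if (n_train == 0L) stop_invalid("validation mask leaves no training entries")

  set.seed(seed)
  W1 <- matrix(stats::rnorm(d * hidden, 0, 0.1), d, hidden)
  W2 <- matrix(stats::rnorm(hidden * d, 0, 0.1), hidden, d)
  adam <- list(mW1 = W1 * 0, vW1 = W1 * 0, mW2 = W2 * 0, vW2 = W2 * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(epochs)
  AX <- A_hat %*% X

  for (ep in seq_len(epochs)) {
    Z1 <- AX %*% W1
    Hh <- pmax(Z1, 0)
    AH <- A_hat %*% Hh
    X_hat <- AH %*% W2
    R <- (X_hat - X) * train_mask
    loss <- sum(R^2) / n_train
    loss_trace[ep] <- loss
    if (!is.finite(loss)) {
      hrvnet_error("hrvnet_training_failure",
                   sprintf("loss diverged at epoch %d (hidden = %d, lr = %g)", ep, hidden, lr))
    }
    G <- 2 * R / n_train
    gW2 <- crossprod(AH, G)
    dH <- (A_hat %*% G %*% t(W2)) * (Z1 > 0)
    gW1 <- crossprod(AX, dH)
    # Adam updates with bias correction
    adam$mW1 <- b1 * adam$mW1 + (1 - b1) * gW1
    adam$vW1 <- b2 * adam$vW1 + (1 - b2) * gW1^2
    adam$mW2 <- b1 * adam$mW2 + (1 - b1) * gW2
    adam$vW2 <- b2 * adam$vW2 + (1 - b2) * gW2^2
    c1 <- 1 - b1^ep; c2 <- 1 - b2^ep
    W1 <- W1 - lr * (adam$mW1 / c1) / (sqrt(adam$vW1 / c2) + eps)
    W2 <- W2 - lr * (adam$mW2 / c1) / (sqrt(adam$vW2 / c2) + eps)
  }
  fin <- gcn_forward(X, A_hat, W1, W2)
  train_mse <- sum(((fin$X_hat - X) * train_mask)^2) / n_train
  val_mse <- if (is.null(val_mask)) NA_real_ else
    sum(((fin$X_hat - X) * val_mask)^2) / sum(val_mask)
  structure(list(W1 = W1, W2 = W2, H = fin$H, X_hat = fin$X_hat,
                 loss_trace = loss_trace, train_mse = train_mse, val_mse = val_mse,
                 hidden = as.integer(hidden), lr = lr, epochs = as.integer(epochs),
                 seed = as.integer(seed), node_names = rownames(X), X = X),
            class = "gcn_fit")
}

#' @export
print.gcn_fit <- function(x, ...) {
  cat(sprintf("Graph-convolutional autoencoder: %d nodes, hidden = %d, lr = %g, %d epochs\n",
              nrow(x$H), x$hidden, x$lr, x$epochs))
  cat(sprintf("  final training MSE %.5g", x$train_mse))
  if (!is.na(x$val_mse)) cat(sprintf(", validation MSE %.5g", x$val_mse))
  cat("\n")
  invisible(x)
}

#' @export
summary.gcn_fit <- function(object, ...) {
  print(object)
  cat("  loss decreased by factor",
      sprintf("%.3g", object$loss_trace[1] / object$loss_trace[length(object$loss_trace)]), "\n")
  imp <- node_importance(object)
  cat("  top features by embedding L2 norm:\n")
  print(utils::head(imp, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.gcn_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l", log = "y",
                 xlab = "epoch", ylab = "training MSE", ...)
  invisible(x)
}

#' @export
predict.gcn_fit <- function(object, ...) object$X_hat

#' @export
fitted.gcn_fit <- function(object, ...) object$X_hat

#' @export
residuals.gcn_fit <- function(object, ...) object$X - object$X_hat

#' @export
coef.gcn_fit <- function(object, ...) list(W1 = object$W1, W2 = object$W2)

#' Grid search over hidden dimension and learning rate
#'
#' Trains every (hidden, lr) grid point for `search_epochs` epochs against
#' a shared entry-masked validation set (a seeded random `val_fraction` of
#' the entries of `X` is hidden from the training loss and scored as
#' validation MSE) and returns the configuration with the lowest
#' validation MSE. Ties break toward the smaller hidden dimension, then
#' the smaller learning rate. Diverging arms are excluded; if every arm
#' diverges an error is raised.
#'
#' @param X,A_hat As in [gcn_fit()].
#' @param hidden_grid,lr_grid Candidate values (defaults 32/64/128/256 and
#'   0.001/0.01/0.1).
#' @param search_epochs Epochs per grid point (default 1000).
#' @param val_fraction Fraction of entries held out, in (0, 0.5].
#' @param seed Integer seed (mask and weight init).
#' @return List `best` (`hidden`, `lr`), `results` (data frame `hidden,
#'   lr, train_mse, val_mse, diverged`), `val_mask`.
#' @export
gcn_grid_search <- function(X, A_hat, hidden_grid = c(32L, 64L, 128L, 256L),
                            lr_grid = c(0.001, 0.01, 0.1),
                            search_epochs = 1000L, val_fraction = 0.2,
                            seed = 1L) {
  if (length(hidden_grid) == 0L || length(lr_grid) == 0L) stop_invalid("empty grid")
  if (val_fraction <= 0 || val_fraction > 0.5) stop_invalid("val_fraction must be in (0, 0.5]")
  X <- as.matrix(X)
  set.seed(derive_seed(seed, 97L))
  val_mask <- matrix(stats::runif(length(X)) < val_fraction, nrow(X), ncol(X))
  if (all(val_mask)) val_mask[1L] <- FALSE
  grid <- expand.grid(lr = sort(lr_grid), hidden = sort(hidden_grid))[, c("hidden", "lr")]
  grid <- grid[order(grid$hidden, grid$lr), ]
  res <- data.frame(hidden = integer(0), lr = numeric(0), train_mse = numeric(0),
                    val_mse = numeric(0), diverged = logical(0))
  best <- NULL
  best_val <- Inf
  for (i in seq_len(nrow(grid))) {
    h <- grid$hidden[i]; lr <- grid$lr[i]
    fit <- tryCatch(
      gcn_fit(X, A_hat, hidden = h, lr = lr, epochs = search_epochs,
              seed = seed, val_mask = val_mask),
      hrvnet_training_failure = function(e) NULL)
    if (is.null(fit)) {
      res <- rbind(res, data.frame(hidden = h, lr = lr, train_mse = NA_real_,
                                   val_mse = NA_real_, diverged = TRUE))
      next
    }
    res <- rbind(res, data.frame(hidden = h, lr = lr, train_mse = fit$train_mse,
                                 val_mse = fit$val_mse, diverged = FALSE))
    if (fit$val_mse < best_val) {  # strict: first minimum wins ties
      best_val <- fit$val_mse
      best <- list(hidden = as.integer(h), lr = lr)
    }
  }
  if (is.null(best)) {
    hrvnet_error("hrvnet_training_failure", "every grid configuration diverged")
  }
  list(best = best, results = res, val_mask = val_mask)
}

#' Fit the graph-convolutional autoencoder to a feature network
#'
#' Convenience wrapper over [node_feature_profile()],
#' [normalize_adjacency()] and [gcn_fit()] / [gcn_grid_search()]: node
#' features are the thresholded correlation profiles and propagation uses
#' the `|r|`-weighted symmetric operator by default (set
#' `weighted = FALSE` for the 0/1 adjacency).
#'
#' @param net A `feature_network`.
#' @param hidden,lr,epochs,seed,val_mask Passed to [gcn_fit()].
#' @param weighted Use `|r|` edge weights in the propagation operator.
#' @return A `gcn_fit`.
#' @export
feature_gcn <- function(net, hidden = 64L, lr = 0.01, epochs = 1000L,
                        seed = 1L, val_mask = NULL, weighted = TRUE) {
  stopifnot(inherits(net, "feature_network"))
  A_hat <- normalize_adjacency(net$graph, weighted = weighted)
  X <- node_feature_profile(net)[rownames(A_hat), rownames(A_hat)]
  gcn_fit(X, A_hat, hidden = hidden, lr = lr, epochs = epochs, seed = seed,
          val_mask = val_mask)
}

#' Feature importance from embedding norms
#'
#' The L2 norm of each node's embedding row, normalized by the maximum so
#' the top feature scores 1.0, with a descending rank (ties broken by
#' node order). With `normalization = "minmax"` the scores are instead
#' mapped linearly onto [0, 1].
#'
#' @param fit A `gcn_fit` (or a plain embedding matrix, rows = nodes).
#' @param groups Optional named feature-to-group vector for reporting.
#' @param normalization `"max"` (default) or `"minmax"`.
#' @return Object of class `importance_ranking`: data frame `feature,
#'   group, l2_norm, normalized_score, rank`, ordered by rank.
#' @export
node_importance <- function(fit, groups = NULL, normalization = c("max", "minmax")) {
  normalization <- match.arg(normalization)
  H <- if (inherits(fit, "gcn_fit")) fit$H else as.matrix(fit)
  nm <- rownames(H) %||% (if (inherits(fit, "gcn_fit")) fit$node_names else NULL) %||%
    paste0("node", seq_len(nrow(H)))
  l2 <- sqrt(rowSums(H^2))
  if (max(l2) == 0) {
    hrvnet_error("hrvnet_degenerate_result", "all embedding norms are zero")
  }
  score <- if (normalization == "max") l2 / max(l2)
  else (l2 - min(l2)) / (max(l2) - min(l2))
  out <- data.frame(
    feature = nm,
    group = if (is.null(groups)) NA_character_ else unname(groups[nm]),
    l2_norm = l2,
    normalized_score = score,
    rank = rank(-l2, ties.method = "first"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' @export
print.importance_ranking <- function(x, top = 20L, ...) {
  cat("Feature importance (embedding L2 norms), top", min(top, nrow(x)), "of", nrow(x), "\n")
  df <- as.data.frame(x)[seq_len(min(top, nrow(x))), ]
  df$l2_norm <- round(df$l2_norm, 4)
  df$normalized_score <- round(df$normalized_score, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
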