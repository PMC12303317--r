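two_node_net <- function() {
  r <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  network_from_r(r)
}

test_that("adjacency normalization matches hand computations", {
  # single isolated node
  A1 <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_equal(normalize_adjacency(A1), matrix(1, 1, 1, dimnames = list("a", "a")))
  # two connected nodes: degrees 2 after self-loops -> all entries 0.5
  Ah <- normalize_adjacency(two_node_net())
  expect_equal(unname(Ah), matrix(0.5, 2, 2))
})

test_that("the normalized operator is symmetric with spectral radius at most one", {
  for (s in 1:10) {
    n <- sample(4:12, 1)
    A <- random_adjacency(n, 0.4, seed = 300 + s)
    Ah <- normalize_adjacency(A)
    expect_equal(Ah, t(Ah), tolerance = 1e-12)
    ev <- eigen(Ah, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("forward pass closed forms hold", {
  set.seed(1)
  X <- matrix(stats::rnorm(5 * 3), 5, 3)
  Ah <- normalize_adjacency(random_adjacency(5, 0.5, seed = 2))
  # zero weights reconstruct nothing
  f0 <- gcn_forward(X, Ah, matrix(0, 3, 4), matrix(0, 4, 3))
  expect_equal(f0$X_hat, matrix(0, 5, 3), ignore_attr = TRUE)
  expect_equal(f0$loss, mean(X^2))
  # single self-looped node, unit weights, scalar feature
  f1 <- gcn_forward(matrix(2, 1, 1), matrix(1, 1, 1),
                    matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(as.numeric(f1$H), 2)
  expect_equal(as.numeric(f1$X_hat), 2)
  expect_equal(f1$loss, 0)
  expect_error(gcn_forward(X, Ah, matrix(0, 4, 4), matrix(0, 4, 3)),
               class = "hrvnet_validation_error")
})

test_that("forward pass is equivariant under node permutation", {
  set.seed(3)
  X <- matrix(stats::rnorm(6 * 4), 6, 4)
  Ah <- normalize_adjacency(random_adjacency(6, 0.5, seed = 4))
  W1 <- matrix(stats::rnorm(4 * 5, 0, 0.3), 4, 5)
  W2 <- matrix(stats::rnorm(5 * 4, 0, 0.3), 5, 4)
  p <- sample(6)
  f <- gcn_forward(X, Ah, W1, W2)
  fp <- gcn_forward(X[p, ], Ah[p, p], W1, W2)
  expect_equal(fp$H, f$H[p, ], tolerance = 1e-12)
  expect_equal(fp$X_hat, f$X_hat[p, ], tolerance = 1e-12)
})

test_that("training reduces the reconstruction loss on almost all seeds", {
  ok <- 0L
  for (s in 1:20) {
    A <- random_adjacency(12, 0.3, seed = 500 + s)
    set.seed(s)
    X <- matrix(stats::rnorm(12 * 8), 12, 8)
    fit <- gcn_fit(X, normalize_adjacency(A), hidden = 32, lr = 0.01,
                   epochs = 200, seed = s)
    if (fit$loss_trace[200] < fit$loss_trace[1]) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.95)
})

test_that("a single-node identity task is driven to near-zero loss", {
  # a few hidden units guard against an all-dead relu draw at init
  fit <- gcn_fit(matrix(2, 1, 1), matrix(1, 1, 1), hidden = 8, lr = 0.01,
                 epochs = 1000, seed = 1)
  expect_lt(fit$train_mse, 1e-4)
})

test_that("training is deterministic given the seed and errors on divergence", {
  set.seed(10)
  X <- matrix(stats::rnorm(8 * 5), 8, 5)
  Ah <- normalize_adjacency(random_adjacency(8, 0.4, seed = 11))
  f1 <- gcn_fit(X, Ah, hidden = 16, lr = 0.01, epochs = 100, seed = 9)
  f2 <- gcn_fit(X, Ah, hidden = 16, lr = 0.01, epochs = 100, seed = 9)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$W2, f2$W2)
  # Adam steps are scale-bounded, so honest divergence needs inputs whose
  # squared reconstruction error can overflow double precision
  expect_error(gcn_fit(X * 1e150, Ah, hidden = 16, lr = 1e18, epochs = 50, seed = 1),
               class = "hrvnet_training_failure")
})

test_that("the training path is equivariant: permuted nodes permute importance", {
  set.seed(21)
  X <- matrix(stats::rnorm(9 * 6), 9, 6,
              dimnames = list(paste0("n", 1:9), NULL))
  Ah <- normalize_adjacency({
    A <- random_adjacency(9, 0.4, seed = 22)
    dimnames(A) <- list(rownames(X), rownames(X)); A
  })
  p <- sample(9)
  f <- gcn_fit(X, Ah, hidden = 8, lr = 0.01, epochs = 300, seed = 5)
  fp <- gcn_fit(X[p, ], Ah[p, p], hidden = 8, lr = 0.01, epochs = 300, seed = 5)
  i1 <- node_importance(f)
  i2 <- node_importance(fp)
  m <- merge(as.data.frame(i1), as.data.frame(i2), by = "feature")
  expect_equal(m$l2_norm.x, m$l2_norm.y, tolerance = 1e-8)
  expect_equal(m$normalized_score.x, m$normalized_score.y, tolerance = 1e-8)
})

test_that("grid search picks the lowest validation MSE and survives divergent arms", {
  set.seed(31)
  X <- matrix(stats::rnorm(10 * 6), 10, 6)
  Ah <- normalize_adjacency(random_adjacency(10, 0.4, seed = 32))
  one <- gcn_grid_search(X, Ah, hidden_grid = 8, lr_grid = 0.01,
                         search_epochs = 100, seed = 1)
  expect_equal(one$best, list(hidden = 8L, lr = 0.01))

  mixed <- gcn_grid_search(X * 1e150, Ah, hidden_grid = 8, lr_grid = c(0.01, 1e18),
                           search_epochs = 50, seed = 1)
  expect_equal(mixed$best$lr, 0.01)
  expect_true(any(mixed$results$diverged))

  full <- gcn_grid_search(X, Ah, hidden_grid = c(4L, 8L, 16L, 32L),
                          lr_grid = c(0.001, 0.01, 0.1),
                          search_epochs = 60, seed = 2)
  expect_equal(nrow(full$results), 12)
  sel <- full$results[full$results$hidden == full$best$hidden &
                        full$results$lr == full$best$lr, ]
  expect_true(all(sel$val_mse <= full$results$val_mse[!full$results$diverged]))

  expect_error(gcn_grid_search(X * 1e150, Ah, hidden_grid = 8, lr_grid = 1e18,
                               search_epochs = 30, seed = 1),
               class = "hrvnet_training_failure")
})

test_that("importance normalization and ranking follow the embedding norms", {
  H <- rbind(a = c(3, 4), b = c(0, 0))
  imp <- node_importance(H)
  expect_equal(imp$l2_norm, c(5, 0))
  expect_equal(imp$normalized_score, c(1, 0))
  expect_equal(imp$rank, c(1L, 2L))
  # equal rows all score 1
  He <- rbind(a = c(1, 2), b = c(1, 2), c = c(1, 2))
  expect_equal(node_importance(He)$normalized_score, rep(1, 3))
  # positive rescaling leaves scores unchanged
  set.seed(41)
  Hr <- matrix(abs(stats::rnorm(12)), 4, 3, dimnames = list(letters[1:4], NULL))
  expect_equal(node_importance(17.3 * Hr)$normalized_score,
               node_importance(Hr)$normalized_score, tolerance = 1e-12)
  expect_error(node_importance(matrix(0, 3, 2)), class = "hrvnet_degenerate_result")
  # min-max alternative maps onto [0, 1]
  mm <- node_importance(H, normalization = "minmax")
  expect_equal(range(mm$normalized_score), c(0, 1))
})

test_that("correlation-profile node features expose connectivity to the embedding", {
  r <- diag(5)
  nm <- letters[1:5]
  dimnames(r) <- list(nm, nm)
  r["a", "b"] <- r["b", "a"] <- 0.9
  r["a", "c"] <- r["c", "a"] <- 0.6
  r["d", "e"] <- r["e", "d"] <- 0.3  # below threshold
  cm <- structure(list(r = r), class = "correlation_matrix")
  X <- node_feature_profile(cm, threshold = 0.5)
  expect_equal(diag(X), rep(1, 5), ignore_attr = TRUE)
  expect_equal(X["d", "e"], 0)
  expect_equal(X["a", "b"], 0.9)
  expect_gt(sqrt(sum(X["a", ]^2)), sqrt(sum(X["d", ]^2)))
})

test_that("feature_gcn fits a network end to end", {
  pl <- planted_pair_loadings(npairs = 3, r = 0.9)
  sim <- simulate_feature_table(29, pl$loadings, noise_sd = pl$noise_sd, seed = 8)
  fm <- assemble_features(sim$hrv, sim$vitals, sim$clinical)
  net <- feature_network(fm)
  fit <- feature_gcn(net, hidden = 16, epochs = 200, seed = 3)
  expect_s3_class(fit, "gcn_fit")
  expect_equal(nrow(fit$H), 51)
  expect_lt(fit$loss_trace[200], fit$loss_trace[1])
  imp <- node_importance(fit, groups = stats::setNames(net$schema$group,
                                                       net$schema$feature))
  expect_equal(sort(imp$rank), 1:51)
})
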