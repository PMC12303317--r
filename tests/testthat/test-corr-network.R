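make_fm <- function(values) {
  # minimal feature_matrix wrapper around a plain numeric matrix
  structure(list(values = values,
                 schema = data.frame(feature = colnames(values),
                                     group = rep("G", ncol(values))),
                 patients = rownames(values)),
            class = "feature_matrix")
}

test_that("perfect linear relations give unit correlations", {
  x <- stats::rnorm(12)
  values <- cbind(a = x, b = 2 * x, c = -x)
  cm <- correlation_matrix(values)
  expect_equal(cm$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(cm$r["a", "c"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(cm$r))
})

test_that("pairwise correlations match the sum-formula oracle on random matrices", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(stats::rnorm(12 * 5), 12, 5, dimnames = list(NULL, letters[1:5]))
    cm <- correlation_matrix(X)
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(cm$r[i, j], oracle_pearson(X[, i], X[, j]), tolerance = 1e-12)
    }
  }
})

test_that("correlations are invariant to affine rescaling of columns", {
  set.seed(9)
  X <- matrix(stats::rnorm(20 * 4), 20, 4, dimnames = list(NULL, letters[1:4]))
  Y <- sweep(sweep(X, 2, c(3, 0.01, 100, 7), `*`), 2, c(-5, 2, 0, 44), `+`)
  expect_equal(correlation_matrix(Y)$r, correlation_matrix(X)$r, tolerance = 1e-12)
})

test_that("pairs with too few complete observations are flagged undefined", {
  X <- matrix(stats::rnorm(8 * 3), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[1:6, "b"] <- NA  # only 2 complete obs for every pair with b
  cm <- correlation_matrix(X)
  expect_true(is.na(cm$r["a", "b"]))
  expect_false(is.na(cm$r["a", "c"]))
  g <- build_graph(cm, threshold = 0.1)
  ends <- igraph::as_edgelist(g)
  expect_false(any(ends == "b"))  # undefined never becomes an edge
})

test_that("p-values follow the t transform of r", {
  set.seed(2)
  X <- matrix(stats::rnorm(15 * 3), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
  cm <- correlation_matrix(X)
  r <- cm$r["a", "b"]
  want <- stats::cor.test(X[, "a"], X[, "b"])$p.value
  expect_equal(cm$p["a", "b"], want, tolerance = 1e-9)
})

test_that("the edge rule is inclusive at the threshold", {
  r <- diag(3)
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  r["a", "b"] <- r["b", "a"] <- 0.50
  r["a", "c"] <- r["c", "a"] <- 0.49
  g <- network_from_r(r, threshold = 0.5)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_false(igraph::are_adjacent(g, "a", "c"))
  expect_equal(igraph::E(g)$r, 0.5)
  ident <- diag(3)
  dimnames(ident) <- dimnames(r)
  expect_equal(igraph::ecount(network_from_r(ident)), 0)
})

test_that("star and complete graphs have the closed-form centralities", {
  star <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  star[1, 2:5] <- star[2:5, 1] <- 0.8
  diag(star) <- 1
  cent <- centralities(network_from_r(star))
  expect_equal(cent$degree_norm[cent$feature == "a"], 1.0)
  expect_equal(cent$betweenness_norm[cent$feature == "a"], 1.0)
  expect_equal(cent$degree_norm[cent$feature != "a"], rep(0.25, 4))
  expect_equal(cent$betweenness_norm[cent$feature != "a"], rep(0, 4))

  full <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(full) <- 1
  centf <- centralities(network_from_r(full))
  expect_equal(centf$degree_norm, rep(1, 4))
  expect_equal(centf$betweenness_norm, rep(0, 4))
})

test_that("centralities equal brute-force path enumeration on random graphs", {
  for (s in 1:20) {
    n <- sample(5:10, 1)
    A <- random_adjacency(n, p = 0.4, seed = 1000 + s)
    dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
    r <- A * 0.7
    diag(r) <- 1
    g <- network_from_r(r, threshold = 0.5)
    cent <- centralities(g)
    want <- oracle_centrality(A)
    ord <- match(cent$feature, rownames(A))
    expect_equal(cent$degree, unname(want$degree[ord]), ignore_attr = TRUE)
    expect_equal(cent$betweenness, unname(want$betweenness[ord]), tolerance = 1e-9)
    expect_equal(cent$betweenness_norm,
                 unname(want$betweenness[ord]) / ((n - 1) * (n - 2) / 2),
                 tolerance = 1e-9)
  }
})

test_that("maximum normalized degree is attained only by fully connected nodes", {
  A <- random_adjacency(8, p = 0.5, seed = 77)
  dimnames(A) <- list(paste0("n", 1:8), paste0("n", 1:8))
  r <- A * 0.9; diag(r) <- 1
  cent <- centralities(network_from_r(r))
  full_nodes <- cent$feature[cent$degree_norm == 1]
  expect_identical(sort(full_nodes), sort(rownames(A)[rowSums(A) == 7]))
})

test_that("group densities match hand counts on a two-group toy", {
  nm <- paste0("f", 1:10)
  schema <- data.frame(feature = nm, group = rep(c("G1", "G2"), each = 5))
  r <- diag(10); dimnames(r) <- list(nm, nm)
  link <- function(i, j, v = 0.8) r[i, j] <<- r[j, i] <<- v
  # G1 internal: 4 of 10 pairs; G2 internal: none; between: 3 of 25
  link(1, 2); link(1, 3); link(2, 3); link(4, 5)
  link(1, 6); link(2, 7); link(5, 10)
  g <- network_from_r(r)
  igraph::V(g)$group <- schema$group[match(igraph::V(g)$name, schema$feature)]
  D <- group_densities(g, schema)
  expect_equal(D["G1", "G1"], 4 / 10)
  expect_equal(D["G2", "G2"], 0)
  expect_equal(D["G1", "G2"], 3 / 25)
  expect_true(isSymmetric(D))
})

test_that("planted strong edges are recovered from 29-patient samples", {
  pl <- planted_pair_loadings(npairs = 4, r = 0.9)
  hits <- fp <- 0; fp_den <- 0
  for (s in 1:10) {
    sim <- simulate_feature_table(29, pl$loadings, noise_sd = pl$noise_sd, seed = s)
    fm <- assemble_features(sim$hrv, sim$vitals, sim$clinical)
    net <- feature_network(fm, threshold = 0.5)
    for (k in 1:4) {
      hits <- hits + igraph::are_adjacent(net$graph, pl$pairs[k, 1], pl$pairs[k, 2])
    }
    n_edges <- igraph::ecount(net$graph)
    planted_present <- sum(sapply(1:4, function(k)
      igraph::are_adjacent(net$graph, pl$pairs[k, 1], pl$pairs[k, 2])))
    fp <- fp + (n_edges - planted_present)
    fp_den <- fp_den + (choose(51, 2) - 4)
  }
  expect_gte(hits / 40, 0.95)
  expect_lte(fp / fp_den, 0.05)
})

test_that("the fitted network object reports and exports consistently", {
  pl <- planted_pair_loadings(npairs = 3, r = 0.9)
  sim <- simulate_feature_table(29, pl$loadings, noise_sd = pl$noise_sd, seed = 42)
  fm <- assemble_features(sim$hrv, sim$vitals, sim$clinical)
  net <- feature_network(fm)
  expect_s3_class(net, "feature_network")
  expect_output(print(net), "Feature correlation network")
  d <- file.path(tempdir(), "netout")
  unlink(d, recursive = TRUE)
  write_network(net, d)
  expect_true(all(file.exists(file.path(d, c("correlation_matrix.csv", "edges.csv",
                                             "centrality.csv", "group_density.csv",
                                             "network.graphml")))))
  g2 <- igraph::read_graph(file.path(d, "network.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  expect_setequal(igraph::V(g2)$name, feature_schema()$feature)
})
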