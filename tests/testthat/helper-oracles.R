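# Independent brute-force oracles used to validate the implementation.
# These are deliberately written in the most literal (slow) form possible
# and share no code path with the package internals.

# Recurrence quantification by explicit loops over the recurrence matrix.
oracle_rqa <- function(x, m, tau, radius, lmin) {
  N <- length(x) - (m - 1) * tau
  V <- matrix(0, N, m)
  for (i in 1:N) for (j in 1:m) V[i, j] <- x[i + (j - 1) * tau]
  D <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) D[i, j] <- sqrt(sum((V[i, ] - V[j, ])^2))
  eps <- radius * max(D)
  R <- D <= eps
  diag(R) <- FALSE
  nrec <- sum(R)
  if (nrec == 0) return(list(REC = 0, DET = 0, LAM = 0))
  detp <- 0
  for (k in 1:(N - 1)) {
    run <- 0
    for (i in 1:(N - k)) {
      if (R[i, i + k]) run <- run + 1
      if (!R[i, i + k] || i == N - k) {
        if (run >= lmin) detp <- detp + 2 * run
        run <- 0
      }
    }
  }
  lamp <- 0
  for (j in 1:N) {
    run <- 0
    for (i in 1:N) {
      if (R[i, j]) run <- run + 1
      if (!R[i, j] || i == N) {
        if (run >= lmin) lamp <- lamp + run
        run <- 0
      }
    }
  }
  list(REC = 100 * nrec / (N * (N - 1)), DET = detp / nrec, LAM = lamp / nrec)
}

# Degree and betweenness by BFS distances plus explicit enumeration of
# every shortest path for every node pair.
oracle_centrality <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    q <- s
    while (length(q) > 0) {
      v <- q[1]
      q <- q[-1]
      for (w in which(A[v, ] == 1)) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          q <- c(q, w)
        }
      }
    }
    if (!is.finite(dist[t])) next
    paths <- list()
    enum <- function(v, acc) {
      if (v == s) {
        paths[[length(paths) + 1]] <<- acc
        return(invisible(NULL))
      }
      for (w in which(A[v, ] == 1)) {
        if (dist[w] == dist[v] - 1) enum(w, c(acc, w))
      }
    }
    enum(t, integer(0))
    through <- numeric(n)
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      through[inner] <- through[inner] + 1
    }
    btw <- btw + through / length(paths)
  }
  list(degree = rowSums(A), betweenness = btw)
}

# Pearson correlation from raw sum formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Random symmetric 0/1 adjacency with no self-loops.
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
  }
  A
}

# Loadings planting `npairs` feature pairs at population correlation r,
# all remaining features independent. Returns loadings + noise vector +
# the planted pair index matrix.
planted_pair_loadings <- function(npairs = 5, r = 0.9) {
  schema <- feature_schema()
  feats <- schema$feature
  L <- matrix(0, length(feats), 2 * npairs, dimnames = list(feats, NULL))
  noise <- rep(1, length(feats))
  names(noise) <- feats
  pairs <- matrix("", npairs, 2)
  for (i in seq_len(npairs)) {
    a <- feats[2 * i - 1]
    b <- feats[2 * i]
    L[a, 2 * i - 1] <- 1
    L[b, 2 * i - 1] <- r
    L[b, 2 * i] <- sqrt(1 - r^2)
    noise[c(a, b)] <- 0
    pairs[i, ] <- c(a, b)
  }
  list(loadings = L, noise_sd = noise, pairs = pairs)
}

# Small graph helper: feature_network from a hand-specified correlation
# matrix (bypasses data simulation).
network_from_r <- function(r, threshold = 0.5) {
  cm <- structure(list(r = r, n_obs = matrix(100, nrow(r), ncol(r)),
                       p = matrix(0, nrow(r), ncol(r))),
                  class = "correlation_matrix")
  build_graph(cm, threshold = threshold)
}
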