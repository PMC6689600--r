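# Nearest-neighbour manifold embeddings of the question rows, one component
# each. Points are the n questions in k-dimensional (individual) space; the
# neighbour graph is built on Euclidean distances with ties broken by row
# index so runs are reproducible on degenerate geometry.

manifold_embed <- function(v, method, n_neighbors) {
  n <- nrow(v)
  if (n_neighbors < 1 || n_neighbors >= n) {
    abort(sprintf("`n_neighbors` must satisfy 1 <= n_neighbors < %d; got %d.",
                  n, n_neighbors))
  }
  scores <- switch(method,
    lle = embed_lle(v, n_neighbors),
    hessian_lle = embed_hessian(v, n_neighbors),
    ltsa = embed_ltsa(v, n_neighbors),
    isomap = embed_isomap(v, n_neighbors),
    spectral = embed_spectral(v, n_neighbors)
  )
  list(scores = scores, weights = NULL)
}

# n x n_neighbors index matrix of nearest neighbours (self excluded)
knn_index <- function(dmat, n_neighbors) {
  n <- nrow(dmat)
  idx <- vapply(seq_len(n), function(i) {
    order(dmat[i, ])[-1][seq_len(n_neighbors)]  # stable: ties by row index
  }, integer(n_neighbors))
  matrix(idx, nrow = n, ncol = n_neighbors, byrow = TRUE)
}

# symmetric (union) adjacency of the kNN graph
knn_adjacency <- function(dmat, n_neighbors) {
  n <- nrow(dmat)
  nbr <- knn_index(dmat, n_neighbors)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) adj[i, nbr[i, ]] <- 1
  pmax(adj, t(adj))
}

check_connected <- function(adj, method) {
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  if (igraph::components(g)$no > 1) {
    abort(sprintf("The %s neighbour graph is disconnected; increase `n_neighbors`.", method))
  }
}

# eigenvector(s) of the smallest nonzero eigenvalue(s) of a PSD alignment
# matrix, skipping the trivial constant direction
null_space_coord <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- order(abs(e$values))
  e$vectors[, idx[2]]
}

embed_lle <- function(v, m, reg = 1e-3) {
  n <- nrow(v)
  dmat <- as.matrix(dist(v))
  nbr <- knn_index(dmat, m)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Z <- sweep(v[nbr[i, ], , drop = FALSE], 2, v[i, ])
    G <- tcrossprod(Z)
    tr <- sum(diag(G))
    G <- G + diag(if (tr > 0) reg * tr else reg, m)
    w <- solve(G, rep(1, m))
    W[i, nbr[i, ]] <- w / sum(w)
  }
  IW <- diag(n) - W
  null_space_coord(crossprod(IW))
}

embed_hessian <- function(v, m) {
  # one target dimension: each local Hessian estimator needs the constant,
  # linear and quadratic functions of the single tangent coordinate
  if (m < 3) abort("Hessian LLE with one component needs `n_neighbors` >= 3.")
  n <- nrow(v)
  dmat <- as.matrix(dist(v))
  nbr <- knn_index(dmat, m)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Gi <- v[nbr[i, ], , drop = FALSE]
    Gi <- sweep(Gi, 2, colMeans(Gi))
    u <- svd(Gi, nu = 1, nv = 0)$u[, 1]
    Yi <- cbind(1, u, u * u)
    Q <- qr.Q(qr(Yi))
    w <- Q[, 3]
    s <- sum(w)
    if (abs(s) >= 1e-4) w <- w / s
    M[nbr[i, ], nbr[i, ]] <- M[nbr[i, ], nbr[i, ]] + tcrossprod(w)
  }
  null_space_coord(M)
}

embed_ltsa <- function(v, m) {
  if (m < 2) abort("LTSA with one component needs `n_neighbors` >= 2.")
  n <- nrow(v)
  dmat <- as.matrix(dist(v))
  nbr <- knn_index(dmat, m)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Xi <- v[nbr[i, ], , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    u <- svd(Xi, nu = 1, nv = 0)$u[, 1]
    Gi <- cbind(1 / sqrt(m), u)
    M[nbr[i, ], nbr[i, ]] <- M[nbr[i, ], nbr[i, ]] - tcrossprod(Gi)
    diag(M)[nbr[i, ]] <- diag(M)[nbr[i, ]] + 1
  }
  null_space_coord(M)
}

embed_isomap <- function(v, m) {
  dmat <- as.matrix(dist(v))
  adj <- knn_adjacency(dmat, m)
  check_connected(adj, "Isomap")
  g <- igraph::graph_from_adjacency_matrix(adj * dmat, mode = "undirected",
                                           weighted = TRUE)
  geo <- igraph::distances(g)
  drop(cmdscale(geo, k = 1))
}

embed_spectral <- function(v, m) {
  dmat <- as.matrix(dist(v))
  adj <- knn_adjacency(dmat, m)
  check_connected(adj, "spectral-embedding")
  deg <- rowSums(adj)
  dinv <- 1 / sqrt(deg)
  lsym <- diag(nrow(adj)) - (dinv * adj) * rep(dinv, each = nrow(adj))
  e <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
  idx <- order(e$values)
  dinv * e$vectors[, idx[2]]
}
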