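# Independent oracles used across the suite. Each reimplements the
# quantity it checks by the most naive route available so the two code
# paths share nothing but the definition.

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
floyd_warshall <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[nodes, nodes]
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# average distortion by an explicit double loop over ordered pairs
naive_distortion <- function(embedding, dG) {
  nodes <- embedding$nodes
  dG <- dG[nodes, nodes]
  tot <- 0; cnt <- 0
  for (u in seq_along(nodes)) for (v in seq_along(nodes)) {
    if (u == v) next
    pu <- lapply(embedding$points, function(X) X[u, ])
    pv <- lapply(embedding$points, function(X) X[v, ])
    dp <- product_distance(pu, pv, embedding$signature)
    tot <- tot + abs(dp - dG[u, v]) / dG[u, v]
    cnt <- cnt + 1
  }
  tot / cnt
}

# AUROC / AP by explicit enumeration
brute_auroc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

brute_ap <- function(pos, neg) {
  sc <- c(pos, neg)
  y <- c(rep(1, length(pos)), rep(0, length(neg)))
  thr <- sort(unique(sc), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (th in thr) {
    tp <- sum(y == 1 & sc >= th)
    fp <- sum(y == 0 & sc >= th)
    prec <- tp / (tp + fp)
    rec <- tp / length(pos)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# a small connected graph set reused by property tests
fixture_graphs <- function() {
  list(path = generate_synthetic("path", n = 8),
       cycle = generate_synthetic("cycle", n = 10),
       tree = generate_synthetic("balanced_tree", branching = 2, depth = 3))
}

# plain Euclidean GCN + Fermi-Dirac decoder + Adam, written without any
# manifold machinery; mirrors the trainer's sampling order and moment
# schemes so an all-Euclidean product GCN must reproduce it exactly
plain_gcn_fit <- function(g_train, X0, val_edges, exclude_graph,
                          n_layers = 2, lr = 0.01, epochs = 50, seed = 1,
                          r_init = 2, t_init = 1, t_min = 1e-3) {
  nodes <- sort(igraph::V(g_train)$name)
  X <- X0[nodes, , drop = FALSE]
  d <- ncol(X)
  A <- igraph::as_adjacency_matrix(g_train, sparse = FALSE)[nodes, nodes]
  A <- A + diag(nrow(A))
  dd <- 1 / sqrt(rowSums(A))
  adj <- A * (dd %o% dd)
  withr::local_seed(seed)
  lim <- sqrt(6 / (2 * d))
  Ws <- lapply(seq_len(n_layers), function(l)
    matrix(stats::runif(d * d, -lim, lim), d, d))
  bs <- lapply(seq_len(n_layers), function(l) numeric(d))
  r <- r_init; tt <- t_init
  withr::local_seed(seed + 7)
  train_pos <- cbind(match(igraph::as_edgelist(g_train)[, 1], nodes),
                     match(igraph::as_edgelist(g_train)[, 2], nodes))
  val_pos <- cbind(match(val_edges[, 1], nodes), match(val_edges[, 2], nodes))
  val_neg <- sample_negatives(exclude_graph, nrow(val_pos))
  relu <- function(z) pmax(z, 0)
  fwd <- function(X) {
    H <- X; Hs <- list(H); Zs <- list()
    for (l in seq_len(n_layers)) {
      Z <- sweep(adj %*% (H %*% Ws[[l]]), 2, bs[[l]], "+")
      Zs[[l]] <- Z
      H <- if (l < n_layers) relu(Z) else Z
      Hs[[l + 1]] <- H
    }
    list(H = H, Hs = Hs, Zs = Zs)
  }
  score <- function(H, pr) {
    d2 <- rowSums((H[pr[, 1], , drop = FALSE] - H[pr[, 2], , drop = FALSE])^2)
    1 / (1 + exp((d2 - r) / tt))
  }
  z0 <- function(x) list(m = x * 0, v = x * 0)
  stW <- lapply(Ws, z0); stb <- lapply(bs, z0)
  str_ <- z0(0); stt <- z0(0)
  stXm <- X * 0; stXv <- numeric(nrow(X))
  adam <- function(st, g, ep) {
    st$m <- 0.9 * st$m + 0.1 * g
    st$v <- 0.999 * st$v + 0.001 * g^2
    list(st = st,
         delta = -lr * (st$m / (1 - 0.9^ep)) /
           (sqrt(st$v / (1 - 0.999^ep)) + 1e-8))
  }
  for (ep in seq_len(epochs)) {
    neg <- sample_negatives(exclude_graph, nrow(train_pos))
    pr <- rbind(train_pos,
                cbind(match(neg[, 1], nodes), match(neg[, 2], nodes)))
    y <- c(rep(1, nrow(train_pos)), rep(0, nrow(neg)))
    fw <- fwd(X)
    d2 <- rowSums((fw$H[pr[, 1], , drop = FALSE] -
                     fw$H[pr[, 2], , drop = FALSE])^2)
    p <- 1 / (1 + exp((d2 - r) / tt))
    m <- length(y)
    eps <- 1e-12
    sb <- pmin(pmax(p, eps), 1 - eps)
    dL_dp <- (sb - y) / (sb * (1 - sb)) / m
    pq <- p * (1 - p)
    dL_dd2 <- dL_dp * pq * (-1 / tt)
    g_r <- sum(dL_dp * pq / tt)
    g_t <- sum(dL_dp * pq * (d2 - r) / tt^2)
    gu <- dL_dd2 * 2 * (fw$H[pr[, 1], , drop = FALSE] -
                          fw$H[pr[, 2], , drop = FALSE])
    GH <- matrix(0, nrow(X), d)
    su <- rowsum(gu, pr[, 1]); sv <- rowsum(-gu, pr[, 2])
    GH[as.integer(rownames(su)), ] <- GH[as.integer(rownames(su)), ] + su
    GH[as.integer(rownames(sv)), ] <- GH[as.integer(rownames(sv)), ] + sv
    for (l in rev(seq_len(n_layers))) {
      GZ <- if (l < n_layers) GH * (fw$Zs[[l]] > 0) else GH
      AH <- adj %*% fw$Hs[[l]]
      aw <- adam(stW[[l]], t(AH) %*% GZ, ep); stW[[l]] <- aw$st
      ab <- adam(stb[[l]], colSums(GZ), ep); stb[[l]] <- ab$st
      GH <- t(adj) %*% GZ %*% t(Ws[[l]])
      Ws[[l]] <- Ws[[l]] + aw$delta
      bs[[l]] <- bs[[l]] + ab$delta
    }
    ar <- adam(str_, g_r, ep); str_ <- ar$st; r <- r + ar$delta
    at <- adam(stt, g_t, ep); stt <- at$st
    tt <- max(tt + at$delta, t_min)
    ## node features: scalar second moment per row, as in the trainer
    stXm <- 0.9 * stXm + 0.1 * GH
    stXv <- 0.999 * stXv + 0.001 * rowSums(GH^2)
    X <- X - lr * (stXm / (1 - 0.9^ep)) /
      (sqrt(stXv / (1 - 0.999^ep)) + 1e-8)
  }
  fw <- fwd(X)
  list(X = X, Ws = Ws, r = r, t = tt,
       val_scores = score(fw$H, val_pos))
}
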