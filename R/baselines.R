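## Euclidean baseline embeddings and the post-hoc scaling optimization
## that makes their distortions comparable to the distortion-trained
## embeddings (node2vec and spectral embeddings are free to scale their
## vectors arbitrarily, so raw distortion would be meaningless).

#' Wrap a flat coordinate matrix as a Euclidean embedding
#'
#' Represents an `n x d` matrix as an [mc_embedding] with a single
#' Euclidean component, so all distortion machinery applies to baseline
#' embeddings unchanged.
#'
#' @param X numeric matrix, rows = nodes; must have rownames.
#' @return an [mc_embedding] with signature `E<d>`.
#' @export
euclidean_embedding <- function(X) {
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  sig <- mc_signature(mc_component("euclidean", ncol(X)))
  mc_embedding(rownames(X), sig, list(unname(X)))
}

#' Graph-Laplacian eigenvector embedding
#'
#' Rows of the eigenvector matrix of the combinatorial Laplacian
#' \eqn{L = D - A}, eigenvalues in ascending order, embedding dimension
#' equal to the number of nodes. The first column is the constant
#' eigenvector (eigenvalue 0) and is kept. Eigenvector signs are fixed so
#' the largest-magnitude entry of each vector is positive, which makes
#' the embedding deterministic.
#'
#' @param g a connected igraph pathway graph.
#' @return an [mc_embedding] with signature `E<|V|>`.
#' @export
laplacian_embed <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- A[nodes, nodes]
  L <- diag(rowSums(A)) - A
  eg <- eigen(L, symmetric = TRUE)
  ord <- order(eg$values)           # ascending; eigen() returns descending
  vec <- eg$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- nodes
  attr(vec, "eigenvalues") <- eg$values[ord]
  out <- euclidean_embedding(vec)
  attr(out, "eigenvalues") <- eg$values[ord]
  out
}

## ---- node2vec --------------------------------------------------------

## biased second-order random walks (return bias p, in-out bias q)
node2vec_walks <- function(g, walk_length = 80L, walks_per_node = 10L,
                           p = 1, q = 1) {
  nodes <- sort(igraph::V(g)$name)
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- lapply(igraph::adjacent_vertices(g, nodes), function(vs)
    sort(idx[vs$name]))
  walks <- list()
  k <- 0L
  for (rep in seq_len(walks_per_node)) {
    for (start in seq_len(n)) {
      w <- integer(walk_length)
      w[1L] <- start
      if (length(adj[[start]]) == 0L) { k <- k + 1L; walks[[k]] <- w[1L]; next }
      w[2L] <- resample(adj[[start]], 1L)
      if (walk_length >= 3L) for (t in 3:walk_length) {
        prev <- w[t - 2L]; cur <- w[t - 1L]
        nb <- adj[[cur]]
        if (length(nb) == 0L) { w <- w[seq_len(t - 1L)]; break }
        wt <- ifelse(nb == prev, 1 / p,
                     ifelse(nb %in% adj[[prev]], 1, 1 / q))
        w[t] <- resample(nb, 1L, prob = wt)
      }
      k <- k + 1L
      walks[[k]] <- w[w > 0L]
    }
  }
  attr(walks, "nodes") <- nodes
  walks
}

## sample() with the scalar-x gotcha removed
resample <- function(x, size, prob = NULL) {
  if (length(x) == 1L) return(rep_len(x, size))
  sample(x, size, replace = FALSE, prob = prob)
}

## skip-gram with negative sampling on a walk corpus, minibatched
## vectorized updates (pair order fixed by the seed, so reproducible)
sgns_train <- function(walks, n_vocab, dim, window = 10L, epochs = 5L,
                       negatives = 5L, lr = 0.1, batch = 256L) {
  toks <- unlist(walks)
  freq <- tabulate(toks, nbins = n_vocab)
  neg_prob <- (freq / sum(freq))^0.75
  neg_prob <- neg_prob / sum(neg_prob)
  ## center-context pairs from all walks (both directions per offset)
  cl <- list(); xl <- list(); k <- 0L
  for (w in walks) {
    lw <- length(w)
    if (lw < 2L) next
    for (off in seq_len(min(window, lw - 1L))) {
      k <- k + 1L
      a <- w[seq_len(lw - off)]; b <- w[(off + 1L):lw]
      cl[[k]] <- c(a, b); xl[[k]] <- c(b, a)
    }
  }
  centers <- unlist(cl); contexts <- unlist(xl)
  W_in <- matrix(stats::runif(n_vocab * dim, -0.5, 0.5) / dim, n_vocab, dim)
  W_out <- matrix(0, n_vocab, dim)
  npair <- length(centers)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(npair)
    for (b0 in seq(1L, npair, by = batch)) {
      ii <- ord[b0:min(b0 + batch - 1L, npair)]
      ctr <- centers[ii]; pos <- contexts[ii]
      m <- length(ii)
      neg <- matrix(sample.int(n_vocab, m * negatives, replace = TRUE,
                               prob = neg_prob), m, negatives)
      Vin <- W_in[ctr, , drop = FALSE]
      ## positive term
      Vp <- W_out[pos, , drop = FALSE]
      sp <- 1 / (1 + exp(-rowSums(Vin * Vp)))
      gp <- sp - 1                       # d(-log sigma(s))/ds
      Gin <- gp * Vp
      Gout_pos <- gp * Vin
      ## negative terms
      Gout_neg_rows <- integer(0); Gout_neg <- NULL
      for (j in seq_len(negatives)) {
        Vn <- W_out[neg[, j], , drop = FALSE]
        sn <- 1 / (1 + exp(-rowSums(Vin * Vn)))
        Gin <- Gin + sn * Vn
        gj <- sn * Vin
        Gout_neg <- rbind(Gout_neg, gj)
        Gout_neg_rows <- c(Gout_neg_rows, neg[, j])
      }
      ## aggregate per-row updates; the mean (not sum) over a row's
      ## occurrences keeps the effective step bounded at any batch size
      upd_in <- rowsum(Gin, group = ctr)
      cnt_in <- as.vector(table(ctr)[rownames(upd_in)])
      W_in[as.integer(rownames(upd_in)), ] <-
        W_in[as.integer(rownames(upd_in)), ] - lr * upd_in / cnt_in
      rows <- c(pos, Gout_neg_rows)
      upd_out <- rowsum(rbind(Gout_pos, Gout_neg), group = rows)
      cnt_out <- as.vector(table(rows)[rownames(upd_out)])
      W_out[as.integer(rownames(upd_out)), ] <-
        W_out[as.integer(rownames(upd_out)), ] - lr * upd_out / cnt_out
    }
  }
  W_in
}

#' node2vec embedding
#'
#' Biased second-order random walks (return bias `p`, in-out bias `q`)
#' feed a skip-gram model with negative sampling; the learned input
#' vectors are the node embedding. Reproducible under `seed` (walk corpus
#' and minibatch order are both seed-determined).
#'
#' @param g an igraph pathway graph.
#' @param dim embedding dimension (default 100).
#' @param walk_length,walks_per_node,window,p,q walk and skip-gram
#'   parameters (standard published defaults).
#' @param epochs skip-gram epochs over the pair corpus.
#' @param negatives negative samples per positive pair.
#' @param lr skip-gram step size.
#' @param batch minibatch size for the vectorized skip-gram updates.
#' @param seed integer seed.
#' @return an [mc_embedding] with signature `E<dim>`.
#' @export
node2vec_embed <- function(g, dim = 100L, walk_length = 80L,
                           walks_per_node = 10L, window = 10L,
                           p = 1, q = 1, epochs = 5L, negatives = 5L,
                           lr = 0.1, batch = 256L, seed = 1L) {
  withr::local_seed(as.integer(seed))
  walks <- node2vec_walks(g, walk_length, walks_per_node, p, q)
  nodes <- attr(walks, "nodes")
  X <- sgns_train(walks, n_vocab = length(nodes), dim = dim,
                  window = window, epochs = epochs, negatives = negatives,
                  lr = lr, batch = batch)
  rownames(X) <- nodes
  euclidean_embedding(X)
}

#' Optimal distortion rescaling factor
#'
#' Embeddings that do not optimize distortion directly can be arbitrarily
#' scaled, so before comparing distortions a constant `c` minimizing
#' \deqn{\sum_{i<j} \left(c\, d(x_i, x_j) / d_G(n_i, n_j) - 1\right)^2}
#' is applied. The least-squares minimizer is the closed form
#' \eqn{c^* = \sum r_{ij} / \sum r_{ij}^2} with
#' \eqn{r_{ij} = d(x_i, x_j)/d_G(n_i, n_j)} over unordered pairs.
#'
#' @param embedding an [mc_embedding] (typically Euclidean).
#' @param dG graph-distance matrix.
#' @return the scalar \eqn{c^* > 0}.
#' @export
optimal_scaling <- function(embedding, dG) {
  dG <- check_pairs(embedding, dG)
  dP <- embedding_distances(embedding)
  ut <- upper.tri(dG)
  r <- dP[ut] / dG[ut]
  if (all(r < .mc_zero)) stop("degenerate embedding: all distances zero")
  sum(r) / sum(r^2)
}

#' Distortion after optimal rescaling
#'
#' Multiplies all embedding vectors by the closed-form [optimal_scaling]
#' factor and recomputes [average_distortion]. Only meaningful for
#' Euclidean embeddings (scaling a curved component's coordinates would
#' leave its constraint surface).
#'
#' @inheritParams optimal_scaling
#' @return list with `c_star` and `distortion`.
#' @export
scaled_distortion <- function(embedding, dG) {
  comps <- embedding$signature$components
  if (any(vapply(comps, function(cm) cm$space_type != "euclidean",
                 logical(1))))
    stop("scaled_distortion applies to Euclidean embeddings")
  cs <- optimal_scaling(embedding, dG)
  scaled <- embedding
  scaled$points <- lapply(embedding$points, function(X) cs * X)
  list(c_star = cs, distortion = average_distortion(scaled, dG))
}

#' Distortion-trained Euclidean embedding
#'
#' The Euclidean special case of [train_embedding]: a single `E<dim>`
#' component trained on the same relative squared-distance loss. Used as
#' the "pretrained Euclidean" baseline.
#'
#' @param g a connected igraph pathway graph.
#' @param dim embedding dimension (default 100).
#' @param ... passed to [embedding_config] (epochs, learning_rate, seed, ...).
#' @return an `mc_embed_result`.
#' @export
euclidean_distortion_embed <- function(g, dim = 100L, ...) {
  sig <- mc_signature(mc_component("euclidean", dim))
  train_embedding(g, embedding_config(sig, ...))
}
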