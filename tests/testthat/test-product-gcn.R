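test_that("embedding slices have equal width and drop the remainder", {
  sig7 <- mc_signature(lapply(1:7, function(i) mc_component("euclidean", 14)))
  X <- matrix(seq_len(300), 3, 100)
  sl <- slice_embedding(X, sig7)
  expect_length(sl, 7L)
  expect_true(all(vapply(sl, ncol, 1L) == 14L))
  expect_equal(sl[[1]], X[, 1:14])
  expect_equal(sl[[7]], X[, 85:98])  # columns 99-100 dropped
  sl1 <- slice_embedding(X, mc_signature(mc_component("euclidean", 100)))
  expect_equal(sl1[[1]], X)
  sl2 <- slice_embedding(X[, 1:10], parse_signature("H5_1.0 x E5"))
  expect_true(all(vapply(sl2, ncol, 1L) == 5L))
  expect_error(slice_embedding(X[, 1:2, drop = FALSE],
                               parse_signature("E1 x E1 x E1")),
               "more components")
})

test_that("lifting treats features as tangent vectors at the origin", {
  hyp <- mc_component("hyperbolic", 2)
  expect_equal(lift_to_manifold(matrix(c(1, 0), 1), hyp)[1, ],
               c(cosh(1), sinh(1), 0), tolerance = 1e-12)
  expect_equal(lift_to_manifold(matrix(0, 1, 2), hyp)[1, ], origin(hyp))
  euc <- mc_component("euclidean", 3)
  M <- matrix(stats::rnorm(6), 2, 3)
  expect_identical(lift_to_manifold(M, euc), M)
  expect_error(lift_to_manifold(M, hyp), "dimension")
  # lift inverts the tangent-coordinate flattening
  sph <- mc_component("spherical", 3, curvature = 2)
  withr::with_seed(2, {
    P <- random_points(sph, 5)
    emb <- mc_embedding(letters[1:5], mc_signature(sph), list(P))
    F <- embedding_features(emb)
    expect_equal(lift_to_manifold(unname(F), sph), P, tolerance = 1e-8)
  })
})

test_that("a tangent layer with identity weights fixes isolated points", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  g1 <- igraph::set_vertex_attr(g1, "name", value = "a")
  adj <- gcn_adjacency(g1)
  for (sigstr in c("S3_1.0", "H3_2.0", "E3")) {
    cm <- parse_signature(sigstr)$components[[1]]
    P <- random_points(cm, 1, seed = 4)
    out <- tangent_gcn_layer(P, adj, diag(cm$dim), numeric(cm$dim), cm)
    expect_equal(unname(out), P, tolerance = 1e-10)
  }
})

test_that("two connected nodes with identity weights meet at the tangent midpoint", {
  adj_avg <- matrix(0.5, 2, 2)  # explicit averaging aggregation
  cm <- mc_component("spherical", 2)
  # points symmetric about the origin basepoint: exp0(+v), exp0(-v)
  v <- c(0.7, -0.3)
  P <- rbind(exp_map(origin(cm), c(0, v), cm),
             exp_map(origin(cm), c(0, -v), cm))
  out <- tangent_gcn_layer(P, adj_avg, diag(2), numeric(2), cm)
  expect_equal(out[1, ], out[2, ], tolerance = 1e-10)
  # the tangent average is 0, so both map to the origin, equidistant
  expect_equal(out[1, ], origin(cm), tolerance = 1e-10)
  d1 <- component_distance(out[1, ], P[1, ], cm)
  d2 <- component_distance(out[1, ], P[2, ], cm)
  expect_lt(abs(d1 - d2), 1e-6)
})

test_that("a Euclidean component layer is a plain GCN layer", {
  g <- generate_synthetic("cycle", n = 6)
  adj <- gcn_adjacency(g)
  cm <- mc_component("euclidean", 4)
  X <- matrix(stats::rnorm(24), 6, 4)
  W <- matrix(stats::rnorm(16), 4, 4)
  b <- stats::rnorm(4)
  out <- tangent_gcn_layer(X, adj, W, b, cm)
  expect_equal(out, sweep(adj %*% (X %*% W), 2, b, "+"))
})

test_that("decoder scores average components and decay with distance", {
  sig <- parse_signature("H2_1.0 x E2")
  model <- product_gcn(sig, seed = 1)
  o <- lapply(sig$components, origin)
  same <- decode_edge(o, o, model)
  expect_gt(same$score, 0.5)
  expect_equal(same$score, mean(same$component_scores), tolerance = 1e-12)
  far <- list(exp_map(o[[1]], c(0, 12, 0), sig$components[[1]]),
              o[[2]] + c(50, 0))
  expect_lt(decode_edge(far, far, model)$score + 0 - 0, 1.000001) # sanity
  expect_lt(decode_edge(o, far, model)$score, 0.05)
  # strict monotonicity in one component distance on a grid
  sc <- vapply(seq(0, 5, by = 0.25), function(d) {
    p <- list(exp_map(o[[1]], c(0, d, 0), sig$components[[1]]), o[[2]])
    decode_edge(o, p, model)$score
  }, numeric(1))
  expect_true(all(diff(sc) < 0))
})

test_that("backpropagation matches finite differences on all geometries", {
  sig <- parse_signature("H3_1.5 x S3_0.5 x E3")
  n <- 6
  withr::with_seed(7, {
    inputs <- lapply(sig$components, function(cm) random_points(cm, n))
  })
  g <- generate_synthetic("erdos_renyi", n = 6, p = 0.5, seed = 2)
  adj <- gcn_adjacency(g)
  model <- product_gcn(sig, n_layers = 2, seed = 3)
  pairs <- rbind(c(1, 2), c(3, 5), c(2, 6), c(4, 1))
  y <- c(1, 0, 1, 0)
  fw <- mcpathway:::gcn_forward(model, inputs, adj)
  bk <- mcpathway:::gcn_backward(model, inputs, adj, fw, pairs, y,
                                 grad_inputs = TRUE)
  lossfn <- function(model, inputs) {
    fw <- mcpathway:::gcn_forward(model, inputs, adj)
    s <- mcpathway:::gcn_scores(model, fw$points, pairs)$score
    s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
    -mean(y * log(s) + (1 - y) * log(1 - s))
  }
  eps <- 1e-6
  for (i in 1:3) {
    cm <- sig$components[[i]]
    W <- model$stacks[[i]]$layers[[1]]$W
    for (a in 1:2) {
      m2 <- model; m2$stacks[[i]]$layers[[1]]$W[a, a] <- W[a, a] + eps
      m3 <- model; m3$stacks[[i]]$layers[[1]]$W[a, a] <- W[a, a] - eps
      num <- (lossfn(m2, inputs) - lossfn(m3, inputs)) / (2 * eps)
      expect_lt(abs(num - bk$grads[[i]]$layers[[1]]$W[a, a]), 1e-6)
    }
    for (par in c("r", "t")) {
      m2 <- model; m2$stacks[[i]][[par]] <- model$stacks[[i]][[par]] + eps
      m3 <- model; m3$stacks[[i]][[par]] <- model$stacks[[i]][[par]] - eps
      num <- (lossfn(m2, inputs) - lossfn(m3, inputs)) / (2 * eps)
      expect_lt(abs(num - bk$grads[[i]][[par]]), 1e-6)
    }
    ## input-point gradients compared after tangent projection
    X <- inputs[[i]]
    num <- X * 0
    for (cc in seq_len(ncol(X))) {
      i2 <- inputs; i2[[i]][1, cc] <- X[1, cc] + eps
      i3 <- inputs; i3[[i]][1, cc] <- X[1, cc] - eps
      num[1, cc] <- (lossfn(model, i2) - lossfn(model, i3)) / (2 * eps)
    }
    pa <- mcpathway:::project_rows(X, bk$input_grads[[i]], cm,
                                   apply_metric = TRUE)
    pn <- mcpathway:::project_rows(X, num, cm, apply_metric = TRUE)
    expect_lt(max(abs(pa[1, ] - pn[1, ])), 1e-6)
  }
})

test_that("points remain on-manifold through layers and training", {
  g <- generate_synthetic("erdos_renyi", n = 20, p = 0.25, seed = 4)
  g <- largest_component_subgraph(g)
  sig <- parse_signature("H4_1.0 x S4_2.0 x E4")
  emb <- random_embedding(sort(igraph::V(g)$name), sig, seed = 1)
  sp <- split_edges(g, 0.1, seed = 1)
  fit <- fit_product_gcn(sp$g_train, emb, sp$val, exclude_graph = g,
                         epochs = 30, lr = 0.02, seed = 1)
  fw <- mcpathway:::gcn_forward(fit$model, fit$points, fit$adj)
  for (i in seq_along(sig$components)) {
    cm <- sig$components[[i]]
    res_in <- apply(fit$points[[i]], 1, constraint_residual, component = cm)
    res_out <- apply(fw$points[[i]], 1, constraint_residual, component = cm)
    expect_lt(max(res_in, res_out), 1e-5)
  }
})

test_that("zero-epoch fits return the initialized validation metrics", {
  g <- generate_synthetic("cycle", n = 12)
  emb <- random_embedding(sort(igraph::V(g)$name),
                          parse_signature("E6"), seed = 3)
  sp <- split_edges(g, 0.1, seed = 3)
  fit <- fit_product_gcn(sp$g_train, emb, sp$val, exclude_graph = g,
                         epochs = 0, seed = 3)
  expect_equal(nrow(fit$metrics), 1L)
  expect_equal(fit$metrics$epoch, 0L)
  expect_false(is.na(fit$val_auroc))
})

test_that("an all-Euclidean product GCN equals a plain GCN run", {
  g <- generate_synthetic("erdos_renyi", n = 15, p = 0.3, seed = 6)
  g <- largest_component_subgraph(g)
  nodes <- sort(igraph::V(g)$name)
  withr::with_seed(11, {
    X0 <- matrix(stats::rnorm(length(nodes) * 6, sd = 0.5),
                 ncol = 6, dimnames = list(nodes, NULL))
  })
  sp <- split_edges(g, 0.1, seed = 2)
  fit <- fit_product_gcn(sp$g_train, euclidean_embedding(X0), sp$val,
                         exclude_graph = g, n_layers = 2, lr = 0.01,
                         epochs = 40, seed = 5)
  oracle <- plain_gcn_fit(sp$g_train, X0, sp$val, g, n_layers = 2,
                          lr = 0.01, epochs = 40, seed = 5)
  expect_equal(fit$points[[1]], oracle$X, tolerance = 1e-5)
  expect_equal(fit$model$stacks[[1]]$layers[[1]]$W, oracle$Ws[[1]],
               tolerance = 1e-5)
  vp <- mcpathway:::edges_to_idx(sp$val, nodes)
  fw <- mcpathway:::gcn_forward(fit$model, fit$points, fit$adj)
  sc <- mcpathway:::gcn_scores(fit$model, fw$points, vp)$score
  expect_equal(sc, oracle$val_scores, tolerance = 1e-5)
})

test_that("training separates planted cliques from random non-edges", {
  base <- igraph::add_edges(
    igraph::disjoint_union(igraph::make_full_graph(8),
                           igraph::make_full_graph(8)),
    c(1, 9))
  base <- igraph::set_vertex_attr(base, "name",
                                  value = sprintf("n%03d", 1:16))
  wins <- 0L
  for (s in 1:5) {
    sp <- split_edges(base, 0.1, seed = s)
    emb <- train_embedding(base, embedding_config("H4_1.0 x E4",
                                                  epochs = 200, seed = s))
    fit <- fit_product_gcn(sp$g_train, emb$embedding, sp$val,
                           exclude_graph = base, epochs = 50, lr = 0.02,
                           seed = s)
    held <- predict(fit, sp$val)
    rnd <- predict(fit, sample_negatives(base, 10, seed = s + 50))
    wins <- wins + (mean(held) > mean(rnd))
  }
  expect_gte(wins, 4L)
})
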