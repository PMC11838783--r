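# embedding of nodes on a line, for hand-computable distances
line_embedding <- function(coords) {
  X <- matrix(coords, ncol = 1)
  rownames(X) <- sprintf("n%03d", seq_along(coords))
  euclidean_embedding(X)
}

test_that("distortion loss matches hand-evaluated pairs", {
  p2 <- generate_synthetic("path", n = 2)
  dG <- graph_distances(p2)
  expect_equal(distortion_loss(line_embedding(c(0, 1)), dG), 0)
  # manifold distance 2 at graph distance 1: ((2/1)^2 - 1)^2 = 9
  expect_equal(distortion_loss(line_embedding(c(0, 2)), dG), 9)
  # and 3 under the absolute reading
  expect_equal(distortion_loss(line_embedding(c(0, 2)), dG, form = "abs"), 3)
  # matching all distances zeroes the loss
  p3 <- generate_synthetic("path", n = 3)
  expect_equal(distortion_loss(line_embedding(c(0, 1, 2)),
                               graph_distances(p3)), 0)
})

test_that("average distortion matches its definition and the naive oracle", {
  p2 <- generate_synthetic("path", n = 2)
  expect_equal(average_distortion(line_embedding(c(0, 1.5)),
                                  graph_distances(p2)), 0.5)
  p3 <- generate_synthetic("path", n = 3)
  expect_equal(average_distortion(line_embedding(c(0, 1, 2)),
                                  graph_distances(p3)), 0)
  # equilateral triangle at unit side on K3
  k3 <- generate_synthetic("erdos_renyi", n = 3, p = 1, seed = 1)
  X <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  rownames(X) <- sort(igraph::V(k3)$name)
  expect_equal(average_distortion(euclidean_embedding(X),
                                  graph_distances(k3)), 0,
               tolerance = 1e-12)
  # V^2 variant differs exactly by (n-1)/n
  g <- generate_synthetic("cycle", n = 7)
  emb <- random_embedding(sort(igraph::V(g)$name),
                          parse_signature("E3"), seed = 2)
  dG <- graph_distances(g)
  expect_equal(average_distortion(emb, dG, denominator = "V2") * 7 / 6,
               average_distortion(emb, dG), tolerance = 1e-12)
  # naive double-loop oracle on mixed signatures
  for (sig in c("E4", "H2_1.0 x S2_2.0")) {
    emb <- random_embedding(sort(igraph::V(g)$name),
                            parse_signature(sig), seed = 5)
    expect_equal(average_distortion(emb, dG), naive_distortion(emb, dG),
                 tolerance = 1e-12)
  }
})

test_that("unreachable pairs are rejected", {
  g <- igraph::set_vertex_attr(
    igraph::disjoint_union(igraph::make_ring(4), igraph::make_ring(3)),
    "name", value = sprintf("n%03d", 1:7))
  dG <- graph_distances(g)
  emb <- random_embedding(sort(igraph::V(g)$name),
                          parse_signature("E2"), seed = 1)
  expect_error(average_distortion(emb, dG), "unreachable")
  expect_error(distortion_loss(emb, dG), "unreachable")
})

test_that("riemannian sgd step behaves like its Euclidean special case", {
  nodes <- c("a", "b")
  emb <- random_embedding(nodes, parse_signature("E3"), seed = 4)
  zero <- lapply(emb$points, function(X) X * 0)
  expect_equal(riemannian_sgd_step(emb, zero, lr = 0.5), emb)
  G <- list(matrix(1:6 / 10, 2, 3))
  stepped <- riemannian_sgd_step(emb, G, lr = 0.2)
  expect_equal(stepped$points[[1]], emb$points[[1]] - 0.2 * G[[1]])
  # non-finite gradients abort
  G[[1]][1] <- NaN
  expect_error(riemannian_sgd_step(emb, G, lr = 0.2), "non-finite")
})

test_that("a spherical point steps toward its target along the geodesic", {
  cm <- mc_component("spherical", 2)
  sig <- mc_signature(cm)
  x <- random_point(cm, seed = 31)
  target <- random_point(cm, seed = 32)
  emb <- mc_embedding("a", sig, list(matrix(x, 1)))
  # ambient gradient of 0.5*d(x,target)^2 is -w*target (see log map)
  d <- component_distance(x, target, cm)
  s <- sum(x * target)
  w <- d / sqrt(max(1 - s^2, 1e-12))
  G <- list(matrix(-w * target, 1))
  stepped <- riemannian_sgd_step(emb, G, lr = 0.05)
  expect_lt(component_distance(stepped$points[[1]][1, ], target, cm), d)
  expect_lt(constraint_residual(stepped$points[[1]][1, ], cm), 1e-10)
})

test_that("training drives distortion down on an isometrically embeddable graph", {
  p3 <- generate_synthetic("path", n = 3)
  res <- train_embedding(p3, embedding_config("E2", epochs = 800, seed = 1))
  expect_lt(res$distortion, 0.05)
  # zero epochs returns the (calibrated) random initialization untouched
  res0 <- train_embedding(p3, embedding_config("E2", epochs = 0, seed = 1))
  expect_length(res0$loss_trace, 0)
  expect_equal(res0$distortion,
               average_distortion(res0$embedding, graph_distances(p3)))
})

test_that("loss decreases in expectation over training", {
  for (g in fixture_graphs()) {
    for (s in 0:2) {
      res <- train_embedding(g, embedding_config("E10", epochs = 200,
                                                 seed = s,
                                                 learning_rate = 0.01))
      tr <- res$loss_trace
      n10 <- max(1, floor(length(tr) * 0.1))
      expect_lte(stats::median(utils::tail(tr, n10)),
                 stats::median(utils::head(tr, n10)))
    }
  }
})

test_that("signature grid obeys the dimension budget and component caps", {
  grid <- signature_grid(total_dim = 100, max_components_per_type = 3)
  expect_gt(length(grid), 0)
  for (cf in grid) {
    expect_equal(total_dim(cf$signature), 100L)
    types <- vapply(cf$signature$components, function(cm) cm$space_type, "")
    expect_true(all(table(types) <= 3))
    expect_gte(length(cf$signature), 1L)
  }
  # both learning rates appear
  expect_setequal(unique(vapply(grid, function(cf) cf$learning_rate, 1)),
                  c(0.01, 0.1))
})

test_that("tiny grids enumerate exactly the feasible signatures", {
  grid <- signature_grid(total_dim = 2, max_components_per_type = 1,
                         dim_choices = c(1, 2), lr_choices = 0.1)
  sigs <- sort(vapply(grid, function(cf) format_signature(cf$signature), ""))
  expect_setequal(sigs, c("E2", "H2_1", "S2_1",
                          "H1_1 x S1_1", "H1_1 x E1", "S1_1 x E1"))
  expect_length(sigs, 6L)
  expect_warning(g2 <- signature_grid(total_dim = 2,
                                      max_components_per_type = 3,
                                      dim_choices = 5),
                 "feasible")
  expect_length(g2, 0L)
})

test_that("sweep selects the minimum-distortion signature and flags ties", {
  p4 <- generate_synthetic("path", n = 4)
  one <- list(embedding_config("E2", epochs = 100, seed = 1))
  sw <- sweep_and_select(p4, one)
  expect_false(sw$tie)
  expect_equal(format_signature(sw$best$embedding$signature), "E2")
  # close distortions across different signatures flag a tie at a loose
  # tolerance and not at a strict one
  grid2 <- list(embedding_config("E2", epochs = 300, seed = 1),
                embedding_config("E3", epochs = 300, seed = 1))
  strict <- sweep_and_select(p4, grid2, tie_tol = 1e-12)
  loose <- sweep_and_select(p4, grid2, tie_tol = 100)
  expect_false(strict$tie)
  expect_true(loose$tie)
  expect_null(loose$best)
})

test_that("the full grid can never lose to its Euclidean-only subset", {
  g <- generate_synthetic("cycle", n = 8)
  grid <- signature_grid(total_dim = 6, max_components_per_type = 1,
                         lr_choices = 0.01, epochs = 150)
  sw <- sweep_and_select(g, grid)
  res <- sw$results
  e_only <- grepl("^E", res$signature) & !grepl("x", res$signature)
  expect_lte(min(res$distortion), min(res$distortion[e_only]))
})

test_that("embedding TSV serialization round-trips", {
  emb <- random_embedding(c("TP53", "MDM2", "ATM"),
                          parse_signature("H2_2.0 x E3"), seed = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_tsv(emb, f)
  emb2 <- read_embedding_tsv(f)
  expect_equal(emb2$nodes, emb$nodes)
  expect_equal(format_signature(emb2$signature), format_signature(emb$signature))
  expect_equal(emb2$points, emb$points, tolerance = 1e-12)
})
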