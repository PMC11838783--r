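test_that("origin and random points satisfy their constraints", {
  expect_equal(origin(mc_component("hyperbolic", 2, curvature = 4)), c(2, 0, 0))
  expect_equal(origin(mc_component("spherical", 2)), c(1, 0, 0))
  expect_equal(origin(mc_component("euclidean", 3)), c(0, 0, 0))
  for (tp in c("spherical", "hyperbolic", "euclidean")) {
    for (C in c(0.5, 1, 2)) {
      cm <- if (tp == "euclidean") mc_component(tp, 3) else
        mc_component(tp, 3, curvature = C)
      p <- random_point(cm, seed = 11)
      expect_lt(constraint_residual(p, cm), 1e-10)
      expect_identical(p, random_point(cm, seed = 11))
    }
  }
  hp <- random_point(mc_component("hyperbolic", 2), seed = 5)
  expect_gte(hp[1], 1)  # upper sheet
})

test_that("exp map reproduces closed-form geodesics", {
  sph <- mc_component("spherical", 1)
  expect_equal(exp_map(c(1, 0), c(0, pi / 2), sph), c(0, 1),
               tolerance = 1e-12)
  hyp <- mc_component("hyperbolic", 1)
  expect_equal(exp_map(c(1, 0), c(0, 1), hyp), c(cosh(1), sinh(1)),
               tolerance = 1e-12)
  euc <- mc_component("euclidean", 2)
  expect_equal(exp_map(c(1, 2), c(-1, 3), euc), c(0, 5))
  # zero tangent returns the basepoint exactly
  expect_identical(exp_map(c(0, 1), c(0, 0), sph), c(0, 1))
  # non-tangent vectors are rejected
  expect_error(exp_map(c(1, 0), c(1, 1), sph), "tangent")
})

test_that("log map inverts exp and measures distance", {
  sph <- mc_component("spherical", 1)
  v <- log_map(c(1, 0), c(0, 1), sph)
  expect_equal(tangent_norm(v, sph), pi / 2, tolerance = 1e-12)
  expect_equal(log_map(c(1, 0), c(1, 0), sph), c(0, 0))
  hyp <- mc_component("hyperbolic", 1)
  v <- log_map(c(1, 0), c(cosh(1), sinh(1)), hyp)
  expect_equal(tangent_norm(v, hyp), 1, tolerance = 1e-10)
  expect_error(log_map(c(1, 0), c(-1, 0), sph), "antipodal")
})

test_that("exp/log inversion holds across space types and curvatures", {
  for (tp in c("spherical", "hyperbolic", "euclidean")) {
    for (C in c(0.5, 1, 2)) {
      cm <- if (tp == "euclidean") mc_component(tp, 4) else
        mc_component(tp, 4, curvature = C)
      withr::with_seed(40 + C * 10, {
        for (rep in 1:20) {
          x <- random_point(cm)
          w <- stats::rnorm(ambient_dim(cm))
          v <- project_to_tangent(x, w, cm)
          nv <- tangent_norm(v, cm)
          if (nv > 1e-8) v <- v / nv * stats::runif(1, 0.05, 1)
          y <- exp_map(x, v, cm)
          expect_lt(constraint_residual(y, cm), 1e-8)
          v2 <- log_map(x, y, cm)
          expect_lt(max(abs(v2 - v)) / max(1, tangent_norm(v, cm)), 1e-6)
        }
      })
    }
  }
})

test_that("constraints survive a long exp-map random walk", {
  for (tp in c("spherical", "hyperbolic")) {
    cm <- mc_component(tp, 3, curvature = 1.5)
    withr::with_seed(7, {
      x <- random_point(cm)
      worst <- 0
      for (i in 1:1000) {
        # partial geodesic jump toward a fresh random point keeps the
        # walk in a bounded region while exercising exp/log every step
        v <- stats::runif(1) * log_map(x, random_point(cm), cm)
        x <- exp_map(x, v, cm)
        worst <- max(worst, constraint_residual(x, cm))
      }
      expect_lt(worst, 1e-8)
    })
  }
})

test_that("component distances match closed forms and the log-map norm", {
  sph <- mc_component("spherical", 1)
  expect_equal(component_distance(c(1, 0), c(-1, 0), sph), pi)
  expect_equal(component_distance(c(1, 0), c(1, 0), sph), 0)
  euc <- mc_component("euclidean", 2)
  expect_equal(component_distance(c(0, 0), c(3, 4), euc), 5)
  for (tp in c("spherical", "hyperbolic")) {
    cm <- mc_component(tp, 3, curvature = 2)
    withr::with_seed(13, {
      for (rep in 1:25) {
        x <- random_point(cm); y <- random_point(cm)
        d <- component_distance(x, y, cm)
        expect_lt(abs(d - tangent_norm(log_map(x, y, cm), cm)), 1e-8)
      }
    })
  }
})

test_that("product distance decomposes as the root sum of squares", {
  sig <- mc_signature(mc_component("spherical", 1), mc_component("euclidean", 1))
  expect_equal(product_distance(list(c(1, 0), 0), list(c(0, 1), 1), sig),
               sqrt(pi^2 / 4 + 1), tolerance = 1e-12)
  # 3-4-5 with two Euclidean components
  sig2 <- mc_signature(mc_component("euclidean", 1), mc_component("euclidean", 1))
  expect_equal(product_distance(list(0, 0), list(3, 4), sig2), 5)
  # single component equals the component distance
  sig1 <- mc_signature(mc_component("euclidean", 2))
  expect_equal(product_distance(list(c(0, 0)), list(c(3, 4)), sig1),
               component_distance(c(0, 0), c(3, 4), sig1$components[[1]]))
  # against independently computed component distances on random points
  sig3 <- parse_signature("H2_2.0 x S2_0.5 x E3")
  withr::with_seed(3, {
    u <- lapply(sig3$components, random_point)
    v <- lapply(sig3$components, random_point)
  })
  d2 <- sum(mapply(function(x, y, cm) component_distance(x, y, cm)^2,
                   u, v, sig3$components))
  expect_equal(product_distance(u, v, sig3)^2, d2, tolerance = 1e-12)
})

test_that("metric axioms hold on sampled triples", {
  for (sigstr in c("S3_1.0", "H3_1.0", "E3", "H2_0.5 x S2_2.0 x E2")) {
    sig <- parse_signature(sigstr)
    withr::with_seed(17, {
      pts <- replicate(60, lapply(sig$components, random_point),
                       simplify = FALSE)
      D <- outer(seq_along(pts), seq_along(pts),
                 Vectorize(function(i, j)
                   product_distance(pts[[i]], pts[[j]], sig)))
      expect_equal(D, t(D))
      idx <- matrix(sample.int(60, 3000, replace = TRUE), ncol = 3)
      viol <- D[idx[, 1:2]] + D[idx[, 2:3]] - D[idx[, c(1, 3)]]
      expect_gt(min(viol), -1e-9)
    })
  }
})

test_that("tangent projection is idempotent and removes the radial part", {
  sph <- mc_component("spherical", 1)
  expect_equal(project_to_tangent(c(1, 0), c(1, 1), sph), c(0, 1))
  euc <- mc_component("euclidean", 3)
  expect_equal(project_to_tangent(c(0, 0, 0), c(1, 2, 3), euc), c(1, 2, 3))
  for (tp in c("spherical", "hyperbolic")) {
    cm <- mc_component(tp, 3, curvature = 1.3)
    withr::with_seed(23, {
      x <- random_point(cm)
      w <- stats::rnorm(4)
      v <- project_to_tangent(x, w, cm)
      expect_equal(project_to_tangent(x, v, cm), v, tolerance = 1e-10)
      ip <- if (tp == "spherical") sum(v * x) else minkowski_dot(v, x)
      expect_lt(abs(ip), 1e-10)
    })
  }
})

test_that("signature strings round-trip and validate", {
  sig <- parse_signature("H2_1.0 x S3_0.5 x E2")
  expect_equal(length(sig), 3L)
  expect_equal(total_dim(sig), 7L)
  expect_equal(parse_signature(format_signature(sig)), sig)
  expect_error(parse_signature("Q5"), "parse")
  expect_error(mc_component("spherical", 0), "positive")
  expect_error(mc_component("hyperbolic", 2, curvature = -1), "positive")
})
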