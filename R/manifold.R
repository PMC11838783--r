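## Constant-curvature model spaces: constraints, exp/log maps, distances.
##
## Conventions. Curvature scale C parameterizes the squared radius of the
## constraint surface (radius R = sqrt(C)):
##   spherical   <x, x>   =  C           (Euclidean inner product)
##   hyperbolic  <x, x>_L = -C, x_0 > 0  (Minkowski inner product, upper sheet)
## Distances carry the sqrt(C) factor:
##   d_S(x, y) = sqrt(C) * acos(<x, y> / C)
##   d_H(x, y) = sqrt(C) * acosh(-<x, y>_L / C)
##   d_E(x, y) = ||x - y||

# on-manifold tolerance on the constraint residual
.mc_tol <- 1e-6
# below this norm a tangent vector is treated as exactly zero (the printed
# exp formulas divide by ||v||)
.mc_zero <- 1e-12

#' Minkowski inner product
#'
#' \eqn{\langle x, y \rangle_L = -x_0 y_0 + \sum_{i \ge 1} x_i y_i}, with the
#' time-like coordinate at index 1 (R indexing).
#'
#' @param x,y numeric vectors of equal length.
#' @return a numeric scalar.
#' @export
minkowski_dot <- function(x, y) {
  -x[1L] * y[1L] + sum(x[-1L] * y[-1L])
}

## clamp with optional diagnostics (drift beyond width 1e-12 is reported
## when options(mcpathway.verbose = TRUE))
clamp <- function(x, lo = -Inf, hi = Inf) {
  out <- pmin(pmax(x, lo), hi)
  if (isTRUE(getOption("mcpathway.verbose", FALSE))) {
    drift <- max(c(0, lo - x, x - hi), na.rm = TRUE)
    if (drift > 1e-12)
      message("mcpathway: clamped argument drift ", format(drift))
  }
  out
}

#' Constraint residual of a point
#'
#' Absolute deviation of a point from its component's manifold constraint:
#' \eqn{|\langle x,x\rangle - C|} (spherical),
#' \eqn{|\langle x,x\rangle_L + C|} (hyperbolic), 0 (Euclidean).
#'
#' @param x ambient coordinate vector.
#' @param component an [mc_component].
#' @return nonnegative numeric scalar.
#' @export
constraint_residual <- function(x, component) {
  check_ambient(x, component)
  switch(component$space_type,
    spherical = abs(sum(x^2) - component$curvature),
    hyperbolic = abs(minkowski_dot(x, x) + component$curvature) +
      if (x[1L] <= 0) Inf else 0,
    euclidean = 0)
}

check_ambient <- function(x, component) {
  if (length(x) != ambient_dim(component))
    stop("ambient dimension mismatch: got ", length(x), ", expected ",
         ambient_dim(component), " for ", format_component(component))
  invisible(TRUE)
}

check_on_manifold <- function(x, component, tol = .mc_tol) {
  if (constraint_residual(x, component) > tol * max(1, abs(component_C(component))))
    stop("point is off the ", component$space_type,
         " manifold (constraint residual beyond tolerance)")
  invisible(TRUE)
}

component_C <- function(component) {
  if (component$space_type == "euclidean") 1 else component$curvature
}

#' Canonical basepoint of a component
#'
#' Returns \eqn{(\sqrt{C}, 0, \dots, 0)} for spherical and hyperbolic
#' components and the zero vector for Euclidean ones. Used as the tangent
#' basepoint for the product GCN layers.
#'
#' @param component an [mc_component].
#' @return ambient coordinate vector satisfying the constraint exactly.
#' @examples
#' origin(mc_component("hyperbolic", 2, curvature = 4))  # (2, 0, 0)
#' @export
origin <- function(component) {
  a <- ambient_dim(component)
  if (component$space_type == "euclidean") return(numeric(a))
  c(sqrt(component$curvature), numeric(a - 1L))
}

#' Random point on a component manifold
#'
#' Spherical points are uniform on the sphere of radius \eqn{\sqrt{C}};
#' hyperbolic points are the exponential image of Gaussian tangent noise
#' at the origin; Euclidean points are Gaussian. The Gaussian spread is
#' \eqn{1/\sqrt{d}} per coordinate so that the expected point norm is ~1
#' independent of the manifold dimension (keeps initial pairwise distances
#' on the scale of small graph distances for any dimension budget).
#'
#' @param component an [mc_component].
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return ambient coordinate vector on the manifold.
#' @export
random_point <- function(component, seed = NULL) {
  drop(random_points(component, 1L, seed = seed))
}

#' @rdname random_point
#' @param n number of points; rows of the returned matrix.
#' @return `random_points`: an `n x ambient_dim` matrix of on-manifold rows.
#' @export
random_points <- function(component, n, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  a <- ambient_dim(component)
  sd0 <- 1 / sqrt(component$dim)
  switch(component$space_type,
    euclidean = matrix(stats::rnorm(n * a, sd = sd0), n, a),
    spherical = {
      g <- matrix(stats::rnorm(n * a), n, a)
      nr <- sqrt(rowSums(g^2))
      nr[nr < .mc_zero] <- 1
      sqrt(component$curvature) * g / nr
    },
    hyperbolic = exp0_rows(matrix(stats::rnorm(n * (a - 1L), sd = sd0),
                                  n, a - 1L), component))
}

#' Project an ambient vector onto a tangent space
#'
#' Removes the radial part of `w` at basepoint `x`, using the Euclidean
#' inner product for spheres and the Minkowski inner product for
#' hyperboloids. Euclidean vectors are returned unchanged. Idempotent.
#'
#' @param x on-manifold basepoint.
#' @param w ambient vector.
#' @param component an [mc_component].
#' @return tangent vector at `x`.
#' @export
project_to_tangent <- function(x, w, component) {
  check_ambient(x, component); check_ambient(w, component)
  C <- component$curvature
  switch(component$space_type,
    euclidean = w,
    spherical = w - (sum(w * x) / C) * x,
    hyperbolic = w + (minkowski_dot(w, x) / C) * x)
}

#' Norm of a tangent vector
#'
#' Euclidean norm on spherical and Euclidean components; Minkowski norm
#' \eqn{\sqrt{\langle v,v\rangle_L}} on hyperbolic ones (nonnegative for
#' tangent vectors at hyperboloid points).
#'
#' @param v tangent vector (ambient coordinates).
#' @param component an [mc_component].
#' @return nonnegative scalar.
#' @export
tangent_norm <- function(v, component) {
  if (component$space_type == "hyperbolic")
    sqrt(max(minkowski_dot(v, v), 0))
  else sqrt(sum(v^2))
}

check_tangent <- function(x, v, component, tol = 1e-5) {
  ip <- switch(component$space_type,
    euclidean = 0,
    spherical = sum(v * x),
    hyperbolic = minkowski_dot(v, x))
  scale <- max(1, sqrt(sum(v^2)) * sqrt(sum(x^2)))
  if (abs(ip) / scale > tol)
    stop("vector is not tangent at the basepoint (inner product ",
         format(ip), ")")
  invisible(TRUE)
}

#' Exponential map on a component manifold
#'
#' Maps a tangent vector `v` at `x` to the endpoint of the geodesic of
#' length \eqn{\|v\|} leaving `x` in direction `v`:
#' \deqn{\exp_x(v) = \cos(\|v\|/\sqrt{C})\,x +
#'   \sqrt{C}\sin(\|v\|/\sqrt{C})\,v/\|v\| \quad (S)}
#' \deqn{\exp_x(v) = \cosh(\|v\|_L/\sqrt{C})\,x +
#'   \sqrt{C}\sinh(\|v\|_L/\sqrt{C})\,v/\|v\|_L \quad (H)}
#' and \eqn{x + v} for Euclidean components. Tangent vectors of norm below
#' `1e-12` return `x` exactly.
#'
#' @param x on-manifold basepoint.
#' @param v tangent vector at `x` (checked to tolerance).
#' @param component an [mc_component].
#' @return on-manifold point.
#' @examples
#' sph <- mc_component("spherical", 1)
#' exp_map(c(1, 0), c(0, pi / 2), sph)   # (0, 1)
#' @export
exp_map <- function(x, v, component) {
  check_ambient(x, component); check_ambient(v, component)
  if (component$space_type == "euclidean") return(x + v)
  check_tangent(x, v, component)
  R <- sqrt(component$curvature)
  nv <- tangent_norm(v, component)
  if (nv < .mc_zero) return(x)
  th <- nv / R
  y <- if (component$space_type == "spherical")
    cos(th) * x + R * sin(th) * v / nv
  else
    cosh(th) * x + R * sinh(th) * v / nv
  renormalize(y, component)
}

#' Logarithmic map on a component manifold
#'
#' Inverse of [exp_map]: returns the tangent vector at `x` whose exponential
#' is `y`, with norm equal to the geodesic distance:
#' \deqn{\log_x(y) = d(x,y)\,\frac{y - (\langle x,y\rangle/C)\,x}
#'   {\|y - (\langle x,y\rangle/C)\,x\|} \quad (S)}
#' \deqn{\log_x(y) = d(x,y)\,\frac{y + (\langle x,y\rangle_L/C)\,x}
#'   {\|y + (\langle x,y\rangle_L/C)\,x\|_L} \quad (H)}
#' and \eqn{y - x} for Euclidean components. Identical points give the zero
#' vector; spherical antipodes are rejected (the log is undefined there).
#'
#' @param x,y on-manifold points of the same component.
#' @param component an [mc_component].
#' @return tangent vector at `x`.
#' @export
log_map <- function(x, y, component) {
  check_ambient(x, component); check_ambient(y, component)
  if (component$space_type == "euclidean") return(y - x)
  C <- component$curvature
  d <- component_distance(x, y, component)
  if (d < .mc_zero) return(numeric(length(x)))
  u <- project_to_tangent(x, y, component)
  nu <- tangent_norm(u, component)
  if (nu < .mc_zero) {
    if (component$space_type == "spherical")
      stop("log map undefined for antipodal spherical points")
    return(numeric(length(x)))
  }
  d * u / nu
}

#' Geodesic distance on one component
#'
#' \eqn{\sqrt{C}\,\mathrm{acos}(\langle x,y\rangle/C)} (spherical, argument
#' clamped to \eqn{[-1,1]}), \eqn{\sqrt{C}\,\mathrm{acosh}(-\langle
#' x,y\rangle_L/C)} (hyperbolic, argument clamped to \eqn{[1,\infty)}),
#' \eqn{\|x-y\|} (Euclidean).
#'
#' @param x,y on-manifold points.
#' @param component an [mc_component].
#' @return nonnegative scalar.
#' @export
component_distance <- function(x, y, component) {
  check_ambient(x, component); check_ambient(y, component)
  C <- component$curvature
  switch(component$space_type,
    euclidean = sqrt(sum((x - y)^2)),
    spherical = sqrt(C) * acos(clamp(sum(x * y) / C, -1, 1)),
    hyperbolic = sqrt(C) * acosh(clamp(-minkowski_dot(x, y) / C, lo = 1)))
}

#' Distance on a product manifold
#'
#' Squared distances decompose over components:
#' \eqn{d_{\mathcal{P}}(u,v)^2 = \sum_i d_{M_i}(u_i, v_i)^2}.
#'
#' @param u,v product points: lists of ambient coordinate vectors, one per
#'   signature component.
#' @param signature an [mc_signature].
#' @return nonnegative scalar.
#' @examples
#' sig <- mc_signature(mc_component("spherical", 1), mc_component("euclidean", 1))
#' product_distance(list(c(1, 0), 0), list(c(0, 1), 1), sig)  # sqrt(pi^2/4 + 1)
#' @export
product_distance <- function(u, v, signature) {
  stopifnot(inherits(signature, "mc_signature"))
  comps <- signature$components
  if (length(u) != length(comps) || length(v) != length(comps))
    stop("product point does not conform to the signature")
  d2 <- mapply(function(x, y, cm) component_distance(x, y, cm)^2,
               u, v, comps)
  sqrt(sum(d2))
}

## exact renormalization onto the constraint surface (used after every
## retraction to stop floating-point drift)
renormalize <- function(x, component) {
  C <- component$curvature
  switch(component$space_type,
    euclidean = x,
    spherical = sqrt(C) * x / sqrt(sum(x^2)),
    hyperbolic = {
      x[1L] <- sqrt(C + sum(x[-1L]^2))
      x
    })
}

## ---- vectorized row-wise kernels -------------------------------------
## Rows of X are points / tangent vectors; these back the training loops.

renormalize_rows <- function(X, component) {
  C <- component$curvature
  switch(component$space_type,
    euclidean = X,
    spherical = sqrt(C) * X / sqrt(rowSums(X^2)),
    hyperbolic = {
      X[, 1L] <- sqrt(C + rowSums(X[, -1L, drop = FALSE]^2))
      X
    })
}

## exp map at the origin from spatial tangent coordinates H (n x dim);
## returns ambient points (n x (dim+1)) for curved components, H itself for
## Euclidean ones
exp0_rows <- function(H, component) {
  if (component$space_type == "euclidean") return(H)
  R <- sqrt(component$curvature)
  nr <- sqrt(rowSums(H^2))
  th <- pmin(nr / R, 250)  # cosh/sinh overflow guard
  dirn <- H / ifelse(nr < .mc_zero, 1, nr)
  if (component$space_type == "spherical")
    P <- cbind(R * cos(th), R * sin(th) * dirn)
  else
    P <- cbind(R * cosh(th), R * sinh(th) * dirn)
  zr <- which(nr < .mc_zero)
  if (length(zr))
    P[zr, ] <- matrix(origin(component), length(zr), ncol(P), byrow = TRUE)
  renormalize_rows(P, component)
}

## log map at the origin: ambient points P -> spatial tangent coords (n x dim)
log0_rows <- function(P, component) {
  if (component$space_type == "euclidean") return(P)
  R <- sqrt(component$curvature)
  s <- P[, 1L] / R
  Ps <- P[, -1L, drop = FALSE]
  rs <- sqrt(rowSums(Ps^2))
  d <- if (component$space_type == "spherical")
    R * acos(clamp(s, -1, 1)) else R * acosh(clamp(s, lo = 1))
  scl <- ifelse(rs < .mc_zero, 0, d / pmax(rs, .mc_zero))
  Ps * scl
}

## row-wise exponential map at arbitrary basepoints X with tangent rows V
exp_rows <- function(X, V, component) {
  if (component$space_type == "euclidean") return(X + V)
  R <- sqrt(component$curvature)
  nv <- if (component$space_type == "hyperbolic")
    sqrt(pmax(-V[, 1L]^2 + rowSums(V[, -1L, drop = FALSE]^2), 0))
  else sqrt(rowSums(V^2))
  th <- pmin(nv / R, 250)  # cosh/sinh overflow guard
  sc <- ifelse(nv < .mc_zero, 0, 1 / pmax(nv, .mc_zero))
  Y <- if (component$space_type == "spherical")
    cos(th) * X + (R * sin(th) * sc) * V
  else
    cosh(th) * X + (R * sinh(th) * sc) * V
  Y[nv < .mc_zero, ] <- X[nv < .mc_zero, ]
  renormalize_rows(Y, component)
}

## row-wise tangent projection of ambient rows W at basepoint rows X;
## for hyperbolic, apply_metric = TRUE first flips the sign of the time-like
## column (Euclidean -> Riemannian gradient conversion)
project_rows <- function(X, W, component, apply_metric = FALSE) {
  C <- component$curvature
  switch(component$space_type,
    euclidean = W,
    spherical = W - (rowSums(W * X) / C) * X,
    hyperbolic = {
      if (apply_metric) W[, 1L] <- -W[, 1L]
      W + (((-W[, 1L] * X[, 1L]) +
             rowSums(W[, -1L, drop = FALSE] * X[, -1L, drop = FALSE])) / C) * X
    })
}

## row-wise squared Riemannian norm of tangent rows (Minkowski for
## hyperbolic components)
tangent_norm2_rows <- function(V, component) {
  if (component$space_type == "hyperbolic")
    pmax(-V[, 1L]^2 + rowSums(V[, -1L, drop = FALSE]^2), 0)
  else rowSums(V^2)
}

## all-pairs distance matrix between rows of X (and rows of Y if given)
comp_dist_matrix <- function(X, component, Y = X) {
  C <- component$curvature
  switch(component$space_type,
    euclidean = {
      xx <- rowSums(X^2); yy <- rowSums(Y^2)
      D2 <- outer(xx, yy, "+") - 2 * X %*% t(Y)
      sqrt(pmax(D2, 0))
    },
    spherical = {
      S <- clamp(X %*% t(Y) / C, -1, 1)
      sqrt(C) * acos(S)
    },
    hyperbolic = {
      G <- X %*% t(Y) - 2 * outer(X[, 1L], Y[, 1L])  # Minkowski Gram
      S <- clamp(-G / C, lo = 1)
      sqrt(C) * acosh(S)
    })
}
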