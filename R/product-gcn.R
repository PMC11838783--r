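## Mixed-curvature Product GCN.
##
## One GCN stack per signature component. At every layer the component's
## points are pulled into the tangent space at the component origin via
## the log map, a standard message-passing update runs there
## (symmetrically normalized adjacency, linear transform, bias, optional
## activation), and the result is pushed back with the exp map. Edge
## scores come from a Fermi-Dirac decoder on the component geodesic
## distances, 1 / (exp((d^2 - r)/t) + 1), averaged over components.
## Training is binary cross-entropy on positive vs sampled negative edges
## with Riemannian Adam: Euclidean parameters (layer weights, decoder
## r/t) get standard Adam moments; the manifold-valued input points (when
## trainable) get tangent-space moments with exponential-map retraction.

#' Split a flat embedding into per-component slices
#'
#' A `total`-dimensional embedding consumed by a `k`-component product
#' GCN is split into `k` contiguous slices of dimension
#' `floor(total / k)`; trailing remainder dimensions are dropped (a note
#' is emitted when `options(mcpathway.verbose = TRUE)`). Slice order
#' follows signature order.
#'
#' @param X numeric `n x total` feature matrix.
#' @param signature an [mc_signature] (only its component count is used).
#' @return list of `n x floor(total/k)` matrices, one per component.
#' @examples
#' X <- matrix(rnorm(300), 3, 100)
#' sig <- parse_signature("H14_1.0 x S14_1.0 x E14")
#' # 7-component signature: slice_embedding(X, sig) gives 7 slices of 14
#' @export
slice_embedding <- function(X, signature) {
  stopifnot(is.matrix(X), inherits(signature, "mc_signature"))
  k <- length(signature$components)
  total <- ncol(X)
  if (k > total) stop("more components (", k, ") than dimensions (", total, ")")
  d <- total %/% k
  dropped <- total - k * d
  if (dropped > 0) mc_msg(dropped, " trailing dimension(s) dropped in slicing")
  lapply(seq_len(k), function(i)
    X[, ((i - 1L) * d + 1L):(i * d), drop = FALSE])
}

#' Lift flat features onto a component manifold
#'
#' Treats each feature row as a tangent vector at the component origin
#' (the constrained ambient coordinate is implicitly 0) and applies the
#' exponential map; Euclidean features are returned unchanged. Feature
#' dimension must equal the component's manifold dimension.
#'
#' @param X numeric `n x dim` feature matrix.
#' @param component an [mc_component].
#' @return `n x ambient_dim` matrix of on-manifold rows.
#' @examples
#' lift_to_manifold(matrix(c(1, 0), 1), mc_component("hyperbolic", 2))
#' # (cosh 1, sinh 1, 0)
#' @export
lift_to_manifold <- function(X, component) {
  stopifnot(is.matrix(X))
  if (ncol(X) != component$dim)
    stop("feature dimension ", ncol(X), " != manifold dimension ",
         component$dim)
  exp0_rows(X, component)
}

#' Tangent coordinates of an embedding
#'
#' Flattens a product-manifold embedding to an `n x total_dim` matrix of
#' tangent coordinates at the component origins (log map per component,
#' concatenated in signature order). The Euclidean identity case returns
#' the coordinates unchanged, so this is the exact inverse of slicing and
#' lifting when dimensions are compatible.
#'
#' @param embedding an [mc_embedding].
#' @return numeric matrix with node rownames.
#' @export
embedding_features <- function(embedding) {
  comps <- embedding$signature$components
  F <- do.call(cbind, lapply(seq_along(comps), function(i)
    log0_rows(embedding$points[[i]], comps[[i]])))
  rownames(F) <- embedding$nodes
  F
}

#' Symmetrically normalized adjacency with self-loops
#'
#' \eqn{\hat A = D^{-1/2} (A + I) D^{-1/2}}, the canonical GCN
#' propagation operator, rows/columns in lexicographic node order.
#'
#' @param g an igraph pathway graph.
#' @return dense numeric matrix with node dimnames.
#' @export
gcn_adjacency <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[nodes, nodes,
                                                      drop = FALSE]
  A <- A + diag(nrow(A))
  dd <- 1 / sqrt(rowSums(A))
  A * (dd %o% dd)
}

#' Construct a product GCN model
#'
#' Per component: `n_layers` square weight matrices (width = the
#' component's manifold dimension) with biases, plus Fermi-Dirac decoder
#' parameters `r` (distance threshold) and `t` (temperature). Weights are
#' Glorot-uniform initialized under `seed`.
#'
#' @param signature an [mc_signature]; one GCN stack per component.
#' @param n_layers stack depth (default 2).
#' @param seed integer seed for the weight initialization.
#' @param r_init,t_init initial decoder threshold and temperature.
#' @return an object of class `mc_product_gcn`.
#' @export
product_gcn <- function(signature, n_layers = 2L, seed = 1L,
                        r_init = 2, t_init = 1) {
  stopifnot(inherits(signature, "mc_signature"), n_layers >= 1L)
  withr::local_seed(as.integer(seed))
  comps <- signature$components
  stacks <- lapply(comps, function(cm) {
    d <- cm$dim
    lim <- sqrt(6 / (d + d))
    layers <- lapply(seq_len(n_layers), function(l)
      list(W = matrix(stats::runif(d * d, -lim, lim), d, d),
           b = numeric(d)))
    list(layers = layers, r = r_init, t = t_init)
  })
  structure(list(signature = signature, stacks = stacks,
                 n_layers = as.integer(n_layers)),
            class = "mc_product_gcn")
}

#' @export
print.mc_product_gcn <- function(x, ...) {
  cat("<mc_product_gcn> ", format_signature(x$signature), ", depth ",
      x$n_layers, "\n", sep = "")
  invisible(x)
}

## activation per component type: tangent features of curved components
## pass through unchanged, Euclidean features get ReLU
act_fun <- function(space_type) {
  if (space_type == "euclidean") function(z) pmax(z, 0) else identity
}
act_grad <- function(space_type, Z) {
  if (space_type == "euclidean") (Z > 0) * 1 else 1
}

#' One tangent-space GCN layer
#'
#' Log map at the component origin, then \eqn{\hat A H W + b} with
#' optional activation, then exp map back onto the manifold.
#'
#' @param P `n x ambient_dim` matrix of on-manifold points.
#' @param adj normalized adjacency from [gcn_adjacency].
#' @param W,b layer weight matrix (`dim x dim`) and bias.
#' @param component an [mc_component].
#' @param activation apply the component's nonlinearity (default FALSE).
#' @return `n x ambient_dim` matrix of on-manifold points.
#' @export
tangent_gcn_layer <- function(P, adj, W, b, component, activation = FALSE) {
  H <- log0_rows(P, component)
  Z <- adj %*% (H %*% W)
  Z <- sweep(Z, 2L, b, "+")
  if (activation) Z <- act_fun(component$space_type)(Z)
  exp0_rows(Z, component)
}

## forward pass, caching tangent activations for backprop
gcn_forward <- function(model, inputs, adj) {
  comps <- model$signature$components
  out <- vector("list", length(comps))
  cache <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    cm <- comps[[i]]
    H <- log0_rows(inputs[[i]], cm)
    Hs <- list(H); Zs <- list()
    for (l in seq_len(model$n_layers)) {
      ly <- model$stacks[[i]]$layers[[l]]
      Z <- sweep(adj %*% (H %*% ly$W), 2L, ly$b, "+")
      Zs[[l]] <- Z
      H <- if (l < model$n_layers) act_fun(cm$space_type)(Z) else Z
      Hs[[l + 1L]] <- H
    }
    out[[i]] <- exp0_rows(H, cm)
    cache[[i]] <- list(Hs = Hs, Zs = Zs)
  }
  list(points = out, cache = cache)
}

## Fermi-Dirac probability from squared distance
fd_score <- function(d2, r, t) 1 / (1 + exp((d2 - r) / t))

## per-component squared distances for an index pair list (m x 2)
pair_d2 <- function(points, pairs, comps) {
  lapply(seq_along(comps), function(i) {
    X <- points[[i]]; cm <- comps[[i]]
    xu <- X[pairs[, 1L], , drop = FALSE]
    xv <- X[pairs[, 2L], , drop = FALSE]
    d <- switch(cm$space_type,
      euclidean = sqrt(rowSums((xu - xv)^2)),
      spherical = sqrt(cm$curvature) *
        acos(clamp(rowSums(xu * xv) / cm$curvature, -1, 1)),
      hyperbolic = sqrt(cm$curvature) *
        acosh(clamp(-(-xu[, 1L] * xv[, 1L] +
                      rowSums(xu[, -1L, drop = FALSE] *
                              xv[, -1L, drop = FALSE])) / cm$curvature,
                    lo = 1)))
    d^2
  })
}

#' Score a node pair with the product GCN decoder
#'
#' Per-component Fermi-Dirac probability
#' \eqn{1/(\exp((d_i^2 - r_i)/t_i) + 1)} on the component geodesic
#' distance, averaged across components. Monotonically decreasing in each
#' component distance.
#'
#' @param u_parts,v_parts product points: lists of ambient coordinate
#'   vectors conforming to the model signature.
#' @param model an [product_gcn] model.
#' @return list with `component_scores` and their mean `score`.
#' @export
decode_edge <- function(u_parts, v_parts, model) {
  comps <- model$signature$components
  sc <- vapply(seq_along(comps), function(i) {
    d <- component_distance(u_parts[[i]], v_parts[[i]], comps[[i]])
    fd_score(d^2, model$stacks[[i]]$r, model$stacks[[i]]$t)
  }, numeric(1))
  list(component_scores = sc, score = mean(sc))
}

## scores for an m x 2 index matrix of pairs
gcn_scores <- function(model, points, pairs) {
  comps <- model$signature$components
  d2 <- pair_d2(points, pairs, comps)
  ps <- vapply(seq_along(comps), function(i)
    fd_score(d2[[i]], model$stacks[[i]]$r, model$stacks[[i]]$t),
    numeric(nrow(pairs)))
  if (nrow(pairs) == 1L) ps <- matrix(ps, nrow = 1L)
  list(score = rowMeans(ps), per_comp = ps, d2 = d2)
}

## transpose-Jacobian of exp0 applied to ambient cotangents G (n x a),
## returning tangent-coordinate gradients (n x dim); H are the tangent
## coordinates at which exp0 was evaluated
exp0_backprop <- function(H, G, component) {
  if (component$space_type == "euclidean") return(G)
  R <- sqrt(component$curvature)
  nr <- sqrt(rowSums(H^2))
  th <- nr / R
  U <- H / ifelse(nr < .mc_zero, 1, nr)
  g0 <- G[, 1L]
  Gs <- G[, -1L, drop = FALSE]
  ug <- rowSums(U * Gs)
  if (component$space_type == "spherical") {
    out <- (-sin(th) * g0 + cos(th) * ug) * U +
      (R * sin(th) / pmax(nr, .mc_zero)) * (Gs - ug * U)
  } else {
    out <- (sinh(th) * g0 + cosh(th) * ug) * U +
      (R * sinh(th) / pmax(nr, .mc_zero)) * (Gs - ug * U)
  }
  z <- nr < .mc_zero
  if (any(z)) out[z, ] <- Gs[z, , drop = FALSE]
  out
}

## transpose-Jacobian of log0: ambient-point gradients from tangent
## cotangents G (n x dim); P are the on-manifold points
log0_backprop <- function(P, G, component) {
  if (component$space_type == "euclidean") return(G)
  R <- sqrt(component$curvature)
  s <- P[, 1L] / R
  Ps <- P[, -1L, drop = FALSE]
  rs <- sqrt(rowSums(Ps^2))
  U <- Ps / ifelse(rs < .mc_zero, 1, rs)
  d <- if (component$space_type == "spherical")
    R * acos(clamp(s, -1, 1)) else R * acosh(clamp(s, lo = 1))
  ug <- rowSums(U * G)
  dd_dp0 <- if (component$space_type == "spherical")
    -R / pmax(rs, .mc_zero) else R / pmax(rs, .mc_zero)
  g0 <- dd_dp0 * ug
  Gspat <- (d / pmax(rs, .mc_zero)) * (G - ug * U)
  z <- rs < .mc_zero
  if (any(z)) { g0[z] <- 0; Gspat[z, ] <- G[z, , drop = FALSE] }
  cbind(g0, Gspat)
}

## gradient of sum_e coef_e * d2_e(points) wrt the point matrix (n x a)
d2_backprop <- function(X, pairs, coef, component) {
  xu <- X[pairs[, 1L], , drop = FALSE]
  xv <- X[pairs[, 2L], , drop = FALSE]
  if (component$space_type == "euclidean") {
    gu <- coef * 2 * (xu - xv)
    gv <- -gu
  } else {
    C <- component$curvature; R <- sqrt(C)
    if (component$space_type == "spherical") {
      s <- clamp(rowSums(xu * xv) / C, -1, 1)
      d <- R * acos(s)
      w <- ifelse(s > 1 - 1e-12, 1, d / (R * sqrt(pmax(1 - s^2, 1e-30))))
      gu <- coef * (-2 * w) * xv
      gv <- coef * (-2 * w) * xu
    } else {
      mk <- -xu[, 1L] * xv[, 1L] +
        rowSums(xu[, -1L, drop = FALSE] * xv[, -1L, drop = FALSE])
      s <- clamp(-mk / C, lo = 1)
      d <- R * acosh(s)
      w <- ifelse(s < 1 + 1e-12, 1, d / (R * sqrt(pmax(s^2 - 1, 1e-30))))
      Ju <- xu; Ju[, 1L] <- -Ju[, 1L]
      Jv <- xv; Jv[, 1L] <- -Jv[, 1L]
      gu <- coef * (-2 * w) * Jv
      gv <- coef * (-2 * w) * Ju
    }
  }
  G <- matrix(0, nrow(X), ncol(X))
  gu_s <- rowsum(gu, group = pairs[, 1L])
  gv_s <- rowsum(gv, group = pairs[, 2L])
  G[as.integer(rownames(gu_s)), ] <- G[as.integer(rownames(gu_s)), ] + gu_s
  G[as.integer(rownames(gv_s)), ] <- G[as.integer(rownames(gv_s)), ] + gv_s
  G
}

## full backward pass: BCE loss on pairs with labels y (0/1), returns
## gradients for all parameters and (optionally) the input points
gcn_backward <- function(model, inputs, adj, fw, pairs, y,
                         grad_inputs = FALSE) {
  comps <- model$signature$components
  k <- length(comps)
  sc <- gcn_scores(model, fw$points, pairs)
  m <- nrow(pairs)
  eps <- 1e-12
  sbar <- pmin(pmax(sc$score, eps), 1 - eps)
  dL_dsbar <- (sbar - y) / (sbar * (1 - sbar)) / m
  grads <- vector("list", k)
  gin <- if (grad_inputs) vector("list", k) else NULL
  for (i in seq_len(k)) {
    cm <- comps[[i]]
    st <- model$stacks[[i]]
    p <- sc$per_comp[, i]
    d2 <- sc$d2[[i]]
    dL_dp <- dL_dsbar / k
    pq <- p * (1 - p)
    dL_dd2 <- dL_dp * pq * (-1 / st$t)
    g_r <- sum(dL_dp * pq / st$t)
    g_t <- sum(dL_dp * pq * (d2 - st$r) / st$t^2)
    GQ <- d2_backprop(fw$points[[i]], pairs, dL_dd2, cm)
    ## through exp0 into the last tangent layer
    HL <- fw$cache[[i]]$Hs[[model$n_layers + 1L]]
    GH <- exp0_backprop(HL, GQ, cm)
    gl <- vector("list", model$n_layers)
    for (l in rev(seq_len(model$n_layers))) {
      Z <- fw$cache[[i]]$Zs[[l]]
      GZ <- if (l < model$n_layers) GH * act_grad(cm$space_type, Z) else GH
      Hprev <- fw$cache[[i]]$Hs[[l]]
      AH <- adj %*% Hprev
      gl[[l]] <- list(W = t(AH) %*% GZ, b = colSums(GZ))
      GH <- t(adj) %*% GZ %*% t(st$layers[[l]]$W)
    }
    grads[[i]] <- list(layers = gl, r = g_r, t = g_t)
    if (grad_inputs)
      gin[[i]] <- log0_backprop(inputs[[i]], GH, cm)
  }
  loss <- -mean(y * log(sbar) + (1 - y) * log(1 - sbar))
  list(grads = grads, input_grads = gin, loss = loss, score = sc$score)
}

## ---- Riemannian Adam training ----------------------------------------

adam_init <- function(x) list(m = x * 0, v = x * 0)

adam_step <- function(state, g, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(state = state, delta = -lr * mhat / (sqrt(vhat) + eps))
}

edges_to_idx <- function(edges, nodes) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L)
  iu <- match(edges[, 1L], nodes)
  iv <- match(edges[, 2L], nodes)
  if (any(is.na(iu)) || any(is.na(iv)))
    stop("edge endpoint not among the graph nodes")
  cbind(iu, iv)
}

#' Train a product GCN on the edge prediction task with Riemannian Adam
#'
#' Binary cross-entropy on positive training edges versus uniformly
#' sampled negative (non-adjacent) pairs, resampled every epoch. Layer
#' weights and decoder parameters are Euclidean and receive standard Adam
#' moments; when `train_points = TRUE` the manifold-valued input points
#' are fine-tuned too, with tangent-space Adam moments and exponential-map
#' retraction (moments re-projected onto the new tangent space after each
#' retraction). Validation AUROC and AP are logged every epoch against a
#' fixed seed-determined negative set; with `epochs = 0` the returned
#' trace holds the metrics of the initialized model.
#'
#' @param g_train igraph with the training edges only (its adjacency
#'   drives message passing).
#' @param embedding an [mc_embedding] of the same node set; its signature
#'   defines the model architecture and its points are the initial node
#'   representations.
#' @param val_edges two-column character matrix of held-out edges.
#' @param exclude_graph igraph whose edges may never be sampled as
#'   negatives (defaults to `g_train`; pass the full graph when
#'   validation edges must be excluded too).
#' @param n_layers,lr,epochs architecture depth, Adam step size, epochs.
#' @param train_points fine-tune the input points (default TRUE).
#' @param seed integer seed (weights, negative sampling).
#' @param r_init,t_init,t_min decoder initialization and temperature floor.
#' @return an `mc_gcn_fit`: trained `model`, final input `points`,
#'   `metrics` data.frame (epoch, train loss, val AUROC/AP), `adj`,
#'   `nodes`.
#' @export
fit_product_gcn <- function(g_train, embedding, val_edges,
                            exclude_graph = g_train,
                            n_layers = 2L, lr = 0.01, epochs = 100L,
                            train_points = TRUE, seed = 1L,
                            r_init = 2, t_init = 1, t_min = 1e-3) {
  nodes <- sort(igraph::V(g_train)$name)
  if (!identical(sort(embedding$nodes), nodes))
    stop("embedding nodes do not match the graph")
  ord <- match(nodes, embedding$nodes)
  inputs <- lapply(embedding$points, function(X) X[ord, , drop = FALSE])
  sig <- embedding$signature
  comps <- sig$components
  adj <- gcn_adjacency(g_train)
  model <- product_gcn(sig, n_layers = n_layers, seed = seed,
                       r_init = r_init, t_init = t_init)
  withr::local_seed(as.integer(seed) + 7L)
  train_pos <- edges_to_idx(igraph::as_edgelist(g_train), nodes)
  val_pos <- if (length(val_edges)) edges_to_idx(val_edges, nodes) else NULL
  ## fixed negatives for validation metrics
  val_neg <- if (!is.null(val_pos))
    sample_nonedges(exclude_graph, nrow(val_pos)) else NULL
  val_neg_idx <- if (!is.null(val_neg)) edges_to_idx(val_neg, nodes) else NULL

  eval_val <- function(points) {
    if (is.null(val_pos)) return(c(auroc = NA_real_, ap = NA_real_))
    fw <- gcn_forward(model, points, adj)
    sp <- gcn_scores(model, fw$points, val_pos)$score
    sn <- gcn_scores(model, fw$points, val_neg_idx)$score
    m <- evaluate_model(sp, sn)
    c(auroc = m$auroc, ap = m$ap)
  }

  ## optimizer state
  st <- list(stacks = lapply(seq_along(comps), function(i) {
    list(layers = lapply(model$stacks[[i]]$layers, function(ly)
      list(W = adam_init(ly$W), b = adam_init(ly$b))),
      r = adam_init(0), t = adam_init(0))
  }),
  points = if (train_points) lapply(inputs, function(X)
    list(m = X * 0, v = numeric(nrow(X)))) else NULL)

  v0 <- eval_val(inputs)
  metrics <- data.frame(epoch = 0L, loss = NA_real_,
                        val_auroc = v0[["auroc"]], val_ap = v0[["ap"]])
  for (ep in seq_len(epochs)) {
    neg <- sample_nonedges(exclude_graph, nrow(train_pos))
    pairs <- rbind(train_pos, edges_to_idx(neg, nodes))
    y <- c(rep(1, nrow(train_pos)), rep(0, nrow(neg)))
    fw <- gcn_forward(model, inputs, adj)
    bk <- gcn_backward(model, inputs, adj, fw, pairs, y,
                       grad_inputs = train_points)
    if (!is.finite(bk$loss))
      stop("training diverged (non-finite loss) at epoch ", ep)
    for (i in seq_along(comps)) {
      for (l in seq_len(model$n_layers)) {
        aw <- adam_step(st$stacks[[i]]$layers[[l]]$W,
                        bk$grads[[i]]$layers[[l]]$W, lr, ep)
        st$stacks[[i]]$layers[[l]]$W <- aw$state
        model$stacks[[i]]$layers[[l]]$W <-
          model$stacks[[i]]$layers[[l]]$W + aw$delta
        ab <- adam_step(st$stacks[[i]]$layers[[l]]$b,
                        bk$grads[[i]]$layers[[l]]$b, lr, ep)
        st$stacks[[i]]$layers[[l]]$b <- ab$state
        model$stacks[[i]]$layers[[l]]$b <-
          model$stacks[[i]]$layers[[l]]$b + ab$delta
      }
      ar <- adam_step(st$stacks[[i]]$r, bk$grads[[i]]$r, lr, ep)
      st$stacks[[i]]$r <- ar$state
      model$stacks[[i]]$r <- model$stacks[[i]]$r + ar$delta
      at <- adam_step(st$stacks[[i]]$t, bk$grads[[i]]$t, lr, ep)
      st$stacks[[i]]$t <- at$state
      model$stacks[[i]]$t <- max(model$stacks[[i]]$t + at$delta, t_min)
      if (train_points) {
        ## Riemannian Adam: tangent first moment, per-point scalar second
        ## moment (EMA of the squared Riemannian gradient norm), so the
        ## update is a scalar multiple of a tangent vector and stays
        ## bounded at any basepoint
        cm <- comps[[i]]
        X <- inputs[[i]]
        gR <- project_rows(X, bk$input_grads[[i]], cm, apply_metric = TRUE)
        ps <- st$points[[i]]
        ps$m <- 0.9 * ps$m + 0.1 * gR
        ps$v <- 0.999 * ps$v + 0.001 * tangent_norm2_rows(gR, cm)
        mhat <- ps$m / (1 - 0.9^ep)
        vhat <- ps$v / (1 - 0.999^ep)
        step <- project_rows(X, -lr * mhat / (sqrt(vhat) + 1e-8), cm)
        inputs[[i]] <- exp_rows(X, step, cm)
        ## transport approximation: re-project the first moment
        ps$m <- project_rows(inputs[[i]], ps$m, cm)
        st$points[[i]] <- ps
      }
    }
    vv <- eval_val(inputs)
    metrics <- rbind(metrics,
                     data.frame(epoch = ep, loss = bk$loss,
                                val_auroc = vv[["auroc"]],
                                val_ap = vv[["ap"]]))
  }
  structure(list(model = model, points = inputs, nodes = nodes, adj = adj,
                 metrics = metrics,
                 val_auroc = metrics$val_auroc[nrow(metrics)],
                 val_ap = metrics$val_ap[nrow(metrics)]),
            class = "mc_gcn_fit")
}

#' @export
print.mc_gcn_fit <- function(x, ...) {
  cat("<mc_gcn_fit> ", format_signature(x$model$signature),
      "  val AUROC ", format(x$val_auroc, digits = 4),
      "  val AP ", format(x$val_ap, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Score node pairs with a trained product GCN
#'
#' Runs the forward pass with the fitted points and returns the averaged
#' Fermi-Dirac edge probability for each requested pair.
#'
#' @param object an `mc_gcn_fit`.
#' @param pairs two-column character matrix of node pairs.
#' @param ... unused.
#' @return numeric vector of scores in (0, 1).
#' @export
predict.mc_gcn_fit <- function(object, pairs, ...) {
  idx <- edges_to_idx(pairs, object$nodes)
  fw <- gcn_forward(object$model, object$points, object$adj)
  gcn_scores(object$model, fw$points, idx)$score
}
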