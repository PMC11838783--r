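## Distortion-minimizing product-manifold embeddings.
##
## A node embedding stores one n x ambient_dim coordinate matrix per
## signature component (rows = nodes in lexicographic order). The loss
## optimized is the relative squared-distance deviation over unordered
## node pairs,
##     L(f) = sum_{u<v} ( (d_P(f(u),f(v)) / d_G(u,v))^2 - 1 )^2,
## and embeddings are evaluated by the average relative distance distortion
##     D(f) = (1/P) sum_{u != v} |d_P - d_G| / d_G.

#' Node embedding on a product manifold
#'
#' Constructs an embedding container from per-component coordinate
#' matrices. Use [random_embedding] for a seeded random initialization.
#'
#' @param nodes character vector of node identifiers.
#' @param signature an [mc_signature].
#' @param points list of `n x ambient_dim` matrices, one per component.
#' @return an object of class `mc_embedding`.
#' @export
mc_embedding <- function(nodes, signature, points) {
  stopifnot(inherits(signature, "mc_signature"),
            length(points) == length(signature$components))
  for (i in seq_along(points)) {
    if (!is.matrix(points[[i]]) ||
        nrow(points[[i]]) != length(nodes) ||
        ncol(points[[i]]) != ambient_dim(signature$components[[i]]))
      stop("points[[", i, "]] does not conform to the signature")
  }
  structure(list(nodes = as.character(nodes), signature = signature,
                 points = points),
            class = "mc_embedding")
}

#' @rdname mc_embedding
#' @param seed integer seed for the random initialization.
#' @export
random_embedding <- function(nodes, signature, seed = 1L) {
  withr::local_seed(as.integer(seed))
  pts <- lapply(signature$components, function(cm)
    random_points(cm, length(nodes)))
  mc_embedding(nodes, signature, pts)
}

#' @export
print.mc_embedding <- function(x, ...) {
  cat("<mc_embedding> ", length(x$nodes), " nodes on ",
      format_signature(x$signature), "\n", sep = "")
  invisible(x)
}

#' Product-manifold distance matrix of an embedding
#'
#' All-pairs geodesic distances between embedded nodes; squared distances
#' sum over the signature components.
#'
#' @param embedding an [mc_embedding].
#' @return symmetric numeric matrix with node dimnames.
#' @export
embedding_distances <- function(embedding) {
  comps <- embedding$signature$components
  D2 <- 0
  for (i in seq_along(comps))
    D2 <- D2 + comp_dist_matrix(embedding$points[[i]], comps[[i]])^2
  D <- sqrt(pmax(D2, 0))
  diag(D) <- 0
  dimnames(D) <- list(embedding$nodes, embedding$nodes)
  D
}

check_pairs <- function(embedding, dG) {
  if (!all(embedding$nodes %in% rownames(dG)))
    stop("embedding and distance matrix node sets differ")
  dG <- dG[embedding$nodes, embedding$nodes, drop = FALSE]
  off <- dG[upper.tri(dG)]
  if (any(!is.finite(off)))
    stop("unreachable node pairs: restrict to a connected component first")
  dG
}

#' Relative squared-distance embedding loss
#'
#' \deqn{L(f) = \sum_{1 \le u < v \le n}
#'   \left(\left(d_{\mathcal{P}}(f(u), f(v)) / d_G(u,v)\right)^2 -
#'   1\right)^2} (default), or its absolute-value reading
#' \eqn{\sum |(d_{\mathcal{P}}/d_G)^2 - 1|} with `form = "abs"`. Zero iff
#' every pair's manifold distance matches its graph distance.
#'
#' @param embedding an [mc_embedding] covering all nodes of `dG`.
#' @param dG graph-distance matrix from [graph_distances]; all pairs must
#'   be reachable.
#' @param form `"squared"` (default) or `"abs"`.
#' @return nonnegative scalar.
#' @export
distortion_loss <- function(embedding, dG, form = c("squared", "abs")) {
  form <- match.arg(form)
  dG <- check_pairs(embedding, dG)
  dP <- embedding_distances(embedding)
  ut <- upper.tri(dG)
  q <- (dP[ut] / dG[ut])^2 - 1
  if (form == "squared") sum(q^2) else sum(abs(q))
}

#' Average graph-distance distortion
#'
#' \deqn{\mathcal{D}(f) = \frac{1}{P} \sum_{u \ne v}
#'   \frac{|d_{\mathcal{P}}(f(u), f(v)) - d_G(u, v)|}{d_G(u, v)}}
#' where `P` is the number of ordered pairs \eqn{u \ne v} (default), or
#' \eqn{|V|^2} with `denominator = "V2"`. Zero for an isometric embedding.
#'
#' @inheritParams distortion_loss
#' @param denominator `"pairs"` (ordered pairs, default) or `"V2"`.
#' @return nonnegative scalar.
#' @export
average_distortion <- function(embedding, dG, denominator = c("pairs", "V2")) {
  denominator <- match.arg(denominator)
  dG <- check_pairs(embedding, dG)
  dP <- embedding_distances(embedding)
  ut <- upper.tri(dG)
  tot <- 2 * sum(abs(dP[ut] - dG[ut]) / dG[ut])
  n <- nrow(dG)
  tot / if (denominator == "pairs") n * (n - 1) else n^2
}

## ambient gradient of the loss (sum over unordered pairs) with
## respect to every coordinate matrix; pair_mask restricts to a sampled
## minibatch, rescaled to an unbiased estimate of the full-sum gradient
embedding_gradients <- function(embedding, dG, form = "squared",
                                pair_mask = NULL) {
  comps <- embedding$signature$components
  n <- length(embedding$nodes)
  Ds <- lapply(seq_along(comps), function(i)
    comp_dist_matrix(embedding$points[[i]], comps[[i]]))
  D2 <- Reduce(`+`, lapply(Ds, function(D) D^2))
  q <- D2 / dG^2 - 1
  ## dL/d(d^2_uv) per unordered pair, spread symmetrically
  Cf <- if (form == "squared") 2 * q / dG^2 else sign(q) / dG^2
  diag(Cf) <- 0
  if (!is.null(pair_mask)) {
    Cf <- Cf * pair_mask
    Cf <- Cf * (n * (n - 1) / 2) / max(sum(pair_mask) / 2, 1)
  }
  grads <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    cm <- comps[[i]]; X <- embedding$points[[i]]; D <- Ds[[i]]
    if (cm$space_type == "euclidean") {
      grads[[i]] <- 2 * (rowSums(Cf) * X - Cf %*% X)
    } else {
      R <- sqrt(cm$curvature)
      if (cm$space_type == "spherical") {
        S <- clamp(X %*% t(X) / cm$curvature, -1, 1)
        W <- ifelse(S > 1 - 1e-12, 1, D / (R * sqrt(pmax(1 - S^2, 1e-30))))
      } else {
        G <- X %*% t(X) - 2 * outer(X[, 1L], X[, 1L])
        S <- clamp(-G / cm$curvature, lo = 1)
        W <- ifelse(S < 1 + 1e-12, 1, D / (R * sqrt(pmax(S^2 - 1, 1e-30))))
      }
      Gm <- -2 * ((Cf * W) %*% X)
      if (cm$space_type == "hyperbolic") {
        ## d(d^2)/dx = -2 w J y: flip the time-like column of the sum
        Gm[, 1L] <- -Gm[, 1L]
      }
      grads[[i]] <- Gm
    }
  }
  grads
}

## Rescale the random initialization so that the mean embedded distance
## matches the mean graph distance. Euclidean and hyperbolic components are
## scaled in tangent coordinates at the origin (both can expand without
## bound); spherical components are left as drawn (their diameter is fixed
## at pi*sqrt(C)). Skips the rescale when no scalable component exists.
calibrate_init <- function(embedding, dG) {
  comps <- embedding$signature$components
  scalable <- vapply(comps, function(cm) cm$space_type != "spherical",
                     logical(1))
  if (!any(scalable)) return(embedding)
  target <- mean(dG[upper.tri(dG)])
  for (it in 1:25) {
    dP <- embedding_distances(embedding)
    cur <- mean(dP[upper.tri(dP)])
    if (cur < .mc_zero) break
    s <- target / cur
    if (abs(s - 1) < 1e-3) break
    for (i in which(scalable))
      embedding$points[[i]] <- exp0_rows(
        s * log0_rows(embedding$points[[i]], comps[[i]]), comps[[i]])
  }
  embedding
}

#' One Riemannian gradient-descent step
#'
#' Converts ambient (Euclidean) gradients into Riemannian gradients — for
#' hyperboloid components the Minkowski metric correction is applied first,
#' then the tangent projection — scales by `-lr`, retracts along geodesics
#' with the exponential map, and renormalizes every point exactly onto its
#' constraint surface. `max_step` caps the geodesic length of each
#' per-point update (a trust region: the relative squared-distance loss is
#' quartic in the distances, and uncapped early steps diverge).
#'
#' @param embedding an [mc_embedding].
#' @param gradients list of ambient gradient matrices conforming to the
#'   embedding's coordinate matrices.
#' @param lr positive step size.
#' @param max_step cap on each point's geodesic step length (default
#'   `Inf`, no cap).
#' @return the updated [mc_embedding].
#' @export
riemannian_sgd_step <- function(embedding, gradients, lr, max_step = Inf) {
  stopifnot(lr > 0, length(gradients) == length(embedding$points))
  comps <- embedding$signature$components
  for (i in seq_along(comps)) {
    G <- gradients[[i]]
    if (any(!is.finite(G)))
      stop("non-finite gradient in component ", i, " (",
           format_component(comps[[i]]), ")")
    X <- embedding$points[[i]]
    V <- project_rows(X, G, comps[[i]], apply_metric = TRUE)
    S <- -lr * V
    if (is.finite(max_step)) {
      nr <- sqrt(rowSums(S^2))
      f <- ifelse(nr > max_step, max_step / nr, 1)
      S <- S * f
    }
    embedding$points[[i]] <- exp_rows(X, S, comps[[i]])
  }
  embedding
}

#' Embedding training configuration
#'
#' @param signature an [mc_signature] (or signature string).
#' @param learning_rate positive step size for Riemannian SGD.
#' @param epochs number of full passes.
#' @param batch_pairs number of node pairs sampled per step, or `NULL` for
#'   full-batch (all pairs; the default for pathway-scale graphs).
#' @param seed integer seed (initialization and pair sampling).
#' @param loss_form `"squared"` or `"abs"`, see [distortion_loss].
#' @param max_step geodesic trust-region cap per point and step, see
#'   [riemannian_sgd_step].
#' @return an `mc_embed_config`.
#' @export
embedding_config <- function(signature, learning_rate = 0.01, epochs = 1000L,
                             batch_pairs = NULL, seed = 1L,
                             loss_form = c("squared", "abs"),
                             max_step = 1) {
  if (is.character(signature)) signature <- parse_signature(signature)
  stopifnot(inherits(signature, "mc_signature"), learning_rate > 0,
            epochs >= 0, max_step > 0)
  structure(list(signature = signature, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_pairs = batch_pairs,
                 seed = as.integer(seed), loss_form = match.arg(loss_form),
                 max_step = max_step),
            class = "mc_embed_config")
}

#' Train a distortion-minimizing embedding
#'
#' Random-initializes one point per node on the configured product
#' manifold, then runs full-batch Riemannian gradient descent on the
#' relative squared-distance loss (pairs are sampled when `batch_pairs`
#' is set). The per-epoch loss (the sum over unordered pairs) is
#' recorded; the final embedding is scored by [average_distortion]. If the
#' loss becomes non-finite, training stops with a warning and the last
#' finite state is returned.
#'
#' @param g a connected igraph pathway graph (restrict with
#'   [largest_component_subgraph] first if needed).
#' @param config an [embedding_config].
#' @return an `mc_embed_result`: list with `embedding`, `final_loss`,
#'   `distortion`, `loss_trace`.
#' @examples
#' g <- generate_synthetic("cycle", n = 6)
#' res <- train_embedding(g, embedding_config("E2", epochs = 200, seed = 1))
#' res$distortion
#' @export
train_embedding <- function(g, config) {
  stopifnot(inherits(config, "mc_embed_config"))
  dG <- graph_distances(g)
  if (any(!is.finite(dG)))
    stop("graph is disconnected; embed the largest component")
  nodes <- rownames(dG)
  emb <- random_embedding(nodes, config$signature, seed = config$seed)
  emb <- calibrate_init(emb, dG)
  withr::local_seed(as.integer(config$seed) + 1L)
  n <- length(nodes)
  npairs_all <- n * (n - 1) / 2
  trace <- numeric(config$epochs)
  last_ok <- emb
  for (ep in seq_len(config$epochs)) {
    mask <- NULL
    if (!is.null(config$batch_pairs) && config$batch_pairs < npairs_all) {
      ut <- which(upper.tri(dG))
      pick <- sample(ut, config$batch_pairs)
      mask <- matrix(0, n, n); mask[pick] <- 1
      mask <- mask + t(mask)
    }
    gr <- embedding_gradients(emb, dG, form = config$loss_form,
                              pair_mask = mask)
    emb <- riemannian_sgd_step(emb, gr, config$learning_rate,
                               max_step = config$max_step)
    trace[ep] <- distortion_loss(emb, dG, form = config$loss_form)
    if (!is.finite(trace[ep])) {
      warning("loss diverged at epoch ", ep,
              "; returning last finite state")
      emb <- last_ok
      trace <- trace[seq_len(ep - 1L)]
      break
    }
    last_ok <- emb
  }
  final_loss <- distortion_loss(emb, dG, form = config$loss_form)
  structure(list(embedding = emb, final_loss = final_loss,
                 distortion = average_distortion(emb, dG),
                 loss_trace = trace, config = config),
            class = "mc_embed_result")
}

#' @export
print.mc_embed_result <- function(x, ...) {
  cat("<mc_embed_result> ", format_signature(x$embedding$signature),
      "  loss ", format(x$final_loss, digits = 4),
      "  distortion ", format(x$distortion, digits = 4), "\n", sep = "")
  invisible(x)
}

split_dims <- function(total, k) {
  base <- total %/% k
  rem <- total %% k
  c(rep(base + 1L, rem), rep(base, k - rem))
}

#' Enumerate the signature hyperparameter grid
#'
#' Builds every product-space signature with 0 to
#' `max_components_per_type` components per space type (at least one
#' component overall) whose manifold dimensions sum exactly to
#' `total_dim`, crossed with the learning-rate and curvature-scale
#' choices. By default the total dimension is partitioned as evenly as
#' possible across the components (1 component: 100; 2: 50+50;
#' 3: 34+33+33; ...); supplying `dim_choices` instead enumerates all
#' draws from those dimensions that hit the total, deduplicated up to
#' reordering within a space type.
#'
#' @param total_dim total manifold dimension budget (default 100).
#' @param max_components_per_type maximum components per space type.
#' @param dim_choices optional dimension choices per component.
#' @param lr_choices learning rates to cross into the grid.
#' @param curvature_choices curvature scales applied to every curved
#'   component of a configuration.
#' @param epochs,seed training settings copied into every configuration.
#' @return a list of [embedding_config] objects (empty, with a warning, if
#'   the constraints are infeasible).
#' @export
signature_grid <- function(total_dim = 100L, max_components_per_type = 3L,
                           dim_choices = NULL, lr_choices = c(0.01, 0.1),
                           curvature_choices = 1,
                           epochs = 1000L, seed = 1L) {
  counts <- expand.grid(nh = 0:max_components_per_type,
                        ns = 0:max_components_per_type,
                        ne = 0:max_components_per_type)
  counts <- counts[rowSums(counts) >= 1 & rowSums(counts) <= total_dim, ,
                   drop = FALSE]
  sig_strings <- character(0)
  sigs <- list()
  for (r in seq_len(nrow(counts))) {
    k <- sum(counts[r, ])
    dim_sets <- if (is.null(dim_choices)) {
      list(split_dims(total_dim, k))
    } else {
      dc <- as.integer(dim_choices)
      combos <- do.call(expand.grid, rep(list(dc), k))
      combos <- combos[rowSums(combos) == total_dim, , drop = FALSE]
      if (nrow(combos) == 0L) list() else
        unique(lapply(seq_len(nrow(combos)), function(i)
          as.integer(combos[i, ])))
    }
    for (dims in dim_sets) {
      ## canonical per-type order: H, S, E, dims descending within type
      types <- rep(c("hyperbolic", "spherical", "euclidean"),
                   times = c(counts$nh[r], counts$ns[r], counts$ne[r]))
      dd <- dims
      key_dims <- integer(0)
      for (tp in c("hyperbolic", "spherical", "euclidean")) {
        idx <- which(types == tp)
        if (length(idx))
          dd[idx] <- sort(dd[idx], decreasing = TRUE)
      }
      for (curv in curvature_choices) {
        comps <- mapply(function(tp, d) {
          if (tp == "euclidean") mc_component(tp, d)
          else mc_component(tp, d, curvature = curv)
        }, types, dd, SIMPLIFY = FALSE)
        sg <- mc_signature(unname(comps))
        key <- format_signature(sg)
        if (!key %in% sig_strings) {
          sig_strings <- c(sig_strings, key)
          sigs <- c(sigs, list(sg))
        }
      }
    }
  }
  if (length(sigs) == 0L) {
    warning("no feasible signatures for the given constraints")
    return(list())
  }
  ord <- order(sig_strings)
  sigs <- sigs[ord]
  out <- list()
  for (sg in sigs)
    for (lr in lr_choices)
      out <- c(out, list(embedding_config(sg, learning_rate = lr,
                                          epochs = epochs, seed = seed)))
  out
}

#' Sweep a configuration grid and select the best space
#'
#' Trains one embedding per configuration and returns the configuration of
#' strictly minimum distortion. When the minimum is attained by more than
#' one *signature* within a relative tie tolerance, the graph has no
#' unique best space and a tie is flagged (such graphs are excluded from
#' downstream comparisons).
#'
#' @param g a connected igraph pathway graph.
#' @param grid list of [embedding_config]s, e.g. from [signature_grid].
#' @param tie_tol relative distortion difference below which two
#'   signatures are considered tied.
#' @return list with `best` (the winning `mc_embed_result`, or `NULL` on a
#'   tie), `tie` (logical), and `results` (a data.frame of signature,
#'   learning rate, final loss and distortion per configuration).
#' @export
sweep_and_select <- function(g, grid, tie_tol = 1e-4) {
  stopifnot(length(grid) >= 1L)
  runs <- lapply(grid, function(cf) train_embedding(g, cf))
  df <- data.frame(
    signature = vapply(grid, function(cf) format_signature(cf$signature),
                       character(1)),
    learning_rate = vapply(grid, function(cf) cf$learning_rate, numeric(1)),
    final_loss = vapply(runs, function(r) r$final_loss, numeric(1)),
    distortion = vapply(runs, function(r) r$distortion, numeric(1)),
    stringsAsFactors = FALSE)
  if (all(!is.finite(df$distortion))) stop("all sweep runs diverged")
  ## best distortion per signature, then check uniqueness across signatures
  best_by_sig <- tapply(df$distortion, df$signature, min)
  ord <- order(best_by_sig)
  best_val <- best_by_sig[ord[1L]]
  tie <- length(best_by_sig) > 1L &&
    (best_by_sig[ord[2L]] - best_val) / max(best_val, .Machine$double.eps) <
      tie_tol
  df$tie <- tie
  ibest <- which.min(df$distortion)
  list(best = if (tie) NULL else runs[[ibest]], tie = tie, results = df,
       best_index = if (tie) NA_integer_ else ibest)
}

#' Read and write embedding TSV files
#'
#' Flat tab-separated serialization: a `# signature:` header line followed
#' by one row per node (node identifier, then the concatenated ambient
#' coordinates of all components).
#'
#' @param embedding an [mc_embedding].
#' @param path file path.
#' @return `write_embedding_tsv`: `path`, invisibly;
#'   `read_embedding_tsv`: an [mc_embedding].
#' @export
write_embedding_tsv <- function(embedding, path) {
  flat <- do.call(cbind, embedding$points)
  hdr <- paste0("# signature: ", format_signature(embedding$signature))
  rows <- vapply(seq_along(embedding$nodes), function(i)
    paste(c(embedding$nodes[i],
            formatC(flat[i, ], format = "g", digits = 17)), collapse = "\t"),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# signature:", lines[1L]))
    stop("missing '# signature:' header in ", path)
  sig <- parse_signature(sub("^# signature:\\s*", "", lines[1L]))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nodes <- vapply(body, `[`, character(1), 1L)
  coords <- t(vapply(body, function(f) as.numeric(f[-1L]),
                     numeric(length(body[[1L]]) - 1L)))
  adims <- vapply(sig$components, ambient_dim, integer(1))
  if (ncol(coords) != sum(adims))
    stop("coordinate count does not match the signature header")
  idx <- cumsum(c(0L, adims))
  pts <- lapply(seq_along(adims), function(i)
    coords[, (idx[i] + 1L):idx[i + 1L], drop = FALSE])
  mc_embedding(nodes, sig, pts)
}
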