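## Edge-prediction evaluation pipeline: edge splitting, negative
## sampling, external candidate-edge filtering, ranking metrics, and the
## four-model benchmark (three Euclidean-GCN baselines and the product
## GCN matched to the lowest-distortion signature).

#' Split graph edges into training and validation sets
#'
#' Uniform random split without replacement; the validation count is
#' `round(val_fraction * |E|)` with a minimum of one edge. Training-graph
#' connectivity is not enforced (a note is emitted when it breaks and
#' `options(mcpathway.verbose = TRUE)`).
#'
#' @param g an igraph pathway graph with at least 2 edges.
#' @param val_fraction fraction of edges held out (default 0.05).
#' @param seed integer seed.
#' @return list with `train`, `val` (two-column character matrices),
#'   `g_train` (igraph on the same vertex set, training edges only), and
#'   `seed`.
#' @export
split_edges <- function(g, val_fraction = 0.05, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  el <- igraph::as_edgelist(g)
  if (nrow(el) < 2L) stop("graph has fewer than 2 edges")
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  ord <- order(a, b)
  el <- cbind(a, b)[ord, , drop = FALSE]
  m <- nrow(el)
  n_val <- max(1L, round(val_fraction * m))
  withr::local_seed(as.integer(seed))
  iv <- sort(sample.int(m, n_val))
  val <- el[iv, , drop = FALSE]
  train <- el[-iv, , drop = FALSE]
  g_train <- igraph::delete_edges(g, igraph::get_edge_ids(g, t(val)))
  if (igraph::components(g_train)$no > igraph::components(g)$no)
    mc_msg("edge split disconnected the training graph")
  list(train = train, val = val, g_train = g_train, seed = as.integer(seed))
}

all_nonedges <- function(g, exclude = NULL) {
  nodes <- sort(igraph::V(g)$name)
  n <- length(nodes)
  iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- cbind(nodes[iu[, 1L]], nodes[iu[, 2L]])
  key <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
  el <- igraph::as_edgelist(g)
  ek <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
  drop <- key %in% ek
  if (!is.null(exclude) && length(exclude)) {
    xk <- paste(pmin(exclude[, 1L], exclude[, 2L]),
                pmax(exclude[, 1L], exclude[, 2L]), sep = "\r")
    drop <- drop | key %in% xk
  }
  pairs[!drop, , drop = FALSE]
}

#' Sample negative (non-adjacent) node pairs
#'
#' Uniform over unordered node pairs that are not edges of `g` and not in
#' `exclude`; deterministic under `seed`.
#'
#' @param g an igraph pathway graph.
#' @param count number of pairs to draw.
#' @param exclude optional two-column character matrix of additional
#'   pairs that may not be drawn.
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @return `count x 2` character matrix.
#' @export
sample_negatives <- function(g, count, exclude = NULL, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  cand <- all_nonedges(g, exclude)
  if (count > nrow(cand))
    stop("requested ", count, " negatives but only ", nrow(cand),
         " non-edges exist")
  cand[sample.int(nrow(cand), count), , drop = FALSE]
}

## internal shorthand used inside seeded training loops
sample_nonedges <- function(g, count) sample_negatives(g, count)

#' Filter an external candidate-edge table
#'
#' Keeps candidate interactions with confidence score at least
#' `min_score` (scores below 500 out of 1000 are discarded by default)
#' whose endpoints are both pathway nodes and which are not already edges
#' of the graph; the result is deduplicated and undirected. Idempotent
#' and order-independent.
#'
#' @param candidates data.frame with columns `node_a`, `node_b`, `score`
#'   (integer 0-1000).
#' @param g an igraph pathway graph.
#' @param min_score retention threshold (default 500).
#' @return two-column character matrix of test edges (possibly 0 rows).
#' @export
filter_candidate_edges <- function(candidates, g, min_score = 500L) {
  stopifnot(all(c("node_a", "node_b", "score") %in% names(candidates)))
  if (any(candidates$score < 0 | candidates$score > 1000))
    stop("candidate scores must lie in [0, 1000]")
  nodes <- igraph::V(g)$name
  keep <- candidates$score >= min_score &
    candidates$node_a %in% nodes & candidates$node_b %in% nodes &
    candidates$node_a != candidates$node_b
  tab <- candidates[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    mc_msg("candidate filter produced an empty test set")
    return(matrix(character(0), 0L, 2L))
  }
  a <- pmin(tab$node_a, tab$node_b); b <- pmax(tab$node_a, tab$node_b)
  pairs <- unique(cbind(a, b))
  el <- igraph::as_edgelist(g)
  ek <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
  pairs <- pairs[!(paste(pairs[, 1L], pairs[, 2L], sep = "\r") %in% ek), ,
                 drop = FALSE]
  ord <- order(pairs[, 1L], pairs[, 2L])
  unname(pairs[ord, , drop = FALSE])
}

#' Ranking metrics for edge prediction
#'
#' AUROC via the rank-sum formulation (ties get average rank, i.e. the
#' tie-corrected probability that a random positive outranks a random
#' negative) and average precision as the area under the
#' precision-recall step curve, thresholding at each distinct score.
#'
#' @param pos_scores,neg_scores numeric scores of positive and negative
#'   pairs; both must be non-empty.
#' @return list with `auroc` and `ap`, both in \[0, 1\].
#' @export
evaluate_model <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L)
    stop("both positive and negative scores are required")
  r <- rank(c(pos_scores, neg_scores))
  auroc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  ## average precision over descending distinct thresholds
  sc <- c(pos_scores, neg_scores)
  y <- c(rep(1L, np), rep(0L, nn))
  thr <- sort(unique(sc), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(th) sum(y == 1L & sc == th), numeric(1)))
  fp <- cumsum(vapply(thr, function(th) sum(y == 0L & sc == th), numeric(1)))
  prec <- tp / (tp + fp)
  rec <- tp / np
  ap <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, ap = ap)
}

## lift flat features into a uniform-dimension product signature with the
## paper's slicing rule (k slices of floor(total/k), remainder dropped)
sliced_gcn_embedding <- function(features, base_signature, curvature = NULL) {
  k <- length(base_signature$components)
  d <- ncol(features) %/% k
  comps <- lapply(base_signature$components, function(cm) {
    if (cm$space_type == "euclidean") mc_component("euclidean", d)
    else mc_component(cm$space_type, d,
                      curvature = curvature %||% cm$curvature)
  })
  sig <- mc_signature(comps)
  slices <- slice_embedding(features, sig)
  pts <- lapply(seq_len(k), function(i)
    lift_to_manifold(slices[[i]], sig$components[[i]]))
  mc_embedding(rownames(features), sig, pts)
}

#' Run the four-model edge-prediction benchmark
#'
#' Compares, on one pathway graph: a Euclidean GCN initialized with
#' node2vec embeddings; one initialized with graph-Laplacian eigenvector
#' embeddings (dimension `|V|`); one initialized with distortion-trained
#' Euclidean embeddings; and a product GCN whose signature matches the
#' lowest-distortion mixed-curvature embedding of the graph. Each method
#' sweeps the learning-rate grid — the product GCN additionally sweeps
#' the curvature of its non-Euclidean components, tripling its
#' configuration count — and the configuration with the highest average
#' of validation AUROC and AP is selected. External candidate edges
#' (when given) are filtered by [filter_candidate_edges] and scored as an
#' out-of-distribution test set against fresh negatives.
#'
#' @param g a connected igraph pathway graph.
#' @param candidates optional candidate-edge data.frame
#'   (see [filter_candidate_edges]).
#' @param val_fraction held-out edge fraction (default 0.05).
#' @param min_score candidate filter threshold (default 500).
#' @param dim flat embedding dimension budget (default 100).
#' @param seed integer seed for the split, sampling and training.
#' @param embed_grid signature grid for the distortion sweep (default:
#'   all single- and two-component signatures at the dimension budget).
#' @param lr_choices GCN learning-rate grid.
#' @param curvature_choices curvature grid for the product GCN (3 values
#'   by default).
#' @param embed_epochs,gcn_epochs,n_layers training lengths and depth.
#' @return an `mc_benchmark` report: data.frame with one row per method
#'   (chosen hyperparameters, validation AUROC/AP, test AUROC/AP — `NA`
#'   when no candidate edges survive filtering).
#' @export
run_benchmark <- function(g, candidates = NULL, val_fraction = 0.05,
                          min_score = 500L, dim = 100L, seed = 1L,
                          embed_grid = NULL,
                          lr_choices = c(0.01, 0.05),
                          curvature_choices = c(0.5, 1, 2),
                          embed_epochs = 500L, gcn_epochs = 80L,
                          n_layers = 2L) {
  sp <- split_edges(g, val_fraction, seed = seed)
  ## pretrained representations (full graph, as in the embedding task)
  emb_n2v <- node2vec_embed(g, dim = dim, seed = seed)
  emb_lap <- laplacian_embed(g)
  emb_euc <- euclidean_distortion_embed(g, dim = dim, epochs = embed_epochs,
                                        seed = seed)$embedding
  if (is.null(embed_grid))
    embed_grid <- signature_grid(total_dim = dim, max_components_per_type = 1L,
                                 epochs = embed_epochs, seed = seed)
  sw <- sweep_and_select(g, embed_grid)
  best <- if (sw$tie) {
    mc_msg("no unique best signature; using the minimum-distortion run")
    ibest <- which.min(sw$results$distortion)
    train_embedding(g, embed_grid[[ibest]])
  } else sw$best
  emb_mix <- best$embedding

  test_pairs <- if (!is.null(candidates))
    filter_candidate_edges(candidates, g, min_score) else
    matrix(character(0), 0L, 2L)
  test_neg <- if (nrow(test_pairs) > 0L)
    sample_negatives(g, nrow(test_pairs), exclude = test_pairs,
                     seed = seed + 101L) else NULL

  methods <- list(
    node2vec = list(features = embedding_features(emb_n2v), product = FALSE),
    laplacian = list(features = embedding_features(emb_lap), product = FALSE),
    euclidean = list(features = embedding_features(emb_euc), product = FALSE),
    product = list(features = embedding_features(emb_mix), product = TRUE,
                   signature = emb_mix$signature))

  rows <- list()
  for (nm in names(methods)) {
    mt <- methods[[nm]]
    configs <- if (mt$product)
      expand.grid(lr = lr_choices, curvature = curvature_choices)
    else expand.grid(lr = lr_choices, curvature = NA_real_)
    fits <- vector("list", nrow(configs))
    score_cfg <- numeric(nrow(configs))
    for (ci in seq_len(nrow(configs))) {
      init <- if (mt$product)
        sliced_gcn_embedding(mt$features, mt$signature,
                             curvature = configs$curvature[ci])
      else euclidean_embedding(mt$features)
      fit <- fit_product_gcn(sp$g_train, init, sp$val,
                             exclude_graph = g,
                             n_layers = n_layers, lr = configs$lr[ci],
                             epochs = gcn_epochs, seed = seed)
      fits[[ci]] <- fit
      score_cfg[ci] <- (fit$val_auroc + fit$val_ap) / 2
    }
    ci <- which.max(score_cfg)
    fit <- fits[[ci]]
    if (nrow(test_pairs) > 0L) {
      ts <- evaluate_model(predict(fit, test_pairs), predict(fit, test_neg))
      t_auroc <- ts$auroc; t_ap <- ts$ap
    } else {
      t_auroc <- NA_real_; t_ap <- NA_real_
    }
    rows[[nm]] <- data.frame(
      method = nm, lr = configs$lr[ci], curvature = configs$curvature[ci],
      signature = if (mt$product)
        format_signature(fit$model$signature) else paste0("E", ncol(mt$features)),
      val_auroc = fit$val_auroc, val_ap = fit$val_ap,
      test_auroc = t_auroc, test_ap = t_ap,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, best_embedding = emb_mix,
                 sweep = sw$results, tie = sw$tie, split = sp),
            class = "mc_benchmark")
}

#' @export
print.mc_benchmark <- function(x, ...) {
  cat("<mc_benchmark>\n")
  print(x$report, digits = 3)
  invisible(x)
}
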