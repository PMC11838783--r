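## Desk-scale fixtures: pathway-like graphs paired with candidate-edge
## tables that emulate an external interaction database (withheld true
## edges at high confidence plus score-spanning distractors), so the
## whole pipeline is exercisable without any downloads.

#' Fixture specification
#'
#' @param kind a [generate_synthetic] generator name.
#' @param params named list of generator parameters.
#' @param planted_holdout fraction of edges withheld from the graph and
#'   planted into the candidate table as high-confidence "missing" edges
#'   (in \[0, 0.5\]).
#' @param n_distractors number of non-edge distractor rows.
#' @param seed integer seed.
#' @return an `mc_fixture_spec`.
#' @export
fixture_spec <- function(kind, params = list(), planted_holdout = 0.1,
                         n_distractors = 40L, seed = 1L) {
  stopifnot(planted_holdout >= 0, planted_holdout <= 0.5,
            n_distractors >= 0)
  structure(list(kind = kind, params = params,
                 planted_holdout = planted_holdout,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "mc_fixture_spec")
}

#' Build a graph + candidate-table fixture
#'
#' Generates the graph, withholds `planted_holdout` of its edges as
#' ground-truth "missing" interactions (they enter the candidate table
#' with confidence scores of at least 800 and leave the graph), and adds
#' distractor non-edges with scores uniform over 0-1000 so the
#' candidate-score filter is exercised on both sides of its threshold.
#' Byte-identical outputs under one seed.
#'
#' @param spec an [fixture_spec].
#' @return list with `graph` (igraph), `candidates` (data.frame
#'   `node_a`, `node_b`, `score`), and `withheld` (two-column character
#'   matrix of the planted true edges).
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "mc_fixture_spec"))
  g <- do.call(generate_synthetic,
               c(list(kind = spec$kind), spec$params, list(seed = spec$seed)))
  withr::local_seed(spec$seed + 1000L)
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  ord <- order(a, b)
  el <- cbind(a, b)[ord, , drop = FALSE]
  n_hold <- floor(spec$planted_holdout * nrow(el))
  withheld <- el[sort(sample.int(nrow(el), n_hold)), , drop = FALSE]
  g_obs <- igraph::delete_edges(g, igraph::get_edge_ids(g, t(withheld)))
  rows <- list()
  if (n_hold > 0L)
    rows$true <- data.frame(node_a = withheld[, 1L], node_b = withheld[, 2L],
                            score = sample(800:1000, n_hold, replace = TRUE),
                            stringsAsFactors = FALSE)
  if (spec$n_distractors > 0L) {
    neg <- sample_negatives(g, spec$n_distractors, exclude = withheld)
    rows$distract <- data.frame(node_a = neg[, 1L], node_b = neg[, 2L],
                                score = sample(0:1000, spec$n_distractors,
                                               replace = TRUE),
                                stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, rows)
  rownames(cand) <- NULL
  list(graph = g_obs, candidates = cand, withheld = withheld)
}

#' Write fixture files
#'
#' Serializes a fixture as an edge list and a tab-separated candidate
#' table (`node_a`, `node_b`, `score`) under `dir`.
#'
#' @param fixture output of [make_fixture].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, prefix = "fixture") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, paste0(prefix, "_edges.tsv"))
  cp <- file.path(dir, paste0(prefix, "_candidates.tsv"))
  write_pathway_edgelist(fixture$graph, gp)
  utils::write.table(fixture$candidates, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gp, cp))
}

#' Graphs with known best-fitting geometry
#'
#' A labeled suite operationalizing the premise that graph topology
#' determines the best embedding space: balanced trees favor hyperbolic
#' components, cycles favor spherical ones, 2-D grids are
#' Euclidean-competitive, and a tree of cycles favors a mixed signature.
#' All graphs are pathway-scale (10-300 nodes).
#'
#' @return list of entries, each with `name`, `graph`, and
#'   `expected_space` (one of `"hyperbolic"`, `"spherical"`,
#'   `"euclidean"`, `"mixed"`).
#' @export
geometry_suite <- function() {
  list(
    list(name = "balanced_tree",
         graph = generate_synthetic("balanced_tree", branching = 2,
                                    depth = 4),
         expected_space = "hyperbolic"),
    list(name = "cycle",
         graph = generate_synthetic("cycle", n = 20),
         expected_space = "spherical"),
    list(name = "grid",
         graph = generate_synthetic("grid", rows = 4, cols = 5),
         expected_space = "euclidean"),
    list(name = "tree_of_cycles",
         graph = generate_synthetic("tree_of_cycles", branching = 2,
                                    depth = 2, cycle_size = 5),
         expected_space = "mixed"))
}
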