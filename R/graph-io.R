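## Pathway graphs are undirected igraph objects with character vertex
## names, no self-loops, no multi-edges, vertices ordered lexicographically
## (fixed before any seeded operation, for reproducibility).

as_pathway_graph <- function(edges_df, all_nodes = NULL) {
  a <- as.character(edges_df[[1L]])
  b <- as.character(edges_df[[2L]])
  self <- a == b
  n_self <- sum(self)
  if (n_self > 0) {
    mc_msg(n_self, " self-loop(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  nodes <- sort(unique(c(a, b, all_nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

mc_msg <- function(...) {
  if (isTRUE(getOption("mcpathway.verbose", FALSE))) message("mcpathway: ", ...)
}

#' Read a pathway graph from text
#'
#' Supports plain edge lists (two whitespace-separated node identifiers per
#' line) and Pathway Commons-style interaction text (three tab-separated
#' columns: participant A, interaction type, participant B; a header line
#' is tolerated). Interaction types are ignored and every edge is treated
#' as undirected; duplicate and reversed edges collapse to one, and
#' self-loops are dropped (count reported when
#' `options(mcpathway.verbose = TRUE)`).
#'
#' @param path file to read.
#' @param format `"edgelist"` or `"pathway_commons_txt"`.
#' @return an undirected, simplified `igraph` object with lexicographically
#'   ordered vertices.
#' @export
read_pathway_graph <- function(path, format = c("edgelist", "pathway_commons_txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (format == "pathway_commons_txt" && length(lines) > 0) {
    first <- tolower(lines[1L])
    if (grepl("participant", first) || grepl("interaction", first)) {
      lines <- lines[-1L]; lineno <- lineno[-1L]
    }
  }
  if (length(lines) == 0L) stop("no edges in file: ", path)
  pairs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (format == "edgelist") {
      if (length(f) != 2L)
        stop("malformed edge list line ", lineno[i], ": expected 2 fields, got ",
             length(f))
      f
    } else {
      if (length(f) != 3L)
        stop("malformed interaction line ", lineno[i],
             ": expected 3 fields, got ", length(f))
      f[c(1L, 3L)]  # interaction type in column 2 is ignored
    }
  })
  df <- data.frame(a = vapply(pairs, `[`, character(1), 1L),
                   b = vapply(pairs, `[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  as_pathway_graph(df)
}

#' Write a pathway graph as an edge list
#'
#' One edge per line, two tab-separated identifiers, endpoints and lines in
#' canonical (lexicographic) order, so that write followed by
#' [read_pathway_graph] round-trips exactly.
#'
#' @param g an igraph pathway graph.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pathway_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  ord <- order(a, b)
  writeLines(paste(a[ord], b[ord], sep = "\t"), path)
  invisible(path)
}

#' All-pairs shortest-path distances
#'
#' Breadth-first (unweighted) shortest-path lengths between all vertex
#' pairs, as an integer-valued symmetric matrix with vertex-name dimnames.
#' Unreachable pairs are `Inf`.
#'
#' @param g an igraph pathway graph.
#' @return numeric matrix of graph distances.
#' @export
graph_distances <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  D <- igraph::distances(g, algorithm = "unweighted")
  D[order(rownames(D)), order(colnames(D)), drop = FALSE]
}

#' Restrict to the largest connected component
#'
#' Graph distances (and hence distortion) are undefined for unreachable
#' pairs, so embedding always operates on the largest connected component;
#' a note is emitted when vertices are dropped.
#'
#' @param g an igraph pathway graph.
#' @return induced subgraph on the largest component.
#' @export
largest_component_subgraph <- function(g) {
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(g)
  keep <- which(comp$membership == which.max(comp$csize))
  mc_msg(igraph::vcount(g) - length(keep),
         " vertex(es) outside the largest component dropped")
  igraph::induced_subgraph(g, keep)
}

relabel <- function(g) {
  ## zero-padded names give lexicographic == numeric vertex order
  n <- igraph::vcount(g)
  w <- max(3L, nchar(as.character(n)))
  igraph::set_vertex_attr(g, "name",
    value = sprintf(paste0("n%0", w, "d"), seq_len(n)))
}

#' Generate synthetic pathway-scale graphs
#'
#' Deterministic-under-seed generators for graphs with known geometric
#' character at the scale of curated pathways (tens to hundreds of nodes):
#' \describe{
#'   \item{balanced_tree}{`branching`, `depth`: complete b-ary tree
#'     (hyperbolic-friendly).}
#'   \item{cycle}{`n`: ring graph (spherical-friendly).}
#'   \item{path}{`n`: path graph.}
#'   \item{grid}{`rows`, `cols`: 2-D lattice (Euclidean-friendly).}
#'   \item{tree_of_cycles}{`branching`, `depth`, `cycle_size`: balanced tree
#'     whose every node is expanded into a cycle (mixed geometry).}
#'   \item{erdos_renyi}{`n`, `p`: G(n, p) random graph.}
#'   \item{planted_partition}{`n`, `blocks`, `p_in`, `p_out`: stochastic
#'     block model with assortative communities.}
#' }
#'
#' @param kind generator name.
#' @param ... kind-specific parameters, see Details.
#' @param seed integer seed for the random generators.
#' @return an undirected igraph with canonical `n###` vertex names.
#' @examples
#' g <- generate_synthetic("balanced_tree", branching = 2, depth = 4)
#' igraph::vcount(g)  # 31
#' @export
generate_synthetic <- function(kind = c("balanced_tree", "cycle", "grid",
                                        "tree_of_cycles", "erdos_renyi",
                                        "planted_partition", "path"),
                               ..., seed = 1L) {
  kind <- match.arg(kind)
  p <- list(...)
  withr::local_seed(as.integer(seed))
  g <- switch(kind,
    balanced_tree = {
      b <- p$branching %||% 2L; d <- p$depth %||% 4L
      stopifnot(b >= 2L, d >= 1L)
      n <- sum(b^(0:d))
      igraph::make_tree(n, children = b, mode = "undirected")
    },
    cycle = {
      n <- p$n %||% 20L
      stopifnot(n >= 3L)
      igraph::make_ring(n)
    },
    path = {
      n <- p$n %||% 10L
      stopifnot(n >= 2L)
      igraph::make_ring(n, circular = FALSE)
    },
    grid = {
      r <- p$rows %||% 4L; cl <- p$cols %||% 5L
      stopifnot(r >= 2L, cl >= 2L)
      igraph::make_lattice(c(r, cl))
    },
    tree_of_cycles = {
      b <- p$branching %||% 2L; d <- p$depth %||% 2L
      cs <- p$cycle_size %||% 5L
      stopifnot(cs >= 3L)
      nt <- sum(b^(0:d))
      tr <- igraph::make_tree(nt, children = b, mode = "undirected")
      ## expand every tree node into a cycle; tree edges join the first
      ## vertices of the two cycles
      gl <- lapply(seq_len(nt), function(i) igraph::make_ring(cs))
      g2 <- Reduce(igraph::disjoint_union, gl)
      te <- igraph::as_edgelist(tr, names = FALSE)
      extra <- t(apply(te, 1L, function(e) (e - 1L) * cs + 1L))
      igraph::add_edges(g2, as.vector(t(extra)))
    },
    erdos_renyi = {
      n <- p$n %||% 60L; pr <- p$p %||% 0.08
      igraph::sample_gnp(n, pr)
    },
    planted_partition = {
      n <- p$n %||% 60L; k <- p$blocks %||% 2L
      p_in <- p$p_in %||% 0.3; p_out <- p$p_out %||% 0.02
      sizes <- rep(n %/% k, k); sizes[1L] <- sizes[1L] + n %% k
      pm <- matrix(p_out, k, k); diag(pm) <- p_in
      igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
    })
  relabel(igraph::simplify(g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
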