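#' Network filtering configuration
#'
#' Thresholds controlling interactome construction and DEG clustering: the
#' strict lower bound on the interaction confidence score, the minimum
#' connected-component size retained in the network, and the minimum size
#' for a DEG community to count as a cluster.
#'
#' @param score_min Integer; edges are kept only when their confidence score
#'   is strictly greater than this value. Default 150.
#' @param min_component_size Integer; connected components with fewer nodes
#'   are removed. Default 5.
#' @param min_cluster_size Integer; Louvain communities with fewer members
#'   are dissolved into isolated DEGs. Default 3.
#' @return A list of class `network_config`.
#' @export
network_config <- function(score_min = 150L, min_component_size = 5L,
                           min_cluster_size = 3L) {
  stopifnot(score_min >= 0, min_component_size >= 1, min_cluster_size >= 1)
  structure(list(score_min = as.integer(score_min),
                 min_component_size = as.integer(min_component_size),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "network_config")
}

#' Load protein-level interactions and translate them to gene pairs
#'
#' Reads a STRING-style links table (two protein columns plus a confidence
#' score in 0--1000) and an identifier mapping, emits gene-level edges.
#' Protein pairs whose members map to the same gene become self-loops and
#' are dropped; duplicate gene pairs are collapsed keeping the maximum
#' score; proteins absent from the mapping are dropped with a message.
#' Many-to-many protein-to-gene mappings contribute all gene-pair cross
#' products before deduplication.
#'
#' @param path Path to a whitespace- or tab-delimited links file with a
#'   header naming the two protein columns (`protein1`, `protein2`, or
#'   `protein_a`/`protein_b`) and a score column (`experimental`,
#'   `combined_score`, or `score`).
#' @param id_map Data frame with columns `protein_id`, `gene_id` (and
#'   optionally `symbol`, `biotype`).
#' @return Data frame with columns `gene_a`, `gene_b`, `score`, one row per
#'   unordered gene pair.
#' @export
load_edges <- function(path, id_map) {
  df <- read_tsv_checked(path, what = "links file")
  p1 <- intersect(c("protein1", "protein_a"), names(df))[1]
  p2 <- intersect(c("protein2", "protein_b"), names(df))[1]
  sc <- intersect(c("experimental", "combined_score", "score"), names(df))[1]
  if (is.na(p1) || is.na(p2) || is.na(sc)) {
    stop("format error: links file must name two protein columns and a score column",
         call. = FALSE)
  }
  edges_from_proteins(df[[p1]], df[[p2]], df[[sc]], id_map)
}

#' Translate protein-level interactions to gene-level edges
#'
#' In-memory counterpart of [load_edges()]: maps two protein-identifier
#' vectors to gene pairs, drops self-loops, and collapses duplicate gene
#' pairs keeping the maximum score.
#'
#' @param pa,pb Character vectors of interacting protein identifiers.
#' @param score Integer confidence scores in \[0, 1000\].
#' @param id_map Data frame with columns `protein_id`, `gene_id`.
#' @return Data frame with columns `gene_a`, `gene_b`, `score`.
#' @export
edges_from_proteins <- function(pa, pb, score, id_map) {
  stopifnot(all(c("protein_id", "gene_id") %in% names(id_map)))
  if (any(score < 0 | score > 1000, na.rm = TRUE)) {
    stop("confidence scores must lie in [0, 1000]", call. = FALSE)
  }
  # many-to-many: expand each endpoint to all its genes, then cross
  idx_a <- split(id_map$gene_id, id_map$protein_id)[pa]
  idx_b <- split(id_map$gene_id, id_map$protein_id)[pb]
  unmapped <- sum(vapply(idx_a, is.null, logical(1)) |
                    vapply(idx_b, is.null, logical(1)))
  if (unmapped > 0L) {
    message(sprintf("load_edges: dropped %d row(s) with unmapped protein(s)",
                    unmapped))
  }
  keep <- !vapply(idx_a, is.null, logical(1)) &
    !vapply(idx_b, is.null, logical(1))
  idx_a <- idx_a[keep]; idx_b <- idx_b[keep]; score <- score[keep]
  if (length(score) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = integer()))
  }
  na <- lengths(idx_a); nb <- lengths(idx_b)
  rep_row <- rep.int(seq_along(score), na * nb)
  ga <- unlist(mapply(function(a, b) rep(a, each = length(b)),
                      idx_a, idx_b, SIMPLIFY = FALSE), use.names = FALSE)
  gb <- unlist(mapply(function(a, b) rep(b, times = length(a)),
                      idx_a, idx_b, SIMPLIFY = FALSE), use.names = FALSE)
  sc <- score[rep_row]
  self <- ga == gb
  ga <- ga[!self]; gb <- gb[!self]; sc <- sc[!self]
  # canonical unordered orientation, dedup keeping max score
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  key <- paste(lo, hi, sep = "\r")
  best <- tapply(sc, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                    gene_b = vapply(parts, `[`, "", 2L),
                    score = as.vector(best),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter edges by confidence score
#'
#' Retains only interactions whose confidence score is strictly greater
#' than `score_min` ("above" the threshold).
#'
#' @param edges Data frame with a `score` column.
#' @param score_min Nonnegative integer threshold (default 150).
#' @return The filtered data frame.
#' @export
filter_confidence <- function(edges, score_min = 150L) {
  stopifnot(score_min >= 0)
  out <- edges[edges$score > score_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a gene-level interactome
#'
#' Assembles the undirected simple graph all downstream stages consume.
#' Nodes are ordered lexicographically by gene identifier so matrix views
#' are deterministic.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `score`.
#' @param node_info Optional data frame with columns `gene_id` and any of
#'   `symbol`, `biotype`; genes not listed default to symbol = gene_id and
#'   biotype = "other".
#' @return An object of class `interactome`: a list with the `igraph`
#'   graph, a node table and the edge table.
#' @export
build_interactome <- function(edges, node_info = NULL) {
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- data.frame(gene_id = genes, symbol = genes,
                      biotype = "other", stringsAsFactors = FALSE)
  if (!is.null(node_info)) {
    m <- match(nodes$gene_id, node_info$gene_id)
    if ("symbol" %in% names(node_info)) {
      hit <- !is.na(m) & !is.na(node_info$symbol[m])
      nodes$symbol[hit] <- node_info$symbol[m[hit]]
    }
    if ("biotype" %in% names(node_info)) {
      hit <- !is.na(m) & !is.na(node_info$biotype[m])
      nodes$biotype[hit] <- node_info$biotype[m[hit]]
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "score")],
    directed = FALSE,
    vertices = nodes$gene_id
  )
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  comp <- igraph::components(x$graph)
  cat(sprintf("interactome: %d genes, %d interactions, %d component(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), comp$no))
  invisible(x)
}

#' Gene identifiers of an interactome
#' @param net An `interactome`.
#' @return Character vector of node gene ids in lexicographic order.
#' @export
interactome_genes <- function(net) {
  sort(igraph::V(net$graph)$name)
}

# rebuild the classed object from an igraph subgraph, keeping node metadata
interactome_from_graph <- function(g, nodes) {
  keep <- nodes[nodes$gene_id %in% igraph::V(g)$name, , drop = FALSE]
  keep <- keep[order(keep$gene_id), , drop = FALSE]
  rownames(keep) <- NULL
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed) > 0L) {
    lo <- pmin(ed$from, ed$to); hi <- pmax(ed$from, ed$to)
    ed <- data.frame(gene_a = lo, gene_b = hi,
                     score = if ("score" %in% names(ed)) ed$score else NA_integer_,
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(gene_a = character(), gene_b = character(),
                     score = integer())
  }
  structure(list(graph = g, nodes = keep, edges = ed), class = "interactome")
}

#' Restrict an interactome to expressed genes
#'
#' Induces the subgraph on the union of genes found expressed in at least
#' one dataset.
#'
#' @param net An `interactome`.
#' @param expressed Character vector of expressed gene ids (union across
#'   datasets).
#' @return The induced `interactome`.
#' @export
restrict_to_expressed <- function(net, expressed) {
  stopifnot(length(expressed) > 0L)
  keep <- intersect(igraph::V(net$graph)$name, expressed)
  if (length(keep) == 0L) {
    stop("no network gene is in the expressed set: empty network", call. = FALSE)
  }
  g <- igraph::induced_subgraph(net$graph, keep)
  interactome_from_graph(g, net$nodes)
}

#' Remove small connected components
#'
#' Drops every node belonging to a connected component with fewer than
#' `min_component_size` nodes. Idempotent.
#'
#' @param net An `interactome`.
#' @param min_component_size Integer minimum component size (default 5).
#' @return The filtered `interactome`.
#' @export
filter_components <- function(net, min_component_size = 5L) {
  comp <- igraph::components(net$graph)
  small <- which(comp$csize < min_component_size)
  drop <- igraph::V(net$graph)$name[comp$membership %in% small]
  if (length(drop) > 0L) {
    message(sprintf("filter_components: removed %d node(s) in %d small component(s)",
                    length(drop), length(small)))
  }
  g <- igraph::delete_vertices(net$graph, drop)
  interactome_from_graph(g, net$nodes)
}

#' Degree-normalized adjacency matrix
#'
#' Computes the normalized adjacency of the unweighted (binarized) graph
#' over the lexicographic node ordering. The symmetric normalization
#' `D^(-1/2) A D^(-1/2)` is the default; the row-stochastic alternative
#' `D^(-1) A` is available via `mode = "row"`.
#'
#' @param net An `interactome`.
#' @param mode `"symmetric"` (default) or `"row"`.
#' @return A dense numeric matrix with genes as dimnames.
#' @export
normalized_adjacency <- function(net, mode = c("symmetric", "row")) {
  mode <- match.arg(mode)
  if (igraph::vcount(net$graph) == 0L) {
    stop("empty network", call. = FALSE)
  }
  ord <- interactome_genes(net)
  A <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  A <- (A[ord, ord, drop = FALSE] > 0) * 1.0
  d <- rowSums(A)
  if (any(d == 0)) {
    stop(sprintf("degenerate node(s) with zero degree: %s",
                 paste(ord[d == 0], collapse = ", ")), call. = FALSE)
  }
  if (mode == "symmetric") {
    s <- 1 / sqrt(d)
    out <- A * tcrossprod(s)
  } else {
    out <- A / d
  }
  dimnames(out) <- list(ord, ord)
  out
}

#' Export interactome node and edge tables
#'
#' Writes the node table (gene, symbol, biotype, degree, component id) and
#' the edge table (gene pair with confidence score) as TSV.
#'
#' @param net An `interactome`.
#' @param node_path,edge_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_interactome <- function(net, node_path, edge_path) {
  ord <- interactome_genes(net)
  comp <- igraph::components(net$graph)
  deg <- igraph::degree(net$graph)
  nd <- net$nodes
  m <- match(nd$gene_id, igraph::V(net$graph)$name)
  nd$degree <- as.integer(deg[m])
  nd$component_id <- as.integer(comp$membership[m])
  write_tsv(nd[order(nd$gene_id), ], node_path)
  write_tsv(net$edges, edge_path)
  invisible(c(node_path, edge_path))
}
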