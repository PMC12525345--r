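# Shared fixtures, all built in code.

# interactome from a plain edge list (default score 500, above threshold)
net_from_pairs <- function(a, b, score = 500L, node_info = NULL) {
  ed <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                   score = score, stringsAsFactors = FALSE)
  build_interactome(ed, node_info)
}

# path graph g1 - g2 - ... - gn
path_net <- function(n, prefix = "g") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  net_from_pairs(ids[-n], ids[-1])
}

# two disjoint cliques of the given sizes
two_cliques_net <- function(n1, n2) {
  ids1 <- sprintf("a%02d", seq_len(n1))
  ids2 <- sprintf("b%02d", seq_len(n2))
  pairs <- function(ids) t(utils::combn(ids, 2))
  p1 <- pairs(ids1); p2 <- pairs(ids2)
  net_from_pairs(c(p1[, 1], p2[, 1]), c(p1[, 2], p2[, 2]))
}

# random graph interactome + membership for oracle checks
random_net <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  ids <- sprintf("g%03d", seq_len(n))
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) stop("fixture graph has no edges")
  net_from_pairs(ids[el[, 1]], ids[el[, 2]])
}

# independent connected-component labelling by breadth-first search over an
# edge data frame (the traversal oracle; no igraph)
bfs_components <- function(genes, edges) {
  adj <- split(c(edges$gene_b, edges$gene_a),
               c(edges$gene_a, edges$gene_b))
  label <- setNames(rep(NA_integer_, length(genes)), genes)
  cur <- 0L
  for (g in genes) {
    if (!is.na(label[g])) next
    cur <- cur + 1L
    queue <- g
    label[g] <- cur
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(label[w])) {
          label[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  label
}

# small embedding configuration to keep unit tests fast
fast_embed_cfg <- function(dimensions = 32L, seed = 1L) {
  embedding_config(dimensions = dimensions, walk_length = 40L,
                   num_walks = 5L, window = 5L, seed = seed)
}

# cached small synthetic bundle shared across tests in one run
small_sim_cfg <- function(seed = 11L) {
  simulation_config(n_genes = 200L, p_in = 0.25, p_out = 0.015,
                    n_deg_near = 8L, n_deg_far = 8L, n_udeg = 12L,
                    n_silent = 10L, seed = seed)
}
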