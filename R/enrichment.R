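#' Read a GMT annotation catalog
#'
#' Standard GMT: one term per line, tab-separated `term_id`, description,
#' then member genes.
#'
#' @param path GMT file path.
#' @param hierarchy Optional data frame of (`parent`, `child`) term pairs,
#'   e.g. from [read_hierarchy()].
#' @return List of class `annotation_catalog` with `terms` (named list of
#'   gene vectors), `names` (term descriptions) and `hierarchy`.
#' @export
read_gmt <- function(path, hierarchy = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  descs <- vapply(parts, `[`, "", 2L)
  genes <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (any(lengths(genes) == 0L)) {
    stop("format error: GMT term(s) with empty gene set", call. = FALSE)
  }
  annotation_catalog(setNames(genes, ids), setNames(descs, ids), hierarchy)
}

#' Construct an annotation catalog
#'
#' @param terms Named list: term id to character vector of genes.
#' @param names Optional named character vector of term descriptions.
#' @param hierarchy Optional data frame (`parent`, `child`); must be
#'   acyclic.
#' @return An `annotation_catalog`.
#' @export
annotation_catalog <- function(terms, names = NULL, hierarchy = NULL) {
  stopifnot(all(lengths(terms) > 0L))
  if (!is.null(hierarchy)) {
    stopifnot(all(c("parent", "child") %in% base::names(hierarchy)))
    check_acyclic(hierarchy)
  }
  structure(list(terms = terms,
                 names = names %||% setNames(base::names(terms),
                                             base::names(terms)),
                 hierarchy = hierarchy),
            class = "annotation_catalog")
}

#' Read a term hierarchy table
#'
#' @param path TSV with columns `parent`, `child` (term ids).
#' @return Data frame.
#' @export
read_hierarchy <- function(path) {
  read_tsv_checked(path, required = c("parent", "child"),
                   what = "hierarchy table")
}

check_acyclic <- function(hierarchy) {
  g <- igraph::graph_from_data_frame(hierarchy[, c("parent", "child")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) stop("cyclic term hierarchy", call. = FALSE)
  invisible(TRUE)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and an annotation term within a gene universe:
#' `P(X >= k)` with population `N = |universe|`, successes
#' `K = |term within universe|`, draws `n = |query|`. Term genes are
#' intersected with the universe first.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param term_genes Character vector of the term's genes.
#' @param universe Character vector; the gene universe.
#' @return One-row data frame `k`, `K`, `n`, `N`, `pvalue`,
#'   `overlap_genes` (comma-separated).
#' @export
ora_test <- function(query, term_genes, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- intersect(unique(query), universe)
  term <- intersect(unique(term_genes), universe)
  overlap <- intersect(query, term)
  k <- length(overlap); K <- length(term)
  n <- length(query); N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, K = K, n = n, N = N, pvalue = p,
             overlap_genes = paste(sort(overlap), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; input order is preserved.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of DEG clusters
#'
#' Tests every catalog term against every cluster's gene list with the
#' hypergeometric test, adjusting p-values within each cluster's term
#' family by BH. The universe should be the dataset's network-mapped
#' expressed genes (the space in which clusters were formed).
#'
#' @param clusters A `cluster_set` or named list of gene vectors.
#' @param catalog An `annotation_catalog`.
#' @param universe Character vector; the gene universe.
#' @param padj_threshold Significance threshold on BH-adjusted p-values
#'   (default 0.05).
#' @return Data frame with one row per (cluster, term):
#'   `cluster_id`, `term_id`, `term_name`, `k`, `K`, `n`, `N`, `pvalue`,
#'   `padj`, `significant`, `overlap_genes`.
#' @export
enrich_clusters <- function(clusters, catalog, universe,
                            padj_threshold = 0.05) {
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  out <- lapply(names(cl), function(id) {
    res <- do.call(rbind, lapply(names(catalog$terms), function(tid) {
      r <- ora_test(cl[[id]], catalog$terms[[tid]], universe)
      cbind(data.frame(cluster_id = id, term_id = tid,
                       term_name = unname(catalog$names[tid]),
                       stringsAsFactors = FALSE), r)
    }))
    res$padj <- bh_adjust(res$pvalue)
    res$significant <- res$padj < padj_threshold
    res[order(res$padj, res$pvalue, res$term_id), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# terms that are ancestors of other retained terms, via transitive closure
ancestors_of <- function(terms, hierarchy) {
  if (is.null(hierarchy) || nrow(hierarchy) == 0L) return(character(0))
  g <- igraph::graph_from_data_frame(hierarchy[, c("parent", "child")],
                                     directed = TRUE)
  present <- intersect(terms, igraph::V(g)$name)
  drop <- character(0)
  for (t in present) {
    desc <- igraph::subcomponent(g, t, mode = "out")$name
    if (length(intersect(setdiff(desc, t), terms)) > 0L) {
      drop <- c(drop, t)
    }
  }
  drop
}

#' Cross-dataset comparative enrichment network
#'
#' Builds the term network summarizing significant enrichment results
#' across datasets. When both an ancestor and one of its descendants are
#' significant, only the descendant is retained (pruning applies along the
#' full transitive closure of the hierarchy). Nodes carry the datasets in
#' which the term is significant; an edge joins two terms sharing at least
#' one DEG across the contributing datasets, weighted by the shared-DEG
#' count.
#'
#' @param per_dataset_results Named list (dataset -> data frame as from
#'   [enrich_clusters()] or any table with `term_id`, `pvalue`,
#'   `overlap_genes`).
#' @param hierarchy Data frame (`parent`, `child`), or NULL.
#' @param p_threshold Unadjusted p-value threshold for inclusion
#'   (default 0.05).
#' @return List of class `comparative_network` with `nodes`
#'   (`term_id`, `datasets`) and `edges` (`term_a`, `term_b`, `weight`).
#' @export
comparative_network <- function(per_dataset_results, hierarchy = NULL,
                                p_threshold = 0.05) {
  if (!is.null(hierarchy)) check_acyclic(hierarchy)
  term_genes <- list()
  term_datasets <- list()
  for (ds in names(per_dataset_results)) {
    res <- per_dataset_results[[ds]]
    sig <- res[res$pvalue < p_threshold & res$k > 0, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      tid <- sig$term_id[i]
      genes <- strsplit(sig$overlap_genes[i], ",", fixed = TRUE)[[1]]
      term_genes[[tid]] <- union(term_genes[[tid]] %||% character(0), genes)
      term_datasets[[tid]] <- union(term_datasets[[tid]] %||% character(0), ds)
    }
  }
  terms <- sort(names(term_genes))
  terms <- setdiff(terms, ancestors_of(terms, hierarchy))
  nodes <- data.frame(
    term_id = terms,
    datasets = vapply(terms,
                      function(t) paste(sort(term_datasets[[t]]),
                                        collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  ea <- character(0); eb <- character(0); ew <- integer(0)
  if (length(terms) > 1L) {
    for (i in seq_len(length(terms) - 1L)) {
      for (j in seq((i + 1L), length(terms))) {
        shared <- length(intersect(term_genes[[terms[i]]],
                                   term_genes[[terms[j]]]))
        if (shared >= 1L) {
          ea <- c(ea, terms[i]); eb <- c(eb, terms[j])
          ew <- c(ew, shared)
        }
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(term_a = ea, term_b = eb, weight = ew,
                                    stringsAsFactors = FALSE)),
            class = "comparative_network")
}

#' @export
print.comparative_network <- function(x, ...) {
  cat(sprintf("comparative_network: %d term(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a comparative network
#'
#' Writes node and edge TSVs plus an edge-list graph export (`.ncol`
#' style: term_a term_b weight).
#'
#' @param cn A `comparative_network`.
#' @param node_path,edge_path,graph_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_comparative_network <- function(cn, node_path, edge_path, graph_path) {
  write_tsv(cn$nodes, node_path)
  write_tsv(cn$edges, edge_path)
  writeLines(sprintf("%s %s %d", cn$edges$term_a, cn$edges$term_b,
                     cn$edges$weight), graph_path)
  invisible(c(node_path, edge_path, graph_path))
}
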