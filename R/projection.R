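#' Project DEGs onto the interactome
#'
#' Splits a dataset's DEGs into those present in the network (mapped) and
#' unmapped DEGs (uDEGs), the latter triaged by gene biotype:
#' protein-coding genes become `coding`, lncRNA and other non-coding RNAs
#' become `ncRNA`, pseudogenes become `pseudogene`, anything else `other`.
#'
#' @param net An `interactome`.
#' @param degs Data frame from [classify_degs()]; only rows with status
#'   `over` or `down` are projected.
#' @param biotypes Named character vector or data frame
#'   (`gene_id`, `biotype`) giving biotypes for genes outside the network;
#'   missing genes default to `other`.
#' @return List of class `deg_projection` with elements `mapped`
#'   (character vector) and `udegs` (data frame `gene_id`, `category`).
#' @export
project_degs <- function(net, degs, biotypes = NULL) {
  deg_genes <- unique(degs$gene_id[degs$status %in% c("over", "down")])
  in_net <- deg_genes %in% igraph::V(net$graph)$name
  mapped <- sort(deg_genes[in_net])
  out_genes <- sort(deg_genes[!in_net])
  bt <- rep("other", length(out_genes))
  if (length(out_genes) > 0L && !is.null(biotypes)) {
    if (is.data.frame(biotypes)) {
      biotypes <- setNames(biotypes$biotype, biotypes$gene_id)
    }
    hit <- out_genes %in% names(biotypes)
    bt[hit] <- unname(biotypes[out_genes[hit]])
  }
  category <- rep("other", length(out_genes))
  category[bt == "protein_coding"] <- "coding"
  category[bt %in% c("lncRNA", "other_ncRNA", "ncRNA")] <- "ncRNA"
  category[bt == "pseudogene"] <- "pseudogene"
  structure(list(mapped = mapped,
                 udegs = data.frame(gene_id = out_genes, category = category,
                                    stringsAsFactors = FALSE)),
            class = "deg_projection")
}

#' @export
print.deg_projection <- function(x, ...) {
  tab <- table(factor(x$udegs$category,
                      levels = c("coding", "ncRNA", "pseudogene", "other")))
  cat(sprintf("deg_projection: %d mapped, %d uDEGs (%s)\n",
              length(x$mapped), nrow(x$udegs),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Cluster mapped DEGs with the Louvain method
#'
#' Runs Louvain modularity optimization on the subgraph induced by the
#' mapped DEGs. Communities of at least `min_cluster_size` members become
#' clusters; every other mapped DEG is reported as isolated. A community
#' that is internally disconnected is first split into its connected
#' parts. Cluster ids are stable integers starting at 0, assigned by
#' decreasing size with ties broken by the lexicographically smallest
#' member.
#'
#' @param net An `interactome`.
#' @param projection A `deg_projection` from [project_degs()].
#' @param cfg A [network_config()]; only `min_cluster_size` is used.
#' @param seed Integer seed controlling Louvain's randomized vertex order.
#' @return List of class `cluster_set` with elements `clusters` (named
#'   list of character vectors), `isolated` (character vector) and
#'   `membership` (data frame `gene_id`, `cluster_id`, `"isolated"` for
#'   unclustered genes).
#' @export
cluster_degs <- function(net, projection, cfg = network_config(),
                         seed = 1L) {
  mapped <- projection$mapped
  stopifnot(length(mapped) > 0L)
  sub <- igraph::induced_subgraph(net$graph, mapped)
  comms <- list()
  if (igraph::ecount(sub) == 0L) {
    warning("induced DEG subgraph has no edges; all mapped DEGs are isolated")
  } else {
    set.seed(seed)
    cl <- igraph::cluster_louvain(sub, resolution = 1)
    groups <- split(igraph::V(sub)$name, igraph::membership(cl))
    # repair rule: a community must be internally connected
    for (g in groups) {
      part <- igraph::induced_subgraph(sub, g)
      pc <- igraph::components(part)
      comms <- c(comms, split(igraph::V(part)$name, pc$membership))
    }
  }
  comms <- lapply(comms, sort)
  keep <- vapply(comms, length, 0L) >= cfg$min_cluster_size
  clusters <- comms[keep]
  if (length(clusters) > 0L) {
    ord <- order(-vapply(clusters, length, 0L),
                 vapply(clusters, `[`, "", 1L))
    clusters <- clusters[ord]
    names(clusters) <- as.character(seq_along(clusters) - 1L)
  } else {
    clusters <- setNames(list(), character())
  }
  isolated <- sort(setdiff(mapped, unlist(clusters, use.names = FALSE)))
  membership <- data.frame(
    gene_id = c(unlist(clusters, use.names = FALSE), isolated),
    cluster_id = c(rep(names(clusters), lengths(clusters)),
                   rep("isolated", length(isolated))),
    stringsAsFactors = FALSE
  )
  membership <- membership[order(membership$gene_id), , drop = FALSE]
  rownames(membership) <- NULL
  structure(list(clusters = clusters, isolated = isolated,
                 membership = membership),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) (sizes %s), %d isolated DEG(s)\n",
              length(x$clusters),
              if (length(x$clusters)) paste(lengths(x$clusters), collapse = ", ")
              else "-",
              length(x$isolated)))
  invisible(x)
}

#' Tabulate projection results in the summary layout
#'
#' One row per dataset: mapped DEGs, uDEG total and its biotype
#' subcategories, and the number of clusters.
#'
#' @param projection A `deg_projection`.
#' @param clusters A `cluster_set`.
#' @param name Dataset name.
#' @return One-row data frame.
#' @export
projection_summary <- function(projection, clusters, name = NA_character_) {
  tab <- table(factor(projection$udegs$category,
                      levels = c("coding", "ncRNA", "pseudogene", "other")))
  data.frame(dataset = name,
             mapped_degs = length(projection$mapped),
             udegs = nrow(projection$udegs),
             coding = as.integer(tab[["coding"]]),
             ncRNA = as.integer(tab[["ncRNA"]]),
             pseudogene = as.integer(tab[["pseudogene"]]),
             other = as.integer(tab[["other"]]),
             clusters = length(clusters$clusters),
             stringsAsFactors = FALSE)
}
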