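#' Pipeline configuration
#'
#' Collects all inputs of a full run: paths to the interaction and mapping
#' files, one or more dataset descriptions (each a [dataset_config()] plus
#' its DE stats table and optionally counts + sample sheet and a biotype
#' table), the annotation catalog, thresholds and the global seed.
#'
#' @param edges_path,mapping_path Interactome links and protein-to-gene
#'   mapping TSVs.
#' @param datasets List; each element a list with `config`
#'   (a [dataset_config()]), `stats_path`, and optionally `counts_path`,
#'   `samples_path`, `biotypes_path`.
#' @param gmt_path,hierarchy_path Optional annotation catalog files.
#' @param network A [network_config()].
#' @param embedding An [embedding_config()] (scoring parameter set).
#' @param padj_threshold BH threshold for cluster enrichment.
#' @param p_threshold Unadjusted threshold for the comparative network.
#' @param probability_mode `"rank"` or `"direct"` cluster-score conversion.
#' @param umap Logical; compute the 2-D layout.
#' @param seed Integer global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(edges_path, mapping_path, datasets,
                            gmt_path = NULL, hierarchy_path = NULL,
                            network = network_config(),
                            embedding = embedding_config(),
                            padj_threshold = 0.05, p_threshold = 0.05,
                            probability_mode = c("rank", "direct"),
                            umap = TRUE, seed = 1L) {
  probability_mode <- match.arg(probability_mode)
  cfg <- structure(list(edges_path = edges_path, mapping_path = mapping_path,
                        datasets = datasets, gmt_path = gmt_path,
                        hierarchy_path = hierarchy_path, network = network,
                        embedding = embedding,
                        padj_threshold = padj_threshold,
                        p_threshold = p_threshold,
                        probability_mode = probability_mode,
                        umap = umap, seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  files <- c(cfg$edges_path, cfg$mapping_path, cfg$gmt_path,
             cfg$hierarchy_path,
             unlist(lapply(cfg$datasets, function(d)
               c(d$stats_path, d$counts_path, d$samples_path,
                 d$biotypes_path))))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    stop(sprintf("validation: missing input file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  names <- vapply(cfg$datasets, function(d) d$config$name, "")
  if (anyDuplicated(names)) {
    stop("validation: dataset names must be unique", call. = FALSE)
  }
  for (d in cfg$datasets) {
    if (is.null(d$config$causal_gene) || is.na(d$config$causal_gene) ||
        !nzchar(d$config$causal_gene)) {
      stop(sprintf("validation: dataset %s has no causal gene",
                   d$config$name), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# cheap deterministic hash for the run manifest
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- ((h * 16777619) + ch) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Run the full integrative pipeline
#'
#' Executes interactome construction, DEG statistics, projection,
#' clustering, proximity scoring and enrichment for every dataset, and
#' writes all report tables under `outdir`: the network node/edge tables,
#' the dataset summary (expressed / DEG / over / down counts), the
#' projection summary (mapped DEGs, uDEG triage, cluster counts),
#' per-dataset DEG, cluster-membership, cluster-score, isolated-DEG,
#' per-gene proximity and enrichment tables, the cross-dataset comparative
#' enrichment network, the 2-D layout, and a machine-readable manifest
#' recording seeds and the configuration hash. All randomness derives from
#' the single global seed via per-stage derived seeds.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @return An object of class `degnet_run`.
#' @export
run_pipeline <- function(cfg, outdir) {
  validate_pipeline_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "interactome"
  res <- tryCatch({
    mapping <- read_tsv_checked(cfg$mapping_path,
                                required = c("protein_id", "gene_id"),
                                what = "mapping")
    edges <- load_edges(cfg$edges_path, mapping)
    edges <- filter_confidence(edges, cfg$network$score_min)

    stage <- "deg_stats"
    per_ds <- list()
    expressed_union <- character(0)
    for (d in cfg$datasets) {
      dc <- d$config
      stats <- read_deg_stats(d$stats_path)
      gene_col <- intersect(c("gene_id", "gene"), names(stats))[1]
      if (!is.null(d$counts_path)) {
        cm <- read_counts(d$counts_path, d$samples_path)
        expressed <- expression_filter(cm$counts, cm$groups, dc)
        stats <- stats[stats[[gene_col]] %in% expressed, , drop = FALSE]
      } else {
        expressed <- stats[[gene_col]]
      }
      degs <- classify_degs(stats, dc)
      biotypes <- if (!is.null(d$biotypes_path)) {
        bt <- read_tsv_checked(d$biotypes_path,
                               required = c("gene_id", "biotype"),
                               what = "biotype table")
        setNames(bt$biotype, bt$gene_id)
      } else if ("biotype" %in% names(mapping)) {
        setNames(mapping$biotype, mapping$gene_id)
      } else NULL
      per_ds[[dc$name]] <- list(config = dc, degs = degs,
                                expressed = expressed, biotypes = biotypes)
      expressed_union <- union(expressed_union, expressed)
    }

    net <- build_interactome(edges, mapping)
    net <- restrict_to_expressed(net, expressed_union)
    net <- filter_components(net, cfg$network$min_component_size)
    write_interactome(net, file.path(outdir, "network_nodes.tsv"),
                      file.path(outdir, "network_edges.tsv"))

    stage <- "proximity"
    model <- fit_proximity(net, cfg$embedding,
                           seed = derive_seed(cfg$seed, "embedding"))

    stage <- "per_dataset"
    t1 <- list(); t2 <- list(); all_scores <- list(); enr_by_ds <- list()
    catalog <- if (!is.null(cfg$gmt_path)) {
      hier <- if (!is.null(cfg$hierarchy_path))
        read_hierarchy(cfg$hierarchy_path) else NULL
      read_gmt(cfg$gmt_path, hier)
    } else NULL

    for (nm in names(per_ds)) {
      ds <- per_ds[[nm]]
      t1[[nm]] <- dataset_summary(ds$degs, length(ds$expressed), nm)
      proj <- project_degs(net, ds$degs, ds$biotypes)
      clus <- cluster_degs(net, proj, cfg$network,
                           seed = derive_seed(cfg$seed,
                                              paste0("louvain_", nm)))
      t2[[nm]] <- projection_summary(proj, clus, nm)
      prox <- predict(model, ds$config$causal_gene)
      scores <- score_clusters(clus, prox, mode = cfg$probability_mode)
      iso <- rank_isolated(clus$isolated, prox)
      all_scores[[nm]] <- scores

      deg_out <- ds$degs[ds$degs$status != "not_significant", , drop = FALSE]
      write_tsv(deg_out, file.path(outdir, paste0(nm, "_degs.tsv")))
      memb <- clus$membership
      memb$log2fc <- ds$degs$log2fc[match(memb$gene_id, ds$degs$gene_id)]
      memb$status <- ds$degs$status[match(memb$gene_id, ds$degs$gene_id)]
      write_tsv(cbind(dataset = nm, memb),
                file.path(outdir, paste0(nm, "_clusters.tsv")))
      write_tsv(cbind(dataset = nm, proj$udegs),
                file.path(outdir, paste0(nm, "_udegs.tsv")))
      write_tsv(cbind(dataset = nm, scores),
                file.path(outdir, paste0(nm, "_cluster_scores.tsv")))
      write_tsv(cbind(dataset = nm, iso),
                file.path(outdir, paste0(nm, "_isolated_top.tsv")))
      prox_out <- prox
      prox_out$is_DEG <- prox_out$gene_id %in% proj$mapped
      prox_out$cluster_id <- clus$membership$cluster_id[
        match(prox_out$gene_id, clus$membership$gene_id)]
      prox_out$cluster_id[is.na(prox_out$cluster_id)] <- ""
      write_tsv(prox_out, file.path(outdir, paste0(nm, "_proximity.tsv")))

      if (!is.null(catalog)) {
        stage <- "enrichment"
        universe <- intersect(ds$expressed, interactome_genes(net))
        enr <- enrich_clusters(clus, catalog, universe,
                               padj_threshold = cfg$padj_threshold)
        write_tsv(enr, file.path(outdir, paste0(nm, "_enrichment.tsv")))
        deg_genes <- unique(deg_out$gene_id)
        ds_res <- do.call(rbind, lapply(names(catalog$terms), function(tid) {
          r <- ora_test(deg_genes, catalog$terms[[tid]], ds$expressed)
          cbind(data.frame(term_id = tid, stringsAsFactors = FALSE), r)
        }))
        enr_by_ds[[nm]] <- ds_res
        stage <- "per_dataset"
      }
    }

    summary1 <- do.call(rbind, t1)
    summary2 <- do.call(rbind, t2)
    rownames(summary1) <- rownames(summary2) <- NULL
    cross <- cross_dataset_summary(summary1)
    write_tsv(summary1, file.path(outdir, "summary_datasets.tsv"))
    write_tsv(summary2, file.path(outdir, "summary_projection.tsv"))

    comp <- NULL
    if (length(enr_by_ds) > 0L) {
      stage <- "enrichment"
      hier <- if (!is.null(cfg$hierarchy_path))
        read_hierarchy(cfg$hierarchy_path) else NULL
      comp <- comparative_network(enr_by_ds, hier,
                                  p_threshold = cfg$p_threshold)
      write_comparative_network(comp,
                                file.path(outdir, "comparative_nodes.tsv"),
                                file.path(outdir, "comparative_edges.tsv"),
                                file.path(outdir, "comparative_graph.ncol"))
    }

    coords <- NULL
    if (isTRUE(cfg$umap)) {
      stage <- "umap"
      coords <- umap_coords(net, seed = derive_seed(cfg$seed, "umap"))
      write_tsv(coords, file.path(outdir, "umap_coords.tsv"))
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("degnet")),
      global_seed = cfg$seed,
      stage_seeds = list(
        embedding = derive_seed(cfg$seed, "embedding"),
        umap = derive_seed(cfg$seed, "umap")
      ),
      config_hash = config_hash(cfg),
      probability_mode = cfg$probability_mode,
      datasets = names(per_ds)
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    structure(list(network = net, model = model, summary_datasets = summary1,
                   summary_projection = summary2,
                   mean_expressed = cross$mean_expressed,
                   cluster_scores = all_scores, comparative = comp,
                   coords = coords, outdir = outdir, config = cfg),
              class = "degnet_run")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' @export
print.degnet_run <- function(x, ...) {
  cat("degnet pipeline run\n")
  print(x$network)
  cat(sprintf("datasets: %s\n",
              paste(x$summary_datasets$dataset, collapse = ", ")))
  cat(sprintf("mean expressed genes: %.1f\n", x$mean_expressed))
  invisible(x)
}

#' @export
summary.degnet_run <- function(object, ...) {
  cat("Dataset summary:\n")
  print(object$summary_datasets)
  cat("\nProjection summary:\n")
  print(object$summary_projection)
  for (nm in names(object$cluster_scores)) {
    cat(sprintf("\nTop cluster scores (%s):\n", nm))
    print(utils::head(object$cluster_scores[[nm]], 5))
  }
  invisible(object)
}
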