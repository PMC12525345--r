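#' Simulation configuration
#'
#' Parameters of the synthetic benchmark bundle: a stochastic block model
#' (SBM) interactome with a designated causal gene inside one block, DEG
#' sets planted near (same block) and far (most distant block) from it,
#' extra unmapped DEGs with configurable biotype proportions,
#' negative-binomial counts, and a block-aligned annotation catalog. The
#' defaults are the package's reference benchmark conditions: 500 genes in
#' 5 blocks with within/between edge probabilities 0.2/0.01, 10 near and
#' 10 far DEGs with mean absolute log2 fold change 2.
#'
#' @param n_genes Number of network genes.
#' @param n_blocks Number of SBM blocks (equal sizes).
#' @param p_in,p_out Within-/between-block edge probabilities.
#' @param causal_block Block index (1-based) containing the causal gene.
#' @param n_deg_near,n_deg_far Planted DEGs in the causal block / the most
#'   distant block.
#' @param n_udeg Extra DEG records for genes absent from the network.
#' @param biotype_props Named proportions for uDEG biotypes (coding /
#'   ncRNA / pseudogene).
#' @param effect_mean,effect_sd Mean and sd of the absolute planted log2
#'   fold change.
#' @param n_samples_per_group Libraries per group in the count matrix.
#' @param nb_dispersion Negative-binomial dispersion of the counts.
#' @param n_silent Genes with near-zero expression added to the counts to
#'   exercise the expression filter.
#' @param decoy_edge_frac Fraction of decoy edges scored at or below the
#'   confidence threshold (exercises the score filter).
#' @param n_decoy_terms Random-gene decoy terms in the annotation catalog.
#' @param seed Integer master seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 500L, n_blocks = 5L, p_in = 0.2,
                              p_out = 0.01, causal_block = 1L,
                              n_deg_near = 10L, n_deg_far = 10L,
                              n_udeg = 20L,
                              biotype_props = c(coding = 0.80,
                                                ncRNA = 0.15,
                                                pseudogene = 0.05),
                              effect_mean = 2, effect_sd = 0.3,
                              n_samples_per_group = 3L,
                              nb_dispersion = 0.2, n_silent = 25L,
                              decoy_edge_frac = 0.1,
                              n_decoy_terms = 5L, seed = 1L) {
  stopifnot(p_out > 0, p_out < p_in, p_in <= 1,
            causal_block >= 1, causal_block <= n_blocks,
            n_deg_near + 1L <= n_genes %/% n_blocks,
            n_deg_far <= n_genes %/% n_blocks,
            abs(sum(biotype_props) - 1) < 1e-8)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a scored interactome with a planted causal gene
#'
#' Draws an SBM graph, assigns integer confidence scores uniformly in
#' (150, 1000\] to true edges and at most 150 to a configurable fraction
#' of decoy edges, designates a causal gene inside the causal block, and
#' emits STRING-style protein pairs with a protein-to-gene mapping. If the
#' causal gene's post-filter component would have fewer than five nodes
#' the graph is regenerated with a warning.
#'
#' @param cfg A [simulation_config()].
#' @return List with `edges` (protein1, protein2, experimental), `mapping`
#'   (protein_id, gene_id, symbol, biotype) and `truth` (per-gene block and
#'   biotype labels plus `causal_gene`).
#' @export
simulate_interactome <- function(cfg) {
  n <- cfg$n_genes
  block_size <- n %/% cfg$n_blocks
  sizes <- rep(block_size, cfg$n_blocks)
  sizes[cfg$n_blocks] <- n - block_size * (cfg$n_blocks - 1L)
  gene_id <- sprintf("G%04d", seq_len(n))
  protein_id <- sprintf("P%04d", seq_len(n))
  block <- rep(seq_len(cfg$n_blocks), sizes)
  causal_gene <- gene_id[match(cfg$causal_block, block)]

  seed0 <- derive_seed(cfg$seed, "interactome")
  for (attempt in 0:9) {
    set.seed(seed0 + attempt)
    pm <- matrix(cfg$p_out, cfg$n_blocks, cfg$n_blocks)
    diag(pm) <- cfg$p_in
    g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
    el <- igraph::as_edgelist(g, names = FALSE)
    scores <- sample(151:1000, nrow(el), replace = TRUE)
    # decoy edges among current non-edges, scored <= 150
    n_decoy <- round(cfg$decoy_edge_frac * nrow(el))
    decoys <- matrix(integer(0), 0, 2)
    if (n_decoy > 0L) {
      existing <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      da <- sample.int(n, 4L * n_decoy, replace = TRUE)
      db <- sample.int(n, 4L * n_decoy, replace = TRUE)
      ok <- da != db & !(paste(pmin(da, db), pmax(da, db)) %in% existing)
      ok <- ok & !duplicated(paste(pmin(da, db), pmax(da, db)))
      decoys <- cbind(da[ok], db[ok])[seq_len(min(n_decoy, sum(ok))), ,
                                      drop = FALSE]
    }
    # check: causal gene survives score + component filtering
    keep_el <- el
    gg <- igraph::graph_from_edgelist(keep_el, directed = FALSE)
    gg <- igraph::add_vertices(gg, max(0L, n - igraph::vcount(gg)))
    comp <- igraph::components(gg)
    ci <- comp$membership[match(causal_gene, gene_id)]
    if (comp$csize[ci] >= 5L) break
    warning("causal gene fell in a component smaller than five nodes; regenerating")
  }

  edges <- data.frame(
    protein1 = protein_id[c(el[, 1], decoys[, 1])],
    protein2 = protein_id[c(el[, 2], decoys[, 2])],
    experimental = c(scores,
                     sample(1:150, nrow(decoys), replace = TRUE)),
    stringsAsFactors = FALSE
  )
  mapping <- data.frame(protein_id = protein_id, gene_id = gene_id,
                        symbol = gene_id, biotype = "protein_coding",
                        stringsAsFactors = FALSE)
  truth <- list(
    genes = data.frame(gene_id = gene_id, block = block,
                       biotype = "protein_coding", in_network = TRUE,
                       stringsAsFactors = FALSE),
    causal_gene = causal_gene
  )
  list(edges = edges, mapping = mapping, truth = truth)
}

# farthest block index from the causal block
distant_block <- function(cfg) {
  blocks <- seq_len(cfg$n_blocks)
  blocks[which.max(abs(blocks - cfg$causal_block))]
}

#' Simulate differential-expression statistics with planted DEGs
#'
#' Samples `n_deg_near` genes from the causal block and `n_deg_far` from
#' the most distant block; planted DEGs get
#' `log2FC ~ sign * Normal(effect_mean, effect_sd)` and
#' `padj ~ Uniform(0, 0.01)`, the remaining network genes
#' `log2FC ~ Normal(0, 0.2)` and `padj ~ Uniform(0.2, 1)`. `n_udeg` extra
#' DEG records are added for genes absent from the network, with biotypes
#' at the configured proportions. The causal gene is never planted as a
#' DEG.
#'
#' @param cfg A [simulation_config()].
#' @param truth The `truth` element from [simulate_interactome()].
#' @return List with `stats` (gene, log2FoldChange, pvalue, padj),
#'   `biotypes` (gene_id, biotype) and an updated `truth` carrying
#'   `is_deg` and `deg_origin` (`near`/`far`/`unmapped`).
#' @export
simulate_degs <- function(cfg, truth) {
  set.seed(derive_seed(cfg$seed, "degs"))
  genes <- truth$genes
  near_pool <- setdiff(genes$gene_id[genes$block == cfg$causal_block],
                       truth$causal_gene)
  far_pool <- genes$gene_id[genes$block == distant_block(cfg)]
  if (cfg$n_deg_near > length(near_pool) || cfg$n_deg_far > length(far_pool)) {
    stop("requested DEG counts exceed block size", call. = FALSE)
  }
  near <- sort(sample(near_pool, cfg$n_deg_near))
  far <- sort(sample(far_pool, cfg$n_deg_far))
  planted <- c(near, far)

  n_net <- nrow(genes)
  log2fc <- stats::rnorm(n_net, 0, 0.2)
  padj <- stats::runif(n_net, 0.2, 1)
  idx <- match(planted, genes$gene_id)
  sign_fc <- sample(c(-1, 1), length(planted), replace = TRUE)
  log2fc[idx] <- sign_fc * stats::rnorm(length(planted), cfg$effect_mean,
                                        cfg$effect_sd)
  padj[idx] <- stats::runif(length(planted), 0, 0.01)

  udeg_id <- if (cfg$n_udeg > 0L) sprintf("U%03d", seq_len(cfg$n_udeg))
             else character(0)
  u_bt <- character(0)
  if (cfg$n_udeg > 0L) {
    counts <- floor(cfg$n_udeg * cfg$biotype_props)
    rest <- cfg$n_udeg - sum(counts)
    if (rest > 0) counts[seq_len(rest)] <- counts[seq_len(rest)] + 1L
    bt_name <- c(coding = "protein_coding", ncRNA = "lncRNA",
                 pseudogene = "pseudogene")[names(cfg$biotype_props)]
    u_bt <- sample(rep(bt_name, counts))
  }
  u_sign <- sample(c(-1, 1), cfg$n_udeg, replace = TRUE)
  u_fc <- u_sign * stats::rnorm(cfg$n_udeg, cfg$effect_mean, cfg$effect_sd)
  u_padj <- stats::runif(cfg$n_udeg, 0, 0.01)

  stats_tab <- data.frame(
    gene = c(genes$gene_id, udeg_id),
    log2FoldChange = c(log2fc, u_fc),
    pvalue = c(padj, u_padj) / 2,
    padj = c(padj, u_padj),
    stringsAsFactors = FALSE
  )
  biotypes <- data.frame(gene_id = c(genes$gene_id, udeg_id),
                         biotype = c(genes$biotype, u_bt),
                         stringsAsFactors = FALSE)
  genes$is_deg <- genes$gene_id %in% planted
  genes$deg_origin <- ifelse(genes$gene_id %in% near, "near",
                             ifelse(genes$gene_id %in% far, "far", NA))
  truth$genes <- genes
  truth$udegs <- data.frame(gene_id = udeg_id, biotype = u_bt,
                            stringsAsFactors = FALSE)
  truth$near_degs <- near
  truth$far_degs <- far
  list(stats = stats_tab, biotypes = biotypes, truth = truth)
}

#' Simulate a count matrix consistent with the planted fold changes
#'
#' Negative-binomial counts with per-gene baseline means; the treatment
#' group's mean is shifted by `2^log2FC` for planted DEGs. A configurable
#' set of silent genes with near-zero means exercises the expression
#' filter.
#'
#' @param cfg A [simulation_config()].
#' @param truth Updated truth from [simulate_degs()].
#' @param stats The stats table from [simulate_degs()] (source of the
#'   planted fold changes).
#' @return List with `counts` (integer matrix genes x samples), `samples`
#'   (sample, group) and `silent_genes`.
#' @export
simulate_counts <- function(cfg, truth, stats) {
  set.seed(derive_seed(cfg$seed, "counts"))
  gene_id <- c(stats$gene,
               if (cfg$n_silent > 0L) sprintf("S%03d", seq_len(cfg$n_silent)))
  n <- length(gene_id)
  m <- cfg$n_samples_per_group
  base <- exp(stats::rnorm(n, log(200), 0.7))
  silent <- grepl("^S", gene_id)
  base[silent] <- 0.05
  fc <- c(ifelse(stats$padj < 0.05, stats$log2FoldChange, 0),
          rep(0, sum(silent)))
  size <- 1 / cfg$nb_dispersion
  ctrl <- matrix(stats::rnbinom(n * m, mu = rep(base, m), size = size), n, m)
  treat <- matrix(stats::rnbinom(n * m, mu = rep(base * 2^fc, m), size = size),
                  n, m)
  counts <- cbind(ctrl, treat)
  rownames(counts) <- gene_id
  colnames(counts) <- c(sprintf("Ctrl_%d", seq_len(m)),
                        sprintf("Treat_%d", seq_len(m)))
  samples <- data.frame(sample = colnames(counts),
                        group = rep(c("ctrl", "treat"), each = m),
                        stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, silent_genes = gene_id[silent])
}

#' Simulate an annotation catalog aligned with the SBM blocks
#'
#' One term per block (that block's genes), one parent term per pair of
#' blocks (the union of the two blocks), and random-gene decoy terms; the
#' hierarchy lists each pair term as parent of its two block terms.
#'
#' @param cfg A [simulation_config()].
#' @param truth Truth labels from [simulate_interactome()].
#' @return List with `catalog` (an `annotation_catalog`) and `hierarchy`
#'   (data frame `parent`, `child`).
#' @export
simulate_annotations <- function(cfg, truth) {
  set.seed(derive_seed(cfg$seed, "annotations"))
  genes <- truth$genes
  terms <- list()
  for (b in seq_len(cfg$n_blocks)) {
    terms[[sprintf("BLOCK_%d", b)]] <- genes$gene_id[genes$block == b]
  }
  parents <- character(0); children <- character(0)
  for (i in seq_len(cfg$n_blocks - 1L)) {
    for (j in seq((i + 1L), cfg$n_blocks)) {
      pid <- sprintf("PAIR_%d_%d", i, j)
      terms[[pid]] <- genes$gene_id[genes$block %in% c(i, j)]
      parents <- c(parents, pid, pid)
      children <- c(children, sprintf("BLOCK_%d", i), sprintf("BLOCK_%d", j))
    }
  }
  for (d in seq_len(cfg$n_decoy_terms)) {
    terms[[sprintf("DECOY_%d", d)]] <- sort(sample(genes$gene_id, 20L))
  }
  hierarchy <- data.frame(parent = parents, child = children,
                          stringsAsFactors = FALSE)
  list(catalog = annotation_catalog(terms, hierarchy = hierarchy),
       hierarchy = hierarchy)
}

#' Write a complete synthetic input bundle
#'
#' Emits every file dialect the pipeline readers consume (links TSV,
#' mapping TSV, counts TSV with sample sheet, DE stats TSV, GMT,
#' hierarchy TSV) plus a truth JSON, all deterministic for the
#' configuration seed.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of file paths plus the in-memory
#'   `truth` labels.
#' @export
simulate_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- simulate_interactome(cfg)
  degs <- simulate_degs(cfg, net$truth)
  cnt <- simulate_counts(cfg, degs$truth, degs$stats)
  ann <- simulate_annotations(cfg, degs$truth)
  paths <- list(
    edges = file.path(dir, "links.tsv"),
    mapping = file.path(dir, "mapping.tsv"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    stats = file.path(dir, "deg_stats.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    hierarchy = file.path(dir, "hierarchy.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_tsv(net$edges, paths$edges)
  write_tsv(net$mapping, paths$mapping)
  cdf <- data.frame(gene = rownames(cnt$counts), cnt$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cdf, paths$counts)
  write_tsv(cnt$samples, paths$samples)
  write_tsv(degs$stats, paths$stats)
  gmt_lines <- vapply(names(ann$catalog$terms), function(t) {
    paste(c(t, t, ann$catalog$terms[[t]]), collapse = "\t")
  }, "")
  writeLines(gmt_lines, paths$gmt)
  write_tsv(ann$hierarchy, paths$hierarchy)
  truth <- degs$truth
  jsonlite::write_json(
    list(causal_gene = truth$causal_gene,
         near_degs = truth$near_degs, far_degs = truth$far_degs,
         udegs = truth$udegs, genes = truth$genes,
         silent_genes = cnt$silent_genes),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, list(truth_labels = truth)))
}
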