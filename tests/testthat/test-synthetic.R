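test_that("bundles are byte-identical across runs with one seed", {
  cfg <- small_sim_cfg(seed = 41)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("decoy edges disappear after the confidence filter", {
  cfg <- small_sim_cfg(seed = 42)
  sim <- simulate_interactome(cfg)
  expect_true(any(sim$edges$experimental <= 150))  # decoys present
  ed <- edges_from_proteins(sim$edges$protein1, sim$edges$protein2,
                                     sim$edges$experimental, sim$mapping)
  kept <- filter_confidence(ed, 150)
  expect_true(all(kept$score > 150))
  expect_equal(nrow(kept), sum(sim$edges$experimental > 150))
})

test_that("within-block edge density is near the configured probability", {
  cfg <- simulation_config(n_genes = 400L, n_blocks = 4L, p_in = 0.2,
                           p_out = 0.01, seed = 43)
  sim <- simulate_interactome(cfg)
  real <- sim$edges[sim$edges$experimental > 150, ]
  block <- setNames(sim$truth$genes$block, sim$truth$genes$gene_id)
  g_of <- setNames(sim$mapping$gene_id, sim$mapping$protein_id)
  b1 <- block[g_of[real$protein1]]
  b2 <- block[g_of[real$protein2]]
  n_in <- sum(b1 == b2 & b1 == 1)
  trials <- choose(100, 2)
  expected <- trials * cfg$p_in
  sd3 <- 3 * sqrt(trials * cfg$p_in * (1 - cfg$p_in))
  expect_lt(abs(n_in - expected), sd3)
})

test_that("classification recovers exactly the planted DEGs", {
  cfg <- small_sim_cfg(seed = 44)
  sim <- simulate_interactome(cfg)
  degs <- simulate_degs(cfg, sim$truth)
  dc <- dataset_config("syn", sim$truth$causal_gene, log2fc_cutoff = 0.6)
  rec <- classify_degs(degs$stats, dc)
  called <- rec$gene_id[rec$status != "not_significant"]
  planted <- c(degs$truth$near_degs, degs$truth$far_degs,
               degs$truth$udegs$gene_id)
  expect_setequal(called, planted)
  expect_false(sim$truth$causal_gene %in% called)
})

test_that("planted uDEG count equals the projection tally", {
  cfg <- small_sim_cfg(seed = 45)
  sim <- simulate_interactome(cfg)
  degs <- simulate_degs(cfg, sim$truth)
  ed <- edges_from_proteins(sim$edges$protein1, sim$edges$protein2,
                                     sim$edges$experimental, sim$mapping)
  net <- build_interactome(filter_confidence(ed, 150), sim$mapping)
  suppressMessages(net <- filter_components(net, 5))
  dc <- dataset_config("syn", sim$truth$causal_gene, log2fc_cutoff = 0.6)
  rec <- classify_degs(degs$stats, dc)
  bt <- setNames(degs$biotypes$biotype, degs$biotypes$gene_id)
  proj <- project_degs(net, rec, bt)
  # all planted uDEGs are off the network; a few network DEGs may also
  # drop out via the component filter
  expect_true(all(degs$truth$udegs$gene_id %in% proj$udegs$gene_id))
  expect_gte(nrow(proj$udegs), cfg$n_udeg)
})

test_that("zero effect spread pins the planted fold-change magnitude", {
  cfg <- simulation_config(n_genes = 100L, n_blocks = 5L, p_in = 0.3,
                           p_out = 0.02, n_deg_near = 5L, n_deg_far = 5L,
                           n_udeg = 4L, effect_sd = 0, seed = 46)
  sim <- simulate_interactome(cfg)
  degs <- simulate_degs(cfg, sim$truth)
  planted <- c(degs$truth$near_degs, degs$truth$far_degs)
  fc <- degs$stats$log2FoldChange[match(planted, degs$stats$gene)]
  expect_equal(abs(fc), rep(cfg$effect_mean, length(planted)))
})

test_that("requesting more DEGs than a block holds is an error", {
  cfg <- small_sim_cfg(seed = 47)
  cfg$n_deg_near <- 1000L
  sim <- simulate_interactome(cfg)
  expect_error(simulate_degs(cfg, sim$truth), "exceed block size")
})

test_that("silent genes fail the expression filter; libraries are nonempty", {
  cfg <- small_sim_cfg(seed = 48)
  sim <- simulate_interactome(cfg)
  degs <- simulate_degs(cfg, sim$truth)
  cnt <- simulate_counts(cfg, degs$truth, degs$stats)
  expect_true(all(colSums(cnt$counts) > 0))
  dc <- dataset_config("syn", sim$truth$causal_gene, log2fc_cutoff = 0.6)
  groups <- cnt$samples$group
  kept <- expression_filter(cnt$counts, groups, dc)
  expect_length(intersect(kept, cnt$silent_genes), 0)
})

test_that("count group-mean ratios track the planted fold changes", {
  cfg <- simulation_config(n_genes = 100L, n_blocks = 5L, p_in = 0.3,
                           p_out = 0.02, n_deg_near = 8L, n_deg_far = 8L,
                           n_udeg = 0L, n_samples_per_group = 50L,
                           effect_sd = 0, seed = 49)
  sim <- simulate_interactome(cfg)
  degs <- simulate_degs(cfg, sim$truth)
  cnt <- simulate_counts(cfg, degs$truth, degs$stats)
  planted <- c(degs$truth$near_degs, degs$truth$far_degs)
  ctrl <- cnt$samples$sample[cnt$samples$group == "ctrl"]
  treat <- cnt$samples$sample[cnt$samples$group == "treat"]
  for (g in planted) {
    fc <- degs$stats$log2FoldChange[degs$stats$gene == g]
    mc <- mean(cnt$counts[g, ctrl]); mt <- mean(cnt$counts[g, treat])
    # 3 standard errors of the log-ratio under the NB dispersion
    se <- 3 * sqrt(2 * (1 / 50) * (1 + cfg$nb_dispersion))
    expect_lt(abs(log2(mt / mc) - fc), max(se, 1))
  }
})

test_that("emitted files round-trip through the pipeline readers", {
  cfg <- small_sim_cfg(seed = 50)
  d <- withr::local_tempdir()
  paths <- simulate_bundle(cfg, d)
  map <- utils::read.delim(paths$mapping)
  expect_silent({
    suppressMessages(ed <- load_edges(paths$edges, map))
    stats <- read_deg_stats(paths$stats)
    cm <- read_counts(paths$counts, paths$samples)
    cat <- read_gmt(paths$gmt, read_hierarchy(paths$hierarchy))
  })
  expect_gt(nrow(ed), 0)
  expect_equal(sort(unique(c(ed$gene_a, ed$gene_b))),
               sort(map$gene_id))
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$causal_gene, paths$truth_labels$causal_gene)
})

test_that("annotation terms mirror the block structure", {
  cfg <- small_sim_cfg(seed = 51)
  sim <- simulate_interactome(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  genes <- sim$truth$genes
  for (b in seq_len(cfg$n_blocks)) {
    expect_setequal(ann$catalog$terms[[sprintf("BLOCK_%d", b)]],
                    genes$gene_id[genes$block == b])
  }
  expect_setequal(ann$catalog$terms[["PAIR_1_2"]],
                  genes$gene_id[genes$block %in% 1:2])
  expect_true(all(c("BLOCK_1", "BLOCK_2") %in%
                    ann$hierarchy$child[ann$hierarchy$parent == "PAIR_1_2"]))
})
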