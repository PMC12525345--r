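test_that("embedding has the contracted shape and is seed-deterministic", {
  net <- path_net(5)
  na <- normalized_adjacency(net)
  cfg <- embedding_config(dimensions = 4L, walk_length = 20L,
                          num_walks = 4L, window = 3L, seed = 5L)
  emb <- embed_network(na, cfg)
  expect_equal(dim(emb$vectors), c(5L, 4L))
  expect_true(all(is.finite(emb$vectors)))
  emb2 <- embed_network(na, cfg)
  expect_identical(emb$vectors, emb2$vectors)
  emb3 <- embed_network(na, embedding_config(dimensions = 4L,
                                             walk_length = 20L,
                                             num_walks = 4L, window = 3L,
                                             seed = 6L))
  expect_false(identical(emb$vectors, emb3$vectors))
})

test_that("embedding separates two disconnected cliques", {
  net <- two_cliques_net(20, 20)
  emb <- embed_network(normalized_adjacency(net), fast_embed_cfg(seed = 3))
  S <- cosine_sim(emb)
  a <- grep("^a", rownames(S)); b <- grep("^b", rownames(S))
  within <- c(S[a, a][upper.tri(S[a, a])], S[b, b][upper.tri(S[b, b])])
  between <- S[a, b]
  expect_gt(mean(within), mean(between))
})

test_that("second parameter set is rejected outside p = q = 1", {
  expect_error(embedding_config(p = 2), "first-order")
})

test_that("cosine similarity matches a double-loop oracle", {
  set.seed(8)
  v <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  emb <- structure(list(genes = rownames(v), vectors = v),
                   class = "embedding")
  S <- cosine_sim(emb)
  for (i in 1:10) {
    for (j in 1:10) {
      expect_equal(S[i, j],
                   sum(v[i, ] * v[j, ]) /
                     (sqrt(sum(v[i, ]^2)) * sqrt(sum(v[j, ]^2))),
                   tolerance = 1e-12)
    }
  }
  expect_identical(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 10))

  v2 <- rbind(v, zero = 0)
  embz <- structure(list(genes = rownames(v2), vectors = v2),
                    class = "embedding")
  expect_error(cosine_sim(embz), "zero")
})

test_that("link model learns a positive slope on a community graph", {
  set.seed(9)
  g <- igraph::sample_sbm(200, matrix(c(0.3, 0.02, 0.02, 0.3), 2),
                          block.sizes = c(100, 100))
  ids <- sprintf("n%03d", 1:200)
  el <- igraph::as_edgelist(g)
  net <- net_from_pairs(ids[el[, 1]], ids[el[, 2]])
  suppressMessages(net <- filter_components(net, 5))
  emb <- embed_network(normalized_adjacency(net), fast_embed_cfg(seed = 4))
  S <- cosine_sim(emb)
  lm <- fit_link_model(S, net, seed = 10)
  expect_gt(lm$slope, 0)
  expect_equal(lm$n_positives, lm$n_negatives)

  # ranking accuracy above chance on freshly sampled edge/non-edge pairs
  genes <- rownames(S)
  ed <- net$edges
  set.seed(11)
  take <- sample(nrow(ed), 200)
  pos_s <- S[cbind(match(ed$gene_a[take], genes),
                   match(ed$gene_b[take], genes))]
  adj_key <- paste(ed$gene_a, ed$gene_b)
  ra <- sample(genes, 600, replace = TRUE)
  rb <- sample(genes, 600, replace = TRUE)
  ok <- ra != rb & !(paste(pmin(ra, rb), pmax(ra, rb)) %in% adj_key)
  neg_s <- S[cbind(match(ra[ok], genes), match(rb[ok], genes))][1:200]
  auc <- mean(outer(pos_s, neg_s, ">") + 0.5 * outer(pos_s, neg_s, "=="))
  expect_gt(auc, 0.5)
})

test_that("constant similarity yields a flat model at the base rate", {
  net <- path_net(6)
  S <- matrix(0.5, 6, 6,
              dimnames = list(interactome_genes(net),
                              interactome_genes(net)))
  diag(S) <- 1  # realistic diagonal; off-diagonal constant
  lm <- fit_link_model(S, net, seed = 12)
  expect_equal(lm$slope, 0)
  pr <- association_prob(lm, S, "g01")
  expect_equal(unname(pr), rep(0.5, 5), tolerance = 1e-8)
})

test_that("association probabilities follow the scalar logistic formula", {
  net <- random_net(50, 0.1, seed = 13)
  emb <- embed_network(normalized_adjacency(net), fast_embed_cfg(seed = 5))
  S <- cosine_sim(emb)
  lm <- fit_link_model(S, net, seed = 14)
  causal <- rownames(S)[1]
  pr <- association_prob(lm, S, causal)
  for (g in names(pr)) {
    expect_equal(unname(pr[g]),
                 1 / (1 + exp(-(lm$intercept + lm$slope * S[g, causal]))))
  }
  expect_false(causal %in% names(pr))
  expect_error(association_prob(lm, S, "missing_gene"), "not in the network")

  # monotonicity for positive slope
  if (lm$slope > 0) {
    ord <- order(S[causal, names(pr)])
    expect_true(all(diff(pr[names(pr)[ord]]) >= 0))
  }
})

test_that("rank normalization maps probabilities to upper-tail ranks", {
  p <- setNames(c(0.1, 0.2, 0.3, 0.4), paste0("g", 1:4))
  expect_equal(unname(rank_normalize(p)), c(0.25, 0.5, 0.75, 1.0))
  expect_equal(unname(rank_normalize(p)["g4"]), 1.0)

  tied <- setNames(rep(0.7, 8), paste0("g", 1:8))
  expect_equal(unname(rank_normalize(tied)), rep(0.5 + 1 / 16, 8))

  # permutation equivariance
  set.seed(15)
  x <- setNames(runif(20), paste0("g", 1:20))
  perm <- sample(20)
  expect_equal(rank_normalize(x)[perm], rank_normalize(x[perm]))
})

test_that("Fisher's method matches its chi-square closed forms", {
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  expect_equal(fisher_combine(0.123), 0.123, tolerance = 1e-12)

  # df = 4 closed form exp(-X/2) (1 + X/2)
  set.seed(16)
  for (i in 1:20) {
    p2 <- runif(2, 1e-6, 1)
    X <- -2 * sum(log(p2))
    expect_equal(fisher_combine(p2), exp(-X / 2) * (1 + X / 2),
                 tolerance = 1e-9)
  }
  expect_error(fisher_combine(numeric(0)), "empty")
})

test_that("cluster scores combine member ranks and order deterministically", {
  rs <- setNames(c(rep(1, 3), rep(0.5, 3), 0.9, 0.2),
                 sprintf("g%d", 1:8))
  cl <- list("0" = c("g1", "g2", "g3"), "1" = c("g4", "g5", "g6"))
  tab <- score_clusters(cl, rs)
  expect_equal(tab$cluster_id[1], "0")
  expect_equal(tab$score[1], 1.00)
  # closed-form check for the all-0.5 cluster (p_i = 0.5 each, k = 3)
  X <- -2 * 3 * log(0.5)
  expect_equal(tab$combined_p[tab$cluster_id == "1"],
               pchisq(X, df = 6, lower.tail = FALSE), tolerance = 1e-12)
  # score is monotone decreasing in combined_p
  expect_true(all(diff(tab$combined_p) >= 0))

  expect_error(score_clusters(list("0" = c("g1", "nope")), rs), "missing")

  # ties broken by the smaller cluster id
  tie <- score_clusters(list("7" = c("g1", "g2"), "2" = c("g1", "g2")), rs)
  expect_equal(tie$cluster_id, c("2", "7"))
})

test_that("isolated DEGs are ranked by score with a top-k cutoff", {
  rs <- setNames(seq(0.01, 1, length.out = 100), sprintf("g%03d", 1:100))
  set.seed(17)
  iso <- sample(names(rs), 30)
  top <- rank_isolated(iso, rs, k = 10)
  expect_equal(nrow(top), 10L)
  full <- sort(rs[iso], decreasing = TRUE)
  expect_equal(top$gene_id, names(full)[1:10])

  few <- rank_isolated(c("g001", "g002"), rs, k = 10)
  expect_equal(nrow(few), 2L)
  expect_true(all(diff(few$rank_score) <= 0))
})

test_that("proximity model methods expose the fit", {
  net <- two_cliques_net(10, 10)
  # two disconnected cliques separate almost perfectly, so the link model
  # may warn about (near-)separation; that is expected here
  model <- suppressWarnings(fit_proximity(net, fast_embed_cfg(), seed = 18))
  expect_s3_class(model, "proximity_model")
  cf <- coef(model)
  expect_named(cf, c("intercept", "slope"))
  prox <- predict(model, "a01")
  expect_equal(nrow(prox), 19L)  # causal gene excluded
  expect_true(all(prox$rank_score > 0 & prox$rank_score <= 1))
  expect_output(print(model), "proximity_model")
  expect_output(print(summary(model)), "link model")
  # same-clique genes rank above the other clique on average
  same <- prox$rank_score[grepl("^a", prox$gene_id)]
  other <- prox$rank_score[grepl("^b", prox$gene_id)]
  expect_gt(mean(same), mean(other))
})

test_that("umap coordinates are shaped, deterministic and separate cliques", {
  net <- two_cliques_net(15, 15)
  vis <- embedding_config(dimensions = 16L, walk_length = 20L,
                          num_walks = 20L, window = 5L)
  xy <- umap_coords(net, seed = 19, vis_cfg = vis, n_epochs = 100L)
  expect_equal(dim(xy), c(30L, 3L))
  xy2 <- umap_coords(net, seed = 19, vis_cfg = vis, n_epochs = 100L)
  expect_identical(xy, xy2)

  a <- xy[grepl("^a", xy$gene_id), c("x", "y")]
  b <- xy[grepl("^b", xy$gene_id), c("x", "y")]
  within <- mean(dist(a)) + mean(dist(b))
  between <- mean(sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2))
  expect_gt(between, within / 2)

  tiny <- path_net(8)
  expect_warning(umap_coords(tiny, seed = 20, vis_cfg = vis,
                             n_neighbors = 15, n_epochs = 50L),
                 "shrunk")
})
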