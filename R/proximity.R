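#' Embedding configuration
#'
#' Parameters of the random-walk (node2vec-style) embedding. The defaults
#' are the scoring parameter set (128 dimensions, walks of length 100, 10
#' walks per node, return and in-out parameters 1, window 10); the
#' visualization set used for the 2-D projection is 64/30/200/1/1/10.
#' With `p = q = 1` the biased second-order walk reduces to a first-order
#' walk, which is the only case supported.
#'
#' @param dimensions Embedding dimensionality.
#' @param walk_length Steps per random walk.
#' @param num_walks Walks started from each node.
#' @param p,q Return and in-out bias parameters; must both be 1.
#' @param window Skip-gram context window.
#' @param seed Integer seed for walks, training order and negative sampling.
#' @param epochs Skip-gram passes over the walk corpus.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial skip-gram learning rate.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(dimensions = 128L, walk_length = 100L,
                             num_walks = 10L, p = 1, q = 1, window = 10L,
                             seed = 1L, epochs = 1L, negative = 5L,
                             alpha = 0.025) {
  stopifnot(dimensions > 0, walk_length > 0, num_walks > 0, window > 0,
            epochs > 0, negative >= 1)
  if (p != 1 || q != 1) {
    stop("only p = 1, q = 1 (first-order walks) is supported", call. = FALSE)
  }
  structure(list(dimensions = as.integer(dimensions),
                 walk_length = as.integer(walk_length),
                 num_walks = as.integer(num_walks), p = p, q = q,
                 window = as.integer(window), seed = as.integer(seed),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha),
            class = "embedding_config")
}

#' Embed network nodes from the degree-normalized adjacency
#'
#' Generates `num_walks` random walks of `walk_length` per node with
#' transition weights proportional to the normalized-adjacency entries,
#' then trains a skip-gram model with negative sampling over the walk
#' corpus. Deterministic for a fixed seed (single-threaded training).
#'
#' @param norm_adj Symmetric nonnegative matrix from
#'   [normalized_adjacency()], with gene dimnames.
#' @param cfg An [embedding_config()].
#' @return List of class `embedding` with `genes` (node order) and
#'   `vectors` (n x dimensions matrix, rows named by gene).
#' @export
embed_network <- function(norm_adj, cfg = embedding_config()) {
  stopifnot(is.matrix(norm_adj), nrow(norm_adj) == ncol(norm_adj))
  genes <- rownames(norm_adj)
  n <- nrow(norm_adj)
  deg <- rowSums(norm_adj > 0)
  if (any(deg == 0)) {
    stop(sprintf("degenerate node(s) with no neighbours: %s",
                 paste(genes[deg == 0], collapse = ", ")), call. = FALSE)
  }
  # CSR view of the weighted graph
  nbr <- lapply(seq_len(n), function(i) which(norm_adj[i, ] > 0))
  indptr <- c(0L, cumsum(lengths(nbr)))
  indices <- as.integer(unlist(nbr, use.names = FALSE) - 1L)
  weights <- unlist(lapply(seq_len(n),
                           function(i) norm_adj[i, nbr[[i]]]),
                    use.names = FALSE)
  walks <- cpp_random_walks(as.integer(indptr), indices, weights,
                            cfg$num_walks, cfg$walk_length,
                            as.numeric(cfg$seed))
  vec <- cpp_sgns(walks, n, cfg$dimensions, cfg$window, cfg$negative,
                  cfg$epochs, cfg$alpha, as.numeric(cfg$seed) + 1)
  rownames(vec) <- genes
  structure(list(genes = genes, vectors = vec, config = cfg),
            class = "embedding")
}

#' Cosine similarity matrix of an embedding
#'
#' `S[i, j] = v_i . v_j / (|v_i| |v_j|)`; symmetric with unit diagonal.
#'
#' @param emb An `embedding`.
#' @return Dense numeric matrix with gene dimnames.
#' @export
cosine_sim <- function(emb) {
  v <- emb$vectors
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) {
    stop(sprintf("zero-norm embedding vector(s): %s",
                 paste(emb$genes[nrm == 0], collapse = ", ")), call. = FALSE)
  }
  vn <- v / nrm
  S <- tcrossprod(vn)
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  dimnames(S) <- list(emb$genes, emb$genes)
  S
}

#' Calibrate a link-probability model on the similarity matrix
#'
#' Logistic regression of the edge indicator on cosine similarity:
#' positives are the network edges (optionally capped by uniform
#' subsampling), negatives an equal-sized uniform sample of non-adjacent
#' pairs. If fitting encounters (near) separation, predicted probabilities
#' are clipped away from 0/1 and a warning is issued at fit time.
#'
#' @param sim Similarity matrix from [cosine_sim()].
#' @param net The `interactome` the embedding was trained on.
#' @param seed Integer seed for the negative (and any positive) sampling.
#' @param max_positives Cap on the number of edge pairs used.
#' @return Object of class `link_model` with `intercept`, `slope` and
#'   training metadata.
#' @export
fit_link_model <- function(sim, net, seed = 1L, max_positives = 20000L) {
  genes <- rownames(sim)
  n <- length(genes)
  ed <- net$edges
  ed <- ed[ed$gene_a %in% genes & ed$gene_b %in% genes, , drop = FALSE]
  if (nrow(ed) == 0L) stop("network has no edges within the similarity matrix",
                           call. = FALSE)
  set.seed(seed)
  if (nrow(ed) > max_positives) {
    ed <- ed[sample.int(nrow(ed), max_positives), , drop = FALSE]
  }
  ia <- match(ed$gene_a, genes); ib <- match(ed$gene_b, genes)
  pos <- sim[cbind(ia, ib)]
  # uniform non-edge sample of equal size (rejection sampling)
  adj_key <- paste(pmin(ia, ib), pmax(ia, ib))
  n_neg <- length(pos)
  neg <- numeric(0)
  guard <- 0L
  while (length(neg) < n_neg && guard < 50L) {
    ra <- sample.int(n, 2L * n_neg, replace = TRUE)
    rb <- sample.int(n, 2L * n_neg, replace = TRUE)
    ok <- ra != rb & !(paste(pmin(ra, rb), pmax(ra, rb)) %in% adj_key)
    neg <- c(neg, sim[cbind(ra[ok], rb[ok])])
    guard <- guard + 1L
  }
  if (length(neg) < n_neg) stop("could not sample enough non-edges",
                                call. = FALSE)
  neg <- neg[seq_len(n_neg)]
  y <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  s <- c(pos, neg)
  if (stats::var(s) < 1e-14) {
    # uninformative feature: flat model at the base rate
    base <- mean(y)
    return(structure(list(intercept = log(base / (1 - base)), slope = 0,
                          n_positives = length(pos),
                          n_negatives = length(neg), seed = seed,
                          separated = FALSE),
                     class = "link_model"))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ s, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    warning("near-separation in link-model fit; probabilities will be clipped")
  }
  cf <- stats::coef(fit)
  if (is.na(cf[2])) cf[2] <- 0
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 n_positives = length(pos), n_negatives = length(neg),
                 seed = seed, separated = separated),
            class = "link_model")
}

#' @export
print.link_model <- function(x, ...) {
  cat(sprintf(
    "link_model: logit(P(edge)) = %.4f + %.4f * similarity (%d pos / %d neg)%s\n",
    x$intercept, x$slope, x$n_positives, x$n_negatives,
    if (x$separated) " [clipped]" else ""))
  invisible(x)
}

#' @export
coef.link_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Association probability of every gene with the causal gene
#'
#' Applies the calibrated link model to each gene's similarity with the
#' causal gene: `prob = logistic(intercept + slope * S(g, causal))`. The
#' causal gene itself is excluded.
#'
#' @param model A `link_model`.
#' @param sim Similarity matrix from [cosine_sim()].
#' @param causal Causal gene id; must be a network gene.
#' @return Named numeric vector of probabilities over all other genes.
#' @export
association_prob <- function(model, sim, causal) {
  genes <- rownames(sim)
  if (!causal %in% genes) {
    stop(sprintf("causal gene %s is not in the network", causal),
         call. = FALSE)
  }
  s <- sim[causal, setdiff(genes, causal)]
  eta <- model$intercept + model$slope * s
  pr <- 1 / (1 + exp(-eta))
  if (isTRUE(model$separated)) {
    pr <- pmin(pmax(pr, 1e-6), 1 - 1e-6)
  }
  pr
}

#' Rank-normalize association probabilities
#'
#' Maps each probability to its empirical upper-tail rank among all
#' network genes: `rank_score = rank(prob) / n` with mean ranks for ties,
#' so values lie in (0, 1] and the top gene scores 1 (absent ties).
#'
#' @param probs Named numeric vector of association probabilities.
#' @return Named numeric vector of rank scores.
#' @export
rank_normalize <- function(probs) {
  stopifnot(length(probs) >= 2L)
  rank(probs, ties.method = "average") / length(probs)
}

#' Fisher's combined probability test
#'
#' Combines k p-like values via `X = -2 sum(log p)` referred to a
#' chi-square distribution with 2k degrees of freedom. Values are floored
#' at `eps` to avoid `log(0)`.
#'
#' @param pvals Numeric vector of values in (0, 1].
#' @param eps Floor applied before taking logs (default 1e-12).
#' @return The combined upper-tail p-value.
#' @export
fisher_combine <- function(pvals, eps = 1e-12) {
  if (length(pvals) == 0L) stop("fisher_combine: empty input", call. = FALSE)
  p <- pmax(pvals, eps)
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Fit the proximity model of a network
#'
#' The estimator at the core of the pipeline: embeds the network from its
#' degree-normalized adjacency, computes the cosine similarity matrix, and
#' calibrates the logistic link-probability model. The fitted object can
#' then be queried for any causal gene via [predict()].
#'
#' @param net An `interactome` (post component filtering).
#' @param cfg An [embedding_config()].
#' @param seed Integer seed; overrides `cfg$seed` and drives the link
#'   model's sampling.
#' @param adjacency_mode Passed to [normalized_adjacency()].
#' @return Object of class `proximity_model` with the embedding,
#'   similarity matrix and link model.
#' @export
fit_proximity <- function(net, cfg = embedding_config(), seed = cfg$seed,
                          adjacency_mode = "symmetric") {
  cfg$seed <- as.integer(seed)
  na <- normalized_adjacency(net, mode = adjacency_mode)
  emb <- embed_network(na, cfg)
  sim <- cosine_sim(emb)
  lm <- fit_link_model(sim, net, seed = cfg$seed)
  structure(list(embedding = emb, similarity = sim, link_model = lm,
                 config = cfg, n_genes = length(emb$genes)),
            class = "proximity_model")
}

#' @export
print.proximity_model <- function(x, ...) {
  cat(sprintf("proximity_model: %d genes embedded in %d dimensions\n",
              x$n_genes, x$config$dimensions))
  print(x$link_model)
  invisible(x)
}

#' @export
summary.proximity_model <- function(object, ...) {
  s <- object$similarity[upper.tri(object$similarity)]
  out <- list(n_genes = object$n_genes,
              dimensions = object$config$dimensions,
              coef = coef(object$link_model),
              similarity_quartiles = stats::quantile(s, c(.25, .5, .75)))
  class(out) <- "summary.proximity_model"
  out
}

#' @export
print.summary.proximity_model <- function(x, ...) {
  cat(sprintf("proximity model over %d genes (%d dimensions)\n",
              x$n_genes, x$dimensions))
  cat(sprintf("link model: intercept %.4f, slope %.4f\n",
              x$coef[["intercept"]], x$coef[["slope"]]))
  cat("similarity quartiles:",
      paste(sprintf("%.3f", x$similarity_quartiles), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.proximity_model <- function(object, ...) {
  coef(object$link_model)
}

#' Per-gene proximity to a causal gene
#'
#' @param object A `proximity_model`.
#' @param causal Causal gene id.
#' @param ... Unused.
#' @return Data frame `gene_id`, `association_prob`, `rank_score`, sorted
#'   by `rank_score` decreasing.
#' @export
predict.proximity_model <- function(object, causal, ...) {
  pr <- association_prob(object$link_model, object$similarity, causal)
  rs <- rank_normalize(pr)
  out <- data.frame(gene_id = names(pr), association_prob = unname(pr),
                    rank_score = unname(rs), stringsAsFactors = FALSE)
  out <- out[order(-out$rank_score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score DEG clusters by proximity to the causal gene
#'
#' Each member gene contributes a p-like value — `1 - rank_score` in the
#' default rank mode, or `1 - association_prob` in direct mode — floored
#' at `eps`; the values are combined with Fisher's test and the cluster
#' score is `1 - combined_p` (reported to two decimals). Clusters are
#' ranked by score descending, ties broken by the smaller cluster id.
#'
#' @param clusters A `cluster_set` (or plain named list of gene vectors).
#' @param proximity Data frame from [predict.proximity_model()], or a
#'   named numeric vector of rank scores.
#' @param eps Floor for the per-gene p-values (default 1e-12).
#' @param mode `"rank"` (default) or `"direct"`.
#' @return Data frame `cluster_id`, `size`, `combined_p`, `score`.
#' @export
score_clusters <- function(clusters, proximity, eps = 1e-12,
                           mode = c("rank", "direct")) {
  mode <- match.arg(mode)
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  if (is.data.frame(proximity)) {
    vals <- if (mode == "rank") proximity$rank_score else proximity$association_prob
    vals <- setNames(vals, proximity$gene_id)
  } else {
    vals <- proximity
  }
  if (length(cl) == 0L) {
    return(data.frame(cluster_id = character(), size = integer(),
                      combined_p = numeric(), score = numeric()))
  }
  rows <- lapply(names(cl), function(id) {
    members <- cl[[id]]
    miss <- setdiff(members, names(vals))
    if (length(miss) > 0L) {
      stop(sprintf("cluster %s member(s) missing from the network: %s", id,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    p <- pmax(1 - vals[members], eps)
    cp <- fisher_combine(p, eps = eps)
    data.frame(cluster_id = id, size = length(members), combined_p = cp,
               score_raw = 1 - cp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score_raw,
                   suppressWarnings(as.numeric(out$cluster_id)),
                   out$cluster_id), , drop = FALSE]
  out$score <- round_half_up(out$score_raw, 2L)
  out$score_raw <- NULL
  rownames(out) <- NULL
  out
}

#' Rank isolated DEGs by proximity
#'
#' @param isolated Character vector of isolated DEG gene ids.
#' @param proximity Data frame from [predict.proximity_model()], or a
#'   named numeric vector of rank scores.
#' @param k Number of top genes to return (default 10).
#' @return Data frame `gene_id`, `rank_score` sorted decreasing, at most
#'   `k` rows.
#' @export
rank_isolated <- function(isolated, proximity, k = 10L) {
  if (is.data.frame(proximity)) {
    vals <- setNames(proximity$rank_score, proximity$gene_id)
  } else {
    vals <- proximity
  }
  vals <- vals[names(vals) %in% isolated]
  out <- data.frame(gene_id = names(vals), rank_score = unname(vals),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rank_score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}
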