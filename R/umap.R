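# Compact UMAP implementation for the 2-D network view: exact knn on the
# embedding vectors, smooth-knn bandwidth calibration, fuzzy-union graph,
# and an SGD layout (C++ kernel) with the 1/(1 + a d^(2b)) kernel whose
# (a, b) are fitted from min_dist. Deliberately minimal: dense distances,
# PCA initialization, single thread.

# fit the low-dimensional kernel parameters from min_dist (least squares
# against the target membership curve, as in the reference algorithm)
umap_ab <- function(min_dist, spread = 1) {
  xv <- seq(0, spread * 3, length.out = 300)
  yv <- ifelse(xv <= min_dist, 1, exp(-(xv - min_dist) / spread))
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    sum((1 / (1 + a * xv^(2 * b)) - yv)^2)
  }
  par <- stats::optim(c(log(1.5), log(1)), obj, method = "Nelder-Mead")$par
  c(a = exp(par[1]), b = exp(par[2]))
}

# smooth-knn calibration: per-point bandwidth so that the effective number
# of neighbours is log2(k)
smooth_knn_weights <- function(dists, target) {
  rho <- min(dists)
  lo <- 0; hi <- Inf; mid <- 1
  for (iter in 1:64) {
    val <- sum(exp(-pmax(dists - rho, 0) / mid))
    if (abs(val - target) < 1e-5) break
    if (val > target) {
      hi <- mid; mid <- (lo + hi) / 2
    } else {
      lo <- mid
      mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
    }
  }
  exp(-pmax(dists - rho, 0) / mid)
}

#' Two-dimensional layout of the interactome
#'
#' Embeds the network with the visualization parameter set of the
#' random-walk embedding (64 dimensions, walks of length 30, 200 walks per
#' node, window 10) and projects the vectors to 2-D with UMAP
#' (`n_neighbors = 15`, `min_dist = 0.1`, Euclidean metric). Deterministic
#' for a fixed seed. If the network has fewer nodes than `n_neighbors`,
#' the neighbourhood size is shrunk with a warning.
#'
#' @param net An `interactome`.
#' @param seed Integer seed.
#' @param vis_cfg Embedding configuration for the visualization embedding.
#' @param n_neighbors Neighbourhood size (default 15).
#' @param min_dist Minimum separation in the layout (default 0.1).
#' @param n_epochs Layout optimization epochs (default 200).
#' @return Data frame `gene_id`, `x`, `y` in lexicographic gene order.
#' @export
umap_coords <- function(net, seed = 1L,
                        vis_cfg = embedding_config(dimensions = 64L,
                                                   walk_length = 30L,
                                                   num_walks = 200L,
                                                   window = 10L),
                        n_neighbors = 15L, min_dist = 0.1,
                        n_epochs = 200L) {
  vis_cfg$seed <- as.integer(seed)
  na <- normalized_adjacency(net)
  emb <- embed_network(na, vis_cfg)
  v <- emb$vectors
  n <- nrow(v)
  if (n < 3L) stop("network too small for a 2-D layout", call. = FALSE)
  k <- as.integer(n_neighbors)
  if (n <= k) {
    k <- n - 1L
    warning(sprintf("n_neighbors shrunk to %d for a %d-node network", k, n))
  }
  d2 <- as.matrix(stats::dist(v))
  target <- log2(k)
  heads <- integer(0); tails <- integer(0); w <- numeric(0)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, -i])
    nbr <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    W[i, nbr] <- smooth_knn_weights(d2[i, nbr], target)
  }
  P <- W + t(W) - W * t(W)  # fuzzy set union
  idx <- which(upper.tri(P) & P > 0, arr.ind = TRUE)
  ab <- umap_ab(min_dist)
  # deterministic PCA initialization, scaled to a 10-unit box
  pc <- stats::prcomp(v, rank. = 2L)$x
  init <- 10 * pc / max(abs(pc))
  xy <- cpp_umap_layout(init, as.integer(idx[, 1] - 1L),
                        as.integer(idx[, 2] - 1L), P[idx],
                        ab[["a"]], ab[["b"]], as.integer(n_epochs), 5L, 1.0,
                        as.numeric(seed) + 7)
  data.frame(gene_id = emb$genes, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}
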