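#' Per-dataset analysis configuration
#'
#' Bundles the parameters that vary between expression datasets: the
#' disease-causal gene used as the proximity seed, the absolute log2
#' fold-change cutoff, the minimum number of libraries per group in which a
#' gene must pass the CPM threshold, and the CPM / adjusted-p thresholds.
#'
#' @param name Dataset name (unique within a run).
#' @param causal_gene Gene identifier of the disease-causal gene.
#' @param log2fc_cutoff Nonnegative absolute log2 fold-change cutoff.
#' @param min_libraries Minimum libraries per group at or above the CPM
#'   threshold (default 2).
#' @param cpm_threshold Counts-per-million expression threshold (default 2).
#' @param padj_threshold Adjusted p-value threshold for DEG calls
#'   (default 0.05).
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(name, causal_gene, log2fc_cutoff,
                           min_libraries = 2L, cpm_threshold = 2,
                           padj_threshold = 0.05) {
  stopifnot(log2fc_cutoff >= 0, min_libraries >= 1,
            cpm_threshold >= 0, padj_threshold > 0, padj_threshold <= 1)
  structure(list(name = name, causal_gene = causal_gene,
                 log2fc_cutoff = log2fc_cutoff,
                 min_libraries = as.integer(min_libraries),
                 cpm_threshold = cpm_threshold,
                 padj_threshold = padj_threshold),
            class = "dataset_config")
}

#' Counts-per-million transformation
#'
#' Scales each library to a common depth of one million: entry (g, s)
#' becomes `counts[g, s] * 1e6 / sum(counts[, s])`.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @return Numeric matrix of CPM values with the same dimnames.
#' @export
cpm_transform <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop(sprintf("degenerate sample(s) with zero total count: %s",
                 paste(colnames(counts)[totals == 0], collapse = ", ")),
         call. = FALSE)
  }
  sweep(counts, 2L, totals, "/") * 1e6
}

# libraries required per group: MLS for small groups, two-thirds rule above
required_libraries <- function(group_size, min_libraries) {
  if (group_size > 3L) {
    max(min_libraries, ceiling(2 / 3 * group_size))
  } else {
    min_libraries
  }
}

#' Expression filter
#'
#' A gene is retained when, in each sample group, the number of libraries
#' with CPM at or above the threshold reaches the per-group requirement:
#' `min_libraries` for groups of three or fewer, otherwise the larger of
#' `min_libraries` and two-thirds of the group size (rounded up). The
#' retained set is the expressed-gene universe for the dataset.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @param groups Character or factor vector of group labels, one per
#'   sample column (two groups, e.g. `ctrl`/`treat`).
#' @param cfg A [dataset_config()].
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(counts, groups, cfg) {
  stopifnot(length(groups) == ncol(counts))
  cpm <- cpm_transform(counts)
  keep <- rep(TRUE, nrow(counts))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    need <- required_libraries(length(cols), cfg$min_libraries)
    n_pass <- rowSums(cpm[, cols, drop = FALSE] >= cfg$cpm_threshold)
    keep <- keep & (n_pass >= need)
  }
  rownames(counts)[keep]
}

#' Classify genes as over-expressed, down-regulated or not significant
#'
#' Applies the dataset's absolute log2 fold-change cutoff together with the
#' adjusted-p threshold: `over` when `log2fc >= cutoff` and
#' `padj < padj_threshold`, `down` when `log2fc <= -cutoff` and
#' `padj < padj_threshold`, otherwise `not_significant`.
#'
#' @param stats Data frame with columns `gene` (or `gene_id`),
#'   `log2FoldChange` (or `log2fc`), `pvalue`, `padj`.
#' @param cfg A [dataset_config()].
#' @return Data frame with columns `gene_id`, `log2fc`, `pvalue`, `padj`,
#'   `status`.
#' @export
classify_degs <- function(stats, cfg) {
  gene_col <- intersect(c("gene_id", "gene"), names(stats))[1]
  fc_col <- intersect(c("log2fc", "log2FoldChange"), names(stats))[1]
  if (is.na(gene_col) || is.na(fc_col) ||
      !all(c("pvalue", "padj") %in% names(stats))) {
    stop("format error: stats table needs gene, log2 fold-change, pvalue and padj columns",
         call. = FALSE)
  }
  log2fc <- stats[[fc_col]]
  padj <- stats$padj
  status <- rep("not_significant", nrow(stats))
  sig <- !is.na(padj) & padj < cfg$padj_threshold
  status[sig & log2fc >= cfg$log2fc_cutoff] <- "over"
  status[sig & log2fc <= -cfg$log2fc_cutoff] <- "down"
  data.frame(gene_id = stats[[gene_col]], log2fc = log2fc,
             pvalue = stats$pvalue, padj = padj, status = status,
             stringsAsFactors = FALSE)
}

#' Summarize a dataset's differential expression
#'
#' Reports the counts of expressed genes, DEGs, over-expressed and
#' down-regulated genes, and the percentage of DEGs that are
#' down-regulated (one decimal, round half up; 0 when there are no DEGs).
#'
#' @param records Output of [classify_degs()].
#' @param expressed_genes Integer size of the expressed universe.
#' @param name Optional dataset name.
#' @return One-row data frame with columns `dataset`, `expressed_genes`,
#'   `degs`, `over`, `down`, `pct_down`.
#' @export
dataset_summary <- function(records, expressed_genes, name = NA_character_) {
  over <- sum(records$status == "over")
  down <- sum(records$status == "down")
  degs <- over + down
  pct <- if (degs > 0) round_half_up(100 * down / degs, 1L) else 0
  data.frame(dataset = name, expressed_genes = as.integer(expressed_genes),
             degs = degs, over = over, down = down, pct_down = pct,
             stringsAsFactors = FALSE)
}

# round half away from zero at `digits` decimals (R's round() is banker's)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate dataset summaries
#'
#' Echoes the per-dataset rows and appends the mean expressed-gene count
#' across datasets (one decimal).
#'
#' @param summaries Data frame of rows from [dataset_summary()].
#' @return List with `table` (the input) and `mean_expressed`.
#' @export
cross_dataset_summary <- function(summaries) {
  stopifnot(nrow(summaries) >= 1L)
  list(table = summaries,
       mean_expressed = round_half_up(mean(summaries$expressed_genes), 1L))
}

#' Read a DE statistics table
#'
#' @param path TSV with columns `gene` (or `gene_id`), `log2FoldChange`
#'   (or `log2fc`), `pvalue`, `padj`.
#' @return Data frame.
#' @export
read_deg_stats <- function(path) {
  df <- read_tsv_checked(path, what = "DE stats table")
  gene_col <- intersect(c("gene_id", "gene"), names(df))[1]
  fc_col <- intersect(c("log2fc", "log2FoldChange"), names(df))[1]
  if (is.na(gene_col) || is.na(fc_col) ||
      !all(c("pvalue", "padj") %in% names(df))) {
    stop("format error: stats table needs gene, log2 fold-change, pvalue and padj columns",
         call. = FALSE)
  }
  df
}

#' Read a counts matrix with its sample sheet
#'
#' @param counts_path TSV of counts, first column gene ids, remaining
#'   columns samples.
#' @param samples_path TSV with columns `sample`, `group`.
#' @return List with `counts` (integer matrix) and `groups` (character
#'   vector aligned with the columns).
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read_tsv_checked(counts_path, what = "counts matrix")
  genes <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "numeric"
  rownames(mat) <- genes
  ss <- read_tsv_checked(samples_path, required = c("sample", "group"),
                         what = "sample sheet")
  m <- match(colnames(mat), ss$sample)
  if (any(is.na(m))) {
    stop("format error: sample sheet is missing samples present in the counts matrix",
         call. = FALSE)
  }
  list(counts = mat, groups = ss$group[m])
}
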