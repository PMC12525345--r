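test_that("CPM transform scales libraries to one million", {
  m <- matrix(c(10, 0, 999990, 5, 5, 999990), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cpm <- cpm_transform(m)
  expect_equal(cpm["g1", "s1"], 10)
  expect_equal(cpm["g2", "s1"], 0)

  set.seed(1)
  r <- matrix(rpois(20, 50), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_equal(unname(colSums(cpm_transform(r))), rep(1e6, 4))

  z <- m; z[, 2] <- 0
  expect_error(cpm_transform(z), "zero total")
})

test_that("CPM transform matches the edgeR implementation", {
  set.seed(2)
  m <- matrix(rpois(60, 100), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  ours <- cpm_transform(m)
  ref <- edgeR::cpm(m, normalized.lib.sizes = FALSE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("expression filter applies the per-group library rule", {
  cfg <- dataset_config("d", "gX", 1, min_libraries = 2, cpm_threshold = 2)
  # 3v3: CPM exactly 2 in two libraries per group -> retained
  depth <- 1e6
  counts <- rbind(
    gene_on = c(2, 2, 0, 2, 2, 0),
    gene_off = c(0, 0, 0, 0, 0, 0)
  )
  # pad totals so every CPM equals the raw count
  counts <- rbind(counts, filler = depth - colSums(counts))
  groups <- rep(c("ctrl", "treat"), each = 3)
  kept <- expression_filter(counts, groups, cfg)
  expect_true("gene_on" %in% kept)
  expect_false("gene_off" %in% kept)

  # 12v12: passing 7 of 12 fails the two-thirds rule (needs 8)
  on7 <- c(rep(2, 7), rep(0, 5))
  counts2 <- rbind(gene7 = c(on7, on7),
                   gene8 = c(rep(2, 8), rep(0, 4), rep(2, 8), rep(0, 4)))
  counts2 <- rbind(counts2, filler = depth - colSums(counts2))
  groups2 <- rep(c("ctrl", "treat"), each = 12)
  kept2 <- expression_filter(counts2, groups2, cfg)
  expect_false("gene7" %in% kept2)
  expect_true("gene8" %in% kept2)
})

test_that("expression filter is monotone in the CPM threshold", {
  set.seed(3)
  counts <- matrix(rpois(300, 30), 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  groups <- rep(c("ctrl", "treat"), each = 3)
  kept_sets <- lapply(c(1, 2, 5, 20), function(th) {
    cfg <- dataset_config("d", "gX", 1, cpm_threshold = th)
    expression_filter(counts, groups, cfg)
  })
  for (i in seq_len(length(kept_sets) - 1)) {
    expect_true(all(kept_sets[[i + 1]] %in% kept_sets[[i]]))
  }
})

test_that("DEG classification applies cutoff and significance jointly", {
  cfg15 <- dataset_config("d", "gX", 1.5)
  one <- data.frame(gene = "g1", log2FoldChange = 1.6, pvalue = 0.005,
                    padj = 0.01)
  expect_equal(classify_degs(one, cfg15)$status, "over")

  cfg06 <- dataset_config("d", "gX", 0.6)
  two <- data.frame(gene = "g2", log2FoldChange = -0.59, pvalue = 5e-4,
                    padj = 0.001)
  expect_equal(classify_degs(two, cfg06)$status, "not_significant")

  expect_error(classify_degs(data.frame(gene = "g", padj = 0.1), cfg06),
               "format error")
})

test_that("classification counts match a linear-scan oracle and partition", {
  set.seed(4)
  n <- 1000
  stats <- data.frame(gene = sprintf("g%04d", 1:n),
                      log2FoldChange = rnorm(n, 0, 1.5),
                      pvalue = runif(n), padj = runif(n))
  cfg <- dataset_config("d", "gX", 1.0)
  rec <- classify_degs(stats, cfg)
  over_oracle <- sum(stats$log2FoldChange >= 1 & stats$padj < 0.05)
  down_oracle <- sum(stats$log2FoldChange <= -1 & stats$padj < 0.05)
  expect_equal(sum(rec$status == "over"), over_oracle)
  expect_equal(sum(rec$status == "down"), down_oracle)
  expect_equal(sum(rec$status == "not_significant"),
               n - over_oracle - down_oracle)
})

test_that("dataset summary arithmetic and reporting rules hold", {
  mk <- function(over, down) {
    n <- over + down
    data.frame(gene_id = sprintf("g%d", seq_len(n)),
               log2fc = c(rep(2, over), rep(-2, down)),
               pvalue = rep(0.001, n), padj = rep(0.001, n),
               status = c(rep("over", over), rep("down", down)))
  }
  s1 <- dataset_summary(mk(38, 399), 12832)
  expect_equal(s1$degs, 437)
  expect_equal(s1$pct_down, 91.3)

  s2 <- dataset_summary(mk(199, 349), 13838)
  expect_equal(s2$pct_down, 63.7)  # 63.686... rounded half up

  s0 <- dataset_summary(mk(0, 0)[0, ], 1000)
  expect_equal(s0$degs, 0)
  expect_equal(s0$pct_down, 0)

  set.seed(5)
  for (i in 1:10) {
    o <- sample(0:50, 1); d <- sample(0:50, 1)
    s <- dataset_summary(mk(o, d), 100)
    expect_equal(s$degs, s$over + s$down)
  }
})

test_that("cross-dataset summary reports the mean expressed-gene count", {
  one <- dataset_summary(data.frame(status = character()), 5000, "only")
  expect_equal(cross_dataset_summary(one)$mean_expressed, 5000)

  set.seed(6)
  counts <- sample(8000:16000, 6)
  rows <- do.call(rbind, lapply(seq_along(counts), function(i) {
    dataset_summary(data.frame(status = character()), counts[i],
                    paste0("d", i))
  }))
  expect_equal(cross_dataset_summary(rows)$mean_expressed,
               degnet:::round_half_up(sum(counts) / length(counts), 1))
})

test_that("counts and stats readers round-trip the TSV dialects", {
  d <- withr::local_tempdir()
  counts <- matrix(rpois(12, 40), 3, 4,
                   dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  write.table(data.frame(gene = rownames(counts), counts),
              file.path(d, "c.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = paste0("s", 1:4),
                         group = rep(c("ctrl", "treat"), 2)),
              file.path(d, "s.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cm <- read_counts(file.path(d, "c.tsv"), file.path(d, "s.tsv"))
  expect_equal(unname(cm$counts), unname(counts))
  expect_equal(cm$groups, rep(c("ctrl", "treat"), 2))
})
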