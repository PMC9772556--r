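# independent step-up oracle: n * p_(i) / i with a cumulative minimum
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

test_that("BH adjustment matches the closed-form step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signed fold change conversion is an exact bijection", {
  expect_equal(signed_fc_from_log2fc(0), 1)
  expect_equal(signed_fc_from_log2fc(c(1, -1)), c(2, -2))
  expect_equal(round(signed_fc_from_log2fc(-0.585), 2), -1.50)
  set.seed(9)
  x <- rnorm(100, sd = 3)
  fc <- signed_fc_from_log2fc(x)
  expect_true(all(abs(fc) >= 1))
  expect_equal(log2fc_from_signed_fc(fc), x)
  expect_error(log2fc_from_signed_fc(0.5), "\\|fc\\| >= 1")
})

test_that("delta-delta-Ct gives exact powers of two", {
  expect_equal(ddct(26, 20, 24, 20)$relative_expression, 0.25)
  expect_equal(ddct(24, 20, 24, 20)$relative_expression, 1)
  expect_equal(ddct(24, 21, 24, 20)$relative_expression, 2)
  expect_error(ddct(NA, 20, 24, 20), "finite")
})

test_that("DEGG intersection filters strictly at alpha and annotates", {
  gl <- assemble_gene_list(data.frame(
    group = "Glycosyltransferases", family = "Sia-T",
    gene_id = c(101, 102, 103), symbol = c("StA", "StB", "StC"),
    source = "CAZy"))
  de <- data.frame(gene_id = c(101, 102, 103, 104, 105),
                   symbol = c("StA", "StB", "StC", "Other1", "Other2"),
                   log2fc = c(1, -1, 0.5, 2, -2),
                   pvalue = c(0.001, 0.02, 0.004, 0.001, 0.5),
                   padj = c(0.01, 0.2, 0.04, 0.01, 0.9))
  deggs <- intersect_with_gene_list(de, gl, alpha = 0.05)
  expect_equal(sort(deggs$gene_id), c(101, 103))
  expect_equal(deggs$group, rep("Glycosyltransferases", 2))
  expect_equal(deggs$regulation[deggs$gene_id == 101], "up")
  # strictness: padj exactly at alpha is excluded
  at_alpha <- de; at_alpha$padj <- 0.05
  expect_equal(nrow(intersect_with_gene_list(at_alpha, gl, alpha = 0.05)), 0)
  expect_equal(nrow(intersect_with_gene_list(de, gl, alpha = 0)), 0)
  # symbol fallback (case-insensitive) when gene_id does not resolve
  de_sym <- de; de_sym$gene_id <- paste0("ENSRNO", 1:5)
  de_sym$symbol <- toupper(de_sym$symbol)
  deggs_sym <- intersect_with_gene_list(de_sym, gl, alpha = 0.05)
  expect_equal(sort(deggs_sym$symbol), c("StA", "StC"))
})

test_that("DEGG set is monotone in alpha", {
  set.seed(11)
  gl <- assemble_gene_list(data.frame(
    group = "Lectins", family = "C-Type", gene_id = 1:50,
    symbol = sprintf("L%d", 1:50), source = "KEGG"))
  de <- data.frame(gene_id = 1:80, symbol = sprintf("L%d", 1:80),
                   log2fc = rnorm(80), pvalue = runif(80),
                   padj = runif(80))
  alphas <- c(0.01, 0.05, 0.2, 0.8)
  sets <- lapply(alphas, function(a)
    sort(intersect_with_gene_list(de, gl, alpha = a)$gene_id))
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("fold filter is inclusive and partitions the published table", {
  deggs <- published_deggs()
  split <- filter_by_fold(deggs, fold = 1.5)
  expect_true("Fut9" %in% split$down$symbol)     # -5.51
  expect_true("Chpf2" %in% split$down$symbol)    # exactly -1.5, inclusive
  expect_false("Chpf" %in% split$down$symbol)    # -1.21
  expect_true("Asgr2" %in% split$up$symbol)      # 1.91
  expect_false(any(split$up$symbol %in% split$down$symbol))
  expect_true(all(c(split$down$symbol, split$up$symbol) %in% deggs$symbol))

  none <- filter_by_fold(data.frame(symbol = "X", fc = 1.4), fold = 1.5)
  expect_equal(nrow(none$down) + nrow(none$up), 0)
  edge <- filter_by_fold(data.frame(symbol = c("U", "D"), fc = c(1.5, -1.5)))
  expect_equal(edge$up$symbol, "U")
  expect_equal(edge$down$symbol, "D")
  expect_error(filter_by_fold(deggs, fold = 0.5), "fold")
})

test_that("NB Wald test is calibrated on null data and flags degeneracies", {
  sim <- simulate_counts(n_genes = 2000, planted = numeric(0),
                         dispersion = 0.05, seed = 11)
  res <- nb_de_test(sim$counts, sim$groups)
  typeI <- mean(res$pvalue < 0.05)
  expect_gte(typeI, 0.03)
  expect_lte(typeI, 0.07)

  const <- matrix(5L, nrow = 2, ncol = 6,
                  dimnames = list(c("c1", "c2"), NULL))
  res_const <- nb_de_test(const, rep(c("control", "case"), each = 3))
  expect_equal(res_const$pvalue, c(1, 1))

  zero <- rbind(matrix(rpois(24, 50), 4), 0)
  rownames(zero) <- sprintf("g%d", 1:5)
  res_zero <- nb_de_test(zero, rep(c("control", "case"), each = 3))
  expect_equal(res_zero$flag[5], "all-zero")
  expect_equal(res_zero$pvalue[5], 1)
  expect_equal(res_zero$log2fc[5], 0)
})

test_that("NB Wald test recovers planted 4-fold effects", {
  planted <- stats::setNames(rep(2, 50), sprintf("g%d", 1:50))
  sim <- simulate_counts(n_genes = 2000, planted = planted,
                         dispersion = 0.05, seed = 5)
  res <- nb_de_test(sim$counts, sim$groups)
  est <- res$log2fc[match(names(planted), res$gene_id)]
  expect_lt(abs(median(abs(est)) - 2), 0.3)
})

test_that("NB Wald test agrees with an established NB framework", {
  skip_if_not_installed("DESeq2")
  planted <- stats::setNames(rep(c(1.5, -1.5), 10), sprintf("g%d", 1:20))
  sim <- simulate_counts(n_genes = 300, planted = planted,
                         dispersion = 0.05, seed = 21)
  res <- nb_de_test(sim$counts, sim$groups)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts, data.frame(condition = factor(sim$groups,
                                                levels = c("control", "case"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds)
  })
  ok <- is.finite(ref$log2FoldChange) & is.finite(res$log2fc)
  expect_gt(cor(res$log2fc[ok], ref$log2FoldChange[ok]), 0.9)
  both_called <- res$padj < 0.05 & !is.na(ref$padj) & ref$padj < 0.05
  expect_true(all(sign(res$log2fc[both_called]) ==
                    sign(ref$log2FoldChange[both_called])))
})

test_that("full DEGG chain recovers planted regulation directions", {
  gl <- packaged_gene_list()
  ids <- as.character(gl$records$gene_id[1:20])
  n_sim <- 200
  ok <- 0
  for (s in seq_len(n_sim)) {
    planted <- stats::setNames(rep(c(1, -1), 10), ids)  # |fc| = 2
    sim <- simulate_counts(n_genes = 500,
                           gene_ids = c(ids, sprintf("x%d", 1:480)),
                           planted = planted, dispersion = 0.05,
                           seed = 7000 + s)
    res <- nb_de_test(sim$counts, sim$groups)
    de <- data.frame(gene_id = res$gene_id, symbol = NA_character_,
                     log2fc = res$log2fc, pvalue = res$pvalue,
                     padj = res$padj)
    deggs <- intersect_with_gene_list(de, gl, alpha = 0.05)
    hit <- deggs[deggs$gene_id %in% as.integer(ids), ]
    sign_ok <- sign(hit$fc) == sign(planted[as.character(hit$gene_id)])
    ok <- ok + (nrow(hit) > 0 && mean(sign_ok) >= 0.95)
  }
  expect_gte(ok / n_sim, 0.95)
})

naive_average_linkage <- function(d) {
  # O(n^3) agglomeration oracle: merge the closest pair, average by size
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  diag(dm) <- Inf
  active <- seq_len(n)
  sizes <- rep(1, n)
  id <- -seq_len(n)              # hclust convention: negatives are leaves
  merges <- matrix(0, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    sub <- dm[active, active, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[min(k)]; j <- active[max(k)]
    heights[step] <- dm[i, j]
    merges[step, ] <- sort(c(id[i], id[j]))
    new_d <- (dm[i, ] * sizes[i] + dm[j, ] * sizes[j]) / (sizes[i] + sizes[j])
    dm[i, ] <- new_d; dm[, i] <- new_d
    dm[i, i] <- Inf
    sizes[i] <- sizes[i] + sizes[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}

test_that("DEGG clustering equals a naive average-linkage oracle", {
  set.seed(33)
  mat <- matrix(rnorm(120), nrow = 20, ncol = 6,
                dimnames = list(sprintf("g%d", 1:20), NULL))
  cl <- cluster_degg_matrix(mat, standardize = TRUE)
  m <- t(scale(t(mat)))
  d <- stats::as.dist(1 - stats::cor(t(m)))
  oracle <- naive_average_linkage(d)
  expect_equal(cl$hclust$height, oracle$height, tolerance = 1e-10)
  # same partitions at every merge height
  for (k in c(2, 5, 10)) {
    a <- stats::cutree(cl$hclust, k)
    b_tree <- cl$hclust; b_tree$merge <- oracle$merge
    b_tree$height <- oracle$height
    b <- stats::cutree(b_tree, k)
    expect_equal(length(unique(paste(a, b))), k)  # one-to-one label match
  }
})

test_that("clustering orders forced structure correctly", {
  base <- c(1, 2, 3, 4, 5, 6)
  mat <- rbind(r1 = base, r2 = base * 2 + 1, r3 = rev(base))
  cl <- cluster_degg_matrix(mat)
  # the two perfectly correlated rows merge first at distance 0
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)

  ident <- rbind(a = base, b = base)
  cl2 <- cluster_degg_matrix(ident)
  expect_equal(cl2$hclust$height, 0, tolerance = 1e-12)

  expect_warning(cluster_degg_matrix(rbind(a = rep(1, 4), b = 1:4)),
                 "constant row")
  expect_error(cluster_degg_matrix(matrix(1:4, 1)), "at least 2 rows")
})
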