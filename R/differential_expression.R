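#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in \[0, 1\], same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a differential-expression results table
#'
#' @param path TSV with header and columns `gene_id`, `symbol`, `log2fc`,
#'   `pvalue`, `padj`.
#' @param readjust Recompute `padj` from `pvalue` with [bh_adjust()]
#'   instead of trusting the supplied column.
#' @return data.frame of DE results.
#' @export
read_de_table <- function(path, readjust = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("gene_id", "symbol", "log2fc", "pvalue", "padj")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (readjust) df$padj <- bh_adjust(df$pvalue)
  df
}

#' Minimal two-group negative-binomial Wald test
#'
#' A compact differential-expression test for synthetic two-group count
#' matrices: library sizes are estimated by the median-of-ratios method,
#' per-gene dispersion by method of moments, moderated by taking the
#' maximum of the per-gene estimate and the across-gene median (per-gene
#' moment estimates at n = 3 are too noisy to use alone) and floored at
#' 1e-8, and the Wald statistic is formed on the log2 ratio of normalized
#' group means with a delta-method standard error. P-values are two-sided normal and BH
#' adjusted. Genes with all-zero counts get `p = 1`, `log2fc = 0` and are
#' flagged.
#'
#' @param counts Integer matrix, genes x samples, rownames = gene ids.
#' @param groups Character/factor of length `ncol(counts)` with exactly two
#'   levels; `ref` is the control level.
#' @param ref Reference (control) group label; defaults to the first level.
#' @return data.frame `gene_id`, `base_mean`, `log2fc`, `pvalue`, `padj`,
#'   `flag` (`ok` or `all-zero`), one row per gene in input order.
#' @export
nb_de_test <- function(counts, groups, ref = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups are required")
  if (is.null(ref)) ref <- lv[1]
  if (!(ref %in% lv)) stop("ref must be one of the group labels")
  case <- setdiff(lv, ref)
  if (min(table(groups)) < 2) stop("at least 2 samples per group are required")

  # median-of-ratios size factors over genes with all-positive counts
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2,
                function(col) exp(stats::median(log(col) - loggeo)))
  } else {
    ls <- colSums(counts)
    sf <- ls / mean(ls)
  }
  q <- sweep(counts, 2, sf, "/")

  iA <- which(groups == ref)
  iB <- which(groups == case)
  nA <- length(iA); nB <- length(iB)
  mA <- rowMeans(q[, iA, drop = FALSE])
  mB <- rowMeans(q[, iB, drop = FALSE])
  mu <- rowMeans(q)

  # pooled within-group variance -> method-of-moments dispersion
  vA <- apply(q[, iA, drop = FALSE], 1, stats::var)
  vB <- apply(q[, iB, drop = FALSE], 1, stats::var)
  v <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  xi <- mean(1 / sf)  # Poisson part of Var(K/sf) = mu/sf + alpha*mu^2
  alpha <- (v - mu * xi) / mu^2
  alpha[!is.finite(alpha)] <- 1e-8
  expressed <- mu > 10
  alpha_med <- if (any(expressed)) stats::median(alpha[expressed]) else 0
  alpha <- pmax(alpha, alpha_med, 1e-8)

  zero <- mu == 0
  eps <- 0.5 * xi  # continuity value on the normalized scale
  mA2 <- pmax(mA, eps)
  mB2 <- pmax(mB, eps)
  log2fc <- log2(mB2 / mA2)

  varA <- (mA2 * xi + alpha * mA2^2) / nA
  varB <- (mB2 * xi + alpha * mB2^2) / nB
  se_log2 <- sqrt(varA / mA2^2 + varB / mB2^2) / log(2)
  z <- log2fc / se_log2
  p <- 2 * stats::pnorm(-abs(z))
  p[zero] <- 1
  log2fc[zero] <- 0

  data.frame(gene_id = if (is.null(rownames(counts)))
               as.character(seq_len(nrow(counts))) else rownames(counts),
             base_mean = mu,
             log2fc = log2fc,
             pvalue = p,
             padj = bh_adjust(p),
             flag = ifelse(zero, "all-zero", "ok"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert log2 fold change to signed fold change
#'
#' Maps the reals onto `(-Inf, -1] U [1, Inf)`: `2^log2fc` when
#' `log2fc >= 0`, otherwise `-2^(-log2fc)`.
#'
#' @param log2fc Finite numeric vector.
#' @return Signed fold change(s).
#' @export
signed_fc_from_log2fc <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Convert signed fold change back to log2 fold change
#'
#' Exact inverse of [signed_fc_from_log2fc()] on its range.
#'
#' @param fc Signed fold change(s) with `|fc| >= 1`.
#' @return log2 fold change(s).
#' @export
log2fc_from_signed_fc <- function(fc) {
  if (any(!is.finite(fc)) || any(abs(fc) < 1)) {
    stop("signed fold changes must satisfy |fc| >= 1")
  }
  out <- numeric(length(fc))
  pos <- fc >= 1
  out[pos] <- log2(fc[pos])
  out[!pos] <- -log2(-fc[!pos])
  out
}

#' Intersect differential-expression results with the glycan gene list
#'
#' A gene is a differentially expressed glycan-related gene (DEGG) when its
#' FDR-adjusted p-value is strictly below `alpha` and it is present in the
#' curated list. Identifiers are resolved by GeneID first, then by
#' case-insensitive symbol; unresolvable significant genes are counted but
#' excluded.
#'
#' @param de data.frame of DE results (`gene_id`, `symbol`, `log2fc`,
#'   `padj`).
#' @param gene_list A `glyco_gene_list`.
#' @param alpha Adjusted-p cutoff (strict; default 0.05).
#' @return data.frame of DEGGs: `gene_id`, `symbol`, `group`, `family`,
#'   `fc` (signed), `padj`, `regulation`; attributes `group_counts` and
#'   `n_unresolved`.
#' @export
intersect_with_gene_list <- function(de, gene_list, alpha = 0.05) {
  stopifnot(inherits(gene_list, "glyco_gene_list"))
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be in [0, 1]")
  }
  rec <- gene_list$records
  sig <- de[is.finite(de$padj) & de$padj < alpha, , drop = FALSE]

  idx <- match(suppressWarnings(as.integer(sig$gene_id)), rec$gene_id)
  use_sym <- is.na(idx) & !is.na(sig$symbol)
  idx[use_sym] <- match(tolower(sig$symbol[use_sym]), tolower(rec$symbol))
  unresolved <- sum(is.na(suppressWarnings(as.integer(sig$gene_id))) &
                      is.na(idx))
  hit <- !is.na(idx)

  fc <- signed_fc_from_log2fc(sig$log2fc[hit])
  out <- data.frame(gene_id = rec$gene_id[idx[hit]],
                    symbol = rec$symbol[idx[hit]],
                    group = rec$group[idx[hit]],
                    family = rec$family[idx[hit]],
                    fc = fc,
                    padj = sig$padj[hit],
                    regulation = ifelse(fc >= 1, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "group_counts") <- table(factor(out$group, levels = glyco_groups()))
  attr(out, "n_unresolved") <- unresolved
  out
}

#' Split DEGGs at a fold threshold
#'
#' @param deggs data.frame with a signed `fc` column.
#' @param fold Fold threshold (default 1.5, must be >= 1); both cutoffs are
#'   inclusive (`fc <= -fold` is down, `fc >= fold` is up).
#' @return List with `down` and `up` data.frames.
#' @export
filter_by_fold <- function(deggs, fold = 1.5) {
  if (!is.numeric(fold) || length(fold) != 1 || fold < 1) {
    stop("fold must be a single number >= 1")
  }
  list(down = deggs[deggs$fc <= -fold, , drop = FALSE],
       up = deggs[deggs$fc >= fold, , drop = FALSE])
}

#' Hierarchical clustering of a DEGG expression or fold-change matrix
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` across
#' columns and average linkage; rows may be standardized first (the default,
#' matching the usual heatmap convention). A constant row has no defined
#' correlation and is placed at the maximum distance (2) from everything,
#' with a warning.
#'
#' @param mat Numeric matrix with at least 2 rows (genes) and 2 columns.
#' @param standardize Center and scale rows before computing correlations.
#' @return Object of class `degg_clustering`: list with the `hclust` tree,
#'   the leaf `order`, and row `labels`.
#' @export
cluster_degg_matrix <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("at least 2 rows are required")
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  rs <- apply(mat, 1, stats::sd)
  if (any(rs == 0)) warning("constant row(s): correlation undefined, distance set to 2")
  if (standardize) {
    m <- t(scale(t(mat)))
    m[!is.finite(m)] <- 0
  } else {
    m <- mat
  }
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- -1  # constant rows: maximum distance
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, order = hc$order, labels = rownames(mat)),
            class = "degg_clustering")
}

#' @export
print.degg_clustering <- function(x, ...) {
  cat("DEGG hierarchical clustering of", length(x$labels), "genes",
      "(1 - Pearson, average linkage)\n")
  cat("leaf order:", paste(x$labels[x$order], collapse = ", "), "\n")
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,control -
#' Ct_ref,control)`; relative expression is `2^(-ddCt)` against the
#' reference gene and control condition.
#'
#' @param ct_target_case,ct_ref_case,ct_target_control,ct_ref_control
#'   Finite cycle-threshold values (vectorized).
#' @return List with `ddct` and `relative_expression`.
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) stop("all Ct values must be finite")
  dd <- (ct_target_case - ct_ref_case) - (ct_target_control - ct_ref_control)
  list(ddct = dd, relative_expression = 2^(-dd))
}

#' Write a DEGG report as TSV
#'
#' Columns mirror the published layout: regulation, category, sub-category,
#' GeneID, symbol, signed fold change.
#'
#' @param deggs data.frame from [intersect_with_gene_list()].
#' @param path Output path.
#' @export
write_degg_report <- function(deggs, path) {
  rep <- data.frame(regulation = deggs$regulation,
                    category = deggs$group,
                    sub_category = deggs$family,
                    gene_id = deggs$gene_id,
                    symbol = deggs$symbol,
                    fc = deggs$fc,
                    stringsAsFactors = FALSE)
  rep <- rep[order(rep$regulation, rep$category, rep$sub_category), ]
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
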