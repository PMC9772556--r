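#' Predicted direction of a glycan motif from one enzyme's fold change
#'
#' An enzyme that removes a motif and is down-regulated predicts the motif
#' accumulates (+1); removal with up-regulation predicts depletion (-1);
#' addition follows the gene's own sign. A gene whose |fold change| is
#' below the significance floor contributes no prediction (0).
#'
#' @param action `"adds"` or `"removes"`.
#' @param gene_fc Signed fold change of the gene (|fc| >= 1).
#' @param floor Significance floor on |fc| (default 1.2).
#' @return +1, -1 or 0.
#' @examples
#' expected_glycan_shift("removes", -1.30) # +1: less trimming, motif accumulates
#' expected_glycan_shift("adds", -1.62)    # -1: less transfer, motif depleted
#' @export
expected_glycan_shift <- function(action, gene_fc, floor = 1.2) {
  if (!(action %in% c("adds", "removes"))) {
    stop("unknown action ", shQuote(action))
  }
  if (!is.finite(gene_fc) || abs(gene_fc) < 1) {
    stop("gene_fc must be a signed fold change with |fc| >= 1")
  }
  if (abs(gene_fc) < floor) return(0L)
  gene_dir <- if (gene_fc > 0) 1L else -1L
  if (action == "adds") gene_dir else -gene_dir
}

majority_sign <- function(x) {
  s <- sum(sign(x))
  if (s > 0) 1L else if (s < 0) -1L else 0L
}

#' Motif-level concordance between lectin calls and enzyme predictions
#'
#' For every motif in the lectin catalog or the action map, the observed
#' direction is the majority sign of the calls of lectins recognizing the
#' motif (up = +1, down = -1, unchanged = 0; ties give 0) and the predicted
#' direction is the majority sign of the per-enzyme predictions from
#' [expected_glycan_shift()]. A motif is concordant when both directions
#' are nonzero and equal; motifs lacking either a lectin observation or an
#' enzyme contributor are reported as unevaluable and excluded from the
#' summary denominator.
#'
#' @param lectin_calls data.frame with `lectin`, `fc`, `call` (from
#'   [call_significant_lectins()]).
#' @param deggs data.frame with `symbol` and signed `fc` (e.g. from
#'   [intersect_with_gene_list()]).
#' @param actions Enzyme-action table from [load_enzyme_actions()].
#' @param catalog Lectin catalog from [load_lectin_catalog()].
#' @param floor Significance floor passed to [expected_glycan_shift()].
#' @return Object of class `concordance_report`: list with `records`
#'   (per-motif data.frame) and `summary` (fraction of concordant motifs
#'   among those with both directions nonzero; `NA` when none qualify).
#' @export
concordance_report <- function(lectin_calls, deggs, actions, catalog,
                               floor = 1.2) {
  motifs <- sort(unique(c(unlist(catalog$motifs), actions$motif)))
  call_dir <- c(up = 1L, down = -1L, unchanged = 0L)
  rows <- lapply(motifs, function(m) {
    lec <- catalog$lectin[vapply(catalog$motifs, function(v) m %in% v, logical(1))]
    obs_calls <- lectin_calls[lectin_calls$lectin %in% lec, , drop = FALSE]
    act <- actions[actions$motif == m, , drop = FALSE]
    contrib <- merge(act, deggs[, c("symbol", "fc")], by = "symbol")
    observed <- if (nrow(obs_calls) == 0) NA_integer_ else
      majority_sign(call_dir[obs_calls$call])
    predicted <- if (nrow(contrib) == 0) NA_integer_ else
      majority_sign(vapply(seq_len(nrow(contrib)), function(i) {
        expected_glycan_shift(contrib$action[i], contrib$fc[i], floor)
      }, integer(1)))
    evaluable <- !is.na(observed) && !is.na(predicted)
    data.frame(motif = m,
               lectins = paste(obs_calls$lectin, collapse = ";"),
               genes = paste(contrib$symbol, collapse = ";"),
               observed_direction = observed,
               predicted_direction = predicted,
               evaluable = evaluable,
               concordant = evaluable && observed != 0 &&
                 observed == predicted,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  both <- rec$evaluable & rec$observed_direction != 0 &
    rec$predicted_direction != 0
  denom <- sum(both, na.rm = TRUE)
  summary <- if (denom == 0) NA_real_ else sum(rec$concordant[both]) / denom
  structure(list(records = rec, summary = summary),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  rec <- x$records
  cat("Glycan-motif concordance report:", nrow(rec), "motifs\n")
  cat("  evaluable (lectin + enzyme evidence):", sum(rec$evaluable), "\n")
  cat("  concordant:", sum(rec$concordant), "\n")
  cat("  summary fraction:",
      if (is.na(x$summary)) "not applicable" else format(x$summary, digits = 3),
      "\n")
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a query gene set
#' within a gene universe using the upper-tail hypergeometric probability
#' `P(X >= k)`, with BH adjustment across terms.
#'
#' @param query Character vector of query genes (must be a subset of the
#'   universe; genes outside it are dropped with a warning).
#' @param annotation Named list: term -> character vector of genes.
#' @param universe Gene universe; defaults to the union of all annotation
#'   gene sets.
#' @return data.frame `term`, `k` (overlap), `n` (query size), `K` (term
#'   size), `N` (universe size), `pvalue`, `padj`, sorted by `padj`. Terms
#'   with no gene in the universe are skipped.
#' @export
ora_enrichment <- function(query, annotation, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(annotation))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
  }
  q <- unique(intersect(query, universe))
  n <- length(q)
  N <- length(universe)
  rows <- lapply(names(annotation), function(term) {
    tg <- unique(intersect(annotation[[term]], universe))
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(q, tg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), pvalue = numeric(0),
                      padj = numeric(0)))
  }
  res$padj <- bh_adjust(res$pvalue)
  res <- res[order(res$padj, res$pvalue, res$term), ]
  rownames(res) <- NULL
  res
}

#' Read a GMT-style annotation file
#'
#' Each line: term, description, then tab-separated gene symbols.
#'
#' @param path Path to the GMT file.
#' @return Named list term -> gene character vector.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line with fewer than 3 fields: ", ln)
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Read a confidence-weighted network edge list
#'
#' @param path TSV with header and columns `node_a`, `node_b`,
#'   `confidence` (in \[0, 1\]).
#' @return data.frame of edges.
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("node_a", "node_b", "confidence")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("network table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$confidence < 0 | df$confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  df
}

#' Markov clustering of a confidence-weighted network
#'
#' Edges below the confidence cutoff are dropped (their nodes remain, so
#' isolated nodes become singleton clusters), a self-loop with the node's
#' maximum incident weight is added, and the column-stochastic transition
#' matrix is iterated through expansion (matrix squaring) and inflation
#' (entrywise power followed by column renormalization) until the maximum
#' entry change falls below `tol` or `max_iter` iterations. Clusters are
#' the connected components of the nonzero structure of the limit matrix
#' and always partition the node set.
#'
#' @param edges data.frame with `node_a`, `node_b`, `confidence`.
#' @param cutoff Confidence cutoff (default 0.4).
#' @param inflation Inflation exponent (default 2).
#' @param prune Entries below this value are zeroed each iteration.
#' @param tol Convergence tolerance on the max entry change.
#' @param max_iter Iteration cap.
#' @return Object of class `mcl_partition`: list with `clusters` (list of
#'   node-name vectors, largest first), `membership` (named integer),
#'   `n_iter`, `converged`.
#' @export
mcl_cluster <- function(edges, cutoff = 0.4, inflation = 2.0,
                        prune = 1e-6, tol = 1e-8, max_iter = 200) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  if (inflation <= 1) stop("inflation must exceed 1")
  nodes <- sort(unique(c(as.character(edges$node_a),
                         as.character(edges$node_b))))
  nn <- length(nodes)
  if (nn == 0) stop("empty network")
  A <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  keep <- edges$confidence >= cutoff
  for (i in which(keep)) {
    a <- as.character(edges$node_a[i]); b <- as.character(edges$node_b[i])
    w <- edges$confidence[i]
    A[a, b] <- max(A[a, b], w)
    A[b, a] <- max(A[b, a], w)
  }
  self <- apply(A, 1, max)
  diag(A) <- ifelse(self > 0, self, 1)

  normalize_cols <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize_cols(A)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }

  adj <- (M > prune) | t(M > prune)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- nodes
  clusters <- split(nodes, membership)
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, `[`, character(1), 1))]
  membership <- stats::setNames(integer(nn), nodes)
  for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
  structure(list(clusters = unname(clusters), membership = membership,
                 n_iter = iter, converged = converged),
            class = "mcl_partition")
}

#' @export
print.mcl_partition <- function(x, ...) {
  cat("MCL partition:", length(x$clusters), "cluster(s),",
      length(x$membership), "nodes",
      sprintf("(%d iterations, %s)\n", x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  sizes <- lengths(x$clusters)
  cat("cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
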