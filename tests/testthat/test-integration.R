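test_that("enzyme-shift sign table matches the hand truth table", {
  # removes + down => motif accumulates; adds follows the gene's sign
  expect_equal(expected_glycan_shift("removes", -1.30), 1)
  expect_equal(expected_glycan_shift("removes", 1.30), -1)
  expect_equal(expected_glycan_shift("adds", -1.62), -1)
  expect_equal(expected_glycan_shift("adds", 1.62), 1)
  # below the significance floor: no prediction
  expect_equal(expected_glycan_shift("adds", 1.0), 0)
  expect_equal(expected_glycan_shift("removes", -1.19), 0)
  expect_error(expected_glycan_shift("destroys", 1.5), "unknown action")
  expect_error(expected_glycan_shift("adds", 0.5), "\\|fc\\| >= 1")
})

test_that("concordance flags match brute-force enumeration of all 8 cases", {
  catalog <- load_lectin_catalog(data.frame(
    lectin = "Lec1", monosaccharide_class = "Sia",
    motifs = "poly-Sia"))
  for (action in c("adds", "removes")) {
    for (gene_sign in c(1, -1)) {
      for (lectin_sign in c(1, -1)) {
        deggs <- data.frame(symbol = "Enz1", fc = gene_sign * 2)
        actions <- data.frame(symbol = "Enz1", enzyme_class = "GT",
                              motif = "poly-Sia", action = action)
        calls <- data.frame(lectin = "Lec1", fc = lectin_sign * 2,
                            call = if (lectin_sign > 0) "up" else "down")
        rep <- concordance_report(calls, deggs, actions, catalog)
        predicted <- if (action == "adds") gene_sign else -gene_sign
        expect_equal(rep$records$predicted_direction, predicted)
        expect_equal(rep$records$observed_direction, lectin_sign)
        expect_equal(rep$records$concordant, predicted == lectin_sign)
        expect_equal(rep$summary, as.numeric(predicted == lectin_sign))
      }
    }
  }
})

test_that("published calls and fold changes give concordant key motifs", {
  calls <- call_significant_lectins(published_nfi(), 1.2)
  conc <- concordance_report(calls, published_deggs(), packaged_actions(),
                             packaged_catalog())
  rec <- conc$records
  hm <- rec[rec$motif == "high-mannose-branched", ]
  expect_equal(hm$observed_direction, 1)   # ConA up
  expect_equal(hm$predicted_direction, 1)  # mannosidase trimming reduced
  expect_true(hm$concordant)
  sia <- rec[rec$motif == "sialyl-Gal-GalNAc", ]
  expect_equal(sia$observed_direction, -1) # WGA and MAL-I down
  expect_equal(sia$predicted_direction, -1)# St6gal2 down
  expect_true(sia$concordant)
  # motifs with no enzyme or no lectin coverage are unevaluable
  expect_false(rec$evaluable[rec$motif == "poly-Sia"])
  expect_false(rec$evaluable[rec$motif == "beta-Gal"])
})

test_that("empty DEGG set makes every motif unevaluable", {
  calls <- call_significant_lectins(published_nfi(), 1.2)
  conc <- concordance_report(calls,
                             data.frame(symbol = character(0),
                                        fc = numeric(0)),
                             packaged_actions(), packaged_catalog())
  expect_true(all(!conc$records$evaluable))
  expect_true(is.na(conc$summary))
})

test_that("noiseless integrated simulation is fully concordant", {
  # plant enzyme changes, derive lectin fold changes through the action map,
  # then check the concordance summary is exactly 1
  actions <- packaged_actions()
  catalog <- packaged_catalog()
  deggs <- data.frame(symbol = c("Man1a2", "Man2a2", "St6gal2", "B4galnt1"),
                      fc = c(-1.4, -1.4, -1.6, -1.3))
  # implied motif directions: high-mannose +, sialyl -, terminal-GalNAc -
  planted_lectin <- c(ConA = 1.6, WGA = -1.7, "MAL-I" = -1.5,
                      BPL = -1.4, VVA = -1.4, "PTL-I" = -1.3)
  sim <- simulate_lectin_slides(planted_fc = planted_lectin, spot_cv = 0,
                                bg_sd = 0, seed = 2)
  agg <- aggregate_sample(spot_profiles(sim$spots))
  calls <- call_significant_lectins(lectin_fold_changes(agg$group_nfi), 1.2)
  conc <- concordance_report(calls, deggs, actions, catalog)
  expect_equal(conc$summary, 1.0)
})

# exact hypergeometric tail by enumeration over the overlap count
ora_oracle <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

test_that("over-representation p-values equal exact enumeration", {
  ann <- list(term1 = sprintf("g%d", 1:4))
  universe <- sprintf("g%d", 1:20)
  res <- ora_enrichment(sprintf("g%d", 1:5), ann, universe)
  expect_equal(res$pvalue, 16 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 4)

  set.seed(55)
  for (rep in 1:25) {
    N <- sample(8:25, 1)
    universe <- sprintf("u%d", seq_len(N))
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    query <- sample(universe, n)
    term <- sample(universe, K)
    res <- ora_enrichment(query, list(t = term), universe)
    k <- length(intersect(query, term))
    expect_equal(res$pvalue, ora_oracle(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("ORA edge conventions: full query, zero overlap, empty universe", {
  universe <- sprintf("g%d", 1:10)
  ann <- list(t1 = universe[1:4], t2 = universe[5:6])
  full <- ora_enrichment(universe, ann, universe)
  expect_equal(full$pvalue, c(1, 1))
  disjoint <- ora_enrichment(universe[7:10], list(t = universe[1:3]), universe)
  expect_equal(disjoint$k, 0)
  expect_equal(disjoint$pvalue, 1)
  expect_error(ora_enrichment("g1", list(t = "g1"), character(0)),
               "empty universe")
  # term with no gene in universe is skipped
  skipped <- ora_enrichment(universe[1:2],
                            list(t = "absent", s = universe[1:3]), universe)
  expect_equal(skipped$term, "s")
})

test_that("MCL separates modules split by the confidence cutoff", {
  tri <- function(nodes, w) {
    pairs <- utils::combn(nodes, 2)
    data.frame(node_a = pairs[1, ], node_b = pairs[2, ], confidence = w)
  }
  edges <- rbind(tri(c("a1", "a2", "a3"), 0.9), tri(c("b1", "b2", "b3"), 0.9))
  part <- mcl_cluster(edges, cutoff = 0.4)
  expect_length(part$clusters, 2)
  expect_equal(sort(lengths(part$clusters)), c(3, 3))

  single <- mcl_cluster(data.frame(node_a = "x", node_b = "x",
                                   confidence = 1))
  expect_length(single$clusters, 1)

  sim <- simulate_network(modules = c(5, 5), within_w = 0.8,
                          between_w = 0.3, seed = 8)
  part2 <- mcl_cluster(sim$edges, cutoff = 0.4)
  expect_length(part2$clusters, 2)
  member_mod <- sim$truth$membership[names(part2$membership)]
  expect_equal(length(unique(paste(part2$membership, member_mod))), 2)
})

test_that("MCL always yields a partition; cutoffs only split further", {
  set.seed(66)
  for (rep in 1:10) {
    n <- sample(6:14, 1)
    nodes <- sprintf("n%d", seq_len(n))
    pairs <- utils::combn(nodes, 2)
    pick <- runif(ncol(pairs)) < 0.4
    if (!any(pick)) pick[1] <- TRUE
    edges <- data.frame(node_a = pairs[1, pick], node_b = pairs[2, pick],
                        confidence = round(runif(sum(pick)), 2))
    covered <- sort(unique(c(edges$node_a, edges$node_b)))
    p_low <- mcl_cluster(edges, cutoff = 0.2)
    p_high <- mcl_cluster(edges, cutoff = 0.6)
    for (p in list(p_low, p_high)) {
      expect_setequal(unlist(p$clusters), covered)
      expect_equal(sum(lengths(p$clusters)), length(covered))  # disjoint cover
    }
    # nodes separated into different components at the low cutoff stay
    # separated at the high cutoff
    comp_of <- function(edges, cutoff, nodes) {
      keep <- edges$confidence >= cutoff
      g <- igraph::graph_from_data_frame(edges[keep, 1:2], directed = FALSE,
                                         vertices = nodes)
      igraph::components(g)$membership
    }
    c_low <- comp_of(edges, 0.2, covered)
    c_high <- comp_of(edges, 0.6, covered)
    n <- length(covered)
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      if (c_low[i] != c_low[j]) expect_true(c_high[i] != c_high[j])
    }
  }
})

test_that("edges entirely below the cutoff leave every node a singleton", {
  edges <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                      confidence = 0.2)
  part <- mcl_cluster(edges, cutoff = 0.4)
  expect_length(part$clusters, 3)
  expect_true(all(lengths(part$clusters) == 1))
})

test_that("GMT and network readers validate their inputs", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc\tg1\tg2\tg3", "term2\tdesc\tg2\tg4"), gmt)
  ann <- read_gmt(gmt)
  expect_equal(names(ann), c("term1", "term2"))
  expect_equal(ann$term2, c("g2", "g4"))

  net <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tconfidence", "a\tb\t1.4"), net)
  expect_error(read_network_tsv(net), "\\[0, 1\\]")
})
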