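# Interaction-graph construction, direct-link annotation, directed shortest
# paths (with BFS cross-checked against igraph) and connectivity enrichment.

test_that("graph construction filters scores, deduplicates and keeps direction", {
  g <- build_graph(toy_edges())
  # the 0.69-scored functional edge is below the >0.7 cutoff
  expect_false(any(g$edges$gene_a == "A" & g$edges$gene_b == "D"))
  expect_true(any(g$edges$gene_a == "A" & g$edges$gene_b == "B"))

  # boundary: 0.71 kept, 0.70 dropped (high confidence means strictly > 0.7)
  ed <- data.table::data.table(
    gene_a = c("X", "X"), gene_b = c("Y", "Z"), edge_type = "functional",
    directed = 0L, score = c(0.71, 0.70))
  g2 <- build_graph(ed)
  expect_equal(g2$edges$gene_b, "Y")

  # (A,B) and (B,A) undirected duplicates collapse to one edge
  dup <- data.table::data.table(
    gene_a = c("M", "N"), gene_b = c("N", "M"), edge_type = "ppi",
    directed = 0L, score = NA_real_)
  expect_equal(nrow(build_graph(dup)$edges), 1)

  # kinase-substrate direction is preserved
  ks <- build_graph(toy_edges())$edges[edge_type == "kinase_substrate" &
                                         gene_a == "STK11"]
  expect_equal(ks$gene_b, "MARK2")
  expect_equal(ks$directed, 1L)

  bad <- data.table::copy(toy_edges())[6, score := 1.5]
  expect_error(build_graph(bad), "\\[0, 1\\]")
  loop <- data.table::data.table(gene_a = "A", gene_b = "A",
                                 edge_type = "ppi", directed = 0L,
                                 score = NA_real_)
  expect_warning(gl <- build_graph(loop), "self-loop")
  expect_equal(nrow(gl$edges), 0)
})

test_that("direct links match known relationships in either orientation", {
  g <- build_graph(toy_edges())
  ann <- annotate_direct_links(
    data.table::data.table(driver = c("EGFR", "STK11", "MARK2", "EGFR"),
                           target = c("FES", "MARK2", "STK11", "MYC")), g)
  expect_equal(ann[driver == "EGFR" & target == "FES", direct_link], "ppi")
  expect_equal(ann[driver == "STK11", direct_link], "kinase_substrate")
  # orientation is ignored for the annotation
  expect_equal(ann[driver == "MARK2", direct_link], "kinase_substrate")
  expect_equal(ann[driver == "EGFR" & target == "MYC", direct_link], "")
})

test_that("shortest paths respect edge direction and known intermediates", {
  g <- build_graph(toy_edges())
  # two directed kinase-substrate hops: ERBB2 -> CDK1 -> NEK9
  p <- shortest_driver_target_path("ERBB2", "NEK9", g)
  expect_equal(p, c("ERBB2", "CDK1", "NEK9"))
  # regulatory chain STK11 -> MARK2 is one hop; STK11 -> MYC unreachable
  expect_equal(length(shortest_driver_target_path("STK11", "MARK2", g)) - 1, 1)
  expect_null(shortest_driver_target_path("STK11", "MYC", g))
  # directed edges cannot be walked backwards
  expect_null(shortest_driver_target_path("NEK9", "ERBB2", g))
  # trivial and missing endpoints
  expect_equal(shortest_driver_target_path("EGFR", "EGFR", g), "EGFR")
  expect_null(shortest_driver_target_path("EGFR", "NOSUCH", g))
})

test_that("equal-length paths break ties lexicographically", {
  ed <- data.table::data.table(
    gene_a = c("A", "A", "ZB", "CC"), gene_b = c("ZB", "CC", "D", "D"),
    edge_type = "ppi", directed = 0L, score = NA_real_)
  g <- build_graph(ed)
  expect_equal(shortest_driver_target_path("A", "D", g), c("A", "CC", "D"))
})

test_that("BFS path lengths equal the igraph oracle on random typed graphs", {
  withr::with_seed(31, {
    for (rep in 1:8) {
      nodes <- sprintf("N%02d", 1:10)
      ne <- 18
      ed <- data.table::data.table(
        gene_a = sample(nodes, ne, replace = TRUE),
        gene_b = sample(nodes, ne, replace = TRUE),
        edge_type = sample(c("ppi", "kinase_substrate", "regulatory"), ne,
                           replace = TRUE),
        score = NA_real_)
      ed[, directed := as.integer(edge_type != "ppi")]
      ed <- ed[gene_a != gene_b]
      g <- build_graph(ed)
      org <- igraph_path_oracle(g)
      dmat <- igraph::distances(org, mode = "out")
      for (i in 1:12) {
        pair <- sample(g$nodes, 2)
        p <- shortest_driver_target_path(pair[1], pair[2], g)
        d_oracle <- dmat[pair[1], pair[2]]
        if (is.null(p)) {
          expect_true(is.infinite(d_oracle))
        } else {
          expect_equal(length(p) - 1, unname(d_oracle))
        }
      }
    }
  })
})

test_that("one-intermediate counting matches a brute-force all-pairs oracle", {
  ed <- data.table::data.table(
    gene_a = c("D1", "I1", "D2", "I2", "D3", "D4"),
    gene_b = c("I1", "K1", "I2", "K2", "K3", "K4"),
    edge_type = "kinase_substrate", directed = 1L, score = NA_real_)
  g <- build_graph(ed)
  pairs <- data.table::data.table(
    driver = c("D1", "D2", "D3", "D4", "D1"),
    target = c("K1", "K2", "K3", "K4", "K2"))
  ann <- annotate_dependencies(pairs, g)
  res <- count_one_intermediate(ann)
  # D1->K1 and D2->K2 are two-hop, D3/D4 are direct, D1->K2 unreachable
  expect_equal(res$count, 2)
  expect_equal(ann[driver == "D3", path_length], 1L)
  expect_true(is.na(ann[driver == "D1" & target == "K2", path_length]))

  # oracle: igraph distance exactly 2 among pairs without a direct edge
  org <- igraph_path_oracle(g)
  dmat <- igraph::distances(org, mode = "out")
  oracle <- sum(vapply(seq_len(nrow(pairs)), function(i) {
    d <- dmat[pairs$driver[i], pairs$target[i]]
    is.finite(d) && d == 2
  }, logical(1)))
  expect_equal(res$count, oracle)

  # direct link implies path length 1 (the annotation invariant)
  expect_true(all(ann[has_direct_link == TRUE, path_length] == 1L))
})

test_that("connectivity enrichment matches exhaustive enumeration on a 6-node toy", {
  # background of 6 genes; edges form a triangle on A,B,C plus one spur
  ed <- data.table::data.table(
    gene_a = c("A", "A", "B", "D"), gene_b = c("B", "C", "C", "E"),
    edge_type = "functional", directed = 0L, score = 0.9)
  g <- build_graph(ed)
  bg <- c("A", "B", "C", "D", "E", "F")
  res <- connectivity_enrichment(c("A", "B", "C"), g, bg,
                                 n_permutations = 2e4, seed = 5)
  expect_equal(res$observed_edges, 3L)
  # enumeration oracle over all C(6,3) = 20 subsets
  subsets <- combn(bg, 3)
  adj <- matrix(0, 6, 6, dimnames = list(bg, bg))
  adj[cbind(ed$gene_a, ed$gene_b)] <- 1
  adj <- adj + t(adj)
  null_counts <- apply(subsets, 2, function(s) sum(adj[s, s]) / 2)
  p_exact <- mean(null_counts >= 3)
  se <- sqrt(p_exact * (1 - p_exact) / 2e4)
  expect_lt(abs(res$p_empirical - p_exact), 3 * se + 1e-4)
})

test_that("a planted clique is flagged and an independent set is not", {
  genes <- sprintf("G%02d", 1:50)
  ed <- generate_network(genes, background_edge_prob = 0.02,
                         planted_module = genes[1:5], module_edge_prob = 1,
                         seed = 12)
  g <- build_graph(ed)
  res <- connectivity_enrichment(genes[1:5], g, genes,
                                 n_permutations = 1e4, seed = 2)
  expect_lte(res$p_empirical, 0.01)

  # genes picked to carry no mutual edges: p indistinguishable from chance
  adj <- g$edges[edge_type == "functional"]
  indep <- character(0)
  for (cand in rev(genes)) {
    if (!any((adj$gene_a == cand & adj$gene_b %in% indep) |
               (adj$gene_b == cand & adj$gene_a %in% indep))) {
      indep <- c(indep, cand)
    }
    if (length(indep) == 5) break
  }
  res0 <- connectivity_enrichment(indep, g, genes, n_permutations = 5000,
                                  seed = 3)
  expect_equal(res0$observed_edges, 0L)
  expect_gt(res0$p_empirical, 0.5)

  expect_warning(r1 <- connectivity_enrichment(genes[1], g, genes, 100, 1),
                 "set size")
  expect_equal(r1$p_empirical, 1)
  expect_error(connectivity_enrichment("NOTINBG", g, genes, 100, 1),
               "subset of background")
})

test_that("raising the functional score cutoff never adds edges", {
  genes <- sprintf("G%02d", 1:30)
  ed <- generate_network(genes, background_edge_prob = 0.1, seed = 7)
  sizes <- vapply(c(0.5, 0.7, 0.8, 0.9),
                  function(s) nrow(build_graph(ed, string_min_score = s)$edges),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
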