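# Generator contracts: determinism, QC of generated screens, planted-effect
# calibration, alteration frequencies, network structure, dose-response gaps.

test_that("every generator is a pure function of its seed", {
  a <- generate_screen(n_lines = 4, n_histotypes = 2, n_targets = 30,
                       plate_format = 96, seed = 77)
  b <- generate_screen(n_lines = 4, n_histotypes = 2, n_targets = 30,
                       plate_format = 96, seed = 77)
  expect_identical(a$plates, b$plates)
  c <- generate_screen(n_lines = 4, n_histotypes = 2, n_targets = 30,
                       plate_format = 96, seed = 78)
  expect_false(identical(a$plates$signal, c$plates$signal))

  expect_identical(
    generate_alterations(30, c(KRAS = 0.2, TP53 = 0.4), seed = 5),
    generate_alterations(30, c(KRAS = 0.2, TP53 = 0.4), seed = 5))
  expect_identical(generate_network(sprintf("G%d", 1:20), seed = 5),
                   generate_network(sprintf("G%d", 1:20), seed = 5))
  expect_identical(
    generate_dose_response(10, rep(c(TRUE, FALSE), 5), seed = 5),
    generate_dose_response(10, rep(c(TRUE, FALSE), 5), seed = 5))

  # generators leave the caller's RNG stream untouched
  withr::with_seed(1, {
    before <- rnorm(1)
  })
  withr::with_seed(1, {
    invisible(generate_screen(n_lines = 2, n_histotypes = 1, n_targets = 20,
                              plate_format = 96, seed = 9))
    expect_equal(rnorm(1), before)
  })
})

test_that("generated screens pass default QC up to noise_sd = 0.1", {
  for (ns in c(0.05, 0.1)) {
    sim <- generate_screen(n_lines = 4, n_histotypes = 2, n_targets = 100,
                           plate_format = 96, noise_sd = ns, seed = 33)
    sm <- build_screen_matrix(sim$plates, sim$plate_map, sim$plate_lines)
    expect_true(all(sm$qc$passes_qc),
                label = sprintf("all screens pass QC at noise_sd %.2f", ns))
  }
})

test_that("a -5 essential gene is a KGD in every line and tops the frequency ranks", {
  tops <- vapply(1:6, function(s) {
    tr <- simulation_truth(essential_genes = "PLK1")
    sim <- generate_screen(n_lines = 10, n_histotypes = 2, n_targets = 150,
                           truth = tr, plate_format = 384, seed = 200 + s)
    sm <- build_screen_matrix(sim$plates, sim$plate_map, sim$plate_lines)
    k <- call_kgds(sm)
    expect_equal(unname(k$per_gene_frequency["PLK1"]), 10)
    which.max(k$per_gene_frequency) == which(names(k$per_gene_frequency) == "PLK1")
  }, logical(1))
  expect_true(all(tops))
})

test_that("planted Z shifts are calibrated within ten percent", {
  memb <- matrix(0L, 60, 1, dimnames = list(NULL, "MUT"))
  memb[1:30, 1] <- 1L
  tr <- simulation_truth(planted_dependencies = data.frame(
    feature = "MUT", target = "DEPK01", delta_z = -2.5))
  sim <- generate_screen(n_lines = 60, n_histotypes = 3, n_targets = 300,
                         truth = tr, feature_membership = memb, seed = 404)
  sm <- build_screen_matrix(sim$plates, sim$plate_map, sim$plate_lines)
  planted_z <- sm$z[1:30, "DEPK01"]
  # mean over 30 affected lines: tolerance = 10% calibration + sampling error
  expect_lt(abs(mean(planted_z) - (-2.5)),
            0.25 + 3 * sd(planted_z) / sqrt(30))
})

test_that("alteration matrices honor frequencies, exact counts and co-mutation", {
  m <- generate_alterations(117, c(KRAS = 7 / 117, TP53 = 0.4), seed = 10)
  expect_setequal(unique(as.vector(m)), c(0L, 1L))
  # binomial 99.9% bounds around the expected count
  expect_true(abs(sum(m[, "KRAS"]) - 7) < 3.3 * sqrt(7 * (1 - 7 / 117)) + 1)

  me <- generate_alterations(100, c(A = 0.1, B = 0.25), exact = TRUE,
                             seed = 2)
  expect_equal(unname(colSums(me)), c(10, 25))

  mc <- generate_alterations(200, c(A = 0.3, B = 0.3),
                             co_mutation = list(list(pair = c("A", "B"),
                                                     overlap = 1)),
                             seed = 3)
  expect_equal(mc[, "A"], mc[, "B"])

  expect_error(generate_alterations(10, c(A = 0)), "\\(0, 1\\)")
  expect_error(generate_alterations(10, setNames(0.5, "")), "named")
})

test_that("generated networks plant modules, decoys and typed paths as asked", {
  genes <- sprintf("G%02d", 1:40)
  ed <- generate_network(genes, background_edge_prob = 0.03,
                         planted_module = genes[1:5], module_edge_prob = 1,
                         typed_paths = list(list(genes = c("G01", "G07",
                                                           "G09"),
                                                 type = "kinase_substrate",
                                                 directed = 1)),
                         seed = 15)
  # decoy edges (score <= 0.7) vanish after the score filter
  expect_gt(nrow(ed[edge_type == "functional" & score <= 0.7]), 0)
  g <- build_graph(ed)
  expect_false(any(g$edges[edge_type == "functional", score] <= 0.7))
  # the planted clique is fully wired
  mod <- g$edges[edge_type == "functional" &
                   gene_a %in% genes[1:5] & gene_b %in% genes[1:5]]
  expect_equal(nrow(mod), choose(5, 2))
  # the requested directed path exists with length 2
  expect_equal(shortest_driver_target_path("G01", "G09", g),
               c("G01", "G07", "G09"))

  expect_error(generate_network(genes, 0.5, genes[1:3], 0.2),
               "must exceed")
})

test_that("dose-response panels realize the requested AUC gap", {
  mask <- seq_len(120) <= 60
  gaps <- vapply(1:5, function(s) {
    dr <- generate_dose_response(120, sensitive_mask = mask, auc_shift = 0.2,
                                 noise_sd = 0.05, seed = 500 + s)
    aucs <- auc_matrix(dr)[, 1]
    mean(aucs[!mask]) - mean(aucs[mask])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 0.2), 0.05)

  # no planted shift: groups indistinguishable
  dr0 <- generate_dose_response(60, sensitive_mask = rep(FALSE, 60),
                                auc_shift = 0, seed = 9)
  aucs0 <- auc_matrix(dr0)[, 1]
  expect_gt(drug_association(aucs0, seq_len(60) <= 20)$p, 0.05)

  expect_error(generate_dose_response(10, rep(TRUE, 10), auc_shift = 1.2),
               "auc_shift")
})

test_that("a null study yields calibrated false-positive rates downstream", {
  study <- simulate_study("null", seed = 71, n_lines = 30, n_targets = 60,
                          n_histotypes = 3)
  sm <- build_screen_matrix(study$screen$plates, study$screen$plate_map,
                            study$screen$plate_lines)
  af <- filter_testable(alteration_features(study$alterations), 7)
  rec <- run_association_screen(sm, af, n_permutations = 1000, seed = 72)
  rate <- rec[, mean(p_empirical <= 0.05)]
  n <- nrow(rec)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.01)
})
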