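# Screen processing: normalization, replicate summaries, robust Z, QC,
# KGD calling and clustering.

test_that("plate normalization divides by the library median and is scale invariant", {
  tp <- toy_plate(c(2, 4, 6, 8, 10))
  norm <- normalize_plate(tp$records, tp$map)
  lib <- norm[content_kind == "library"][order(well)]
  expect_equal(lib$norm_signal, c(2, 4, 6, 8, 10) / 6)

  # constant plate: everything normalizes to 1
  tpc <- toy_plate(rep(7, 6))
  normc <- normalize_plate(tpc$records, tpc$map)
  expect_true(all(normc[content_kind == "library", norm_signal] == 1))

  # a 10x brighter plate with the same relative pattern normalizes identically
  tp10 <- toy_plate(10 * c(2, 4, 6, 8, 10), plate_id = "P2")
  both <- normalize_plate(rbind(tp$records, tp10$records),
                          rbind(tp$map, tp10$map))
  expect_equal(both[content_kind == "library" & plate_id == "P1",
                    norm_signal][order(both[content_kind == "library" &
                                              plate_id == "P1", well])],
               both[content_kind == "library" & plate_id == "P2",
                    norm_signal][order(both[content_kind == "library" &
                                              plate_id == "P2", well])])
})

test_that("normalization rejects plates without library wells or with zero median", {
  tp <- toy_plate(c(0, 0, 0, 0, 0))
  expect_error(normalize_plate(tp$records, tp$map), "median 0")
  # mostly-control plates are rejected
  tp2 <- toy_plate(c(1, 2), pos = rep(0.1, 4), neg = rep(1, 4))
  expect_error(normalize_plate(tp2$records, tp2$map), "50%")
})

test_that("replicate summarization is the median of available replicates", {
  expect_equal(as.numeric(summarize_replicates(c(0.2, 0.5, 0.9))), 0.5)
  expect_equal(as.numeric(summarize_replicates(c(0.2, 0.9))), 0.55)
  expect_equal(as.numeric(summarize_replicates(0.7)), 0.7)
  expect_equal(attr(summarize_replicates(c(0.2, NA, 0.9)), "n_replicates"), 2L)
  expect_warning(res <- summarize_replicates(c(NA, NA)), "no replicate")
  expect_true(is.na(res))
})

test_that("robust Z matches the hand example and is location-scale invariant", {
  z <- robust_z(c(1, 2, 3, 4, 100), min_values = 5)
  expect_equal(z[5], 97 / 1.4826, tolerance = 1e-9)
  expect_equal(z[3], 0)  # the median scores 0

  withr::with_seed(42, {
    x <- rnorm(50)
    expect_equal(robust_z(3.7 * x + 11), robust_z(x), tolerance = 1e-9)
  })
})

test_that("robust Z output has median 0 and unit robust scale on random screens", {
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- exp(rnorm(200, 0, runif(1, 0.05, 0.5)))
      z <- robust_z(x)
      expect_equal(median(z), 0, tolerance = 1e-9)
      expect_equal(mad(z, constant = 1.4826), 1, tolerance = 1e-9)
    }
  })
  expect_error(robust_z(rep(1, 20)), "degenerate scale")
  expect_error(robust_z(c(1, 2, 3)), ">= 10")
})

test_that("Z'-factor and replicate correlation follow their definitions", {
  pos <- c(0.08, 0.10, 0.12)  # mean 0.1, sd 0.02
  neg <- c(0.95, 1.00, 1.05)  # mean 1.0, sd 0.05
  q <- qc_screen(pos, neg)
  expect_equal(q$zprime, 1 - 3 * (0.02 + 0.05) / 0.9, tolerance = 1e-9)

  # identical replicates correlate perfectly
  withr::with_seed(1, rz <- matrix(rnorm(50), 50, 1)[, c(1, 1)])
  q2 <- qc_screen(pos, neg, rz)
  expect_equal(q2$replicate_correlation, 1)
  expect_true(q2$passes_qc)

  # noiseless controls give the ideal Z' of 1
  q3 <- qc_screen(rep(0.1, 3), rep(1, 3))
  expect_equal(q3$zprime, 1)

  # equal control means leave Z' undefined and the screen failed
  q4 <- qc_screen(rep(1, 3) + c(-0.01, 0, 0.01), rep(1, 3) + c(-0.01, 0, 0.01))
  expect_false(q4$passes_qc)
  expect_match(q4$reason, "undefined")

  expect_error(qc_screen(c(0.1, 0.1), neg), ">= 3")
})

test_that("KGD calling applies Z <= -2 and keeps margins consistent", {
  z <- matrix(c(-3, -1, -3, -3, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("g1", "g2")))
  k <- call_kgds(z)
  expect_equal(unname(k$per_gene_frequency), c(2, 1))
  expect_equal(unname(k$per_line_count), c(1, 2, 0))
  expect_equal(k$summary$mean_per_line, 1)

  # threshold boundary: Z = -2 is a call, Z just above is not
  zb <- matrix(c(-2, -1.999, -2.5, 0), nrow = 2,
               dimnames = list(c("A", "B"), c("g1", "g2")))
  kb <- call_kgds(zb)
  expect_equal(unname(kb$is_kgd[, "g1"]), c(TRUE, FALSE))
  expect_equal(unname(kb$is_kgd[, "g2"]), c(TRUE, FALSE))

  # margin identity on random matrices
  withr::with_seed(11, {
    for (i in 1:10) {
      zr <- matrix(rnorm(20 * 15), 20, 15,
                   dimnames = list(sprintf("L%d", 1:20), sprintf("g%d", 1:15)))
      zr[sample(length(zr), 30)] <- NA
      kr <- call_kgds(zr)
      expect_equal(sum(kr$per_line_count), sum(kr$per_gene_frequency))
      expect_equal(sum(kr$per_line_count), sum(kr$is_kgd))
    }
  })

  zna <- rbind(z, D = c(NA, NA))
  expect_warning(kna <- call_kgds(zna), "all-NA")
  expect_equal(nrow(kna$is_kgd), 3)
})

test_that("clustering separates planted pairs and honors the distance definition", {
  withr::with_seed(5, {
    base1 <- rnorm(60); base2 <- rnorm(60)
    z <- rbind(A1 = base1 + rnorm(60, 0, 0.1),
               A2 = base1 + rnorm(60, 0, 0.1),
               B1 = base2 + rnorm(60, 0, 0.1),
               B2 = base2 + rnorm(60, 0, 0.1))
    colnames(z) <- sprintf("g%d", 1:60)
    cl <- cluster_cell_lines(z, var_quantile = 0)
    m <- cl$hclust$merge
    # the first two merges join the within-pair leaves
    first_pairs <- lapply(1:2, function(i) sort(rownames(z)[-m[i, ]]))
    expect_setequal(vapply(first_pairs, paste, "", collapse = "+"),
                    c("A1+A2", "B1+B2"))
  })

  # identical lines merge at distance 0; anticorrelated lines sit at 2
  z2 <- rbind(A = c(1, -1, 2, -2, 0.5), B = c(1, -1, 2, -2, 0.5),
              C = -c(1, -1, 2, -2, 0.5))
  colnames(z2) <- sprintf("g%d", 1:5)
  cl2 <- cluster_cell_lines(z2, var_quantile = 0)
  dm <- as.matrix(cl2$dist)
  expect_equal(dm["A", "B"], 0, tolerance = 1e-12)
  expect_equal(dm["A", "C"], 2, tolerance = 1e-12)

  zc <- rbind(z2, D = rep(1, 5))
  expect_error(cluster_cell_lines(zc, var_quantile = 0), "D")
  expect_error(cluster_cell_lines(z2[1:2, ], var_quantile = 0), ">= 3")
})

test_that("variance filter keeps the top 20% most variable targets including ties", {
  withr::with_seed(9, {
    z <- matrix(rnorm(10 * 50), 10, 50,
                dimnames = list(sprintf("L%d", 1:10), sprintf("g%d", 1:50)))
    z[, 1:40] <- z[, 1:40] * 0.1  # low variance block
    cl <- cluster_cell_lines(z, var_quantile = 0.8)
    expect_length(cl$targets_used, 10)
    expect_setequal(cl$targets_used, sprintf("g%d", 41:50))
  })
})

test_that("multiplying one plate's raw signals by a constant leaves Z unchanged", {
  sim <- generate_screen(n_lines = 3, n_histotypes = 2, n_targets = 40,
                         plate_format = 96, seed = 21)
  sm1 <- build_screen_matrix(sim$plates, sim$plate_map, sim$plate_lines)
  scaled <- data.table::copy(sim$plates)
  one_plate <- scaled$plate_id[1]
  scaled[plate_id == one_plate, signal := signal * 5]
  sm2 <- build_screen_matrix(scaled, sim$plate_map, sim$plate_lines)
  expect_equal(sm1$z, sm2$z, tolerance = 1e-12)
})
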