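# Shared fixtures, built in code at test time.

# one plate of library wells with given signals plus a few control wells
toy_plate <- function(signals, plate_id = "P1", replicate = 1L,
                      pos = c(0.1, 0.1) * stats::median(signals),
                      neg = rep(stats::median(signals), 2)) {
  n <- length(signals)
  lib_wells <- sprintf("A%02d", seq_len(n))
  ctrl_wells <- sprintf("B%02d", seq_len(length(pos) + length(neg)))
  records <- data.table::data.table(
    plate_id = plate_id, replicate = replicate,
    well = c(lib_wells, ctrl_wells),
    signal = c(signals, pos, neg))
  map <- data.table::data.table(
    plate_id = plate_id,
    well = c(lib_wells, ctrl_wells),
    content_kind = c(rep("library", n),
                     rep("positive_control", length(pos)),
                     rep("negative_control", length(neg))),
    target_gene = c(sprintf("G%03d", seq_len(n)),
                    rep(NA_character_, length(pos) + length(neg))))
  list(records = records, map = map)
}

# small typed edge table exercising every edge class
toy_edges <- function() {
  data.table::data.table(
    gene_a = c("EGFR", "STK11", "MYC",  "ERBB2", "CDK1", "A",  "B",  "C",
               "A"),
    gene_b = c("FES",  "MARK2", "SRP72", "CDK1",  "NEK9", "B",  "C",  "D",
               "D"),
    edge_type = c("ppi", "kinase_substrate", "regulatory",
                  "kinase_substrate", "kinase_substrate",
                  "functional", "functional", "functional", "functional"),
    directed = c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    score = c(NA, NA, NA, NA, NA, 0.9, 0.8, 0.95, 0.69))
}

# directed igraph equivalent of the package's path-traversal rules,
# used as an independent shortest-path oracle
igraph_path_oracle <- function(graph) {
  ed <- graph$edges[edge_type %in% c("ppi", "kinase_substrate", "regulatory")]
  fwd <- ed[, .(gene_a, gene_b)]
  back <- ed[directed == 0, .(gene_a = gene_b, gene_b = gene_a)]
  el <- unique(rbind(fwd, back))
  igraph::graph_from_data_frame(el, directed = TRUE,
                                vertices = graph$nodes)
}

# quick z matrix with one planted (feature, target) shift
planted_z_matrix <- function(n_lines = 40, n_targets = 30, n_mut = 10,
                             delta = -2.5, seed = 1) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n_lines * n_targets), n_lines, n_targets,
                dimnames = list(sprintf("L%02d", 1:n_lines),
                                sprintf("T%02d", 1:n_targets)))
    mut <- seq_len(n_mut)
    z[mut, 1] <- z[mut, 1] + delta
    list(z = z, mask = seq_len(n_lines) %in% mut, target = "T01")
  })
}
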