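#!/usr/bin/env Rscript
# Stage 4: interaction-network context for driver dependencies.
#
# Nominally significant driver dependencies are annotated with known direct
# molecular links (PPI / kinase-substrate / regulatory, either orientation);
# pairs without a direct link get a shortest directed path; and each
# driver's dependency set is tested for excess within-set connectivity on
# the high-confidence functional network (score > 0.7) against uniformly
# drawn same-size gene sets from the screened background.

suppressMessages({
  library(kinasedep)
  library(data.table)
})

inp <- "results/01_inputs"; out <- "results/04_network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20160303

z <- read_matrix_tsv("results/02_screen/zscores.tsv")
rec <- read_association_table("results/03_associations/associations.tsv")
graph <- build_graph(read_edge_table(file.path(inp, "edges.tsv")))
print(graph)

pairs <- unique(rec[feature_kind == "driver_gene" &
                      scope == "all_histotypes" &
                      p_empirical <= 0.05 & delta_median < 0,
                    .(driver = feature, target = target_gene)])
ann <- annotate_dependencies(pairs, graph)
n_direct <- ann[, sum(has_direct_link)]
one_int <- count_one_intermediate(ann)
cat(sprintf("%d driver dependencies: %d with a direct link, %d more reachable via one intermediate\n",
            nrow(ann), n_direct, one_int$count))
fwrite(ann, file.path(out, "network_annotations.tsv"), sep = "\t")

background <- intersect(colnames(z), graph$nodes)
conn <- rbindlist(lapply(unique(pairs$driver), function(drv) {
  gs <- intersect(pairs[driver == drv, target], background)
  if (length(gs) < 2) return(NULL)
  ce <- connectivity_enrichment(gs, graph, background,
                                n_permutations = 1e4,
                                seed = seed + match(drv, unique(pairs$driver)))
  data.table(driver = drv, set_size = ce$set_size,
             observed_edges = ce$observed_edges, null_mean = ce$null_mean,
             p = ce$p_empirical)
}))
if (nrow(conn)) {
  cat(sprintf("%d of %d drivers have dependency sets more connected than chance (p <= 0.05)\n",
              conn[, sum(p <= 0.05)], nrow(conn)))
  fwrite(conn, file.path(out, "connectivity.tsv"), sep = "\t")
}
export_sif(graph, file.path(out, "network.sif"))
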