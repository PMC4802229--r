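#!/usr/bin/env Rscript
# Stage 2: raw plates -> robust Z matrix, QC report, KGD calls, clustering.
#
# Each library well is normalized by its plate's library-median signal,
# replicates are summarized by their median, and each screen is standardized
# with a robust Z score over library targets. Screens must pass a Z'-factor
# and replicate-correlation filter. A (line, target) pair with Z <= -2 is
# called a kinase genetic dependency (KGD).

suppressMessages({
  library(kinasedep)
  library(data.table)
})

inp <- "results/01_inputs"; out <- "results/02_screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pd <- read_plate_data(file.path(inp, "plates.tsv"),
                      file.path(inp, "plate_map.tsv"))
plate_lines <- fread(file.path(inp, "plate_lines.tsv"))
sm <- build_screen_matrix(pd$records, pd$map, plate_lines)
cat(sprintf("%d of %d screens pass QC (median Z' = %.2f, median replicate r = %.2f)\n",
            sum(sm$qc$passes_qc), nrow(sm$qc), median(sm$qc$zprime),
            median(sm$qc$replicate_correlation)))

sm$z <- sm$z[sm$qc[passes_qc == TRUE, cell_line], , drop = FALSE]
write_matrix_tsv(sm$z, file.path(out, "zscores.tsv"))
fwrite(sm$qc, file.path(out, "qc_report.tsv"), sep = "\t")

k <- call_kgds(sm)
print(k)
write_matrix_tsv(1 * k$is_kgd, file.path(out, "kgd_calls.tsv"))

cl <- cluster_cell_lines(sm)
export_tree_newick(cl, file.path(out, "dendrogram.newick"))
cat(sprintf("Clustered %d lines on the %d most variable targets\n",
            nrow(sm$z), length(cl$targets_used)))
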