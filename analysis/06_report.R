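#!/usr/bin/env Rscript
# Stage 6: headline descriptive statistics of the run, checked against the
# simulation's ground truth.

suppressMessages({
  library(kinasedep)
  library(data.table)
})

calls <- read_matrix_tsv("results/02_screen/kgd_calls.tsv") == 1
per_gene <- colSums(calls); per_line <- rowSums(calls)
cat(sprintf("Targets that are a KGD in >=1 / >=5 / >=10 lines: %.0f%% / %.0f%% / %.0f%%\n",
            100 * mean(per_gene >= 1), 100 * mean(per_gene >= 5),
            100 * mean(per_gene >= 10)))
cat(sprintf("Mean KGDs per line: %.1f\n", mean(per_line)))

rec <- read_association_table("results/03_associations/associations.tsv")
truth <- fread("results/01_inputs/truth.tsv")
sig <- rec[significant == TRUE]
recov <- truth[sig, on = c(feature = "feature", target = "target_gene"),
               nomatch = 0]
cat(sprintf("Planted dependencies recovered as significant: %d of %d\n",
            nrow(unique(recov[, .(feature, target)])), nrow(truth)))
counts <- rec[, .(tests = .N, significant = sum(significant)),
              by = .(feature_kind, scope = scope != "all_histotypes")]
print(counts)
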