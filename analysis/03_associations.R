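#!/usr/bin/env Rscript
# Stage 3: median-permutation association tests.
#
# For every (feature, siRNA target) pair, the difference between the median
# Z of the feature's lines and the median Z of the remaining lines is
# compared against a label-permutation null (one-sided toward
# sensitization). BH FDR is applied per feature: 0.1 for histotype
# contrasts, 0.5 for the driver focus set (an intentionally permissive
# hypothesis-generating threshold). Driver tests are repeated within each
# histotype, and dependencies recurring in >= 2 histotypes are collected.

suppressMessages({
  library(kinasedep)
  library(data.table)
})

inp <- "results/01_inputs"; out <- "results/03_associations"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20160303
n_perm <- 2000  # desk-scale; full runs use 10^6

z <- read_matrix_tsv("results/02_screen/zscores.tsv")
ann <- fread(file.path(inp, "histotypes.tsv"))[cell_line %in% rownames(z)]
alt <- read_matrix_tsv(file.path(inp, "alterations.tsv"))[rownames(z), ]

hf <- filter_testable(histotype_features(ann), 2)
hist_rec <- run_association_screen(z, hf, n_permutations = n_perm,
                                   seed = seed, fdr = 0.1)
cat(sprintf("Histotype scope: %d tests, %d dependencies at FDR 0.1\n",
            nrow(hist_rec), hist_rec[, sum(significant)]))

df <- filter_testable(alteration_features(alt), 7)
drv_rec <- run_association_screen(z, df, n_permutations = n_perm,
                                  seed = seed, fdr = 0.5)
cat(sprintf("Driver scope (%d drivers altered in >= 7 lines): %d dependencies at FDR 0.5\n",
            ncol(df$membership), drv_rec[, sum(significant)]))

per_h <- list()
for (h in unique(ann$histotype)) {
  lines_h <- ann[histotype == h, cell_line]
  if (length(lines_h) < 6) next
  dh <- filter_testable(scope_restrict(alteration_features(alt), lines_h,
                                       sprintf("histotype:%s", h)), 3)
  if (ncol(dh$membership) == 0) next
  per_h[[h]] <- suppressMessages(
    run_association_screen(z, dh, n_permutations = n_perm, seed = seed,
                           fdr = 0.5))
}
within_rec <- rbindlist(per_h)
cat(sprintf("Within-histotype driver scope: %d tests over %d histotypes\n",
            nrow(within_rec), length(per_h)))

recur <- recurrent_dependencies(within_rec)
cat(sprintf("%d driver dependencies recur in >= 2 histotypes\n", nrow(recur)))
fwrite(recur, file.path(out, "recurrent_dependencies.tsv"), sep = "\t")

pws <- read_gmt(file.path(inp, "pathways.gmt"))
grp <- suppressWarnings(pathway_or_grouping(alt, pws))
pf <- filter_testable(pathway_features(grp), 7)
pw_rec <- run_association_screen(z, pf, n_permutations = n_perm,
                                 seed = seed, fdr = 0.5)
hits <- pw_rec[significant == TRUE]
better <- rbindlist(lapply(seq_len(nrow(hits)), function(i) {
  g <- grp[[hits$feature[i]]]
  r <- pathway_better_than_members(z[, hits$target_gene[i]],
                                   g$derived_membership[rownames(z)],
                                   g$member_memberships[rownames(z), ,
                                                        drop = FALSE])
  data.table(feature = hits$feature[i], target_gene = hits$target_gene[i],
             rho_pathway = r$rho_pathway, is_better = r$is_better)
}))
cat(sprintf("Pathway scope: %d dependencies at FDR 0.5, %d where the pathway beats every member gene\n",
            nrow(hits), if (nrow(better)) better[, sum(is_better)] else 0))
fwrite(better, file.path(out, "pathway_better_predictor.tsv"), sep = "\t")

write_association_table(rbindlist(list(hist_rec, drv_rec, within_rec,
                                       pw_rec), fill = TRUE),
                        file.path(out, "associations.tsv"))
cat(sprintf("Association records written under %s\n", out))
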