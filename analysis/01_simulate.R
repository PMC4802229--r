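#!/usr/bin/env Rscript
# Stage 1: generate the simulated study panel.
#
# Emulates the screening campaign's structure: 117 tumor cell lines from 10
# histotypes screened in triplicate 384-well plates against a 714-gene
# kinome library (siPLK1 positive and siCON-style negative controls on every
# plate), a 21-driver binary alteration matrix, pathway definitions, a typed
# interaction network with a planted dense module, and an 8-dose FGFR-
# inhibitor-like sensitivity panel with an osteosarcoma-selective effect.
# Ground truth (which dependencies are real) is recorded alongside.

suppressMessages(library(kinasedep))

seed <- 20160303
out <- "results/01_inputs"

study <- simulate_study("fullpanel", seed = seed)
write_study_inputs(study, out)

truth <- study$truth$planted_dependencies
cat(sprintf("Simulated %d cell lines x %d targets (seed %d)\n",
            nrow(study$screen$annotations), length(study$screen$targets),
            seed))
cat(sprintf("Planted: %d dependencies (%s), %d essential genes, a %d-gene functional module, 1 drug effect\n",
            nrow(truth), paste(unique(truth$feature), collapse = ", "),
            length(study$truth$essential_genes),
            length(study$truth$planted_network_module)))
cat(sprintf("Inputs written under %s\n", out))
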