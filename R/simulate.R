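# Synthetic-data generators with known ground truth: plate-arrayed screens,
# binary alteration matrices, typed interaction networks and dose-response
# panels. Every generator is a pure function of its seed and parameters (the
# caller's RNG stream is left untouched).
#
# Viability noise is multiplicative log-normal (plate screens are intensity
# data). Planted dependencies multiply the affected (line, target)
# viabilities by (1 + delta_z * kappa), where kappa is the analytic
# 1.4826*MAD of summarized normalized viability, so the realized robust Z
# shift matches the requested delta_z.

# default histotype panel (uneven sizes mirroring a 117-line pan-cancer set)
HISTOTYPES <- c("breast", "ovarian", "lung", "osteosarcoma", "esophageal",
                "pancreatic", "headneck", "cervical", "cns", "endometrioid")
HISTOTYPE_WEIGHTS <- c(0.29, 0.17, 0.13, 0.10, 0.09, 0.06, 0.05, 0.04,
                       0.04, 0.03)

# variance deflation of the median of k iid normals (k = 1, 2, 3)
MEDIAN_VAR_FACTOR <- c(1, 0.5, 0.4487)

#' Ground-truth manifest for a simulation
#'
#' @param planted_dependencies data.frame/data.table with columns `feature`,
#'   `target`, `delta_z` (negative = sensitization) or NULL.
#' @param essential_genes targets depleted in every line (robust Z shift
#'   `essential_delta`).
#' @param planted_network_module gene set to embed as a dense module in
#'   generated networks.
#' @param planted_drug_effect list with `drug`, `feature`, `auc_shift`, or
#'   NULL.
#' @param essential_delta Z shift applied to essential genes (default -5).
#' @param seed integer.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(planted_dependencies = NULL,
                             essential_genes = character(),
                             planted_network_module = character(),
                             planted_drug_effect = NULL,
                             essential_delta = -5, seed = 1L) {
  if (!is.null(planted_dependencies)) {
    planted_dependencies <- data.table::as.data.table(planted_dependencies)
    require_columns(planted_dependencies, c("feature", "target", "delta_z"),
                    "planted_dependencies")
  }
  structure(list(planted_dependencies = planted_dependencies,
                 essential_genes = toupper(essential_genes),
                 planted_network_module = toupper(planted_network_module),
                 planted_drug_effect = planted_drug_effect,
                 essential_delta = essential_delta,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

# deterministic uneven histotype assignment for n lines
assign_histotypes <- function(n_lines, n_histotypes) {
  stopifnot(n_histotypes >= 1, n_histotypes <= length(HISTOTYPES))
  w <- HISTOTYPE_WEIGHTS[seq_len(n_histotypes)]
  counts <- diff(c(0, round(cumsum(w / sum(w)) * n_lines)))
  rep(HISTOTYPES[seq_len(n_histotypes)], counts)
}

# plate layout for one plate slot set: control wells evenly spread, library
# wells filled row-major, leftovers empty
plate_layouts <- function(n_targets, plate_format, targets) {
  if (plate_format == 384) {
    rows <- LETTERS[1:16]; cols <- 1:24
    ctrl_kinds <- rep(c("positive_control", "negative_control"), c(8, 16))
  } else if (plate_format == 96) {
    rows <- LETTERS[1:8]; cols <- 1:12
    ctrl_kinds <- rep(c("positive_control", "negative_control"), c(6, 10))
  } else {
    stop_format("plate_format must be 96 or 384")
  }
  wells <- as.vector(t(outer(rows, cols, function(r, c) sprintf("%s%02d", r, c))))
  n_wells <- length(wells)
  n_ctrl <- length(ctrl_kinds)
  ctrl_idx <- unique(round(seq(1, n_wells, length.out = n_ctrl)))
  stopifnot(length(ctrl_idx) == n_ctrl)
  capacity <- n_wells - n_ctrl
  n_plates <- ceiling(n_targets / capacity)
  layout <- vector("list", n_plates)
  for (k in seq_len(n_plates)) {
    kind <- rep("library", n_wells)
    kind[ctrl_idx] <- ctrl_kinds
    tg <- rep(NA_character_, n_wells)
    slot_targets <- targets[((k - 1) * capacity + 1):min(k * capacity, n_targets)]
    lib_idx <- which(kind == "library")
    tg[lib_idx[seq_along(slot_targets)]] <- slot_targets
    kind[kind == "library" & is.na(tg)] <- "empty"
    lay <- data.table::data.table(
      slot = sprintf("p%d", k), well = wells, content_kind = kind,
      target_gene = tg)
    # a sparsely used final plate keeps a few sentinel empty wells, not
    # hundreds (library wells must dominate each plate)
    empty_idx <- which(lay$content_kind == "empty")
    if (length(empty_idx) > 4) lay <- lay[-empty_idx[-(1:4)]]
    layout[[k]] <- lay
  }
  data.table::rbindlist(layout)
}

#' Generate a plate-arrayed siRNA viability screen with known truth
#'
#' Emulates triplicate 384-well (or 96-well) screens: log-normal well
#' signals with per-(plate, replicate) multiplicative plate effects, siPLK1
#' positive-control wells at ~10% of negative-control signal, per-line
#' dependency structure, and planted histotype-/genotype-associated
#' sensitivity shifts of the requested robust-Z effect size.
#'
#' @param n_lines,n_histotypes,n_targets panel shape (defaults mirror the
#'   full study conditions: 117 lines, 10 histotypes, 714 targets).
#' @param plate_format 384 (default) or 96.
#' @param truth [simulation_truth()]; planted features must be histotype
#'   names or columns of `feature_membership`.
#' @param noise_sd log-scale replicate noise (default 0.05; screens pass
#'   default QC up to ~0.1).
#' @param bio_sd log-scale biological spread of per-(line, target) effects
#'   (default 0.18).
#' @param n_replicates screens per line (default 3).
#' @param feature_membership optional binary matrix (cell line x feature)
#'   giving the altered lines of genotype features named in the truth.
#' @param seed integer seed; output is bit-identical for equal seeds.
#' @return list with `plates` (PlateRecord data.table), `plate_map`,
#'   `plate_lines`, `annotations`, `truth`, `kappa` (the analytic Z scale)
#'   and `params`.
#' @export
generate_screen <- function(n_lines = 117, n_histotypes = 10, n_targets = 714,
                            plate_format = 384,
                            truth = simulation_truth(),
                            noise_sd = 0.05, bio_sd = 0.18, n_replicates = 3,
                            feature_membership = NULL, seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  lines <- sprintf("LINE%03d", seq_len(n_lines))
  histo <- assign_histotypes(n_lines, n_histotypes)
  if (!is.null(feature_membership)) {
    stopifnot(is.matrix(feature_membership),
              nrow(feature_membership) == n_lines)
    rownames(feature_membership) <- lines
  }

  targets <- sprintf("KIN%04d", seq_len(n_targets))
  special <- unique(c(truth$essential_genes,
                      if (!is.null(truth$planted_dependencies))
                        toupper(truth$planted_dependencies$target)))
  special <- setdiff(special, targets)
  if (length(special) > n_targets) {
    stop_format("generate_screen: more planted targets than library targets")
  }
  targets[seq_along(special)] <- special

  # resolve planted features to line masks
  feature_lines <- function(f) {
    if (f %in% histo) return(lines[histo == f])
    if (!is.null(feature_membership) && f %in% colnames(feature_membership)) {
      return(lines[feature_membership[, f] == 1])
    }
    stop_format("generate_screen: planted feature '%s' is neither a histotype nor a feature_membership column", f)
  }

  kappa <- sqrt(bio_sd^2 +
                  MEDIAN_VAR_FACTOR[min(n_replicates, 3)] * noise_sd^2)

  with_seed(seed, {
    vmat <- exp(matrix(rnorm(n_lines * n_targets, 0, bio_sd),
                       n_lines, n_targets, dimnames = list(lines, targets)))
    plant <- function(affected_lines, target, delta) {
      if (!target %in% targets) {
        stop_format("generate_screen: planted target '%s' not in library", target)
      }
      vmat[affected_lines, target] <<-
        vmat[affected_lines, target] * max(1 + delta * kappa, 0.02)
    }
    if (!is.null(truth$planted_dependencies)) {
      pd <- truth$planted_dependencies
      for (i in seq_len(nrow(pd))) {
        plant(feature_lines(pd$feature[i]), toupper(pd$target[i]),
              pd$delta_z[i])
      }
    }
    for (g in truth$essential_genes) plant(lines, g, truth$essential_delta)

    layout <- plate_layouts(n_targets, plate_format, targets)
    n_lay <- nrow(layout)
    rec <- layout[rep(seq_len(n_lay), times = n_lines * n_replicates)]
    rec[, cell_line := rep(rep(lines, each = n_lay), times = n_replicates)]
    rec[, replicate := rep(seq_len(n_replicates), each = n_lay * n_lines)]
    rec[, plate_id := paste(cell_line, slot, sep = "_")]
    rec[, plate_eff := exp(rnorm(1, 0, 0.15)), by = .(plate_id, replicate)]
    rec[, noise := exp(rnorm(.N, 0, noise_sd))]
    base <- 1000
    rec[, signal := base * plate_eff * noise]
    rec[content_kind == "library",
        signal := signal * vmat[cbind(cell_line, target_gene)]]
    rec[content_kind == "positive_control", signal := signal * 0.1]
    rec[content_kind == "empty", signal := signal * 0.02]

    plate_map <- unique(rec[, .(plate_id, well, content_kind, target_gene)])
    plate_lines <- unique(rec[, .(plate_id, cell_line)])
    list(
      plates = rec[, .(plate_id, replicate, well, signal)],
      plate_map = plate_map,
      plate_lines = plate_lines,
      annotations = data.table::data.table(cell_line = lines,
                                           histotype = histo,
                                           passes_qc = TRUE),
      truth = truth, kappa = kappa, targets = targets,
      params = list(n_lines = n_lines, n_histotypes = n_histotypes,
                    n_targets = n_targets, plate_format = plate_format,
                    noise_sd = noise_sd, bio_sd = bio_sd,
                    n_replicates = n_replicates, seed = seed))
  })
}

#' Generate a sparse binary alteration matrix
#'
#' Independent Bernoulli columns at the requested per-driver frequencies;
#' optional co-mutation structure copies a fraction of one driver's mutant
#' calls into another.
#'
#' @param n_lines number of cell lines.
#' @param driver_freqs named numeric vector, gene -> mutation frequency in
#'   (0, 1).
#' @param co_mutation NULL, or a list of `list(pair = c(geneA, geneB),
#'   overlap = f)` entries: a fraction `f` of geneB's calls are copied from
#'   geneA.
#' @param line_names optional cell-line names (default LINE001...).
#' @param exact if TRUE, each driver gets exactly `round(f * n_lines)` mutant
#'   lines at random positions (a designed panel); if FALSE (default),
#'   independent Bernoulli draws.
#' @param seed integer seed.
#' @return binary matrix, cell lines x drivers.
#' @export
generate_alterations <- function(n_lines, driver_freqs, co_mutation = NULL,
                                 line_names = NULL, exact = FALSE,
                                 seed = 1L) {
  if (is.null(names(driver_freqs)) || any(!nzchar(names(driver_freqs)))) {
    stop_format("generate_alterations: driver_freqs must be named by gene")
  }
  if (any(driver_freqs <= 0 | driver_freqs >= 1)) {
    stop_format("generate_alterations: frequencies must lie strictly in (0, 1)")
  }
  lines <- line_names %||% sprintf("LINE%03d", seq_len(n_lines))
  with_seed(seed, {
    m <- sapply(driver_freqs, function(f) {
      if (exact) {
        v <- integer(n_lines)
        v[sample(n_lines, max(1, round(f * n_lines)))] <- 1L
        v
      } else {
        rbinom(n_lines, 1, f)
      }
    })
    m <- matrix(m, nrow = n_lines,
                dimnames = list(lines, toupper(names(driver_freqs))))
    if (!is.null(co_mutation)) {
      for (cm in co_mutation) {
        a <- toupper(cm$pair[1]); b <- toupper(cm$pair[2])
        copy <- runif(n_lines) < cm$overlap
        m[copy, b] <- m[copy, a]
      }
    }
    m
  })
}

#' Generate a typed interaction network with a planted dense module
#'
#' Erdős–Rényi background over the gene universe plus a denser planted
#' module; kept functional edges carry scores ~ Uniform(0.71, 1), decoy
#' functional edges (discarded by the score > 0.7 filter) carry scores
#' <= 0.7. Optional typed directed paths (ppi / kinase_substrate /
#' regulatory) are emitted verbatim.
#'
#' @param genes character gene universe.
#' @param background_edge_prob background edge probability.
#' @param planted_module gene subset wired at `module_edge_prob`.
#' @param module_edge_prob within-module edge probability (must exceed the
#'   background probability).
#' @param decoy_frac decoy (sub-threshold) edges as a fraction of kept edges.
#' @param typed_paths list of `list(genes = c(...), type = , directed = 1)`
#'   entries; consecutive genes become edges.
#' @param seed integer seed.
#' @return edge data.table (gene_a, gene_b, edge_type, directed, score).
#' @export
generate_network <- function(genes, background_edge_prob = 0.05,
                             planted_module = NULL, module_edge_prob = 0.9,
                             decoy_frac = 0.2, typed_paths = NULL,
                             seed = 1L) {
  genes <- unique(toupper(genes))
  planted_module <- toupper(planted_module %||% character())
  if (!all(planted_module %in% genes)) {
    stop_format("generate_network: planted module must be a subset of the gene universe")
  }
  if (length(planted_module) > 0 && module_edge_prob <= background_edge_prob) {
    stop_format("generate_network: module_edge_prob must exceed background_edge_prob")
  }
  with_seed(seed, {
    pairs <- t(combn(genes, 2))
    in_module <- pairs[, 1] %in% planted_module & pairs[, 2] %in% planted_module
    prob <- ifelse(in_module, module_edge_prob, background_edge_prob)
    keep <- runif(nrow(pairs)) < prob
    kept <- pairs[keep, , drop = FALSE]
    edges <- data.table::data.table(
      gene_a = kept[, 1], gene_b = kept[, 2], edge_type = "functional",
      directed = 0L, score = runif(nrow(kept), 0.71, 1))
    nonedges <- pairs[!keep, , drop = FALSE]
    n_decoy <- min(round(decoy_frac * nrow(kept)), nrow(nonedges))
    if (n_decoy > 0) {
      di <- sample(nrow(nonedges), n_decoy)
      edges <- rbind(edges, data.table::data.table(
        gene_a = nonedges[di, 1], gene_b = nonedges[di, 2],
        edge_type = "functional", directed = 0L,
        score = runif(n_decoy, 0.3, 0.7)))
    }
    if (!is.null(typed_paths)) {
      for (tp in typed_paths) {
        g <- toupper(tp$genes)
        edges <- rbind(edges, data.table::data.table(
          gene_a = g[-length(g)], gene_b = g[-1],
          edge_type = tp$type %||% "kinase_substrate",
          directed = as.integer(tp$directed %||% 1L), score = NA_real_))
      }
    }
    edges[]
  })
}

# normalized AUC of the noiseless hill curve at a given log10 IC50
noiseless_auc <- function(lic50, ldoses, hill) {
  v <- 1 / (1 + 10^((ldoses - lic50) * hill))
  pracma::trapz(ldoses, v) / (max(ldoses) - min(ldoses))
}

#' Generate a dose-response drug sensitivity panel
#'
#' Sigmoidal (Hill) viability curves over a log-spaced 8-point dose grid;
#' sensitive lines' IC50 is shifted to lower dose so that the noiseless mean
#' AUC difference between groups equals `auc_shift` (solved numerically).
#'
#' @param n_lines number of cell lines.
#' @param sensitive_mask logical vector marking the sensitive group.
#' @param auc_shift requested mean AUC gap in (0, 1) (0 = no planted effect).
#' @param n_doses dose points (default 8).
#' @param doses concentration grid (default 8 log-spaced points,
#'   10^-3 .. 10^0.5 uM).
#' @param noise_sd additive viability noise per well (default 0.05).
#' @param ic50_log_sd per-line log10 IC50 spread (default 0.35, giving an
#'   AUC spread of ~0.1 on this grid).
#' @param hill Hill slope (default 1.5).
#' @param drug drug label.
#' @param line_names optional cell-line names.
#' @param seed integer seed.
#' @return long data.table (cell_line, drug, concentration, viability) with
#'   attribute `truth` (the IC50 centers and requested shift).
#' @export
generate_dose_response <- function(n_lines, sensitive_mask, auc_shift = 0.2,
                                   n_doses = 8,
                                   doses = 10^seq(-3, 0.5,
                                                  length.out = n_doses),
                                   noise_sd = 0.05, ic50_log_sd = 0.35,
                                   hill = 1.5, drug = "DRUG1",
                                   line_names = NULL, seed = 1L) {
  stopifnot(length(sensitive_mask) == n_lines)
  if (auc_shift < 0 || auc_shift >= 1) {
    stop_format("generate_dose_response: auc_shift must lie in [0, 1)")
  }
  lines <- line_names %||% sprintf("LINE%03d", seq_len(n_lines))
  ld <- log10(doses)
  center_res <- max(ld) + 0.5
  auc_res <- noiseless_auc(center_res, ld, hill)
  center_sens <- center_res
  if (auc_shift > 0) {
    lo <- min(ld) - 3
    if (auc_res - noiseless_auc(lo, ld, hill) < auc_shift) {
      stop_format("generate_dose_response: requested auc_shift %.2f not attainable on this grid", auc_shift)
    }
    center_sens <- uniroot(
      function(l) auc_res - noiseless_auc(l, ld, hill) - auc_shift,
      interval = c(lo, center_res))$root
  }
  with_seed(seed, {
    lic50 <- ifelse(sensitive_mask, center_sens, center_res) +
      rnorm(n_lines, 0, ic50_log_sd)
    grid <- data.table::CJ(cell_line = lines, concentration = doses,
                           sorted = FALSE)
    grid[, drug := drug]
    l50 <- setNames(lic50, lines)
    grid[, viability := 1 / (1 + 10^((log10(concentration) - l50[cell_line]) * hill)) +
           rnorm(.N, 0, noise_sd)]
    grid[, viability := pmin(pmax(viability, 0), 1.5)]
    out <- grid[, .(cell_line, drug, concentration, viability)]
    data.table::setattr(out, "truth",
                        list(center_res = center_res,
                             center_sens = center_sens,
                             auc_shift = auc_shift,
                             sensitive_lines = lines[sensitive_mask]))
    out[]
  })
}

#' Full simulated study: screens, alterations, pathways, network, drugs
#'
#' Convenience wrapper assembling all inputs for an end-to-end run under one
#' seed. Presets: `"null"` (no planted structure), `"planted"` (small panel
#' with one planted driver dependency set), `"fullpanel"` (117 lines, 10
#' histotypes, 714 targets, 21-driver alteration matrix, essential mitotic
#' genes, 10 driver-associated dependencies at Z shift -2.5,
#' histotype-associated dependencies, a planted functional module and an
#' FGFR-inhibitor-like drug effect in osteosarcoma lines).
#'
#' @param preset one of "fullpanel", "planted", "null".
#' @param seed integer seed.
#' @param n_lines,n_targets,n_histotypes panel shape overrides.
#' @return list with `screen` (see [generate_screen()]), `alterations`,
#'   `pathways`, `edges`, `dose_response`, `truth`.
#' @export
simulate_study <- function(preset = c("fullpanel", "planted", "null"),
                           seed = 1L, n_lines = NULL, n_targets = NULL,
                           n_histotypes = NULL) {
  preset <- match.arg(preset)
  n_lines <- n_lines %||% switch(preset, fullpanel = 117L, 40L)
  n_targets <- n_targets %||% switch(preset, fullpanel = 714L, 80L)
  n_histotypes <- n_histotypes %||% switch(preset, fullpanel = 10L, 4L)
  lines <- sprintf("LINE%03d", seq_len(n_lines))

  drivers <- c(KRAS = 0.17, ERBB2 = 0.10, CCND1 = 0.10, PIK3CA = 0.15,
               SMAD4 = 0.09, NOTCH2 = 0.07, ARID1A = 0.10, NF1 = 0.08,
               FBXW7 = 0.07, MAP2K4 = 0.07, RB1 = 0.12, TP53 = 0.45,
               STK11 = 0.08, CDKN2A = 0.15, SMARCA4 = 0.08, MYC = 0.12,
               EGFR = 0.09, BRAF = 0.08, PTEN = 0.10, TSC1 = 0.07,
               TSC2 = 0.07)
  alt <- generate_alterations(n_lines, drivers, line_names = lines,
                              exact = TRUE,
                              seed = hash_seed(seed, "alterations"))

  pathways <- list(
    MAPK_SIGNALING = c("KRAS", "BRAF", "NF1"),
    TOR_SIGNALING = c("TSC1", "TSC2", "STK11"),
    SWI_SNF = c("ARID1A", "SMARCA4"),
    CELL_CYCLE = c("RB1", "CDKN2A", "CCND1"),
    PI3K_SIGNALING = c("PIK3CA", "PTEN"))

  essential <- c("PLK1", "AURKA", "WEE1", "CHEK1", "CDK11A", "GUCY2D")
  planted <- NULL
  drug_truth <- NULL
  if (preset == "fullpanel") {
    dep_targets <- sprintf("DEPK%02d", 1:10)
    planted <- data.table::data.table(
      feature = rep(c("ERBB2", "SMAD4"), each = 5),
      target = dep_targets, delta_z = -2.5)
    planted <- rbind(planted, data.table::data.table(
      feature = "osteosarcoma", target = c("FGFR1", "FGFR2", "PDGFRA",
                                           "TGFBR2"),
      delta_z = -2))
    drug_truth <- list(drug = "AZD4547", feature = "osteosarcoma",
                       auc_shift = 0.2)
  } else if (preset == "planted") {
    dep_targets <- sprintf("DEPK%02d", 1:5)
    planted <- data.table::data.table(feature = "KRAS", target = dep_targets,
                                      delta_z = -2.5)
    essential <- c("PLK1", "AURKA")
  } else {
    essential <- character()
  }

  module <- if (preset == "null") character() else
    unique(planted[feature %in% colnames(alt), target])
  truth <- simulation_truth(planted_dependencies = planted,
                            essential_genes = essential,
                            planted_network_module = module,
                            planted_drug_effect = drug_truth, seed = seed)

  screen <- generate_screen(n_lines = n_lines, n_histotypes = n_histotypes,
                            n_targets = n_targets, truth = truth,
                            feature_membership = alt,
                            seed = hash_seed(seed, "screen"))

  net_universe <- unique(c(head(screen$targets, 60),
                           truth$planted_network_module,
                           names(drivers), "CDK1", "NEK9"))
  # typed driver->dependency wiring so the annotation stage has direct links
  # and one-intermediate paths to find among the planted dependencies
  typed <- list(list(genes = c("ERBB2", "CDK1", "NEK9"),
                     type = "kinase_substrate", directed = 1))
  if (!is.null(planted) && preset == "fullpanel") {
    typed <- c(typed, list(
      list(genes = c("ERBB2", "DEPK01"), type = "ppi", directed = 0),
      list(genes = c("ERBB2", "CDK1", "DEPK02"),
           type = "kinase_substrate", directed = 1),
      list(genes = c("SMAD4", "DEPK06"), type = "regulatory",
           directed = 1),
      list(genes = c("SMAD4", "AKT1", "DEPK07"),
           type = "kinase_substrate", directed = 1)))
    net_universe <- unique(c(net_universe, "AKT1"))
  }
  edges <- generate_network(net_universe, background_edge_prob = 0.03,
                            planted_module = truth$planted_network_module,
                            module_edge_prob = 0.9,
                            typed_paths = typed,
                            seed = hash_seed(seed, "network"))

  histo <- screen$annotations$histotype
  sens <- if (preset == "fullpanel") histo == "osteosarcoma" else
    rep(FALSE, n_lines)
  dr <- generate_dose_response(
    n_lines, sensitive_mask = sens,
    auc_shift = if (any(sens)) drug_truth$auc_shift else 0,
    drug = if (!is.null(drug_truth)) drug_truth$drug else "DRUG1",
    line_names = lines, seed = hash_seed(seed, "drugs"))

  list(screen = screen, alterations = alt, pathways = pathways,
       edges = edges, dose_response = dr, truth = truth)
}

#' Write a simulated study to pipeline input files
#'
#' Emits the conventional input file set consumed by [run_pipeline()]:
#' plates.tsv, plate_map.tsv, plate_lines.tsv, histotypes.tsv,
#' alterations.tsv, pathways.gmt, edges.tsv, dose_response.tsv and a
#' ground-truth manifest (truth.tsv).
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t",
                                          na = "NA", quote = FALSE)
  fw(study$screen$plates, "plates.tsv")
  fw(study$screen$plate_map, "plate_map.tsv")
  fw(study$screen$plate_lines, "plate_lines.tsv")
  fw(study$screen$annotations, "histotypes.tsv")
  write_matrix_tsv(study$alterations, file.path(dir, "alterations.tsv"))
  gmt <- vapply(names(study$pathways), function(p)
    paste(c(p, "synthetic", study$pathways[[p]]), collapse = "\t"),
    character(1))
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  fw(study$edges, "edges.tsv")
  fw(study$dose_response, "dose_response.tsv")
  tr <- study$truth$planted_dependencies
  if (!is.null(tr)) fw(tr, "truth.tsv")
  invisible(dir)
}
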