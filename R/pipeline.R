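# End-to-end orchestration: stages communicate only through files so runs
# are restartable, and every output directory carries a reproducibility
# manifest (config snapshot, input checksums, seeds, timestamps).

PIPELINE_STAGES <- c("screen_processing", "kgd_calling", "clustering",
                     "histotype_association", "driver_association",
                     "pathway_association", "network_integration",
                     "drug_sensitivity")

#' Run the full dependency-mapping pipeline on a directory of input files
#'
#' Expects the conventional input file set (see [write_study_inputs()]):
#' plates.tsv, plate_map.tsv, plate_lines.tsv and histotypes.tsv are
#' required; alterations.tsv, pathways.gmt, edges.tsv and dose_response.tsv
#' are optional — stages whose inputs are absent are skipped and the skip is
#' recorded in the manifest. A stage failure halts the run with the failing
#' stage named; outputs of completed stages are retained.
#'
#' @param input_dir directory of input files.
#' @param output_dir directory for outputs (created).
#' @param config list from [default_config()] / [read_config()].
#' @return list of per-stage status ("done"/"skipped"), invisibly; outputs
#'   and manifest.yaml are written under `output_dir`.
#' @export
run_pipeline <- function(input_dir, output_dir, config = default_config()) {
  config <- validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- function(f) file.path(input_dir, f)
  outp <- function(f) file.path(output_dir, f)
  status <- setNames(rep("skipped", length(PIPELINE_STAGES)), PIPELINE_STAGES)
  t_start <- Sys.time()
  run_stage <- function(name, code) {
    tryCatch({
      force(code)
      status[name] <<- "done"
    }, error = function(e) {
      stop_format("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  for (f in c("plates.tsv", "plate_map.tsv", "plate_lines.tsv",
              "histotypes.tsv")) {
    if (!file.exists(inp(f))) stop_format("run_pipeline: missing input %s", f)
  }

  screen <- NULL; ann <- NULL
  run_stage("screen_processing", {
    pd <- read_plate_data(inp("plates.tsv"), inp("plate_map.tsv"))
    plate_lines <- data.table::fread(inp("plate_lines.tsv"), sep = "\t")
    screen <- build_screen_matrix(pd$records, pd$map, plate_lines,
                                   zprime_min = config$zprime_min,
                                   r_min = config$replicate_cor_min)
    ann <- data.table::fread(inp("histotypes.tsv"), sep = "\t")
    ann[, passes_qc := cell_line %in% screen$qc[passes_qc == TRUE, cell_line]]
    keep <- screen$qc[passes_qc == TRUE, cell_line]
    screen$z <- screen$z[rownames(screen$z) %in% keep, , drop = FALSE]
    ann <- ann[cell_line %in% keep]
    write_matrix_tsv(screen$z, outp("zscores.tsv"))
    data.table::fwrite(screen$qc, outp("qc_report.tsv"), sep = "\t")
  })

  kgds <- NULL
  run_stage("kgd_calling", {
    kgds <- call_kgds(screen, z_threshold = config$z_threshold)
    write_matrix_tsv(1 * kgds$is_kgd, outp("kgd_calls.tsv"))
    data.table::fwrite(
      data.table::data.table(statistic = names(unlist(kgds$summary)),
                             value = unlist(kgds$summary)),
      outp("kgd_summary.tsv"), sep = "\t")
  })

  if (nrow(screen$z) >= 3) {
    run_stage("clustering", {
      cl <- cluster_cell_lines(screen)
      export_tree_newick(cl, outp("dendrogram.newick"))
    })
  }

  all_records <- list()
  run_stage("histotype_association", {
    hf <- histotype_features(ann)
    hf <- filter_testable(hf, min_altered_lines = 2)
    rec <- run_association_screen(screen, hf,
                                  n_permutations = config$n_permutations,
                                  seed = config$random_seed,
                                  fdr = config$fdr_histotype)
    all_records$histotype <- rec
  })

  alterations <- NULL
  if (file.exists(inp("alterations.tsv"))) {
    run_stage("driver_association", {
      alterations <- read_matrix_tsv(inp("alterations.tsv"))
      alterations <- alterations[rownames(alterations) %in% rownames(screen$z),
                                  , drop = FALSE]
      df <- filter_testable(alteration_features(alterations),
                            min_altered_lines = config$min_altered_lines)
      if (ncol(df$membership) > 0) {
        rec <- run_association_screen(screen, df,
                                      n_permutations = config$n_permutations,
                                      seed = config$random_seed,
                                      fdr = config$fdr_driver)
        all_records$driver <- rec
      }
      # within-histotype driver runs for histotypes large enough to test
      per_h <- list()
      for (h in unique(ann$histotype)) {
        lines_h <- ann[histotype == h, cell_line]
        if (length(lines_h) < 6) next
        dh <- scope_restrict(alteration_features(alterations), lines_h,
                             sprintf("histotype:%s", h))
        dh <- filter_testable(dh, min_altered_lines = 3)
        if (ncol(dh$membership) == 0) next
        per_h[[h]] <- run_association_screen(
          screen, dh, n_permutations = config$n_permutations,
          seed = config$random_seed, fdr = config$fdr_driver)
      }
      if (length(per_h) > 0) {
        all_records$driver_within <- data.table::rbindlist(per_h)
        if (length(per_h) >= 2) {
          rec2 <- recurrent_dependencies(all_records$driver_within)
          data.table::fwrite(rec2, outp("recurrent_dependencies.tsv"),
                             sep = "\t")
        }
      }
    })
  }

  if (file.exists(inp("pathways.gmt")) && !is.null(alterations)) {
    run_stage("pathway_association", {
      pws <- read_gmt(inp("pathways.gmt"))
      grp <- suppressWarnings(pathway_or_grouping(alterations, pws))
      if (length(grp) > 0) {
        pf <- filter_testable(pathway_features(grp),
                              min_altered_lines = config$min_altered_lines)
        if (ncol(pf$membership) > 0) {
          rec <- run_association_screen(screen, pf,
                                        n_permutations = config$n_permutations,
                                        seed = config$random_seed,
                                        fdr = config$fdr_driver)
          all_records$pathway <- rec
          # better-predictor filter on the significant pathway hits
          hits <- rec[significant == TRUE]
          if (nrow(hits) > 0) {
            bp <- lapply(seq_len(nrow(hits)), function(i) {
              g <- grp[[hits$feature[i]]]
              z <- screen$z[, hits$target_gene[i]]
              memb <- g$derived_membership[rownames(screen$z)]
              mm <- g$member_memberships[rownames(screen$z), , drop = FALSE]
              r <- pathway_better_than_members(z, memb, mm)
              data.table::data.table(
                feature = hits$feature[i], target_gene = hits$target_gene[i],
                rho_pathway = r$rho_pathway,
                rho_best_member = suppressWarnings(
                  max(abs(r$rho_members), na.rm = TRUE)),
                is_better = r$is_better)
            })
            data.table::fwrite(data.table::rbindlist(bp),
                               outp("pathway_better_predictor.tsv"),
                               sep = "\t")
          }
        }
      }
    })
  }

  if (length(all_records) > 0) {
    write_association_table(data.table::rbindlist(all_records, fill = TRUE),
                            outp("associations.tsv"))
  }

  if (file.exists(inp("edges.tsv")) && !is.null(all_records$driver)) {
    run_stage("network_integration", {
      edges <- read_edge_table(inp("edges.tsv"))
      graph <- build_graph(edges, string_min_score = config$string_min_score)
      drec <- all_records$driver
      pairs <- unique(drec[nominal == TRUE,
                           .(driver = feature, target = target_gene)])
      if (nrow(pairs) > 0) {
        ann_net <- annotate_dependencies(pairs, graph)
        data.table::fwrite(ann_net, outp("network_annotations.tsv"),
                           sep = "\t")
        background <- intersect(colnames(screen$z), graph$nodes)
        conn <- list()
        for (drv in unique(pairs$driver)) {
          gs <- intersect(pairs[driver == drv, target], background)
          if (length(gs) < 2) next
          ce <- connectivity_enrichment(
            gs, graph, background,
            n_permutations = min(config$n_permutations, 1e4),
            seed = hash_seed(config$random_seed, "connectivity", drv))
          conn[[drv]] <- data.table::data.table(
            driver = drv, set_size = ce$set_size,
            observed_edges = ce$observed_edges, null_mean = ce$null_mean,
            p_empirical = ce$p_empirical)
        }
        if (length(conn) > 0) {
          data.table::fwrite(data.table::rbindlist(conn),
                             outp("connectivity.tsv"), sep = "\t")
        }
      }
    })
  }

  if (file.exists(inp("dose_response.tsv"))) {
    run_stage("drug_sensitivity", {
      dr <- data.table::fread(inp("dose_response.tsv"), sep = "\t")
      aucm <- suppressWarnings(auc_matrix(dr))
      write_matrix_tsv(aucm, outp("auc_matrix.tsv"))
      groups <- list()
      for (h in unique(ann$histotype)) {
        groups[[sprintf("histotype:%s", h)]] <-
          setNames(ann$histotype == h, ann$cell_line)
      }
      if (!is.null(alterations)) {
        for (g in colnames(alterations)) {
          groups[[sprintf("driver:%s", g)]] <-
            setNames(alterations[, g] == 1, rownames(alterations))
        }
      }
      res <- list()
      for (drug in colnames(aucm)) {
        av <- aucm[, drug]
        for (gn in names(groups)) {
          mask <- groups[[gn]][rownames(aucm)]
          if (sum(mask, na.rm = TRUE) < 3 || sum(!mask, na.rm = TRUE) < 3) next
          da <- tryCatch(drug_association(av, mask), error = function(e) NULL)
          if (is.null(da)) next
          res[[paste(drug, gn)]] <- data.table::data.table(
            drug = drug, feature = gn, n_interest = da$n_interest,
            n_other = da$n_other, p_mwu = da$p)
        }
      }
      if (length(res) > 0) {
        data.table::fwrite(data.table::rbindlist(res),
                           outp("drug_associations.tsv"), sep = "\t")
      }
    })
  }

  # reproducibility manifest
  inputs <- list.files(input_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("kinasedep")),
    config = config,
    seed = config$random_seed,
    stages = as.list(status),
    input_checksums = as.list(tools::md5sum(inputs)),
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  yaml::write_yaml(manifest, outp("manifest.yaml"))
  writeLines(utils::capture.output(report_summary(output_dir)),
             outp("report.txt"))
  invisible(as.list(status))
}

#' Summarize a pipeline run's headline statistics
#'
#' Recomputes and prints the descriptive statistics of a completed run: the
#' fraction of targets that are a KGD in >= 1 / >= 5 / >= 10 lines, the mean
#' KGD count per line, and the number of significant associations per scope
#' and threshold.
#'
#' @param output_dir a [run_pipeline()] output directory.
#' @return named list of the printed statistics, invisibly.
#' @export
report_summary <- function(output_dir) {
  outp <- function(f) file.path(output_dir, f)
  if (!file.exists(outp("kgd_calls.tsv"))) {
    stop_format("report_summary: no kgd_calls.tsv under %s", output_dir)
  }
  calls <- read_matrix_tsv(outp("kgd_calls.tsv")) == 1
  per_gene <- colSums(calls, na.rm = TRUE)
  per_line <- rowSums(calls, na.rm = TRUE)
  out <- list(
    n_lines = nrow(calls), n_targets = ncol(calls),
    pct_kgd_ge1 = 100 * mean(per_gene >= 1),
    pct_kgd_ge5 = 100 * mean(per_gene >= 5),
    pct_kgd_ge10 = 100 * mean(per_gene >= 10),
    mean_kgds_per_line = mean(per_line))
  cat(sprintf("Screens: %d cell lines x %d targets\n", out$n_lines,
              out$n_targets))
  cat(sprintf("Targets KGD in >=1 line: %.1f%%; >=5 lines: %.1f%%; >=10 lines: %.1f%%\n",
              out$pct_kgd_ge1, out$pct_kgd_ge5, out$pct_kgd_ge10))
  cat(sprintf("Mean KGDs per cell line: %.1f\n", out$mean_kgds_per_line))
  if (file.exists(outp("associations.tsv"))) {
    rec <- read_association_table(outp("associations.tsv"))
    if (nrow(rec) > 0) {
      counts <- rec[, .(n_tests = .N, n_significant = sum(significant),
                        n_nominal = sum(p_empirical <= 0.05 &
                                          delta_median < 0)),
                    by = .(feature_kind, scope)]
      out$association_counts <- counts
      for (i in seq_len(nrow(counts))) {
        cat(sprintf("Associations [%s, %s]: %d tests, %d significant at scope FDR, %d nominal (p<=0.05)\n",
                    counts$feature_kind[i], counts$scope[i],
                    counts$n_tests[i], counts$n_significant[i],
                    counts$n_nominal[i]))
      }
    } else {
      out$association_counts <- rec
      cat("Associations: none recorded\n")
    }
  }
  invisible(out)
}
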