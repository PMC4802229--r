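# Readers and writers for every external table the pipeline touches.
# All tables are tab-separated text with a single header row; matrices are
# cell-lines-as-rows. Readers validate strictly and reject rather than
# coerce; gene symbols are uppercased on ingest (no alias resolution).

PLATE_COLS <- c("plate_id", "replicate", "well", "signal")
MAP_COLS <- c("plate_id", "well", "content_kind", "target_gene")
CONTENT_KINDS <- c("library", "positive_control", "negative_control", "empty")
EDGE_COLS <- c("gene_a", "gene_b", "edge_type", "directed", "score")
EDGE_TYPES <- c("ppi", "kinase_substrate", "regulatory", "functional")

require_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing) > 0) {
    stop_format("%s: missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(dt)
}

#' Read plate-level viability data together with its plate map
#'
#' Reads the raw well-level signal table (columns `plate_id`, `replicate`,
#' `well`, `signal`) and the plate map (columns `plate_id`, `well`,
#' `content_kind`, `target_gene`), validates both, and checks that every data
#' well is present in the map.
#'
#' @param path TSV of plate records.
#' @param map_path TSV of the plate map.
#' @return list with elements `records` (data.table of plate records) and
#'   `map` (data.table plate map). `target_gene` is uppercased; every library
#'   well is required to carry a target gene.
#' @examples
#' sim <- generate_screen(n_lines = 3, n_histotypes = 2, n_targets = 20,
#'                        plate_format = 96, seed = 1)
#' d <- file.path(tempdir(), "kd-io-demo")
#' dir.create(d, showWarnings = FALSE)
#' data.table::fwrite(sim$plates, file.path(d, "plates.tsv"), sep = "\t")
#' data.table::fwrite(sim$plate_map, file.path(d, "map.tsv"), sep = "\t")
#' pd <- read_plate_data(file.path(d, "plates.tsv"), file.path(d, "map.tsv"))
#' nrow(pd$records)
#' @export
read_plate_data <- function(path, map_path) {
  for (p in c(path, map_path)) {
    if (!file.exists(p)) stop_format("file not found: %s", p)
  }
  records <- data.table::fread(path, sep = "\t", colClasses = list(
    character = "plate_id"))
  require_columns(records, PLATE_COLS, "plate data")
  map <- read_plate_map(map_path)

  records[, well := toupper(well)]
  if (any(!is.finite(records$signal)) || any(records$signal < 0)) {
    stop_format("plate data: signal must be finite and nonnegative")
  }
  if (any(is.na(records$replicate)) || any(records$replicate < 1)) {
    stop_format("plate data: replicate must be an integer >= 1")
  }
  fmt <- infer_plate_format(unique(c(records$well, map$well)))
  dup <- records[, .N, by = .(plate_id, replicate, well)][N > 1]
  if (nrow(dup) > 0) {
    stop_format("plate data: duplicated wells within (plate_id, replicate): %s",
                paste(head(sprintf("%s/%s/%s", dup$plate_id, dup$replicate,
                                   dup$well), 5), collapse = ", "))
  }
  orphans <- records[!map, on = c("plate_id", "well")]
  if (nrow(orphans) > 0) {
    stop_format("plate data: %d well(s) absent from plate map: %s",
                nrow(orphans),
                paste(head(unique(sprintf("%s:%s", orphans$plate_id,
                                          orphans$well)), 10),
                      collapse = ", "))
  }
  list(records = records[], map = map, plate_format = fmt)
}

#' @rdname read_plate_data
#' @export
read_plate_map <- function(map_path) {
  map <- data.table::fread(map_path, sep = "\t", na.strings = c("", "NA"),
                           colClasses = list(character = "plate_id"))
  require_columns(map, MAP_COLS, "plate map")
  map[, well := toupper(well)]
  bad <- invalid_wells(map$well, 384)
  if (length(bad) > 0) {
    stop_format("plate map: impossible well label(s): %s",
                paste(head(bad, 10), collapse = ", "))
  }
  if (any(!map$content_kind %in% CONTENT_KINDS)) {
    stop_format("plate map: content_kind must be one of %s",
                paste(CONTENT_KINDS, collapse = ", "))
  }
  map[, target_gene := toupper(target_gene)]
  nolib <- map[content_kind == "library" &
                 (is.na(target_gene) | target_gene == "")]
  if (nrow(nolib) > 0) {
    stop_format("plate map: %d library well(s) without a target gene",
                nrow(nolib))
  }
  dup <- map[, .N, by = .(plate_id, well)][N > 1]
  if (nrow(dup) > 0) {
    stop_format("plate map: duplicated wells within plate: %s",
                paste(head(sprintf("%s:%s", dup$plate_id, dup$well), 5),
                      collapse = ", "))
  }
  map[]
}

#' Read a GMT pathway definition file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member symbols are
#' uppercased and deduplicated; a pathway with no members is rejected.
#'
#' @param path GMT file.
#' @return named list of character vectors (pathway name -> member genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_format("GMT: line with fewer than 3 fields: %.40s", ln)
    }
    members <- unique(toupper(trimws(parts[-(1:2)])))
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop_format("GMT: pathway '%s' has no member genes", parts[1])
    }
    out[[parts[1]]] <- members
  }
  out
}

#' Read cell-line annotation, alteration matrix and pathway tables together
#'
#' Reconciles cell-line name sets across the histotype table and the binary
#' alteration matrix: mismatches are reported and the intersection retained.
#'
#' @param histotype_path TSV with columns `cell_line`, `histotype` and
#'   optionally `passes_qc`.
#' @param alteration_path TSV, first column `cell_line`, remaining columns
#'   driver genes with entries in \{0, 1, NA\}.
#' @param pathway_gmt_path GMT file of pathway definitions (optional; `NULL`
#'   to skip).
#' @return list with `annotations` (data.table), `alterations` (binary matrix,
#'   rows = cell lines), `pathways` (named list or NULL).
#' @export
read_feature_tables <- function(histotype_path, alteration_path,
                                pathway_gmt_path = NULL) {
  ann <- data.table::fread(histotype_path, sep = "\t")
  require_columns(ann, c("cell_line", "histotype"), "histotype table")
  if (any(is.na(ann$histotype) | ann$histotype == "")) {
    stop_format("histotype table: histotype must be non-null for every line")
  }
  if (!"passes_qc" %in% names(ann)) ann[, passes_qc := TRUE]

  alt <- read_matrix_tsv(alteration_path)
  ok <- alt %in% c(0, 1) | is.na(alt)
  if (!all(ok)) {
    stop_format("alteration matrix: entries must be 0, 1 or NA (found %s)",
                paste(head(unique(alt[!ok]), 5), collapse = ", "))
  }

  common <- intersect(ann$cell_line, rownames(alt))
  if (length(common) == 0) {
    stop_format("no cell lines shared between histotype table and alteration matrix")
  }
  only_ann <- setdiff(ann$cell_line, common)
  only_alt <- setdiff(rownames(alt), common)
  if (length(only_ann) + length(only_alt) > 0) {
    message(sprintf(
      "read_feature_tables: retaining %d shared cell lines (%d histotype-only, %d alteration-only dropped)",
      length(common), length(only_ann), length(only_alt)))
  }
  ann <- ann[cell_line %in% common]
  alt <- alt[common, , drop = FALSE]

  pathways <- if (!is.null(pathway_gmt_path)) read_gmt(pathway_gmt_path) else NULL
  list(annotations = ann[], alterations = alt, pathways = pathways)
}

#' Read / write a numeric matrix as TSV with cell lines in the first column
#'
#' @param path TSV file; first column must be `cell_line`.
#' @return numeric matrix with cell-line rownames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t")
  require_columns(dt, "cell_line", basename(path))
  rn <- as.character(dt$cell_line)
  m <- as.matrix(dt[, -"cell_line"])
  if (!is.numeric(m)) {
    bad <- unique(as.vector(m[suppressWarnings(is.na(as.numeric(m))) & !is.na(m)]))
    stop_format("%s: non-numeric matrix entries (e.g. %s)", basename(path),
                paste(head(bad, 3), collapse = ", "))
  }
  rownames(m) <- rn
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with rownames.
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table::as.data.table(m, keep.rownames = "cell_line")
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a typed interaction edge table
#'
#' Columns: `gene_a`, `gene_b`, `edge_type` in \{ppi, kinase_substrate,
#' regulatory, functional\}, `directed` in \{0, 1\}, `score` (real in [0,1]
#' for functional edges, NA otherwise).
#'
#' @param path TSV file.
#' @return validated data.table of edges (symbols uppercased).
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  ed <- data.table::fread(path, sep = "\t", na.strings = c("", "NA"))
  require_columns(ed, EDGE_COLS, "edge table")
  ed[, `:=`(gene_a = toupper(gene_a), gene_b = toupper(gene_b))]
  if (any(!ed$edge_type %in% EDGE_TYPES)) {
    stop_format("edge table: edge_type must be one of %s",
                paste(EDGE_TYPES, collapse = ", "))
  }
  if (any(!ed$directed %in% c(0L, 1L))) {
    stop_format("edge table: directed must be 0 or 1")
  }
  sc <- ed[edge_type == "functional", score]
  if (any(is.na(sc))) {
    stop_format("edge table: functional edges must carry a score")
  }
  if (any(sc < 0 | sc > 1)) {
    stop_format("edge table: functional scores must lie in [0, 1]")
  }
  ed[]
}

# columns of the association record contract, in write order
ASSOC_COLS <- c("feature", "feature_kind", "scope", "target_gene",
                "n_interest", "n_other", "delta_median", "p_empirical",
                "q_bh", "n_permutations", "seed", "significant")

#' Write / read an association-record table
#'
#' Records are written sorted by (scope, feature, q) with full double
#' precision so that write -> read is the identity.
#'
#' @param records data.table of association records (see
#'   [run_association_screen()]).
#' @param path output TSV.
#' @export
write_association_table <- function(records, path) {
  records <- data.table::as.data.table(records)
  if (nrow(records) > 0) {
    missing <- setdiff(ASSOC_COLS, names(records))
    if (length(missing) > 0) {
      stop_format("association records: missing column(s): %s",
                  paste(missing, collapse = ", "))
    }
    records <- records[order(scope, feature, q_bh, p_empirical, target_gene),
                       ASSOC_COLS, with = FALSE]
  } else {
    records <- data.table::setDT(
      setNames(lapply(ASSOC_COLS, function(x) logical(0)), ASSOC_COLS))
  }
  data.table::fwrite(records, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  require_columns(dt, ASSOC_COLS, "association table")
  dt[]
}

#' Run configuration
#'
#' Returns the default analysis configuration; values mirror the thresholds
#' used throughout: KGD threshold Z <= -2, 10^6 permutations for full runs,
#' FDR 0.1 for histotype and 0.5 for driver associations, features testable
#' when altered in >= 7 lines, STRING functional score > 0.7.
#'
#' @param ... named overrides of individual config entries.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    z_threshold = -2,
    n_permutations = 1e6,
    fdr_histotype = 0.1,
    fdr_driver = 0.5,
    min_altered_lines = 7L,
    string_min_score = 0.7,
    zprime_min = 0.3,
    replicate_cor_min = 0.7,
    random_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop_format("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' @rdname default_config
#' @param path YAML file whose keys override the defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

validate_config <- function(cfg) {
  if (cfg$n_permutations < 1e3) {
    stop_format("config: n_permutations must be >= 1000")
  }
  for (k in c("fdr_histotype", "fdr_driver", "string_min_score")) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1) stop_format("config: %s must be in [0, 1]", k)
  }
  if (cfg$z_threshold > 0) stop_format("config: z_threshold must be <= 0")
  if (cfg$min_altered_lines < 1) stop_format("config: min_altered_lines must be >= 1")
  cfg
}
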