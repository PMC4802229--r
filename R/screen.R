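# Screen processing: plate normalization, replicate summarization, robust Z
# scoring, screen-level QC, KGD calling and cell-line clustering.
#
# The normalization contract is fixed as: each library well's signal divided
# by the median signal of library wells on its plate (per replicate),
# replicates summarized by their median, then a per-screen robust Z over
# library targets. Controls are carried through flagged but never enter the
# median/MAD estimates (siPLK1 wells would otherwise bias the scale).

#' Normalize plate signals by the per-plate library median
#'
#' Each library well's signal is divided by the median signal of library
#' wells on its (plate, replicate); control and empty wells are normalized by
#' the same factor but flagged by `content_kind` so downstream steps can
#' exclude them.
#'
#' @param records data.table of plate records (`plate_id`, `replicate`,
#'   `well`, `signal`).
#' @param map plate map data.table (`plate_id`, `well`, `content_kind`,
#'   `target_gene`).
#' @return data.table with the joined columns plus `norm_signal`.
#' @export
normalize_plate <- function(records, map) {
  records <- data.table::as.data.table(records)
  map <- data.table::as.data.table(map)
  dt <- merge(records, map, by = c("plate_id", "well"), all.x = TRUE)
  if (any(is.na(dt$content_kind))) {
    bad <- unique(dt[is.na(content_kind), sprintf("%s:%s", plate_id, well)])
    stop_format("normalize_plate: %d well(s) absent from plate map: %s",
                length(bad), paste(head(bad, 10), collapse = ", "))
  }
  frac_lib <- dt[, mean(content_kind == "library")]
  if (frac_lib < 0.5) {
    stop_format("normalize_plate: only %.0f%% of wells are library wells (>= 50%% required)",
                100 * frac_lib)
  }
  dt[, plate_median := {
    lib <- signal[content_kind == "library"]
    if (length(lib) == 0) {
      stop_format("normalize_plate: plate %s replicate %s has no library wells",
                  plate_id[1], replicate[1])
    }
    m <- median(lib, na.rm = TRUE)
    if (!is.finite(m) || m == 0) {
      stop_format("normalize_plate: plate %s replicate %s has library median 0",
                  plate_id[1], replicate[1])
    }
    m
  }, by = .(plate_id, replicate)]
  dt[, norm_signal := signal / plate_median]
  dt[, plate_median := NULL]
  dt[]
}

#' Summarize replicate measurements for one target
#'
#' Median of the available (non-NA) replicate values; the number of
#' contributing replicates is attached as attribute `n_replicates`.
#'
#' @param x numeric vector of 1-3 replicate values (NAs allowed).
#' @return scalar median with attribute `n_replicates`; NA (with a warning)
#'   when no replicate is available.
#' @export
summarize_replicates <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    warning("summarize_replicates: no replicate values available; returning NA")
    return(structure(NA_real_, n_replicates = 0L))
  }
  structure(median(x), n_replicates = length(x))
}

#' Robust Z score
#'
#' `Z_i = (x_i - median(x)) / (1.4826 * MAD(x))`, computed over library
#' targets of a single screen. The 1.4826 consistency constant makes the
#' denominator estimate the standard deviation under normality, so Z values
#' are comparable to ordinary Z scores.
#'
#' @param x numeric vector of summarized viabilities (one screen); NAs are
#'   preserved in the output and excluded from the location/scale estimates.
#' @param min_values refuse to standardize fewer than this many non-NA
#'   values (default 10; a MAD over a handful of points is too unstable for
#'   screen-scale use, but small worked examples may lower it).
#' @return numeric vector of Z scores, same length and names as `x`.
#' @examples
#' robust_z(c(1, 2, 3, 4, 100), min_values = 5)  # Z(100) = 97/1.4826
#' @export
robust_z <- function(x, min_values = 10L) {
  ok <- sum(!is.na(x))
  if (ok < min_values) {
    stop_format("robust_z: need >= %d non-NA values (got %d)", min_values, ok)
  }
  s <- robust_scale(x)
  if (!is.finite(s) || s <= 0) {
    stop_format("robust_z: degenerate scale (1.4826*MAD = %s)", format(s))
  }
  (x - median(x, na.rm = TRUE)) / s
}

#' Screen quality control
#'
#' Z'-factor from control wells, `Z' = 1 - 3*(sd_pos + sd_neg)/|mean_pos -
#' mean_neg|`, plus the median pairwise Pearson correlation between replicate
#' Z vectors. A screen passes QC when both exceed their thresholds.
#'
#' @param pos,neg numeric vectors of positive/negative control values
#'   (normalized viability; >= 3 wells each).
#' @param replicate_z numeric matrix, one column per replicate (library
#'   targets in rows) of per-replicate Z (or normalized viability) vectors;
#'   NULL when only one replicate exists (correlation then NA).
#' @param zprime_min,r_min QC thresholds (defaults 0.3 and 0.7).
#' @return list with `zprime`, `replicate_correlation`, `passes_qc`.
#' @export
qc_screen <- function(pos, neg, replicate_z = NULL,
                      zprime_min = 0.3, r_min = 0.7) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) < 3 || length(neg) < 3) {
    stop_format("qc_screen: need >= 3 positive and >= 3 negative control wells")
  }
  sep <- abs(mean(pos) - mean(neg))
  if (sep == 0) {
    return(list(zprime = NA_real_, replicate_correlation = NA_real_,
                passes_qc = FALSE,
                reason = "Z' undefined: control means are equal"))
  }
  zprime <- 1 - 3 * (sd(pos) + sd(neg)) / sep
  rep_cor <- NA_real_
  if (!is.null(replicate_z) && ncol(replicate_z) >= 2) {
    cc <- cor(replicate_z, use = "pairwise.complete.obs")
    rep_cor <- median(cc[upper.tri(cc)])
  }
  passes <- isTRUE(zprime >= zprime_min) &&
    (is.na(rep_cor) || rep_cor >= r_min)
  list(zprime = zprime, replicate_correlation = rep_cor, passes_qc = passes,
       reason = NULL)
}

#' Build the cell line x target robust Z matrix from raw plates
#'
#' Runs the full screen-processing chain: per-plate median normalization,
#' per-target replicate summarization (median), per-screen robust Z over
#' library targets, and per-screen QC (Z' from controls, median pairwise
#' replicate correlation of per-replicate Z vectors).
#'
#' @param records,map as for [normalize_plate()].
#' @param plate_lines data.table mapping `plate_id` to `cell_line` (a screen
#'   is the set of plates belonging to one cell line).
#' @param zprime_min,r_min QC thresholds passed to [qc_screen()].
#' @return object of class `screen_matrix`: list with `z` (matrix, cell lines
#'   x targets), `qc` (data.table: cell_line, zprime, replicate_correlation,
#'   passes_qc), `n_replicates` (matrix of contributing replicate counts).
#' @export
build_screen_matrix <- function(records, map, plate_lines,
                                zprime_min = 0.3, r_min = 0.7) {
  plate_lines <- data.table::as.data.table(plate_lines)
  require_columns(plate_lines, c("plate_id", "cell_line"), "plate_lines")
  norm <- normalize_plate(records, map)
  norm <- merge(norm, plate_lines, by = "plate_id", all.x = TRUE)
  if (any(is.na(norm$cell_line))) {
    stop_format("build_screen_matrix: plate(s) without a cell line: %s",
                paste(head(unique(norm[is.na(cell_line), plate_id]), 5),
                      collapse = ", "))
  }
  lib <- norm[content_kind == "library"]
  lines <- sort(unique(norm$cell_line))

  summ <- lib[, .(value = median(norm_signal, na.rm = TRUE),
                  n_rep = sum(!is.na(norm_signal))),
              by = .(cell_line, target_gene)]
  wide <- data.table::dcast(summ, cell_line ~ target_gene,
                            value.var = "value")
  x <- as.matrix(wide[, -"cell_line"])
  rownames(x) <- wide$cell_line
  x <- x[lines, , drop = FALSE]
  z <- t(apply(x, 1, robust_z))
  dimnames(z) <- dimnames(x)

  widen <- data.table::dcast(summ, cell_line ~ target_gene,
                             value.var = "n_rep", fill = 0L)
  nrep <- as.matrix(widen[, -"cell_line"])
  rownames(nrep) <- widen$cell_line
  nrep <- nrep[lines, colnames(z), drop = FALSE]

  # per-replicate library vectors: Pearson r is invariant to each
  # replicate's affine robust-Z transform, so correlate normalized signal
  repw <- data.table::dcast(lib, cell_line + target_gene ~ replicate,
                            value.var = "norm_signal")
  data.table::setkey(repw, cell_line)
  ctrl_all <- norm[content_kind %in% c("positive_control",
                                       "negative_control")]
  data.table::setkey(ctrl_all, cell_line)
  qc <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    ctrl <- ctrl_all[.(ln)]
    pos <- ctrl[content_kind == "positive_control", norm_signal]
    neg <- ctrl[content_kind == "negative_control", norm_signal]
    rz <- as.matrix(repw[.(ln), -(1:2)])
    if (ncol(rz) < 2) rz <- NULL
    q <- qc_screen(pos, neg, rz, zprime_min = zprime_min, r_min = r_min)
    qc[[i]] <- data.table::data.table(
      cell_line = ln, zprime = q$zprime,
      replicate_correlation = q$replicate_correlation,
      passes_qc = q$passes_qc)
  }
  structure(list(z = z, qc = data.table::rbindlist(qc), n_replicates = nrep),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen_matrix: %d cell lines x %d targets (%d screens pass QC)\n",
              nrow(x$z), ncol(x$z), sum(x$qc$passes_qc)))
  invisible(x)
}

# accept either a screen_matrix or a bare Z matrix
as_z_matrix <- function(screen) {
  if (inherits(screen, "screen_matrix")) screen$z
  else if (is.matrix(screen)) screen
  else stop_format("expected a screen_matrix or a numeric matrix")
}

#' Call kinase genetic dependencies (KGDs)
#'
#' A (cell line, target) pair is a KGD when its robust Z is at or below the
#' threshold (default -2). Returns the boolean call matrix together with its
#' margins and the headline summary statistics (fraction of targets that are
#' a KGD in >= 1 / >= 5 / >= 10 lines; mean KGDs per line).
#'
#' @param screen `screen_matrix` or Z matrix (cell lines x targets).
#' @param z_threshold KGD threshold (default -2).
#' @return object of class `kgd_calls`: list with `is_kgd`, `per_line_count`,
#'   `per_gene_frequency`, `summary`.
#' @export
call_kgds <- function(screen, z_threshold = -2) {
  z <- as_z_matrix(screen)
  all_na <- rowSums(!is.na(z)) == 0
  if (any(all_na)) {
    warning(sprintf("call_kgds: excluding %d all-NA cell line(s): %s",
                    sum(all_na),
                    paste(head(rownames(z)[all_na], 5), collapse = ", ")))
    z <- z[!all_na, , drop = FALSE]
  }
  is_kgd <- !is.na(z) & z <= z_threshold
  per_line <- rowSums(is_kgd)
  per_gene <- colSums(is_kgd)
  summary <- list(
    frac_ge1 = mean(per_gene >= 1),
    frac_ge5 = mean(per_gene >= 5),
    frac_ge10 = mean(per_gene >= 10),
    mean_per_line = mean(per_line)
  )
  structure(list(is_kgd = is_kgd, per_line_count = per_line,
                 per_gene_frequency = per_gene, summary = summary),
            class = "kgd_calls")
}

#' @export
print.kgd_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "kgd_calls: %d lines x %d targets\n",
    "  targets KGD in >=1 line: %.1f%%  >=5: %.1f%%  >=10: %.1f%%\n",
    "  mean KGDs per line: %.1f\n"),
    nrow(x$is_kgd), ncol(x$is_kgd), 100 * s$frac_ge1, 100 * s$frac_ge5,
    100 * s$frac_ge10, s$mean_per_line))
  invisible(x)
}

#' Hierarchical clustering of cell lines on their dependency profiles
#'
#' Targets are filtered to the top 20% most variable Z scores across lines
#' (ties at the cutoff included), the distance between two lines is
#' `1 - Pearson r` of their Z vectors, and average-linkage hierarchical
#' clustering is applied.
#'
#' @param screen `screen_matrix` or Z matrix.
#' @param var_quantile keep targets with variance at or above this quantile
#'   (default 0.8, i.e. the 20% most variable).
#' @return list with `hclust` (stats::hclust tree), `leaf_order`,
#'   `targets_used`, `dist` (the distance matrix).
#' @export
cluster_cell_lines <- function(screen, var_quantile = 0.8) {
  z <- as_z_matrix(screen)
  if (nrow(z) < 3) stop_format("cluster_cell_lines: need >= 3 cell lines")
  vars <- apply(z, 2, stats::var, na.rm = TRUE)
  cut <- quantile(vars, var_quantile, na.rm = TRUE, names = FALSE)
  keep <- !is.na(vars) & vars >= cut
  zv <- z[, keep, drop = FALSE]
  sds <- apply(zv, 1, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    stop_format("cluster_cell_lines: constant Z vector for line(s): %s",
                paste(rownames(zv)[!is.finite(sds) | sds == 0], collapse = ", "))
  }
  cc <- cor(t(zv), use = "pairwise.complete.obs")
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  list(hclust = hc, leaf_order = rownames(zv)[hc$order],
       targets_used = colnames(zv), dist = d)
}

#' Export a clustering tree as newick text
#'
#' @param clustering result of [cluster_cell_lines()] (or an hclust object).
#' @param path output file.
#' @export
export_tree_newick <- function(clustering, path) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
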