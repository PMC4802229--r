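# Dose-response summarization (normalized AUC over a log-dose grid) and
# one-sided Mann-Whitney group comparison of drug sensitivity.

#' Area under the dose-response curve
#'
#' Viabilities are clipped to [0, 1] (values above 1 reflect growth
#' stimulation and are capped) and integrated by the trapezoid rule over
#' log10 concentration, normalized by the grid width, so AUC = 1 means the
#' drug had no effect at any dose and AUC = 0 means complete kill at all
#' doses. Lower AUC = more sensitive.
#'
#' @param viability numeric vector of vehicle-normalized viabilities.
#' @param concentrations strictly increasing positive doses (same length;
#'   8 by default in generated panels).
#' @param clip_high cap viability at this value before integration
#'   (default 1).
#' @return scalar AUC in [0, 1]; NA with a warning when fewer than 4
#'   concentrations are available.
#' @examples
#' compute_auc(rep(1, 8), 10^seq(-3, 0.5, length.out = 8))  # untouched: 1
#' @export
compute_auc <- function(viability, concentrations, clip_high = 1) {
  if (length(viability) != length(concentrations)) {
    stop_format("compute_auc: viability and concentrations differ in length")
  }
  keep <- !is.na(viability) & !is.na(concentrations)
  viability <- viability[keep]; concentrations <- concentrations[keep]
  if (length(viability) < 4) {
    warning("compute_auc: fewer than 4 dose points; returning NA")
    return(NA_real_)
  }
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop_format("compute_auc: concentrations must be positive and strictly increasing")
  }
  v <- pmin(pmax(viability, 0), clip_high)
  lc <- log10(concentrations)
  pracma::trapz(lc, v) / (max(lc) - min(lc))
}

#' Build an AUC matrix from a long dose-response table
#'
#' @param dose_response data.table with columns `cell_line`, `drug`,
#'   `concentration`, `viability`.
#' @return numeric matrix, cell lines x drugs.
#' @export
auc_matrix <- function(dose_response) {
  dr <- data.table::as.data.table(dose_response)
  require_columns(dr, c("cell_line", "drug", "concentration", "viability"),
                  "dose-response table")
  wide <- dr[order(concentration),
             .(auc = compute_auc(viability, concentration)),
             by = .(cell_line, drug)]
  out <- data.table::dcast(wide, cell_line ~ drug, value.var = "auc")
  m <- as.matrix(out[, -"cell_line"])
  rownames(m) <- out$cell_line
  m
}

#' One-sided Mann-Whitney U test of drug sensitivity
#'
#' Alternative hypothesis: the interest group has lower AUC (is more
#' sensitive). Exact U distribution for small samples without ties; normal
#' approximation with tie correction otherwise.
#'
#' @param auc numeric vector of AUC values.
#' @param interest logical (or 0/1) group mask.
#' @return list with `p`, `statistic` (U for the interest group),
#'   `n_interest`, `n_other`.
#' @examples
#' drug_association(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))  # p = 0.05
#' @export
drug_association <- function(auc, interest) {
  interest <- as.logical(interest)
  keep <- !is.na(auc) & !is.na(interest)
  auc <- auc[keep]; interest <- interest[keep]
  if (sum(interest) < 3 || sum(!interest) < 3) {
    stop_format("drug_association: need >= 3 lines per group")
  }
  if (length(unique(auc)) == 1) {
    warning("drug_association: all AUC values equal; p = 1")
    return(list(p = 1, statistic = NA_real_,
                n_interest = sum(interest), n_other = sum(!interest)))
  }
  wt <- suppressWarnings(
    wilcox.test(auc[interest], auc[!interest], alternative = "less"))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n_interest = sum(interest), n_other = sum(!interest))
}

#' Re-run a drug association excluding a subset of lines
#'
#' Used for robustness checks of the form "the effect is still apparent when
#' the amplified lines are excluded". Reports the p-value with and without
#' the excluded lines.
#'
#' @param auc numeric vector of AUC values.
#' @param interest logical group mask.
#' @param exclude logical mask of lines to drop in the re-run.
#' @return list with `p_all`, `p_excluded`, `excluded_lines` (names or
#'   indices of dropped lines).
#' @export
exclusion_rerun <- function(auc, interest, exclude) {
  interest <- as.logical(interest); exclude <- as.logical(exclude)
  full <- drug_association(auc, interest)
  keep <- !exclude
  if (sum(interest & keep) == 0 || sum(!interest & keep) == 0) {
    stop_format("exclusion_rerun: exclusion empties a group")
  }
  if (sum(interest & keep) < 3 || sum(!interest & keep) < 3) {
    stop_format("exclusion_rerun: exclusion leaves < 3 lines in a group")
  }
  sub <- drug_association(auc[keep], interest[keep])
  excluded <- if (!is.null(names(auc))) names(auc)[exclude] else which(exclude)
  list(p_all = full$p, p_excluded = sub$p, excluded_lines = excluded)
}
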