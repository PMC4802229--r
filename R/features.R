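# Binary cell-line groupings: histotype one-hot features, driver-gene
# alteration features, pathway logical-OR groupings, testability filtering
# and the pathway "better predictor" filter.

new_feature_matrix <- function(membership, kind, scope = "all_histotypes") {
  stopifnot(is.matrix(membership))
  vals <- membership[!is.na(membership)]
  if (any(!vals %in% c(0, 1))) {
    stop_format("feature matrix: membership must be 0, 1 or NA")
  }
  structure(list(membership = membership, kind = kind, scope = scope),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix (%s, scope %s): %d lines x %d features\n",
              x$kind, x$scope, nrow(x$membership), ncol(x$membership)))
  invisible(x)
}

#' One-hot histotype features
#'
#' One binary feature per histotype: the interest group is the histotype's
#' cell lines, the comparison group all other lines. Histotypes with fewer
#' than 2 lines (or no comparison group) are kept but flagged untestable.
#'
#' @param annotations data.table with `cell_line` and `histotype`.
#' @return `feature_matrix` (kind "histotype") with attribute `testable`, a
#'   named logical vector per feature.
#' @export
histotype_features <- function(annotations) {
  annotations <- data.table::as.data.table(annotations)
  require_columns(annotations, c("cell_line", "histotype"), "annotations")
  if (anyNA(annotations$histotype)) {
    stop_format("histotype_features: histotype must be non-null for every line")
  }
  lines <- annotations$cell_line
  hts <- sort(unique(annotations$histotype))
  m <- sapply(hts, function(h) as.integer(annotations$histotype == h))
  m <- matrix(m, nrow = length(lines), dimnames = list(lines, hts))
  fm <- new_feature_matrix(m, kind = "histotype")
  n_in <- colSums(m)
  attr(fm, "testable") <- setNames(n_in >= 2 & (nrow(m) - n_in) >= 2, hts)
  fm
}

#' Driver-gene alteration features
#'
#' Wraps a validated binary alteration matrix (cell line x driver gene) as a
#' feature matrix.
#'
#' @param alterations binary matrix with cell-line rownames.
#' @return `feature_matrix` (kind "driver_gene").
#' @export
alteration_features <- function(alterations) {
  new_feature_matrix(alterations, kind = "driver_gene")
}

#' Restrict a feature matrix to a within-histotype scope
#'
#' Membership outside the in-scope lines is set to NA, so downstream tests
#' compare altered vs unaltered lines within that histotype only (e.g. the
#' clear-cell vs other-ovarian subtype contrast).
#'
#' @param features `feature_matrix`.
#' @param lines_in_scope character vector of in-scope cell lines.
#' @param scope_label label stored on the result (e.g. "histotype:ovarian").
#' @return `feature_matrix` with the restricted scope.
#' @export
scope_restrict <- function(features, lines_in_scope, scope_label) {
  m <- features$membership
  m[!rownames(m) %in% lines_in_scope, ] <- NA
  new_feature_matrix(m, kind = features$kind, scope = scope_label)
}

#' Pathway logical-OR mutation groupings
#'
#' A cell line is pathway-altered if it carries an alteration in any member
#' gene of the pathway. NA propagates only when every member is NA; a single
#' observed 1 dominates. Member genes absent from the alteration matrix are
#' dropped with a warning; pathways with no resolvable member are skipped.
#'
#' @param alterations binary matrix (cell line x gene).
#' @param pathways named list of member-gene character vectors (see
#'   [read_gmt()]).
#' @return list of pathway groupings, each a list with `pathway`, `members`,
#'   `derived_membership` (named 0/1/NA vector) and `member_memberships`
#'   (matrix of the member columns).
#' @export
pathway_or_grouping <- function(alterations, pathways) {
  out <- list()
  for (pw in names(pathways)) {
    members <- unique(toupper(pathways[[pw]]))
    present <- intersect(members, colnames(alterations))
    absent <- setdiff(members, present)
    if (length(absent) > 0) {
      warning(sprintf("pathway '%s': dropping %d member(s) absent from alteration matrix: %s",
                      pw, length(absent), paste(absent, collapse = ", ")))
    }
    if (length(present) == 0) {
      warning(sprintf("pathway '%s': no resolvable members; skipped", pw))
      next
    }
    sub <- alterations[, present, drop = FALSE]
    any1 <- rowSums(sub == 1, na.rm = TRUE) > 0
    allna <- rowSums(!is.na(sub)) == 0
    derived <- ifelse(any1, 1L, ifelse(allna, NA_integer_, 0L))
    names(derived) <- rownames(alterations)
    out[[pw]] <- list(pathway = pw, members = present,
                      derived_membership = derived,
                      member_memberships = sub)
  }
  out
}

#' Assemble pathway groupings into a feature matrix
#'
#' @param groupings result of [pathway_or_grouping()].
#' @return `feature_matrix` (kind "pathway").
#' @export
pathway_features <- function(groupings) {
  if (length(groupings) == 0) stop_format("pathway_features: no groupings")
  m <- sapply(groupings, `[[`, "derived_membership")
  m <- matrix(m, ncol = length(groupings),
              dimnames = list(names(groupings[[1]]$derived_membership),
                              names(groupings)))
  new_feature_matrix(m, kind = "pathway")
}

#' Filter features to those testable at the required group sizes
#'
#' Retains features with at least `min_altered_lines` members AND at least
#' `min_altered_lines` non-members among in-scope (non-NA) lines. Idempotent.
#'
#' @param features `feature_matrix`.
#' @param min_altered_lines minimum group size on both sides (default 7).
#' @return `feature_matrix` with only the testable features.
#' @export
filter_testable <- function(features, min_altered_lines = 7) {
  m <- features$membership
  n1 <- colSums(m == 1, na.rm = TRUE)
  n0 <- colSums(m == 0, na.rm = TRUE)
  keep <- n1 >= min_altered_lines & n0 >= min_altered_lines
  new_feature_matrix(m[, keep, drop = FALSE], kind = features$kind,
                     scope = features$scope)
}

#' Is the pathway a better predictor of dependency than any single member?
#'
#' Spearman correlation between binary membership and the target's Z vector
#' (sensitization appears as negative rho). The pathway wins only if its
#' |rho| strictly exceeds the largest member |rho| — on a tie the single gene
#' is preferred as the more parsimonious explanation.
#'
#' @param z numeric Z vector across cell lines (names matching membership).
#' @param pathway_membership binary vector (pathway OR-grouping).
#' @param member_memberships binary matrix, one column per member gene.
#' @return list with `rho_pathway`, `rho_members` (named), `is_better`,
#'   `reason` (NULL unless the comparison was not evaluable).
#' @export
pathway_better_than_members <- function(z, pathway_membership,
                                        member_memberships) {
  res <- list(rho_pathway = NA_real_, rho_members = NULL,
              is_better = FALSE, reason = NULL)
  ok <- !is.na(z) & !is.na(pathway_membership)
  if (sum(pathway_membership[ok] == 1) < 3 ||
      sum(pathway_membership[ok] == 0) < 3) {
    res$reason <- "fewer than 3 lines in a group"
    return(res)
  }
  if (sd(z[ok]) == 0) {
    res$reason <- "constant Z vector: Spearman rho undefined"
    return(res)
  }
  sp <- function(memb) {
    keep <- !is.na(z) & !is.na(memb)
    if (sd(memb[keep]) == 0 || sd(z[keep]) == 0) return(NA_real_)
    cor(memb[keep], z[keep], method = "spearman")
  }
  res$rho_pathway <- sp(pathway_membership)
  res$rho_members <- apply(member_memberships, 2, sp)
  best_member <- suppressWarnings(max(abs(res$rho_members), na.rm = TRUE))
  if (!is.finite(best_member)) best_member <- 0
  res$is_better <- isTRUE(abs(res$rho_pathway) > best_member)
  res
}
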