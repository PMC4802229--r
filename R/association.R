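# Median-permutation (MP) association testing: the core statistic linking a
# binary cell-line grouping (histotype, driver alteration, pathway) to
# sensitivity to one siRNA target.
#
# For each (feature, target) pair the observed difference between the median
# Z of the interest group and the median Z of the "other" group is compared
# with the same difference under random re-assignments of the group labels at
# fixed group sizes. The test is one-sided toward sensitization (more
# negative difference), and the empirical p uses the +1/(N+1) correction so
# p = 0 is impossible with finite permutations.

#' One-sided median-permutation test
#'
#' @param z numeric vector of robust Z scores across cell lines.
#' @param interest logical (or 0/1) vector marking the interest group.
#' @param n_permutations number of random label permutations (default 10^4;
#'   full-scale runs use 10^6).
#' @param seed integer seed for this test's independent permutation stream.
#' @return list with `delta_median` (median Z interest - median Z other),
#'   `p_empirical` = (1 + #\{permuted delta <= observed\}) / (N + 1),
#'   `n_interest`, `n_other`, `n_permutations`, `seed`.
#' @examples
#' mp_test(c(-5, -5, 0, 0, 0), c(TRUE, TRUE, FALSE, FALSE, FALSE),
#'         n_permutations = 1e4, seed = 7)
#' @export
mp_test <- function(z, interest, n_permutations = 1e4, seed = 1) {
  interest <- as.logical(interest)
  keep <- !is.na(z) & !is.na(interest)
  z <- z[keep]; interest <- interest[keep]
  if (sum(interest) < 2 || sum(!interest) < 2) {
    stop_format("mp_test: need >= 2 cell lines per group after NA removal (got %d vs %d)",
                sum(interest), sum(!interest))
  }
  observed <- median(z[interest]) - median(z[!interest])
  count <- mp_permute_count(z, sum(interest), as.integer(n_permutations),
                            observed, as.double(seed))
  list(delta_median = observed,
       p_empirical = (1 + count) / (n_permutations + 1),
       n_interest = sum(interest), n_other = sum(!interest),
       n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}

#' Exact MP test by complete enumeration
#'
#' Enumerates every assignment of the interest-group labels (all
#' `choose(n, n_interest)` subsets) and reports the exact left-tail
#' probability of the observed median difference. Serves as the oracle for
#' the sampled test on small instances.
#'
#' @inheritParams mp_test
#' @param max_combinations refuse enumeration beyond this many subsets.
#' @return list with `delta_median`, `p_exact`, `n_combinations`.
#' @export
mp_test_exact <- function(z, interest, max_combinations = 1e6) {
  interest <- as.logical(interest)
  keep <- !is.na(z) & !is.na(interest)
  z <- z[keep]; interest <- interest[keep]
  n <- length(z); k <- sum(interest)
  if (k < 1 || k > n) stop_format("mp_test_exact: invalid interest group")
  nc <- choose(n, k)
  if (nc > max_combinations) {
    stop_format("mp_test_exact: %.3g label assignments exceed the enumeration limit; use the sampled mp_test",
                nc)
  }
  observed <- median(z[interest]) - median(z[!interest])
  if (k == n) {
    return(list(delta_median = observed, p_exact = 1, n_combinations = 1))
  }
  idx <- combn(n, k)
  deltas <- apply(idx, 2, function(ii) median(z[ii]) - median(z[-ii]))
  list(delta_median = observed,
       p_exact = sum(deltas <= observed) / nc,
       n_combinations = nc)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) m * p_(j) / j`, clipped at
#' 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return vector of q-values, same order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop_format("bh_fdr: p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Run MP tests for every (feature, target) pair of a screen
#'
#' For each feature, cell lines with non-NA membership define the scope; for
#' each target, NA Z values are dropped with their labels, the one-sided MP
#' test is run with a per-pair seed derived from `(seed, feature, target)`
#' (so results are independent of test order), and BH correction is applied
#' per feature across its targets (optionally globally).
#'
#' @param screen `screen_matrix` or Z matrix (cell lines x targets).
#' @param features `feature_matrix`.
#' @param n_permutations permutations per test.
#' @param seed global seed.
#' @param fdr threshold used for the `significant` flag (0.1 for histotype
#'   runs, 0.5 for the driver focus set).
#' @param bh_scope "per_feature" (default) or "global".
#' @param p_cut additionally flag nominally significant tests (uncorrected
#'   p <= p_cut with delta < 0) in the `nominal` column.
#' @return data.table of association records sorted by (scope, feature, q);
#'   skipped pairs (a group emptied by NA removal or below size 2) are
#'   reported via message and omitted.
#' @export
run_association_screen <- function(screen, features, n_permutations = 1e4,
                                   seed = 1, fdr = 0.1,
                                   bh_scope = c("per_feature", "global"),
                                   p_cut = 0.05) {
  bh_scope <- match.arg(bh_scope)
  z <- as_z_matrix(screen)
  m <- features$membership
  common <- intersect(rownames(z), rownames(m))
  if (length(common) == 0) {
    stop_format("run_association_screen: no shared cell lines between screen and features")
  }
  z <- z[common, , drop = FALSE]
  m <- m[common, , drop = FALSE]

  n_pairs <- ncol(m) * ncol(z)
  col_f <- character(n_pairs); col_t <- character(n_pairs)
  col_ni <- integer(n_pairs); col_no <- integer(n_pairs)
  col_d <- numeric(n_pairs); col_p <- numeric(n_pairs)
  col_seed <- integer(n_pairs)
  ri <- 0L; n_skipped <- 0L
  for (f in colnames(m)) {
    memb <- m[, f]
    in_scope <- which(!is.na(memb))
    mask0 <- memb[in_scope] == 1
    for (tg in colnames(z)) {
      zi <- z[in_scope, tg]
      ok <- !is.na(zi)
      mask <- mask0[ok]; zv <- zi[ok]
      ni <- sum(mask); no <- length(mask) - ni
      if (ni < 2 || no < 2) {
        n_skipped <- n_skipped + 1L
        next
      }
      observed <- median(zv[mask]) - median(zv[!mask])
      ps <- hash_seed(seed, f, tg)
      count <- mp_permute_count(zv, ni, as.integer(n_permutations),
                                observed, as.double(ps))
      ri <- ri + 1L
      col_f[ri] <- f; col_t[ri] <- tg
      col_ni[ri] <- ni; col_no[ri] <- no
      col_d[ri] <- observed
      col_p[ri] <- (1 + count) / (n_permutations + 1)
      col_seed[ri] <- ps
    }
  }
  if (n_skipped > 0) {
    message(sprintf("run_association_screen: skipped %d (feature, target) pair(s) with < 2 lines per group",
                    n_skipped))
  }
  if (ri == 0L) {
    return(data.table::data.table())
  }
  keep <- seq_len(ri)
  out <- data.table::data.table(
    feature = col_f[keep], feature_kind = features$kind,
    scope = features$scope, target_gene = col_t[keep],
    n_interest = col_ni[keep], n_other = col_no[keep],
    delta_median = col_d[keep], p_empirical = col_p[keep],
    n_permutations = as.integer(n_permutations), seed = col_seed[keep])
  if (bh_scope == "per_feature") {
    out[, q_bh := bh_fdr(p_empirical), by = feature]
  } else {
    out[, q_bh := bh_fdr(p_empirical)]
  }
  out[, significant := q_bh <= fdr & delta_median < 0]
  out[, nominal := p_empirical <= p_cut & delta_median < 0]
  data.table::setcolorder(out, c(ASSOC_COLS, "nominal"))
  out[order(scope, feature, q_bh, p_empirical, target_gene)][]
}

#' Dependencies recurring across histotype scopes
#'
#' Given association records pooled from several within-histotype runs,
#' returns the (feature, target) pairs that are nominally significant
#' (p <= `p_cut`, delta < 0) in at least two distinct histotype scopes.
#'
#' @param records data.table of association records carrying a `scope`
#'   column with one value per within-histotype run.
#' @param p_cut nominal significance cutoff (default 0.05).
#' @return data.table with `feature`, `target_gene`, `n_scopes`, `scopes`.
#' @export
recurrent_dependencies <- function(records, p_cut = 0.05) {
  records <- data.table::as.data.table(records)
  if (data.table::uniqueN(records$scope) < 2) {
    stop_format("recurrent_dependencies: need records from >= 2 histotype scopes")
  }
  hits <- records[p_empirical <= p_cut & delta_median < 0]
  rec <- hits[, .(n_scopes = data.table::uniqueN(scope),
                  scopes = paste(sort(unique(scope)), collapse = ",")),
              by = .(feature, target_gene)]
  rec[n_scopes >= 2][order(-n_scopes, feature, target_gene)][]
}
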