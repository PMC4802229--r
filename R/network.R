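# Typed interaction graph: direct-link annotation of driver->kinase
# dependencies, shortest directed molecular paths, one-intermediate
# reachability, and within-set connectivity enrichment on the functional
# (STRING-like) layer.

DIRECT_TYPES <- c("ppi", "kinase_substrate", "regulatory")

#' Build a typed interaction graph from an edge table
#'
#' Functional edges with combined score at or below `string_min_score` are
#' excluded (high-confidence means score > 0.7); self-loops are dropped;
#' duplicate undirected edges (A,B)/(B,A) of the same type are stored once in
#' canonical order; directed edge types keep their stated direction. A pair
#' of genes may carry several edge types (typed multigraph).
#'
#' @param edges data.table from [read_edge_table()] (or equivalent).
#' @param string_min_score keep functional edges with score strictly greater
#'   than this (default 0.7).
#' @return object of class `interaction_graph`: list with `edges`
#'   (data.table) and `nodes` (character).
#' @export
build_graph <- function(edges, string_min_score = 0.7) {
  ed <- data.table::as.data.table(edges)
  require_columns(ed, EDGE_COLS, "edge table")
  ed <- ed[gene_a != "" & gene_b != ""]
  sc <- ed[edge_type == "functional", score]
  if (any(is.na(sc)) || any(sc < 0 | sc > 1)) {
    stop_format("build_graph: functional scores must lie in [0, 1]")
  }
  loops <- ed$gene_a == ed$gene_b
  if (any(loops)) {
    warning(sprintf("build_graph: dropping %d self-loop(s)", sum(loops)))
    ed <- ed[!loops]
  }
  ed <- ed[!(edge_type == "functional" & score <= string_min_score)]
  # canonicalize undirected edges so (A,B) and (B,A) collapse to one row
  undir <- ed$directed == 0
  swap <- undir & ed$gene_a > ed$gene_b
  tmp <- ed$gene_a[swap]
  ed[swap, gene_a := gene_b]
  ed$gene_b[swap] <- tmp
  ed <- unique(ed, by = c("gene_a", "gene_b", "edge_type", "directed"))
  structure(list(edges = ed[], nodes = sort(unique(c(ed$gene_a, ed$gene_b)))),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              paste(sprintf("%s=%d", names(table(x$edges$edge_type)),
                            table(x$edges$edge_type)), collapse = ", ")))
  invisible(x)
}

#' Annotate driver-dependency pairs with known direct molecular links
#'
#' For each (driver, target) pair, reports the set of direct edge types
#' (ppi, kinase_substrate, regulatory) connecting the two genes in either
#' orientation: a substrate of the driver and a kinase acting on the driver
#' both count as a previously reported functional relationship. Genes absent
#' from the graph simply yield an empty link set.
#'
#' @param pairs data.table (or data.frame) with columns `driver`, `target`.
#' @param graph `interaction_graph`.
#' @return data.table with `driver`, `target`, `direct_link` (comma-joined
#'   types, "" when none), `has_direct_link`.
#' @export
annotate_direct_links <- function(pairs, graph) {
  pairs <- data.table::as.data.table(pairs)
  require_columns(pairs, c("driver", "target"), "pairs")
  ed <- graph$edges[edge_type %in% DIRECT_TYPES]
  key <- unique(rbind(ed[, .(a = gene_a, b = gene_b, edge_type)],
                      ed[, .(a = gene_b, b = gene_a, edge_type)]))
  out <- pairs[, {
    types <- sort(unique(key[a == driver & b == target, edge_type]))
    .(direct_link = paste(types, collapse = ","),
      has_direct_link = length(types) > 0)
  }, by = .(driver, target)]
  out[]
}

# adjacency list for path traversal: ppi bidirectional, kinase_substrate /
# regulatory only in their stated direction; functional edges excluded
path_adjacency <- function(graph) {
  ed <- graph$edges[edge_type %in% DIRECT_TYPES]
  fwd <- ed[, .(from = gene_a, to = gene_b)]
  back <- ed[directed == 0, .(from = gene_b, to = gene_a)]
  adj <- unique(rbind(fwd, back))
  split(adj$to, adj$from)
}

#' Shortest known molecular path from a driver to a kinase dependency
#'
#' Minimum-hop path on the typed graph treating ppi edges as bidirectional
#' and kinase_substrate/regulatory edges as traversable only in their stated
#' direction (functional edges are not used for paths). Among equal-length
#' paths, each step takes the lexicographically smallest admissible
#' predecessor, so the result is deterministic.
#'
#' @param driver,target gene symbols.
#' @param graph `interaction_graph`.
#' @return character vector of genes from driver to target (length 1 when
#'   driver == target), or NULL when either gene is absent or the target is
#'   unreachable.
#' @export
shortest_driver_target_path <- function(driver, target, graph) {
  if (!(driver %in% graph$nodes) || !(target %in% graph$nodes)) return(NULL)
  if (driver == target) return(driver)
  adj <- path_adjacency(graph)
  dist <- setNames(rep(NA_integer_, length(graph$nodes)), graph$nodes)
  dist[driver] <- 0L
  frontier <- driver
  d <- 0L
  while (length(frontier) > 0 && is.na(dist[target])) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt) & is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  if (is.na(dist[target])) return(NULL)
  # backtrack, choosing the lexicographically smallest predecessor per step
  rev_adj <- local({
    pairs <- data.table::data.table(
      from = rep(names(adj), lengths(adj)),
      to = unlist(adj, use.names = FALSE))
    split(pairs$from, pairs$to)
  })
  path <- target
  v <- target
  while (dist[v] > 0L) {
    preds <- rev_adj[[v]]
    preds <- preds[!is.na(dist[preds]) & dist[preds] == dist[v] - 1L]
    u <- sort(preds)[1]
    path <- c(u, path)
    v <- u
  }
  unname(path)
}

#' Full dependency annotation: direct links plus shortest paths
#'
#' Pairs with a direct link (any orientation) are annotated path_length 1;
#' only pairs without a direct link are submitted to the directed
#' shortest-path search, mirroring the analysis narrative (paths explain the
#' dependencies that direct interactions cannot).
#'
#' @inheritParams annotate_direct_links
#' @return data.table with `driver`, `target`, `direct_link`,
#'   `has_direct_link`, `shortest_path` ("/"-joined genes or NA),
#'   `path_length` (0 for driver == target, 1 for direct, NA unreachable).
#' @export
annotate_dependencies <- function(pairs, graph) {
  ann <- annotate_direct_links(pairs, graph)
  ann[, `:=`(shortest_path = NA_character_, path_length = NA_integer_)]
  for (i in seq_len(nrow(ann))) {
    if (ann$has_direct_link[i]) {
      ann[i, `:=`(shortest_path = paste(driver, target, sep = "/"),
                  path_length = 1L)]
      next
    }
    p <- shortest_driver_target_path(ann$driver[i], ann$target[i], graph)
    if (!is.null(p)) {
      ann[i, `:=`(shortest_path = paste(p, collapse = "/"),
                  path_length = length(p) - 1L)]
    }
  }
  ann[]
}

#' Count dependencies reachable by adding one intermediate connection
#'
#' Pairs with no direct link whose shortest admissible path has length 2
#' (driver -> intermediate -> target).
#'
#' @param annotations result of [annotate_dependencies()].
#' @return list with `count` and `flags` (logical per pair).
#' @export
count_one_intermediate <- function(annotations) {
  flags <- !annotations$has_direct_link &
    !is.na(annotations$path_length) & annotations$path_length == 2L
  list(count = sum(flags), flags = flags)
}

#' Connectivity enrichment of a gene set on the functional network
#'
#' Tests whether a gene set (e.g. the dependencies of one driver) carries
#' more within-set functional edges than uniformly drawn same-size sets from
#' the screened background. Multiple edges between a pair count once.
#'
#' @param gene_set character vector (subset of `background`).
#' @param graph `interaction_graph` (only its functional edges are used).
#' @param background gene universe to draw null sets from (screened library
#'   genes present in the graph).
#' @param n_permutations null draws (default 10^4).
#' @param seed integer seed.
#' @return list with `set_size`, `observed_edges`, `null_mean`,
#'   `p_empirical`, `n_permutations`, `seed`.
#' @export
connectivity_enrichment <- function(gene_set, graph, background,
                                    n_permutations = 1e4, seed = 1) {
  gene_set <- unique(toupper(gene_set))
  background <- unique(toupper(background))
  if (!all(gene_set %in% background)) {
    stop_format("connectivity_enrichment: gene_set must be a subset of background")
  }
  if (length(gene_set) < 2) {
    warning("connectivity_enrichment: set size < 2; p = 1")
    return(list(set_size = length(gene_set), observed_edges = 0L,
                null_mean = 0, p_empirical = 1,
                n_permutations = as.integer(n_permutations),
                seed = as.integer(seed)))
  }
  ed <- graph$edges[edge_type == "functional" &
                      gene_a %in% background & gene_b %in% background]
  nb <- length(background)
  A <- matrix(FALSE, nb, nb, dimnames = list(background, background))
  A[cbind(ed$gene_a, ed$gene_b)] <- TRUE
  A[cbind(ed$gene_b, ed$gene_a)] <- TRUE
  count_edges <- function(s) sum(A[s, s]) / 2
  observed <- count_edges(gene_set)
  k <- length(gene_set)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) count_edges(sample(background, k)), numeric(1))
  })
  list(set_size = k, observed_edges = as.integer(observed),
       null_mean = mean(null),
       p_empirical = (1 + sum(null >= observed)) / (n_permutations + 1),
       n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}

#' Export an interaction graph in SIF format
#'
#' @param graph `interaction_graph`.
#' @param path output file (lines `gene_a<TAB>edge_type<TAB>gene_b`).
#' @export
export_sif <- function(graph, path) {
  writeLines(sprintf("%s\t%s\t%s", graph$edges$gene_a, graph$edges$edge_type,
                     graph$edges$gene_b), path)
  invisible(path)
}
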