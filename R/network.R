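# Signed Spearman co-occurrence networks and their attribute block.
#
# Edges connect OTU pairs whose Spearman correlation across samples
# passes |r| >= r_cutoff with an FDR-adjusted p < alpha.  The absolute-r
# rule keeps negative associations as edges: real amplicon networks of
# this kind report both positive and negative edge counts, which a
# one-sided r >= cutoff rule could not produce.

#' Select OTUs above an overall relative-abundance threshold
#'
#' Retains OTUs whose summed abundance across all samples exceeds
#' `threshold` times the grand total (strict `>`), i.e., the ">0.1% of
#' total sequences" convention.
#'
#' @param table abundance matrix (samples x OTUs).
#' @param threshold overall proportion cutoff in (0, 1).
#' @param per_sample_mean use the mean of per-sample proportions instead
#'   of the pooled proportion.
#' @return character vector of retained OTU ids.
#' @export
filter_abundant <- function(table, threshold = 0.001,
                            per_sample_mean = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  m <- unclass(table)
  prop <- if (per_sample_mean) colMeans(m / rowSums(m))
  else colSums(m) / sum(m)
  keep <- colnames(m)[prop > threshold]
  if (length(keep) == 0L)
    stop("no OTUs above the abundance threshold; lower it", call. = FALSE)
  keep
}

#' Build a signed Spearman co-occurrence network
#'
#' All pairwise Spearman correlations among the table's OTUs; p-values
#' from the t approximation, Benjamini-Hochberg adjusted over all pairs;
#' edges kept when `q < alpha` and `|r| >= r_cutoff`.  Constant OTUs are
#' excluded with a warning.
#'
#' @param table abundance matrix (samples x OTUs) already restricted to
#'   the abundant subset.
#' @param r_cutoff absolute correlation cutoff.
#' @param alpha adjusted-significance level.
#' @return list of class `htqs_network`: `nodes` (all tested OTUs),
#'   `edges` (data.frame `otu_a`, `otu_b`, `r`, `q`, `sign`), and `graph`
#'   (an igraph object over `nodes`).
#' @export
build_network <- function(table, r_cutoff = 0.6, alpha = 0.05) {
  m <- unclass(table)
  if (nrow(m) < 5L) stop("need >= 5 samples", call. = FALSE)
  if (ncol(m) < 2L) stop("need >= 2 OTUs", call. = FALSE)
  constant <- apply(m, 2, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warning("excluding constant OTUs: ",
            paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
    m <- m[, !constant, drop = FALSE]
  }
  n <- nrow(m); p <- ncol(m)
  r <- stats::cor(m, method = "spearman")
  ut <- upper.tri(r)
  rv <- r[ut]
  tv <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tv), df = n - 2)
  pv[abs(rv) >= 1] <- 0
  qv <- stats::p.adjust(pv, "BH")
  ij <- which(ut, arr.ind = TRUE)
  keep <- qv < alpha & abs(rv) >= r_cutoff
  edges <- data.frame(otu_a = colnames(m)[ij[keep, 1]],
                      otu_b = colnames(m)[ij[keep, 2]],
                      r = rv[keep], q = qv[keep],
                      sign = ifelse(rv[keep] > 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("otu_a", "otu_b")],
                                     directed = FALSE,
                                     vertices = colnames(m))
  igraph::E(g)$r <- edges$r
  igraph::E(g)$q <- edges$q
  igraph::E(g)$sign <- edges$sign
  structure(list(nodes = colnames(m), edges = edges, graph = g),
            class = "htqs_network")
}

#' @export
print.htqs_network <- function(x, ...) {
  cat(sprintf("<htqs network: %d nodes, %d edges (%d+, %d-)>\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign > 0),
              sum(x$edges$sign < 0)))
  invisible(x)
}

#' Attribute block of a co-occurrence network
#'
#' Average degree `2E/N`; average clustering coefficient as the mean of
#' local triangle densities with degree-<2 nodes contributing 0; average
#' path length over connected node pairs only; Newman modularity `Q` of a
#' seeded Louvain partition on the unweighted, sign-ignored graph.
#'
#' @param net an `htqs_network` (or bare igraph object).
#' @param seed seed for the Louvain partition.
#' @return data.frame row: `node_count`, `edge_count`, `positive_edges`,
#'   `negative_edges`, `average_degree`, `average_clustering_coefficient`,
#'   `average_path_length` (NA with a warning if edgeless), `modularity`,
#'   `n_components`.
#' @export
network_attributes <- function(net, seed = 1L) {
  g <- if (inherits(net, "htqs_network")) net$graph else net
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  stopifnot(n >= 1)
  signs <- if (!is.null(igraph::E(g)$sign)) igraph::E(g)$sign
  else rep(1L, e)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0
  if (e > 0) {
    apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    set.seed(seed)
    comm <- igraph::cluster_louvain(g, resolution = 1)
    q <- igraph::modularity(g, igraph::membership(comm))
  } else {
    warning("edgeless graph: average path length undefined", call. = FALSE)
    apl <- NA_real_
    q <- NA_real_
  }
  data.frame(node_count = n, edge_count = e,
             positive_edges = sum(signs > 0),
             negative_edges = sum(signs < 0),
             average_degree = 2 * e / n,
             average_clustering_coefficient = mean(local_cc),
             average_path_length = apl,
             modularity = q,
             n_components = igraph::components(g)$no)
}

#' Write a network to GraphML
#' @param net an `htqs_network`.
#' @param path output path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
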