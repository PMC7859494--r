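# Alpha diversity on the relative-abundance (rarefied) branch.

#' Observed richness
#' @param x non-negative count vector for one sample.
#' @return number of OTUs with count > 0.
#' @export
richness <- function(x) sum(x > 0)

#' Chao 1 richness estimator
#'
#' Bias-corrected form by default:
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1` singletons and `F2`
#' doubletons.  The classic form `S_obs + F1^2 / (2 F2)` is available;
#' it is undefined (returned as `S_obs`) when `F2 = 0`.
#'
#' @param x integer count vector.
#' @param bias_corrected use the bias-corrected variant (default).
#' @return estimated richness, always `>=` observed richness.
#' @export
chao1 <- function(x, bias_corrected = TRUE) {
  if (any(x != round(x))) stop("chao1 requires integer counts", call. = FALSE)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs
}

#' Shannon diversity index
#' @param x non-negative abundance vector with at least one positive entry.
#' @param base logarithm base (default 2).
#' @return `-sum(p * log(p, base))` over positive proportions.
#' @export
shannon <- function(x, base = 2) {
  if (all(x == 0)) stop("Shannon index undefined for an all-zero sample",
                        call. = FALSE)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

# per-node parent edge index lookup for a phylo object
.parent_edges <- function(tree) {
  n_node <- max(tree$edge)
  parent_edge <- integer(n_node)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_edge
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the observed
#' tips to the root (rooted variant, the historical default of amplicon
#' toolchains).  With `include_root = FALSE` the branches on the path
#' between the root and the observed tips' most recent common ancestor
#' are excluded.
#'
#' @param x named non-negative abundance vector (names = tip labels) or a
#'   character vector of observed tip labels.
#' @param tree rooted `phylo` with branch lengths.
#' @param include_root include the root path (default TRUE).
#' @return total branch length of the subtending subtree.
#' @export
faith_pd <- function(x, tree, include_root = TRUE) {
  tips <- if (is.character(x)) x else names(x)[x > 0]
  if (length(tips) == 0L) return(0)
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss) > 0L)
    stop("observed OTUs missing from tree: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  idx <- match(tips, tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent_edge <- .parent_edges(tree)
  root <- ape::Ntip(tree) + 1L
  used <- logical(nrow(tree$edge))
  for (node in idx) {
    while (node != root && !used[parent_edge[node]]) {
      used[parent_edge[node]] <- TRUE
      node <- parent[node]
    }
  }
  pd <- sum(tree$edge.length[used])
  if (!include_root) {
    # subtract the unbranched chain from the root down to the MRCA
    mrca <- if (length(idx) == 1L) idx else ape::getMRCA(tree, tips)
    node <- mrca
    while (node != root) {
      pd <- pd - tree$edge.length[parent_edge[node]]
      node <- parent[node]
    }
  }
  pd
}

#' Alpha-diversity table for all samples
#'
#' @param counts rarefied [count_table()].
#' @param tree rooted `phylo` covering the table's OTUs.
#' @param shannon_base logarithm base for Shannon.
#' @return data.frame with `sample_id`, `richness`, `chao1`, `shannon`,
#'   `faith_pd`.
#' @export
alpha_diversity <- function(counts, tree, shannon_base = 2) {
  m <- unclass(counts)
  data.frame(
    sample_id = rownames(m),
    richness = apply(m, 1, richness),
    chao1 = apply(m, 1, chao1),
    shannon = apply(m, 1, shannon, base = shannon_base),
    faith_pd = apply(m, 1, faith_pd, tree = tree),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Rarefaction curve for one sample
#'
#' Mean observed richness over repeated seeded subsamples at each depth.
#'
#' @param x integer count vector.
#' @param depths increasing subsampling depths (each `<=` the sample
#'   total).
#' @param n_reps subsamples per depth.
#' @param seed integer seed.
#' @return data.frame with `depth` and `mean_richness`.
#' @export
rarefaction_curve <- function(x, depths, n_reps = 10L, seed = 1L) {
  total <- sum(x)
  if (any(depths > total))
    stop("depth exceeds sample total (", total, ")", call. = FALSE)
  set.seed(seed)
  cum <- cumsum(x)
  mean_rich <- vapply(depths, function(d) {
    mean(vapply(seq_len(n_reps), function(r) {
      idx <- sample.int(total, d)
      length(unique(findInterval(idx - 1L, cum)))
    }, numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, mean_richness = mean_rich)
}
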