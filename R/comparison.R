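# Whole-community comparison of the relative and quantitative branches:
# Bray-Curtis distances, principal coordinates, symmetric Procrustes with
# a Monte-Carlo (PROTEST-style) significance test, per-OTU rank
# concordance, and taxonomy-level aggregation.

#' Bray-Curtis distance matrix
#'
#' `d(i,j) = 1 - 2 sum(min(x_i, x_j)) / sum(x_i + x_j)`.
#'
#' @param table non-negative abundance matrix, samples x OTUs.
#' @return symmetric `dist`-free matrix with zero diagonal, entries in
#'   \[0, 1\], sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("Bray-Curtis undefined for all-zero samples: ",
         paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    mins <- colSums(pmin(t(m[(i + 1):n, , drop = FALSE]), m[i, ]))
    d[i, (i + 1):n] <- d[(i + 1):n, i] <-
      1 - 2 * mins / (totals[(i + 1):n] + totals[i])
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared-distance matrix and eigendecomposes it.
#' Axes with non-positive eigenvalues are dropped (with a warning when
#' meaningfully negative eigenvalues are present); for a Euclidean input
#' the embedding reproduces the distances exactly.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return list with `coordinates` (samples x axes, eigenvalue-ordered),
#'   `eigenvalues` (positive, non-increasing), `sample_ids`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(d)
  j <- diag(n) - 1 / n
  g <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  if (any(e$values < -tol))
    warning(sprintf("dropping %d negative-eigenvalue axes (non-Euclidean distances)",
                    sum(e$values < -tol)), call. = FALSE)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = e$values[pos],
       sample_ids = rownames(d))
}

# center, scale to unit sum of squares, optimal rotation; returns the
# symmetric Procrustes statistic m2 = 1 - (sum of singular values)^2
.procrustes_m2 <- function(x, y) {
  x <- scale(x, center = TRUE, scale = FALSE)
  y <- scale(y, center = TRUE, scale = FALSE)
  x <- x / sqrt(sum(x^2))
  y <- y / sqrt(sum(y^2))
  1 - sum(svd(crossprod(x, y))$d)^2
}

#' Symmetric Procrustes agreement with Monte-Carlo significance
#'
#' Both ordinations are centered and scaled to unit trace, the optimal
#' rotation computed, and the goodness of fit reported as the residual
#' `M^2` in \[0, 1\] (0 = identical shapes up to rotation, translation,
#' and scale).  Significance comes from row permutations of the second
#' ordination with the add-one convention
#' `p = (1 + #\{M2_perm <= M2_obs\}) / (n_perm + 1)`.
#'
#' @param ord_rel,ord_quant outputs of [pcoa()] (or plain coordinate
#'   matrices) over the same samples; axes are truncated to the smaller
#'   shared count.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `m_squared`, `p_value`, `n_permutations`, `seed`.
#' @export
procrustes_test <- function(ord_rel, ord_quant, n_perm = 999L, seed = 1L) {
  x <- if (is.list(ord_rel)) ord_rel$coordinates else ord_rel
  y <- if (is.list(ord_quant)) ord_quant$coordinates else ord_quant
  if (nrow(x) != nrow(y) ||
      (!is.null(rownames(x)) && !is.null(rownames(y)) &&
         !identical(rownames(x), rownames(y))))
    stop("ordinations must cover the same samples in the same order",
         call. = FALSE)
  k <- min(ncol(x), ncol(y))
  x <- x[, seq_len(k), drop = FALSE]
  y <- y[, seq_len(k), drop = FALSE]
  m2 <- .procrustes_m2(x, y)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (.procrustes_m2(x, y[sample.int(nrow(y)), , drop = FALSE]) <= m2)
      hits <- hits + 1L
  }
  list(m_squared = m2, p_value = (1 + hits) / (n_perm + 1),
       n_permutations = as.integer(n_perm), seed = as.integer(seed))
}

# Spearman correlation with the t-approximation p-value (AS 89 is
# unnecessary at the sample sizes used here; ties handled by mid-ranks)
.spearman_test <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(c(r = NA_real_, p = NA_real_))
  r <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(r) >= 1) return(c(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Per-OTU concordance between relative and quantitative abundance
#'
#' For OTUs present (count > 0) in every sample of both tables, the
#' Spearman correlation across samples between relative and quantitative
#' abundance, with Benjamini-Hochberg q-values.  Constant OTUs (tied
#' ranks throughout) are excluded with a warning.
#'
#' @param rel relative-abundance matrix (samples x OTUs).
#' @param quant copies-per-liter matrix (samples x OTUs).
#' @return list with `table` (data.frame `otu_id`, `spearman_r`,
#'   `p_value`, `q_value`) and `summary` (`frac_r_below_0.8`,
#'   `frac_nonsignificant` at q >= 0.05).
#' @export
per_otu_concordance <- function(rel, quant) {
  rel <- unclass(rel); quant <- unclass(quant)
  if (nrow(rel) < 5L) stop("need >= 5 samples", call. = FALSE)
  shared <- intersect(colnames(rel), colnames(quant))
  everywhere <- shared[colSums(rel[, shared, drop = FALSE] > 0) == nrow(rel) &
                         colSums(quant[, shared, drop = FALSE] > 0) == nrow(quant)]
  res <- t(vapply(everywhere, function(j) .spearman_test(rel[, j], quant[, j]),
                  numeric(2)))
  drop <- is.na(res[, 1])
  if (any(drop))
    warning(sum(drop), " constant OTUs excluded from concordance",
            call. = FALSE)
  res <- res[!drop, , drop = FALSE]
  tab <- data.frame(otu_id = rownames(res), spearman_r = res[, 1],
                    p_value = res[, 2],
                    q_value = stats::p.adjust(res[, 2], "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       summary = c(frac_r_below_0.8 = mean(tab$spearman_r < 0.8),
                   frac_nonsignificant = mean(tab$q_value >= 0.05)))
}

.rank_index <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L)

#' Aggregate an abundance table at a taxonomic rank
#'
#' Sums OTU columns sharing the lineage label at the requested rank.
#' OTUs without a label at that rank are pooled as `"Others"`.
#'
#' @param table abundance matrix (samples x OTUs).
#' @param taxonomy a [taxonomy_table()].
#' @param rank one of `"phylum"`, `"class"`, `"order"`.
#' @param top keep the `top` most abundant groups and pool the rest into
#'   `"Others"`; `NULL` (default) keeps all groups.
#' @return aggregated matrix (samples x groups), most abundant first.
#' @export
aggregate_taxonomy <- function(table, taxonomy, rank = "order", top = NULL) {
  if (!rank %in% c("phylum", "class", "order"))
    stop("rank must be one of phylum, class, order", call. = FALSE)
  m <- unclass(table)
  lin <- strsplit(taxonomy$lineage[match(colnames(m), taxonomy$otu_id)], ";",
                  fixed = TRUE)
  i <- .rank_index[[rank]]
  lab <- vapply(lin, function(v) if (length(v) >= i) v[i] else "Others",
                character(1))
  lab[is.na(lab) | lab == ""] <- "Others"
  groups <- sort(unique(lab))
  agg <- vapply(groups, function(g) rowSums(m[, lab == g, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) agg <- matrix(agg, 1, dimnames = list(rownames(m), groups))
  ord <- order(colSums(agg), decreasing = TRUE)
  agg <- agg[, ord, drop = FALSE]
  if (!is.null(top) && ncol(agg) > top) {
    keep <- setdiff(colnames(agg)[seq_len(top)], "Others")
    others <- rowSums(agg[, !colnames(agg) %in% keep, drop = FALSE])
    agg <- cbind(agg[, keep, drop = FALSE], Others = others)
  }
  agg
}
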