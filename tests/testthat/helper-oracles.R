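# Independent brute-force oracles.  These deliberately re-derive each
# quantity from first principles (normal equations, double loops, full
# enumerations) and never call the package code paths they check.

oracle_ols <- function(x, y) {
  n <- length(x)
  a <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  b <- mean(y) - a * mean(x)
  ss_res <- sum((y - (a * x + b))^2)
  c(a = a, b = b, r2 = 1 - ss_res / sum((y - mean(y))^2))
}

oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(ncol(m))) {
      num <- num + min(m[i, k], m[j, k])
      den <- den + m[i, k] + m[j, k]
    }
    d[i, j] <- 1 - 2 * num / den
  }
  d
}

oracle_shannon <- function(x, base = 2) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p) / log(base))
}

oracle_chao1 <- function(x) {
  sum(x > 0) + sum(x == 1) * (sum(x == 1) - 1) / (2 * (sum(x == 2) + 1))
}

# Faith's PD by explicit edge enumeration: an edge is in the subtree iff
# its child clade contains an observed tip (rooted variant)
oracle_faith <- function(tips, tree) {
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    clade <- if (child <= ape::Ntip(tree)) tree$tip.label[child]
    else ape::extract.clade(tree, child)$tip.label
    if (any(tips %in% clade)) total <- total + tree$edge.length[e]
  }
  total
}

# all-pairs shortest paths by repeated BFS on an edge list
oracle_apl <- function(edges, n) {
  adj <- lapply(seq_len(n), function(i)
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  tot <- 0; pairs <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) != s)
    tot <- tot + sum(dist[reach]); pairs <- pairs + length(reach)
  }
  if (pairs == 0) NA_real_ else tot / pairs
}

# mean local clustering coefficient by triangle counting
oracle_clustering <- function(edges, n) {
  a <- matrix(0L, n, n)
  a[as.matrix(edges)] <- 1L
  a <- a | t(a)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  mean(cc)
}

# Newman Q for a given membership vector on an unweighted graph
oracle_modularity <- function(edges, n, membership) {
  m <- nrow(edges)
  deg <- tabulate(c(edges[, 1], edges[, 2]), n)
  q <- 0
  for (e in seq_len(m))
    if (membership[edges[e, 1]] == membership[edges[e, 2]]) q <- q + 1 / m
  for (comm in unique(membership))
    q <- q - (sum(deg[membership == comm]) / (2 * m))^2
  q
}

# best modularity over all set partitions (tiny graphs only)
oracle_best_modularity <- function(edges, n) {
  parts <- list(1L)
  for (i in seq(2, n)) {
    parts <- unlist(lapply(parts, function(p)
      lapply(seq_len(max(p) + 1L), function(g) c(p, g))), recursive = FALSE)
  }
  max(vapply(parts, function(p) oracle_modularity(edges, n, p), numeric(1)))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
}

# exact Mantel p by full permutation enumeration (n = 4)
oracle_mantel_exact <- function(d1, d2, method = "spearman") {
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  ut <- upper.tri(d1)
  f <- function(v) if (method == "spearman") rank(v) else v
  r_obs <- cor(f(d1[ut]), f(d2[ut]))
  rs <- apply(perms, 1, function(p) {
    p <- as.integer(p)
    cor(f(d1[ut]), f(d2[p, p][ut]))
  })
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# regression R2 from the normal equations, one response at a time
oracle_rda_r2 <- function(y, x) {
  y <- scale(y, center = TRUE, scale = FALSE)
  x <- cbind(1, as.matrix(x))
  beta <- solve(t(x) %*% x) %*% t(x) %*% y
  fitted <- x %*% beta
  fitted <- scale(fitted, center = TRUE, scale = FALSE)
  sum(fitted^2) / sum(y^2)
}

tiny_sim <- function(seed = 1, n_samples = 12, n_otus = 120, depth = 2e4,
                     ...) {
  sim_config(n_samples = n_samples, n_otus = n_otus, depth = depth,
             seed = seed, ...)
}
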