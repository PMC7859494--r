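# Environmental and spatial driver attribution: variable correlation
# matrices, geographic/environmental distances, Mantel tests, RDA-based
# variation partitioning, and sparse PLS subgroup-variable selection.

.haversine_km <- function(lon1, lat1, lon2, lat2, radius = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Great-circle distance matrix between samples (km)
#'
#' Haversine distance on a sphere of radius 6371 km.  Because longitudes
#' enter through their difference's sine/cosine, antimeridian-crossing
#' pairs get the short arc, not the long way around.
#'
#' @param metadata [sample_metadata()] with `longitude` and `latitude`.
#' @return symmetric matrix of distances in km.
#' @export
geographic_distance <- function(metadata) {
  lon <- metadata$longitude; lat <- metadata$latitude
  if (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    stop("coordinates out of range", call. = FALSE)
  n <- length(lon)
  d <- matrix(0, n, n, dimnames = list(metadata$sample_id,
                                       metadata$sample_id))
  for (i in seq_len(n))
    d[i, ] <- .haversine_km(lon[i], lat[i], lon, lat)
  (d + t(d)) / 2
}

#' Euclidean distance on z-scored environmental variables
#'
#' @param metadata [sample_metadata()] (or any data.frame with
#'   `sample_id`).
#' @param variables character vector of numeric columns to use.
#' @return symmetric distance matrix; zero-variance variables are dropped
#'   with a warning.
#' @export
environmental_distance <- function(metadata,
                                   variables = c("temperature", "salinity",
                                                 "nox", "drp", "silicate",
                                                 "chla")) {
  x <- as.matrix(metadata[, variables, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variables: ",
            paste(variables[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  d <- as.matrix(stats::dist(z))
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  d
}

#' Pairwise Spearman correlations among variables with FDR masking
#'
#' All pairwise Spearman correlations with Benjamini-Hochberg adjusted
#' p-values; in `masked_r` cells with adjusted p >= `alpha` are set NA
#' (the usual correlation-heatmap display convention).
#'
#' @param df data.frame of numeric variables (samples as rows).
#' @param alpha significance level for masking.
#' @return list with matrices `r`, `q`, and `masked_r`; constant
#'   variables are excluded with a warning.
#' @export
variable_correlation_matrix <- function(df, alpha = 0.05) {
  x <- as.matrix(df[, vapply(df, is.numeric, logical(1)), drop = FALSE])
  if (nrow(x) < 5L) stop("need >= 5 samples", call. = FALSE)
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning("excluding constant variables: ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
    x <- x[, !constant, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need >= 2 variables", call. = FALSE)
  n <- nrow(x)
  r <- stats::cor(x, method = "spearman")
  ut <- upper.tri(r)
  rv <- r[ut]
  tv <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tv), df = n - 2)
  pv[abs(rv) >= 1] <- 0
  q <- r * 0
  q[ut] <- stats::p.adjust(pv, "BH")
  q <- q + t(q)
  masked <- r
  masked[q >= alpha & row(q) != col(q)] <- NA
  list(r = r, q = q, masked_r = masked)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  prev <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[prev], nrow(prev), n - 1L))
  }))
}

#' Mantel test between two distance matrices
#'
#' Correlation of the unfolded upper triangles, with significance from
#' simultaneous row/column permutations of the second matrix (one-sided,
#' greater).  For `n <= 5` samples all `n!` permutations are enumerated
#' exactly; otherwise `n_perm` random permutations are drawn and the
#' add-one convention applied.
#'
#' @param d1,d2 symmetric distance matrices over the same samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm random permutations (ignored when enumerating).
#' @param seed integer seed.
#' @return list with `r`, `p`, `method`, `n_permutations`, `seed`.
#' @export
mantel <- function(d1, d2, method = "spearman", n_perm = 999L, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (!all(dim(d1) == dim(d2)))
    stop("distance matrices must have the same samples", call. = FALSE)
  if (n < 4L) stop("need >= 4 samples", call. = FALSE)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (method == "spearman") v1 <- rank(v1)
  stat <- function(m2) {
    v2 <- m2[ut]
    if (method == "spearman") v2 <- rank(v2)
    stats::cor(v1, v2)
  }
  r_obs <- stat(d2)
  if (n <= 5L) {
    perms <- .permutations(n)
    rs <- apply(perms, 1, function(p) stat(d2[p, p]))
    p_val <- mean(rs >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      if (stat(d2[p, p]) >= r_obs - 1e-12) hits <- hits + 1L
    }
    p_val <- (1 + hits) / (n_perm + 1)
    n_used <- as.integer(n_perm)
  }
  list(r = r_obs, p = p_val, method = method, n_permutations = n_used,
       seed = as.integer(seed))
}

#' Hellinger transformation (square root of row proportions)
#' @param m non-negative abundance matrix, samples x OTUs.
#' @return transformed matrix.
#' @export
hellinger <- function(m) {
  m <- unclass(m)
  sqrt(m / rowSums(m))
}

# multivariate redundancy-analysis R2: fraction of the (column-centered)
# community variance captured by the linear projection onto the predictors
.rda_r2 <- function(y, x) {
  y <- scale(y, center = TRUE, scale = FALSE)
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  qx <- qr(x)
  rank <- qx$rank
  fitted <- qr.fitted(qx, y)
  list(r2 = sum(fitted^2) / sum(y^2), rank = rank)
}

.adj_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

#' Variation partitioning between environmental and spatial predictors
#'
#' The community table is Hellinger-transformed (unless `transform =
#' "none"`) and three redundancy analyses fit: environment alone, space
#' alone, and both.  Fractions follow the classic decomposition on
#' adjusted R-squared (Ezekiel correction): pure environment
#' `a = adjR2(env+space) - adjR2(space)`, shared `b`, pure space `c`,
#' unexplained `d = 1 - adjR2(env+space)`.  Raw (unadjusted) fractions
#' always sum to 1 and are reported alongside.  The two pure fractions
#' are tested by permuting the residuals of the reduced model.
#'
#' @param community abundance matrix (samples x OTUs).
#' @param env environmental predictor matrix/data.frame.
#' @param space spatial predictor matrix/data.frame (e.g., longitude and
#'   latitude).
#' @param n_perm permutations for the partial tests.
#' @param seed integer seed.
#' @param transform `"hellinger"` (default) or `"none"`.
#' @param adjust apply the Ezekiel adjustment (default TRUE; when FALSE
#'   the adjusted fractions equal the raw ones).
#' @return list with `fractions` (adjusted a, b, c, d), `raw_fractions`,
#'   `r2` (the three model R2), `p_pure_env`, `p_pure_space`.
#' @export
vpa <- function(community, env, space, n_perm = 999L, seed = 1L,
                transform = "hellinger", adjust = TRUE) {
  y <- unclass(community)
  if (transform == "hellinger") y <- hellinger(y)
  env <- as.matrix(env); space <- as.matrix(space)
  n <- nrow(y)
  f_env <- .rda_r2(y, env)
  f_sp <- .rda_r2(y, space)
  f_both <- .rda_r2(y, cbind(env, space))
  if (f_both$rank < f_env$rank + f_sp$rank)
    warning("collinear predictors across blocks; rank reduced", call. = FALSE)
  if (n <= f_both$rank + 1)
    stop("need n_samples > rank(env) + rank(space) + 1", call. = FALSE)
  a2 <- function(f) if (adjust) .adj_r2(f$r2, n, f$rank) else f$r2
  r_env <- a2(f_env); r_sp <- a2(f_sp); r_both <- a2(f_both)
  fractions <- c(a = r_both - r_sp,
                 b = r_env + r_sp - r_both,
                 c = r_both - r_env,
                 d = 1 - r_both)
  raw <- c(a = f_both$r2 - f_sp$r2,
           b = f_env$r2 + f_sp$r2 - f_both$r2,
           c = f_both$r2 - f_env$r2,
           d = 1 - f_both$r2)

  # permutation test of a pure fraction: permute reduced-model residuals
  partial_p <- function(x_test, x_cond, seed_offset) {
    qc <- qr(scale(as.matrix(x_cond), center = TRUE, scale = FALSE))
    yc <- scale(y, center = TRUE, scale = FALSE)
    fit_red <- qr.fitted(qc, yc)
    res_red <- yc - fit_red
    xb <- cbind(as.matrix(x_cond), as.matrix(x_test))
    stat <- function(ymat) {
      fb <- .rda_r2(ymat, xb)
      fr <- .rda_r2(ymat, x_cond)
      (fb$r2 - fr$r2) / (1 - fb$r2)
    }
    obs <- stat(y)
    set.seed(seed + seed_offset)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
      if (stat(yp) >= obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
  list(fractions = fractions, raw_fractions = raw,
       r2 = c(env = f_env$r2, space = f_sp$r2, both = f_both$r2),
       p_pure_env = partial_p(env, space, 0L),
       p_pure_space = partial_p(space, env, 1L),
       n_permutations = as.integer(n_perm), seed = as.integer(seed))
}

# keep exactly k entries of v nonzero by soft-thresholding at the
# (k+1)-th largest magnitude
.soft_keep <- function(v, k) {
  if (k >= length(v)) return(v)
  lambda <- sort(abs(v), decreasing = TRUE)[k + 1]
  sign(v) * pmax(abs(v) - lambda, 0)
}

#' Sparse partial least squares selection of subgroup-variable links
#'
#' Regression-mode sPLS on standardized blocks: per component, the
#' dominant singular pair of the X-Y cross-covariance is found by
#' alternating power iterations with the X loading soft-thresholded so
#' exactly `keepX` entries stay nonzero; both blocks are then deflated by
#' regression on the X score.  Loadings are unit-norm with the
#' largest-magnitude entry positive.  Alongside the components, a
#' Spearman correlation heatmap of X columns versus Y columns is
#' returned with `|r| > 0.5` flags.
#'
#' @param X subgroup abundance matrix (samples x subgroups).
#' @param Y variable matrix (samples x variables).
#' @param ncomp number of components.
#' @param keepX number of X columns retained per component.
#' @return list with `loadings_x` (subgroups x ncomp), `loadings_y`,
#'   `scores_x`, `selected` (list of selected subgroup names per
#'   component), `heatmap` (`r` and logical `flag` matrices).
#' @export
spls_select <- function(X, Y, ncomp = 2L, keepX = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(keepX)) keepX <- ncol(X)
  if (ncomp > min(dim(X), dim(Y)))
    stop("ncomp exceeds the matrix dimensions", call. = FALSE)
  if (keepX > ncol(X)) stop("keepX exceeds the number of X columns",
                            call. = FALSE)
  zv <- c(colnames(X)[apply(X, 2, stats::sd) == 0],
          colnames(Y)[apply(Y, 2, stats::sd) == 0])
  if (length(zv) > 0L)
    stop("zero-variance columns: ", paste(zv, collapse = ", "),
         call. = FALSE)
  Xs <- scale(X); Ys <- scale(Y)
  px <- ncol(Xs)
  lx <- matrix(0, px, ncomp, dimnames = list(colnames(X), NULL))
  ly <- matrix(0, ncol(Ys), ncomp, dimnames = list(colnames(Y), NULL))
  tx <- matrix(0, nrow(Xs), ncomp)
  selected <- vector("list", ncomp)
  X1 <- Xs; Y1 <- Ys
  for (h in seq_len(ncomp)) {
    M <- crossprod(X1, Y1)
    sv <- svd(M, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]
    for (it in seq_len(200)) {
      u_new <- .soft_keep(as.vector(M %*% v), keepX)
      if (sum(u_new^2) == 0) u_new <- .soft_keep(as.vector(M %*% v), px)
      u_new <- u_new / sqrt(sum(u_new^2))
      v_new <- as.vector(crossprod(M, u_new))
      v_new <- v_new / sqrt(sum(v_new^2))
      if (max(abs(u_new - u), abs(v_new - v)) < 1e-10) {
        u <- u_new; v <- v_new; break
      }
      u <- u_new; v <- v_new
    }
    # fix signs: largest-magnitude X loading positive
    if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
    xi <- as.vector(X1 %*% u)
    c_load <- as.vector(crossprod(X1, xi)) / sum(xi^2)
    d_load <- as.vector(crossprod(Y1, xi)) / sum(xi^2)
    X1 <- X1 - xi %*% t(c_load)
    Y1 <- Y1 - xi %*% t(d_load)
    lx[, h] <- u; ly[, h] <- v; tx[, h] <- xi
    selected[[h]] <- colnames(X)[u != 0]
  }
  r_heat <- stats::cor(X, Y, method = "spearman")
  list(loadings_x = lx, loadings_y = ly, scores_x = tx,
       selected = selected,
       heatmap = list(r = r_heat, flag = abs(r_heat) > 0.5))
}
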