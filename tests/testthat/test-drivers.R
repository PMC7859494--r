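test_that("variable correlation matrix masks by FDR", {
  set.seed(6)
  n <- 20
  x <- runif(n)
  df <- data.frame(x = x, y = -x, z = rnorm(n))
  vc <- variable_correlation_matrix(df)
  expect_equal(diag(vc$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(vc$r["x", "y"], -1)
  expect_lt(vc$q["x", "y"], 0.05)
  expect_false(is.na(vc$masked_r["x", "y"]))

  df$w <- rep(2, n)
  expect_warning(variable_correlation_matrix(df), "constant")

  masked <- vapply(1:20, function(s) {
    set.seed(s)
    noise <- as.data.frame(matrix(rnorm(20 * 5), 20, 5))
    m <- variable_correlation_matrix(noise)$masked_r
    mean(is.na(m[upper.tri(m)]))
  }, numeric(1))
  expect_gte(mean(masked), 0.9)
})

test_that("great-circle distances handle the antimeridian", {
  md <- data.frame(sample_id = c("a", "b", "c", "d"),
                   longitude = c(0, 180, 179.5, -179.5),
                   latitude = c(0, 0, 0, 0))
  d <- geographic_distance(md)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-6)
  expect_equal(d["c", "d"], 2 * pi * 6371 / 360, tolerance = 1e-3)
  expect_lt(d["c", "d"], 200)  # short arc, not the long way round

  set.seed(12)
  for (rep in 1:10) {
    md3 <- data.frame(sample_id = c("p", "q", "r"),
                      longitude = runif(3, -180, 180),
                      latitude = runif(3, -90, 90))
    d3 <- geographic_distance(md3)
    expect_lte(d3[1, 3], d3[1, 2] + d3[2, 3] + 1e-9)
  }
  expect_error(geographic_distance(data.frame(sample_id = "a",
                                              longitude = 200,
                                              latitude = 0)), "range")
})

test_that("environmental distance standardizes before Euclid", {
  md <- data.frame(sample_id = c("a", "b"), v = c(0, 1))
  d <- environmental_distance(md, "v")
  expect_equal(d["a", "b"], sqrt(2))  # z-scores are +-1/sqrt(2)*... -> sqrt2
  md2 <- data.frame(sample_id = c("a", "b", "c"), v = c(1, 2, 4),
                    w = c(3, 1, 2))
  d1 <- environmental_distance(md2, c("v", "w"))
  md3 <- transform(md2, v = v * 1000)
  expect_equal(environmental_distance(md3, c("v", "w")), d1,
               tolerance = 1e-12)
  md4 <- transform(md2, w = 5)
  expect_warning(environmental_distance(md4, c("v", "w")), "zero-variance")
})

test_that("mantel matches exact enumeration and textbook pearson", {
  set.seed(8)
  x <- matrix(rnorm(4 * 2), 4, 2)
  d1 <- as.matrix(dist(x))
  d2 <- as.matrix(dist(x + rnorm(8, 0, 0.5)))
  for (method in c("spearman", "pearson")) {
    res <- mantel(d1, d2, method = method)
    o <- oracle_mantel_exact(d1, d2, method)
    expect_equal(res$r, o$r, tolerance = 1e-12)
    expect_equal(res$p, o$p, tolerance = 1e-12)  # n=4: all 24 permutations
    expect_equal(res$n_permutations, 24L)
  }
  # perfect monotone/linear relation
  res1 <- mantel(d1, 2 * d1, method = "spearman")
  expect_equal(res1$r, 1, tolerance = 1e-12)
  expect_equal(mantel(d1, 2 * d1, method = "pearson")$r, 1,
               tolerance = 1e-12)
  # pearson statistic equals the explicit formula on unfolded triangles
  ut <- upper.tri(d1)
  expect_equal(mantel(d1, d2, method = "pearson")$r,
               oracle_pearson(d1[ut], d2[ut]), tolerance = 1e-12)
  expect_error(mantel(d1, as.matrix(dist(x[1:3, ]))), "same samples")
})

test_that("mantel agrees with vegan on larger matrices", {
  skip_if_not_installed("vegan")
  set.seed(14)
  x <- matrix(rnorm(15 * 4), 15, 4)
  d1 <- as.matrix(dist(x))
  d2 <- as.matrix(dist(x + rnorm(60, 0, 0.8)))
  ours <- mantel(d1, d2, method = "pearson", n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), method = "pearson",
                       permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("vpa fractions decompose consistently", {
  set.seed(10)
  n <- 12
  env <- matrix(rnorm(n), n, 1)
  space <- matrix(rnorm(n), n, 1)
  comm <- matrix(rexp(n * 3), n, 3)
  res <- vpa(comm, env, space, n_perm = 49, seed = 1)
  expect_equal(sum(res$raw_fractions), 1, tolerance = 1e-9)
  raw <- vpa(comm, env, space, n_perm = 9, seed = 1, adjust = FALSE)
  expect_equal(unname(raw$fractions), unname(raw$raw_fractions),
               tolerance = 1e-12)

  # toy R2 values against the normal-equations oracle (no transform)
  res2 <- vpa(comm, env, space, n_perm = 9, seed = 1, transform = "none")
  expect_equal(res2$r2[["env"]], oracle_rda_r2(comm, env), tolerance = 1e-10)
  expect_equal(res2$r2[["space"]], oracle_rda_r2(comm, space),
               tolerance = 1e-10)
  expect_equal(res2$r2[["both"]], oracle_rda_r2(comm, cbind(env, space)),
               tolerance = 1e-10)
  expect_error(vpa(comm[1:3, ], env[1:3, , drop = FALSE],
                   space[1:3, , drop = FALSE], n_perm = 9), "n_samples")
})

test_that("env-driven communities give no pure-spatial fraction", {
  hits <- 0L; cs <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    n <- 30
    env <- matrix(rnorm(n * 3), n, 3)
    space <- matrix(rnorm(n * 2), n, 2)      # orthogonal noise block
    comm <- 10 + env %*% matrix(rnorm(3 * 5), 3, 5) +
      matrix(rnorm(n * 5, 0, 0.3), n, 5)
    res <- vpa(comm, env, space, n_perm = 99, seed = s,
               transform = "none")
    cs[s] <- res$fractions[["c"]]
    if (res$p_pure_env <= 0.05) hits <- hits + 1L
  }
  expect_true(all(abs(cs) < 0.05))
  expect_gte(hits / 20, 0.9)
})

test_that("spls selects the driving columns and obeys its contracts", {
  set.seed(15)
  n <- 30
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  Y <- cbind(y1 = X[, 3], y2 = X[, 3] * 2)   # noiseless copy of column 3
  res <- spls_select(X, Y, ncomp = 1, keepX = 1)
  expect_equal(res$selected[[1]], "g3")
  expect_equal(sum(res$loadings_x[, 1] != 0), 1L)
  expect_equal(sum(res$loadings_x[, 1]^2), 1, tolerance = 1e-9)
  expect_gt(res$loadings_x[which.max(abs(res$loadings_x[, 1])), 1], 0)

  # keepX = all, ncomp = 1 reproduces the leading singular pair
  res_full <- spls_select(X, Y, ncomp = 1, keepX = 6)
  sv <- svd(crossprod(scale(X), scale(Y)))
  u <- sv$u[, 1]; if (u[which.max(abs(u))] < 0) u <- -u
  expect_equal(unname(res_full$loadings_x[, 1]), u, tolerance = 1e-6)

  expect_error(spls_select(cbind(X, const = 1), Y, 1, 2), "zero-variance")
  expect_error(spls_select(X, Y, ncomp = 40), "ncomp")
  expect_true(all(abs(res$heatmap$r[res$heatmap$flag]) > 0.5))
})

test_that("spls recovers truly associated subgroups across seeds", {
  recovered <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 20
    X <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("g", 1:20)))
    Y <- cbind(X[, 3] + rnorm(n, 0, 0.3), X[, 7] + rnorm(n, 0, 0.3),
               rnorm(n), rnorm(n))
    res <- spls_select(X, Y, ncomp = 2, keepX = 2)
    all(c("g3", "g7") %in% unlist(res$selected))
  }, logical(1))
  expect_gte(mean(recovered), 0.8)
})
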