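make_tax <- function(ids, cats) taxonomy_table(ids, ids, cats)

test_that("spike-in split partitions and conserves reads", {
  set.seed(1)
  m <- matrix(rpois(5 * 12, 20), 5, 12,
              dimnames = list(paste0("s", 1:5),
                              c(paste0("sp", 1:3), paste0("o", 1:9))))
  ct <- count_table(m)
  tax <- make_tax(colnames(m), c(rep("spike_in", 3), rep("bacteria", 9)))
  parts <- split_spikeins(ct, tax)
  expect_equal(ncol(parts$spikein), 3L)
  expect_equal(ncol(parts$biological), 9L)
  expect_equal(rowSums(parts$spikein) + rowSums(parts$biological),
               rowSums(ct))

  # design spike missing from the table -> warned, recorded as zero reads
  des <- spikein_design(paste0("sp", 1:4), c(1e3, 1e4, 1e5, 1e6))
  expect_warning(parts2 <- split_spikeins(ct, tax, des), "sp4")
  expect_equal(sum(parts2$spikein[, "sp4"]), 0)

  tax_none <- make_tax(colnames(m), rep("bacteria", 12))
  expect_warning(p3 <- split_spikeins(ct, tax_none), "no spike-in")
  expect_equal(ncol(p3$spikein), 0L)
})

test_that("cleaning removes non-bacterial OTUs and global singletons", {
  m <- rbind(s1 = c(1L, 1L, 10000L, 5L, 0L),
             s2 = c(0L, 1L, 2L, 5L, 1L))
  colnames(m) <- paste0("o", 1:5)
  # o1: global singleton (total 1) -> removed; o2: 1+1=2 -> kept;
  # o3: archaea -> removed despite 1e4 reads; o5: total 1 -> removed
  tax <- make_tax(colnames(m), c("bacteria", "bacteria", "archaea",
                                 "unassigned", "bacteria"))
  cleaned <- clean_biological(count_table(m), tax)
  expect_equal(colnames(cleaned), c("o2", "o4"))

  tax_chl <- make_tax(colnames(m), rep("chloroplast", 5))
  expect_error(clean_biological(count_table(m), tax_chl), "no bacterial")
})

test_that("standard curves match closed-form OLS", {
  des <- spikein_design(paste0("sp", 1:9),
                        c(rep(1e3, 3), rep(1e4, 2), rep(1e5, 2), rep(1e6, 2)))
  # reads exactly equal to added copies -> identity line
  m <- matrix(as.integer(des$added_copies), 1, 9,
              dimnames = list("s1", des$spikein_id))
  cv <- fit_standard_curves(count_table(m), des)
  expect_equal(cv$a, 1, tolerance = 1e-12)
  expect_equal(cv$b, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$n_points, 9L)

  # constant efficiency 0.01 -> slope 1, intercept -2
  m2 <- matrix(as.integer(des$added_copies / 100), 1, 9,
               dimnames = list("s1", des$spikein_id))
  cv2 <- fit_standard_curves(count_table(m2), des)
  expect_equal(c(cv2$a, cv2$b), c(1, -2), tolerance = 1e-12)

  # hand-picked log points (3,3.1) (4,3.9) (5,5.2) (6,5.8)
  des4 <- spikein_design(paste0("q", 1:4), 10^(3:6))
  m3 <- matrix(as.integer(round(10^c(3.1, 3.9, 5.2, 5.8))), 1, 4,
               dimnames = list("s1", des4$spikein_id))
  cv3 <- fit_standard_curves(count_table(m3), des4)
  o <- oracle_ols(log10(des4$added_copies), log10(m3[1, ]))
  expect_equal(c(cv3$a, cv3$b, cv3$r_squared), unname(o), tolerance = 1e-10)

  # random point sets: OLS equals the normal-equation oracle
  set.seed(42)
  for (rep in 1:10) {
    reads <- as.integer(round(10^(runif(9, 1, 5))))
    mr <- matrix(reads, 1, 9, dimnames = list("s1", des$spikein_id))
    cvr <- fit_standard_curves(count_table(mr), des)
    or <- oracle_ols(log10(des$added_copies), log10(reads))
    expect_equal(c(cvr$a, cvr$b, cvr$r_squared), unname(or),
                 tolerance = 1e-10)
  }

  # zero-read spike-ins are dropped and reported; < 3 positive is an error
  m4 <- m; m4[1, 1:2] <- 0L
  cv4 <- fit_standard_curves(count_table(m4), des)
  expect_equal(cv4$n_points, 7L)
  expect_match(cv4$dropped_spikeins, "sp1,sp2")
  m5 <- m; m5[1, 1:7] <- 0L
  expect_error(fit_standard_curves(count_table(m5), des), "need >= 3")
})

meta_row <- function(id, R, V) {
  data.frame(sample_id = id, temperature = 29, salinity = 34, nox = 0.02,
             drp = 0.05, silicate = 1, chla = 20,
             bacterial_abundance = 1.2e5, longitude = 170, latitude = 15,
             recovery_ratio = R, volume = V)
}

test_that("absolute abundance inverts the curve and scales by R*V", {
  counts <- count_table(matrix(c(500L, 1000L, 0L), 1, 3,
                               dimnames = list("s1", c("o1", "o2", "o3"))))
  curves <- data.frame(sample_id = "s1", a = 1, b = 0, r_squared = 1,
                       n_points = 9)
  md <- sample_metadata(meta_row("s1", 1, 1))
  q <- estimate_absolute_abundance(counts, curves, md)
  expect_equal(unname(q[1, ]), c(500, 1000, 0))  # zero reads -> zero copies

  md2 <- sample_metadata(meta_row("s1", 0.5, 2))
  q2 <- estimate_absolute_abundance(counts, curves, md2)
  expect_equal(q2[1, "o2"], 1000 / (0.5 * 2), ignore_attr = TRUE)

  curves3 <- data.frame(sample_id = "s1", a = 0.9, b = 0.5, r_squared = 1,
                        n_points = 9)
  md3 <- sample_metadata(meta_row("s1", 0.4, 5))
  q3 <- estimate_absolute_abundance(counts, curves3, md3)
  expect_equal(q3[1, "o2"], 10^((3 - 0.5) / 0.9) / (0.4 * 5),
               tolerance = 1e-12, ignore_attr = TRUE)

  curves_bad <- transform(curves, a = -0.2)
  expect_error(estimate_absolute_abundance(counts, curves_bad, md),
               "non-monotone")
  expect_error(estimate_absolute_abundance(counts, curves,
                                           sample_metadata(meta_row("sX", 1, 1))),
               "missing R/V|no standard curve")
})

test_that("relative abundance is not proportional to copies across samples", {
  # same OTU: relative abundance rises while copies per liter fall
  counts <- count_table(matrix(c(10L, 90L, 30L, 70L), 2, 2, byrow = TRUE,
                               dimnames = list(c("s1", "s2"),
                                               c("o1", "o2"))))
  curves <- data.frame(sample_id = c("s1", "s2"), a = 1, b = 0,
                       r_squared = 1, n_points = 9)
  md <- sample_metadata(rbind(meta_row("s1", 1, 1), meta_row("s2", 1, 10)))
  q <- estimate_absolute_abundance(counts, curves, md)
  rel <- to_relative(counts)
  expect_gt(rel["s2", "o1"], rel["s1", "o1"])   # 0.3 > 0.1
  expect_lt(q["s2", "o1"], q["s1", "o1"])       # 3 < 10
})

test_that("rarefaction subsamples without replacement, deterministically", {
  m <- count_table(matrix(c(90L, 10L), 1, 2,
                          dimnames = list("s1", c("o1", "o2"))))
  expect_equal(unclass(rarefy(m, 100)), unclass(m))  # depth = total

  draws <- vapply(1:1000, function(s) unclass(rarefy(m, 10, seed = s))[1, 1],
                  numeric(1))
  expect_true(all(colSums(vapply(1:50, function(s)
    unclass(rarefy(m, 10, seed = s))[1, ], numeric(2))) == 10))
  expect_equal(mean(draws), 9, tolerance = 0.5 / 9)  # hypergeometric mean

  expect_identical(unclass(rarefy(m, 10, seed = 3)),
                   unclass(rarefy(m, 10, seed = 3)))
  expect_error(rarefy(m, 101), "s1")

  big <- count_table(matrix(c(40L, 60L, 10L, 5L), 2, 2,
                            dimnames = list(c("a", "b"), c("o1", "o2"))))
  # totals 50 and 65; "min" resolves to 50
  expect_equal(unname(rowSums(rarefy(big, "min", seed = 1))), c(50, 50))
})

test_that("relative abundances normalize per sample", {
  m <- count_table(matrix(c(6L, 4L), 1, 2,
                          dimnames = list("s1", c("o1", "o2"))))
  expect_equal(unname(to_relative(m)[1, ]), c(0.6, 0.4))
  mz <- rbind(s1 = c(1, 1), s2 = c(0, 0))
  colnames(mz) <- c("o1", "o2")
  expect_warning(rz <- to_relative(mz), "all-zero")
  expect_equal(unname(rz["s2", ]), c(0, 0))
  set.seed(2)
  r <- to_relative(matrix(rpois(20, 5) + 1, 4, 5,
                          dimnames = list(paste0("s", 1:4),
                                          paste0("o", 1:5))))
  expect_equal(unname(rowSums(r)), rep(1, 4), tolerance = 1e-9)
})

test_that("totals summarize row sums and ignore column order", {
  q <- structure(matrix(c(1e5, 0, 2e5, 3e5), 2, 2,
                        dimnames = list(c("s1", "s2"), c("o1", "o2"))),
                 class = "htqs_quant")
  tot <- summarize_totals(q)
  expect_equal(unname(tot$totals), c(3e5, 3e5))
  expect_equal(tot$summary[["min"]], 3e5)
  perm <- structure(unclass(q)[, c(2, 1)], class = "htqs_quant")
  expect_equal(summarize_totals(perm)$totals, tot$totals)
})

test_that("noiseless end-to-end recovery is accurate (scaled-down cohort)", {
  # multinomial sampling kept; scaled from 1200 OTUs/1e6 depth to keep the
  # default suite fast -- the full-size check lives in test-acceptance.R
  cfg <- sim_config(n_samples = 6, n_otus = 300, depth = 1e6, noise_cv = 0,
                    seed = 8)
  sim <- simulate_experiment(cfg)
  parts <- split_spikeins(sim$counts, sim$taxonomy, sim$design)
  curves <- fit_standard_curves(parts$spikein, sim$design)
  quant <- estimate_absolute_abundance(clean_biological(sim$counts,
                                                        sim$taxonomy),
                                       curves, sim$metadata)
  shared <- intersect(colnames(quant), colnames(sim$truth))
  truth <- sim$truth[, shared]
  relab <- sim$truth / rowSums(sim$truth)
  sel <- relab[, shared] > 1e-4
  err <- abs(unclass(quant)[, shared][sel] - truth[sel]) / truth[sel]
  expect_lt(median(err), 0.05)
  tot <- summarize_totals(quant)$totals
  expect_lt(max(abs(tot - rowSums(sim$truth)) / rowSums(sim$truth)), 0.05)
})

test_that("within each sample quantitative rank order equals relative", {
  cfg <- tiny_sim(seed = 13)
  sim <- simulate_experiment(cfg)
  parts <- split_spikeins(sim$counts, sim$taxonomy, sim$design)
  curves <- fit_standard_curves(parts$spikein, sim$design)
  cleaned <- clean_biological(sim$counts, sim$taxonomy)
  quant <- estimate_absolute_abundance(cleaned, curves, sim$metadata)
  rel <- to_relative(cleaned)
  for (i in seq_len(nrow(rel)))
    expect_equal(cor(rank(rel[i, ]), rank(unclass(quant)[i, ])), 1,
                 tolerance = 1e-12)
})
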