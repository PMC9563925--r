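make_harmonize_input <- function(n = 30, seed = 1) {
  lib <- phenotype_library("Landscape")
  set.seed(seed)
  l <- simulate_phenotype_features(lib$epi_ctc, n)
  c <- simulate_phenotype_features(phenotype_library("CDX2")$cdx2_ctc, n)
  l$event_id <- seq_len(n); c$event_id <- seq_len(n)
  l$cell_solidity <- 0.95; c$cell_solidity <- 0.95
  list(l = l, c = c)
}

test_that("harmonization z-scores the pooled shared features", {
  inp <- make_harmonize_input()
  h <- harmonize(inp$l, inp$c)
  expect_equal(unname(colMeans(h$z_matrix)), rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(apply(h$z_matrix, 2, sd)), rep(1, 8), tolerance = 1e-10)
  expect_setequal(colnames(h$z_matrix), shared_feature_names())
})

test_that("a cell measured identically in both assays harmonizes identically", {
  inp <- make_harmonize_input()
  inp$c[1, shared_feature_names()] <- inp$l[1, shared_feature_names()]
  h <- harmonize(inp$l, inp$c)
  il <- which(h$cells$protocol == "Landscape")[1]
  ic <- which(h$cells$protocol == "CDX2")[1]
  expect_equal(h$z_matrix[il, ], h$z_matrix[ic, ], tolerance = 1e-12)
})

test_that("QC drops aberrant masks with a reason; oncosomes are excluded", {
  inp <- make_harmonize_input()
  inp$l$nuclear_to_cell_area_ratio[2] <- 1.4
  inp$l$cell_area_um2[3] <- NaN
  inp$l$cell_solidity[4] <- 0.1
  inp$c$is_oncosome <- c(TRUE, rep(FALSE, nrow(inp$c) - 1))
  h <- harmonize(inp$l, inp$c)
  expect_equal(nrow(h$qc), 3)
  expect_setequal(h$qc$qc_reason,
                  c("nuclear_to_cell_area_ratio outside (0,1]",
                    "non-finite feature", "aberrant mask (low solidity)"))
  expect_equal(nrow(h$cells), 2 * nrow(inp$l) - 4)
  expect_error(harmonize(NULL, inp$c), "Landscape")
  expect_error(harmonize(inp$l, inp$c[0, ]), "CDX2")
})

test_that("silhouette selection recovers well-separated Gaussian blobs", {
  set.seed(1)
  mu <- matrix(rnorm(3 * 8), 3)
  mu <- mu / sqrt(rowSums(mu^2)) * 10
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(100 * 8), 100), 2, mu[i, ], "+")
  }))
  truth <- rep(1:3, each = 100)
  sol <- cluster_multi_assay(x, c(2, 16))
  expect_equal(sol$k, 3)
  # assignments match blob labels up to relabeling
  tab <- table(sol$assignments, truth)
  expect_equal(sum(apply(tab, 1, max)), 300)
  # selected k maximizes the silhouette curve by construction
  expect_equal(unname(sol$silhouette_by_k[as.character(sol$k)]),
               max(sol$silhouette_by_k))
  # minimal case: 2 blobs
  x2 <- x[1:200, ]
  expect_equal(cluster_multi_assay(x2, c(2, 16))$k, 2)
})

test_that("cluster solution is invariant to input ordering", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60 * 8), 60),
             matrix(rnorm(60 * 8, mean = 6), 60))
  sol1 <- cluster_multi_assay(x, c(2, 8))
  p <- sample(nrow(x))
  sol2 <- cluster_multi_assay(x[p, ], c(2, 8))
  expect_equal(sol1$k, sol2$k)
  # identical partition up to cluster relabeling
  tab <- table(sol1$assignments[p], sol2$assignments)
  expect_equal(sum(tab > 0), sol1$k)
})

test_that("the default 8-phenotype cohort selects 8 clusters in most seeds", {
  bench <- multi_assay_benchmark_populations()
  ks <- vapply(1:20, function(s) {
    set.seed(s)
    df <- do.call(rbind, lapply(bench, simulate_phenotype_features, n = 60))
    x <- scale(as.matrix(df[, shared_feature_names()]))
    cluster_multi_assay(x, c(2, 16))$k
  }, 0)
  expect_gte(mean(ks == 8), 0.8)
})

test_that("cross-assay correlations detect shared drivers and stay calibrated", {
  lev_l <- classification_levels("Landscape")
  lev_c <- classification_levels("CDX2")
  mk_enum <- function(values, lev, protocol) {
    do.call(rbind, lapply(seq_along(values), function(i) {
      data.frame(sample_id = sprintf("s%02d", i), classification = lev,
                 events_per_ml = c(values[i], rep(1, length(lev) - 1)))
    }))
  }
  # y = x ranks -> rho 1, significant
  x <- 1:10
  el <- mk_enum(x, lev_l, "Landscape")
  ec <- mk_enum(x, lev_c, "CDX2")
  cx <- cross_assay_correlations(el, ec)
  expect_equal(cx$rho[lev_l[1], lev_c[1]], 1)
  expect_lt(cx$p[lev_l[1], lev_c[1]], 0.05)
  expect_equal(cx$n, 10)
  # constant series -> NA
  expect_true(all(is.na(cx$rho[lev_l[2], ])))
  # shared lognormal driver -> positive correlation
  set.seed(8)
  lat <- rlnorm(18, 0, 1)
  el2 <- mk_enum(lat * rlnorm(18, 0, 0.2), lev_l, "Landscape")
  ec2 <- mk_enum(lat * rlnorm(18, 0, 0.2), lev_c, "CDX2")
  cx2 <- cross_assay_correlations(el2, ec2)
  expect_gt(cx2$rho[lev_l[1], lev_c[1]], 0.5)
  # type-I calibration of the screen on independent counts
  set.seed(9)
  sig <- vapply(1:500, function(i) {
    p <- suppressWarnings(cor.test(rlnorm(18), rlnorm(18),
                                   method = "spearman")$p.value)
    p <= 0.05
  }, logical(1))
  expect_lte(abs(mean(sig) - 0.05), 0.03)
})
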