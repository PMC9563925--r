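test_that("PCA reduction matches a direct eigendecomposition", {
  set.seed(1)
  x <- cbind(matrix(rnorm(50 * 2, sd = 4), 50), matrix(rnorm(50 * 4), 50))
  colnames(x) <- paste0("f", 1:6)
  red <- reduce_dimensions(x, var_target = 0.95)
  expect_gte(ncol(red$scores), 2)
  # oracle: eigenvectors of the correlation-scaled covariance
  z <- scale(x)
  eg <- eigen(stats::cov(z))
  m <- ncol(red$scores)
  # principal angle between retained subspaces
  sv <- svd(t(red$rotation) %*% eg$vectors[, seq_len(m)])$d
  expect_lt(max(abs(sv - 1)), 1e-8)
  # variance explained matches eigenvalues
  expect_equal(red$sdev^2, eg$values[seq_len(m)], tolerance = 1e-8)
})

test_that("retained subspace is invariant to orthogonal feature rotations", {
  set.seed(2)
  x <- matrix(rnorm(80 * 5), 80)
  x[, 1] <- x[, 1] * 6
  x[, 2] <- x[, 2] * 3
  colnames(x) <- paste0("f", 1:5)
  q <- qr.Q(qr(matrix(rnorm(25), 5)))
  xr <- x %*% q
  colnames(xr) <- paste0("g", 1:5)
  red1 <- reduce_dimensions(x, 0.95, scale. = FALSE)
  red2 <- reduce_dimensions(xr, 0.95, scale. = FALSE)
  expect_equal(ncol(red1$scores), ncol(red2$scores))
  # principal angles between retained score subspaces are ~0
  s1 <- svd(red1$scores)$u
  s2 <- svd(red2$scores)$u
  sv <- svd(t(s1) %*% s2)$d
  expect_lt(max(abs(sv - 1)), 1e-6)
})

test_that("constant feature columns are dropped with a warning", {
  x <- cbind(rnorm(20), rep(3, 20))
  colnames(x) <- c("a", "b")
  expect_warning(red <- reduce_dimensions(x, 0.95), "constant")
  expect_identical(red$kept_columns, "a")
})

test_that("deterministic sign convention: largest loading is positive", {
  set.seed(3)
  x <- matrix(rnorm(40 * 4), 40)
  colnames(x) <- paste0("f", 1:4)
  red <- reduce_dimensions(x, 0.99)
  for (j in seq_len(ncol(red$rotation))) {
    expect_gt(red$rotation[which.max(abs(red$rotation[, j])), j], 0)
  }
})

make_detection_input <- function(n_wbc, n_rare, seed, rare_pop = "epi_ctc") {
  lib <- phenotype_library("Landscape")
  set.seed(seed)
  wbc <- simulate_phenotype_features(lib$WBC, n_wbc)
  rare <- simulate_phenotype_features(lib[[rare_pop]], n_rare)
  fe <- rbind(wbc, rare)
  fe$event_id <- seq_len(nrow(fe))
  fe$truth_rare <- rep(c(FALSE, TRUE), c(n_wbc, n_rare))
  fe
}

test_that("spiked CTC-like features are recalled among WBC-like features", {
  fe <- make_detection_input(950, 50, seed = 7)
  det <- suppressWarnings(detect_rare(fe, detect_params(scope = "slide")))
  m <- merge(det, fe[, c("event_id", "truth_rare")], by = "event_id")
  recall <- sum(m$is_rare & m$truth_rare) / sum(m$truth_rare)
  precision <- sum(m$is_rare & m$truth_rare) / sum(m$is_rare)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.8)
})

test_that("a single homogeneous population yields no rare DAPI-positive events", {
  fe <- make_detection_input(400, 0, seed = 9)
  det <- suppressWarnings(detect_rare(fe, detect_params(scope = "slide")))
  expect_equal(sum(det$is_rare), 0)
})

test_that("DAPI-negative events bypass clustering and are always rare", {
  fe <- make_detection_input(990, 0, seed = 11)
  lib <- phenotype_library("Landscape")
  set.seed(12)
  onc <- simulate_phenotype_features(lib$onc_ck, 10)
  common <- intersect(names(fe), names(onc))
  pool <- rbind(fe[, common], onc[, common])
  pool$event_id <- seq_len(nrow(pool))
  det <- suppressWarnings(detect_rare(pool, detect_params(scope = "slide")))
  neg <- !pool$dapi_positive[match(det$event_id, pool$event_id)]
  expect_equal(sum(neg), 10)
  expect_true(all(det$is_rare[neg]))
  expect_equal(det$rarity_score[neg], rep(1, 10))
})

test_that("detection partition is invariant to input order", {
  fe <- make_detection_input(200, 12, seed = 21)
  det1 <- suppressWarnings(detect_rare(fe, detect_params(scope = "slide")))
  set.seed(99)
  fe2 <- fe[sample(nrow(fe)), ]
  det2 <- suppressWarnings(detect_rare(fe2, detect_params(scope = "slide")))
  o1 <- det1[order(det1$event_id), ]
  o2 <- det2[order(det2$event_id), ]
  expect_identical(o1$is_rare, o2$is_rare)
})

test_that("fewer than 5 events in scope flags everything rare with a warning", {
  fe <- make_detection_input(3, 0, seed = 31)
  expect_warning(det <- detect_rare(fe, detect_params(scope = "slide")),
                 "fewer than 5")
  expect_true(all(det$is_rare))
})

test_that("rare recall is non-decreasing in phenotype intensity contrast", {
  lib <- phenotype_library("Landscape")
  recalls <- vapply(c(0.2, 0.45, 0.9), function(contrast) {
    pop <- lib$epi_ctc
    pop$channel_profile$ck$intensity_scale <- contrast
    set.seed(77)
    wbc <- simulate_phenotype_features(lib$WBC, 570)
    rare <- simulate_phenotype_features(pop, 30) # 5% spike
    fe <- rbind(wbc, rare)
    fe$event_id <- seq_len(nrow(fe))
    det <- suppressWarnings(detect_rare(fe, detect_params(scope = "slide")))
    sum(det$is_rare[571:600]) / 30
  }, 0)
  expect_true(all(diff(recalls) >= -1e-9))
  expect_gte(recalls[3], recalls[1])
})
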