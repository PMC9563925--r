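mk_enum1 <- function(values, classification = "CK") {
  data.frame(sample_id = sprintf("s%02d", seq_along(values)),
             classification = classification, events_per_ml = values)
}

test_that("identical arms give a rank-sum p of 1", {
  e <- mk_enum1(c(1, 2, 3, 4, 5))
  res <- compare_cohorts(e, e)
  expect_equal(res$p_value, 1, tolerance = 0.05)
  expect_error(compare_cohorts(e[0, ], e), "non-empty")
  expect_error(compare_cohorts(mk_enum1(1:2), e), ">= 3")
})

test_that("rank-sum test is calibrated under the null", {
  set.seed(42)
  rej <- vapply(1:1000, function(i) {
    suppressWarnings(wilcox.test(rlnorm(18), rlnorm(50))$p.value) <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("patient vs donor contrast flags the tumor-linked classes", {
  keyc <- c("CK", "Onc CK", "Onc CK|Vim", "Onc CK|Vim|CD45/CD31")
  hits <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_spec(seed = s))
    en <- simulate_enumeration(co, seed = s + 1000)
    ct <- compare_cohorts(en[en$protocol == "Landscape" & en$arm == "mCRC", ],
                          en[en$arm == "ND", ], keyc)
    ct$p_value[match(keyc, ct$classification)] < 0.05
  }, logical(4))
  expect_true(all(rowMeans(hits) >= 0.8))
})

test_that("Spearman-PFS correlation handles the small-cohort cases", {
  # perfectly monotone
  r <- analyte_pfs_correlation(1:9, (1:9)^2)
  expect_equal(r$rho, 1)
  # rho = 0.70 at n = 9: p near 0.037 under the t-approximation
  x <- 1:9
  set.seed(2)
  repeat {
    y <- sample(9)
    if (abs(cor(x, y, method = "spearman") - 0.7) < 1e-9) break
  }
  r2 <- analyte_pfs_correlation(x, y, method = "t")
  expect_equal(r2$rho, 0.7)
  expect_lt(abs(r2$p_value - 0.0372), 0.005)
  # constant analyte -> undefined
  r3 <- analyte_pfs_correlation(rep(2, 6), 1:6)
  expect_true(is.na(r3$rho))
  expect_error(analyte_pfs_correlation(1:3, 1:3), ">= 4")
})

test_that("link-strength 0.8 is recovered by the correlation screen", {
  rhos <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_spec(seed = s, n_nd_donors = 0,
                                      pfs_strength = 0.8))
    a <- merge(co$truth[co$truth$draw == 1 & co$truth$protocol == "Landscape" &
                          co$truth$classification == "Onc CK|CD45/CD31", ],
               co$survival, by = "patient_id")
    analyte_pfs_correlation(a$true_events_per_ml, a$pfs_months)$rho
  }, 0)
  expect_lt(abs(median(abs(rhos)) - 0.8), 0.15)
})

test_that("median stratification splits [1,2,3,4] at 2.5", {
  km <- km_stratify(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(km$threshold, 2.5)
  expect_equal(as.vector(table(km$group)), c(2, 2))
  # strictly-greater rule: values at the median go low
  km2 <- km_stratify(c(1, 2, 2, 4), c(5, 6, 7, 8), rule = "gt")
  expect_equal(sum(km2$group == "high"), 1)
  km3 <- km_stratify(c(1, 2, 2, 4), c(5, 6, 7, 8), rule = "geq")
  expect_equal(sum(km3$group == "high"), 3)
})

test_that("KM product-limit matches the hand-computed 4-patient fixtures", {
  # all progress at t = 2, 4, 6, 8 -> S drops by 1/4 each time
  km <- km_stratify(c(1, 2, 3, 4), c(2, 4, 6, 8))
  ov <- km$curves[km$curves$group == "overall", ]
  expect_equal(ov$time, c(0, 2, 4, 6, 8))
  expect_equal(ov$surv, c(1, 0.75, 0.5, 0.25, 0))
  # censoring at t = 4: S = 3/4 after t=2, then 3/4 * 1/2 after t=6, then 0
  km2 <- km_stratify(c(1, 2, 3, 4), c(2, 4, 6, 8),
                     event_flag = c(1, 0, 1, 1))
  ov2 <- km2$curves[km2$curves$group == "overall", ]
  expect_equal(ov2$surv[ov2$time == 2], 0.75)
  expect_equal(ov2$surv[ov2$time == 6], 0.375)
  expect_equal(ov2$surv[ov2$time == 8], 0)
  # with no censoring the final KM value is 0 in every group
  expect_equal(min(km$curves$surv[km$curves$group == "high"]), 0)
  expect_equal(min(km$curves$surv[km$curves$group == "low"]), 0)
})

test_that("median stratification is invariant to monotone transforms", {
  set.seed(3)
  v <- rlnorm(9)
  t <- rlnorm(9, 2)
  a <- km_stratify(v, t)
  b <- km_stratify(exp(v), t)
  expect_identical(a$group, b$group)
  expect_identical(a$curves, b$curves)
})

test_that("a protective analyte yields a dominating high-group curve", {
  dominates <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(seed = s, n_nd_donors = 0,
                                      pfs_strength = 0.9, n_missing_pfs = 0))
    a <- merge(co$truth[co$truth$draw == 1 & co$truth$protocol == "Landscape" &
                          co$truth$classification == "Onc CK|CD45/CD31", ],
               co$survival, by = "patient_id")
    km <- km_stratify(a$true_events_per_ml, a$pfs_months)
    mean(a$pfs_months[km$group == "high"]) > mean(a$pfs_months[km$group == "low"])
  }, logical(1))
  expect_gte(mean(dominates), 0.9)
})

test_that("kinetics are draw2 minus draw1 with exclusions counted", {
  expect_equal(unname(kinetics(c(a = 10), c(a = 4))$delta), -6)
  expect_equal(unname(kinetics(c(a = 5), c(a = 5))$delta), 0)
  # 9 patients, 2 missing draw 2 -> 7 deltas
  df <- data.frame(
    patient_id = c(sprintf("P%d", 1:9), sprintf("P%d", 1:7)),
    draw = rep(c(1, 2), c(9, 7)),
    classification = "CK",
    events_per_ml = c(1:9, 2 * (1:7))
  )
  k <- kinetics(df, classification = "CK")
  expect_equal(length(k$delta), 7)
  expect_equal(k$n_excluded, 2)
  expect_equal(unname(k$delta["P3"]), 3)
})
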