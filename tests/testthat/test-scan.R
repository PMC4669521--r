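test_that("detection-p masking is strict and counts match a brute-force oracle", {
  set.seed(31)
  m <- matrix(runif(60, 0.2, 0.8), 10, 6,
    dimnames = list(sprintf("cg%02d", 1:10), sprintf("S%02d", 1:6)))
  tbl <- as_beta_tbl(m)

  tbl$detection_p <- 0
  expect_identical(mask_low_detection(tbl)$beta, tbl$beta)

  # exactly at the threshold is kept (strict ">")
  tbl$detection_p <- 0.01
  expect_identical(mask_low_detection(tbl, 0.01)$beta, tbl$beta)

  tbl$detection_p <- runif(60)
  masked <- mask_low_detection(tbl, 0.01)
  expect_equal(sum(is.na(masked$beta)), sum(tbl$detection_p > 0.01))
  expect_equal(masked$beta[tbl$detection_p <= 0.01],
    tbl$beta[tbl$detection_p <= 0.01])

  tbl$detection_p <- NULL
  expect_error(mask_low_detection(tbl), "detection_p")
})

test_that("KNN imputation follows the documented neighbour rule", {
  # no missing values: identity
  set.seed(32)
  m <- matrix(runif(20), 4, 5,
    dimnames = list(sprintf("cg%02d", 1:4), sprintf("S%02d", 1:5)))
  tbl <- as_beta_tbl(m)
  expect_identical(impute_knn(tbl, k = 2), tbl)

  # three identical site rows: the imputed cell equals the shared value
  m2 <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 3), 3, 4,
    dimnames = list(c("a", "b", "c"), sprintf("S%02d", 1:4)))
  m2["a", "S02"] <- NA
  out <- beta_matrix(impute_knn(as_beta_tbl(m2), k = 2))
  expect_equal(out["a", "S02"], 0.4)

  # k = 1 equals the nearest row's value, by exhaustive distance computation
  set.seed(33)
  m3 <- matrix(runif(20), 5, 4,
    dimnames = list(sprintf("cg%02d", 1:5), sprintf("S%02d", 1:4)))
  m3[1, 2] <- NA
  m3[4, 3] <- NA
  got <- beta_matrix(impute_knn(as_beta_tbl(m3), k = 1))
  expect_equal(got, oracle_knn_impute(m3, k = 1))

  # general brute-force agreement with several missing cells
  set.seed(34)
  m4 <- matrix(runif(48), 8, 6,
    dimnames = list(sprintf("cg%02d", 1:8), sprintf("S%02d", 1:6)))
  m4[sample(length(m4), 7)] <- NA
  expect_equal(beta_matrix(impute_knn(as_beta_tbl(m4), k = 3)),
    oracle_knn_impute(m4, k = 3))

  # a fully missing site is an error naming the site
  m5 <- m3
  m5[2, ] <- NA
  expect_error(impute_knn(as_beta_tbl(m5), k = 1), "cg02")
})

test_that("per-site regression matches an independent lm/cor.test oracle", {
  # perfect line underflows to p = 0 with R = 1
  rec <- site_association(0.001 * c(20, 25, 40, 55, 60, 70, 75, 80) + 0.1,
    c(20, 25, 40, 55, 60, 70, 75, 80))
  expect_equal(rec$R, 1)
  expect_equal(rec$R2, 1)
  expect_equal(rec$p, 0)

  # zero-variance convention
  flat <- site_association(rep(0.4, 5), c(20, 30, 40, 50, 60))
  expect_equal(flat$R, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$slope, 0)
  expect_true(flat$degenerate)

  # worked example against the independent oracle
  o <- oracle_site_lm(c(0.10, 0.30, 0.20, 0.50), c(20, 30, 40, 50))
  rec2 <- site_association(c(0.10, 0.30, 0.20, 0.50), c(20, 30, 40, 50))
  expect_equal(rec2$slope, o$slope, tolerance = 1e-12)
  expect_equal(rec2$R, o$R, tolerance = 1e-12)
  expect_equal(rec2$p, o$p, tolerance = 1e-12)

  # 100 random instances agree to 1e-10
  set.seed(35)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    age <- runif(n, 20, 80)
    beta <- runif(n)
    o <- oracle_site_lm(beta, age)
    r <- site_association(beta, age)
    expect_equal(r$slope, o$slope, tolerance = 1e-10)
    expect_equal(r$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(r$R, o$R, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }

  expect_error(site_association(c(0.1, 0.2), c(20, 30)), "3")
})

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(adjust_bh(c(0.001, 0.02, 0.03, 0.5)), c(0.004, 0.04, 0.04, 0.5))
  expect_equal(adjust_bh(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(adjust_bh(0.2), 0.2) # m = 1
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(36)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- adjust_bh(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("site selection applies strict inequalities exactly as printed", {
  records <- tibble::tibble(
    site_id = sprintf("cg%02d", 1:4),
    slope = c(0.01, -0.02, 0.005, -0.001),
    R2 = c(0.51, 0.50, 0.80, 0.49),
    p = c(0.009, 0.009, 0.01, 0.5),
    q = c(0.009, 0.20, 0.10, 0.9)
  )
  sel <- select_sites(records)
  loose <- sel[sel$rule == "loose", ]
  strict <- sel[sel$rule == "strict", ]
  expect_equal(loose$site_id, "cg01")       # cg02 fails R2 > 0.5, cg03 fails p < 0.01
  expect_equal(strict$site_id, "cg01")
  expect_equal(loose$direction, "positive")

  # filter oracle on a synthetic scan
  co <- simulate_cohort(16, c(21, 32), twin_pairs = 8, seed = 37)
  sim <- simulate_betas(co, n_sites = 300, n_associated = 25,
    slope_range = c(0.015, 0.03), baseline_range = c(0.35, 0.65),
    baseline_age = 26.5, noise_sd = 0.03, seed = 37)
  rec <- scan_associations(sim$betas, co)
  sel2 <- select_sites(rec)
  expect_setequal(
    sel2$site_id[sel2$rule == "loose"],
    rec$site_id[rec$p < 0.01 & rec$R2 > 0.5]
  )
  expect_setequal(
    sel2$site_id[sel2$rule == "strict"],
    rec$site_id[rec$q < 0.01]
  )
})

test_that("island enrichment agrees with hypergeometric enumeration", {
  ann <- tibble::tibble(
    site_id = sprintf("cg%02d", 1:20),
    in_island = rep(c(TRUE, FALSE), 10)
  )
  # identical proportions: p close to 1
  null_res <- test_island_enrichment(sprintf("cg%02d", 1:4), ann)
  expect_gt(null_res$p_value, 0.5)

  # [[8,2],[2,8]] against the exhaustive tail oracle
  ann2 <- tibble::tibble(
    site_id = sprintf("s%02d", 1:20),
    in_island = c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  )
  res <- test_island_enrichment(sprintf("s%02d", 1:10), ann2)
  tab <- attr(res, "contingency")
  expect_equal(unname(tab), matrix(c(8, 2, 2, 8), 2, byrow = TRUE))
  expect_equal(res$p_value, oracle_fisher_2x2(tab), tolerance = 1e-12)

  # swapping row labels leaves the two-sided p unchanged
  res_swap <- test_island_enrichment(sprintf("s%02d", 11:20), ann2)
  expect_equal(res$p_value, res_swap$p_value, tolerance = 1e-12)

  expect_error(test_island_enrichment(character(0), ann), "empty")
  expect_error(test_island_enrichment("nope", ann), "annotation")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("a synthetic scan recovers planted sites and controls background", {
  co <- simulate_cohort(16, c(21, 32), twin_pairs = 8, seed = 38)
  sim <- simulate_betas(co, n_sites = 1000, n_associated = 50,
    slope_range = c(0.017, 0.03), baseline_range = c(0.35, 0.65),
    baseline_age = 26.5, noise_sd = 0.03, missing_rate = 0.01, seed = 38)
  rec <- scan_associations(sim$betas, co)
  sel <- select_sites(rec)
  loose <- sel$site_id[sel$rule == "loose"]
  planted <- sim$truth$site_id[sim$truth$associated]
  recall <- mean(planted %in% loose)
  admit <- mean(setdiff(sim$truth$site_id, planted) %in% loose)
  expect_gt(recall, 0.85)
  expect_lt(admit, 0.01)
})
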