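test_that("calibration fitting recovers known lines", {
  # identity standards
  s <- tibble::tibble(known = seq(0, 1, 0.1), measured = seq(0, 1, 0.1))
  cal <- fit_calibration(s)
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r2_fit, 1, tolerance = 1e-12)

  # standards through the inverse distortion recover the printed line
  d <- platform_distortion(2.285, -1.2176, standard_noise_sd = 0)
  cal2 <- fit_calibration(simulate_standards(d))
  expect_equal(cal2$slope, 2.285, tolerance = 1e-10)
  expect_equal(cal2$intercept, -1.2176, tolerance = 1e-10)

  # two-point closed form: slope = dy/dx, intercept = y1 - slope * x1
  two <- tibble::tibble(known = c(0.0, 1.0), measured = c(0.5, 0.9705))
  cal3 <- fit_calibration(two)
  expect_equal(cal3$slope, 1 / 0.4705, tolerance = 1e-10)
  expect_equal(cal3$intercept, -0.5 / 0.4705, tolerance = 1e-10)

  expect_error(fit_calibration(tibble::tibble(known = c(0, 1), measured = c(0.4, 0.4))),
    "constant")
})

test_that("calibration application is the clipped elementwise line", {
  tbl <- fixture_beta_tbl(matrix(c(0.2, 0.5, NA, 0.9), 2, 2))
  ident <- structure(list(slope = 1, intercept = 0, r2_fit = 1, n = 2),
    class = "calibration_model")
  out <- apply_calibration(tbl, ident)
  expect_identical(out$beta, tbl$beta)

  d <- structure(list(slope = 2.285, intercept = -1.2176, r2_fit = 0.88, n = 11),
    class = "calibration_model")
  # measured 0.5 maps to 2.285*0.5 - 1.2176 = -0.0751, clipped to 0
  half <- fixture_beta_tbl(matrix(0.5, 1, 1))
  corr <- apply_calibration(half, d, quiet = TRUE)
  expect_equal(corr$beta, 0)
  expect_equal(attr(corr, "n_clipped"), 1L)

  set.seed(41)
  m <- matrix(runif(40, 0.4, 1.0), 8, 5,
    dimnames = list(sprintf("X%02d", 1:8), sprintf("F%02d", 1:5)))
  m[2, 3] <- NA
  tbl2 <- as_beta_tbl(m)
  out2 <- apply_calibration(tbl2, d, quiet = TRUE)
  manual <- pmin(1, pmax(0, 2.285 * tbl2$beta - 1.2176))
  expect_equal(out2$beta, manual)
  expect_true(is.na(out2$beta[tbl2$site_id == "X02" & tbl2$sample_id == "F03"]))
})

test_that("confidence filtering is strict and reports the acceptance fraction", {
  tbl <- fixture_beta_tbl(matrix(runif(30, 0.2, 0.8), 5, 6))
  tbl$confidence <- 5
  out <- filter_confidence(tbl, quiet = TRUE)
  expect_equal(attr(out, "acceptance_fraction"), 1)
  expect_identical(out$beta, tbl$beta)

  # exactly at the cutoff is rejected (strict ">")
  tbl$confidence <- 1.9
  out2 <- filter_confidence(tbl, 1.9, quiet = TRUE)
  expect_true(all(is.na(out2$beta)))
  expect_equal(attr(out2, "acceptance_fraction"), 0)

  set.seed(42)
  tbl$confidence <- runif(30, 0, 5)
  out3 <- filter_confidence(tbl, 1.9, quiet = TRUE)
  expect_equal(attr(out3, "acceptance_fraction"), mean(tbl$confidence > 1.9))
  expect_equal(sum(is.na(out3$beta)), sum(tbl$confidence <= 1.9))

  tbl$confidence <- NULL
  expect_error(filter_confidence(tbl), "confidence")
})

test_that("missingness filtering reproduces the worked exclusion pattern", {
  tbl <- fixture_qc_missingness()
  out <- filter_missingness(tbl, 0.70, 0.70, quiet = TRUE)
  excl <- qc_exclusions(out)
  expect_setequal(excl$sites$site_id, c("X74", "X75", "X88", "X89", "X90"))
  expect_equal(nrow(excl$sites), 5)
  expect_equal(excl$samples$sample_id, "F91")
  expect_equal(
    sort(round(excl$sites$missing_frac[order(excl$sites$site_id)], 2)),
    sort(c(0.82, 0.74, 0.74, 0.72, 0.74))
  )
  expect_gt(excl$samples$missing_frac, 0.70)

  # post-condition: nothing left above either threshold
  site_frac <- tapply(is.na(out$beta), out$site_id, mean)
  sample_frac <- tapply(is.na(out$beta), out$sample_id, mean)
  expect_true(all(site_frac <= 0.70))
  expect_true(all(sample_frac <= 0.70))

  # re-running on its own output is a no-op
  again <- filter_missingness(out, 0.70, 0.70, quiet = TRUE)
  expect_equal(nrow(qc_exclusions(again)$sites), 0)
  expect_identical(again$beta, out$beta)

  # no missing data: nothing excluded
  clean <- fixture_beta_tbl(matrix(0.5, 3, 4))
  out2 <- filter_missingness(clean, quiet = TRUE)
  expect_equal(nrow(qc_exclusions(out2)$sites), 0)
  expect_equal(nrow(qc_exclusions(out2)$samples), 0)

  # exactly 70% missing is retained (strict ">")
  m <- matrix(0.5, 2, 10, dimnames = list(c("a", "b"), sprintf("S%02d", 1:10)))
  m["a", 1:7] <- NA
  out3 <- filter_missingness(as_beta_tbl(m), 0.70, 0.70, quiet = TRUE)
  expect_true("a" %in% out3$site_id)
})

test_that("|R| selection is strict, pairwise-complete, and matches brute force", {
  # a noiseless linear site is selected with R = +-1
  ages <- c(20, 30, 40, 50, 60, 70)
  m <- rbind(
    up = 0.2 + 0.005 * ages,
    down = 0.8 - 0.005 * ages,
    flatish = c(0.5, 0.51, 0.5, 0.51, 0.5, 0.51)
  )
  colnames(m) <- sprintf("F%02d", 1:6)
  meta <- tibble::tibble(sample_id = colnames(m), age = ages)
  sel <- select_by_abs_r(as_beta_tbl(m), meta)
  expect_setequal(sel$site_id, c("up", "down"))
  expect_equal(sel$R[sel$site_id == "up"], 1, tolerance = 1e-12)
  expect_equal(sel$R[sel$site_id == "down"], -1, tolerance = 1e-12)

  # a site whose |R| equals the cutoff exactly is excluded
  r_flat <- abs(cor(m["flatish", ], ages))
  sel2 <- select_by_abs_r(as_beta_tbl(m), meta, abs_r_min = r_flat)
  expect_false("flatish" %in% sel2$site_id)

  # pairwise-complete brute force on a matrix with missing cells
  set.seed(43)
  m2 <- matrix(runif(80), 8, 10,
    dimnames = list(sprintf("X%02d", 1:8), sprintf("F%02d", 1:10)))
  m2[sample(length(m2), 10)] <- NA
  meta2 <- tibble::tibble(sample_id = colnames(m2), age = runif(10, 20, 80))
  sel3 <- select_by_abs_r(as_beta_tbl(m2), meta2, abs_r_min = 0.3)
  brute <- rownames(m2)[vapply(seq_len(nrow(m2)), function(i) {
    ok <- !is.na(m2[i, ])
    sum(ok) >= 3 && abs(cor(m2[i, ok], meta2$age[ok])) > 0.3
  }, logical(1))]
  expect_setequal(sel3$site_id, brute)

  # sites with fewer than 3 observations warn and are excluded
  m3 <- m2
  m3[1, 3:10] <- NA
  expect_warning(sel4 <- select_by_abs_r(as_beta_tbl(m3), meta2, abs_r_min = 0),
    "X01")
  expect_false("X01" %in% sel4$site_id)
})
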