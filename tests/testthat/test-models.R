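test_that("linear fits are exact least squares with rank diagnostics", {
  d <- tibble::tibble(age = c(1, 3, 5), x = c(0, 1, 2))
  fit <- fit_age_model(d, "linear", sites = "x")
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$train_mad, 0, tolerance = 1e-12)

  # duplicated column triggers a rank error naming the column
  d2 <- tibble::tibble(age = runif(8, 20, 80), a = runif(8), b = runif(8))
  d2$b_dup <- d2$b
  expect_error(fit_age_model(d2, "linear", sites = c("a", "b", "b_dup")),
    "b_dup")

  # random instances match the normal-equations oracle to 1e-10
  set.seed(51)
  for (i in 1:10) {
    x <- matrix(runif(60), 20, 3)
    colnames(x) <- c("s1", "s2", "s3")
    y <- runif(20, 20, 80)
    fit <- fit_age_model(make_model_tbl(x, y), "linear")
    o <- oracle_ols(cbind(1, x), y)
    expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(o),
      tolerance = 1e-10)
  }
})

test_that("quadratic fits use pure squares and match the expanded-design oracle", {
  d <- tibble::tibble(age = c(4, 1, 0, 1, 4), x = c(-2, -1, 0, 1, 2))
  fit <- fit_age_model(d, "quadratic", sites = "x")
  expect_equal(unname(fit$sq_coefficients), 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)

  # p = 11 sites with n = 49 gives 23 parameters and must fit
  v <- simulate_validation_cohort(n_samples = 49, n_sites = 11, seed = 52)
  fitq <- fit_age_model(v$data, "quadratic")
  expect_equal(length(fitq$coefficients) + length(fitq$sq_coefficients) + 1, 23)

  set.seed(53)
  x <- matrix(runif(80), 20, 4)
  colnames(x) <- paste0("s", 1:4)
  y <- runif(20, 20, 80)
  fit2 <- fit_age_model(make_model_tbl(x, y), "quadratic")
  o <- oracle_ols(cbind(1, x, x^2), y)
  expect_equal(
    unname(c(fit2$intercept, fit2$coefficients, fit2$sq_coefficients)),
    unname(o), tolerance = 1e-10
  )
})

test_that("BPNN training is deterministic and reduces the loss", {
  set.seed(54)
  x <- matrix(runif(45), 15, 3)
  colnames(x) <- paste0("s", 1:3)

  # constant target: predictions settle on the constant
  d <- make_model_tbl(x, rep(33, 15))
  fit <- fit_age_model(d, "bpnn", seed = 2)
  expect_true(all(abs(predict(fit, d) - 33) < 0.1))

  # same seed, identical weights; different seed, different weights
  y <- runif(15, 20, 80)
  d2 <- make_model_tbl(x, y)
  f1 <- fit_age_model(d2, "bpnn", seed = 9)
  f2 <- fit_age_model(d2, "bpnn", seed = 9)
  f3 <- fit_age_model(d2, "bpnn", seed = 10)
  expect_identical(f1$w1, f2$w1)
  expect_identical(f1$w2, f2$w2)
  expect_false(identical(f1$w1, f3$w1))

  # the recorded loss curve ends no higher than it starts
  expect_lte(f1$loss_curve[length(f1$loss_curve)], f1$loss_curve[1])
  expect_lte(f1$epochs_run, 1000)
})

test_that("SVR handles the degenerate branches exactly", {
  x <- matrix(runif(12), 6, 2)
  colnames(x) <- c("s1", "s2")

  # constant response: constant predictor, no solver call
  fitc <- fit_age_model(make_model_tbl(x, rep(40, 6)), "svr")
  expect_equal(predict(fitc, make_model_tbl(x, rep(0, 6))), rep(40, 6))
  expect_equal(fitc$dual_coefficients, rep(0, 6))

  # epsilon wider than the standardized response range: empty support,
  # bias at the midpoint of the optimal interval
  y <- c(20, 25, 30, 35, 40, 45)
  fit <- fit_age_model(make_model_tbl(x, y), "svr", epsilon = 5)
  expect_equal(fit$dual_coefficients, rep(0, 6))
  ys <- (y - mean(y)) / sd(y)
  expect_equal(fit$bias, (max(ys) + min(ys)) / 2, tolerance = 1e-12)
  pred <- predict(fit, make_model_tbl(x, y))
  expect_equal(pred, rep(mean(c(max(y), min(y))), 6), tolerance = 1e-8)
})

test_that("SVR solutions satisfy the dual feasibility and KKT structure", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(6:14, 1)
    p <- sample(1:3, 1)
    x <- matrix(runif(n * p), n, p)
    colnames(x) <- paste0("s", seq_len(p))
    y <- runif(n, 20, 80)
    fit <- fit_age_model(make_model_tbl(x, y), "svr")
    beta <- fit$dual_coefficients
    expect_lt(abs(sum(beta)), 1e-8)
    expect_true(all(abs(beta) <= 2 + 1e-10))
    # points strictly inside the epsilon-tube carry zero dual weight
    ys <- (y - mean(y)) / sd(y)
    fitted_s <- (predict(fit, make_model_tbl(x, y)) - mean(y)) / sd(y)
    inside <- abs(fitted_s - ys) < 0.1 - 1e-5
    expect_true(all(abs(beta[inside]) < 1e-6))
    expect_lte(fit$kkt_gap, 1e-6)
  }
})

test_that("SVR agrees with an independent LIBSVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(56)
  for (i in 1:5) {
    n <- sample(10:25, 1)
    x <- matrix(runif(n * 2), n, 2)
    colnames(x) <- c("s1", "s2")
    y <- 20 + 50 * x[, 1] + rnorm(n, 0, 3)
    fit <- fit_age_model(make_model_tbl(x, y), "svr")
    ref <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
      cost = 2, gamma = 0.1, epsilon = 0.1, tolerance = 1e-6)
    expect_equal(predict(fit, make_model_tbl(x, y)),
      unname(predict(ref, x)), tolerance = 1e-3)
  }
})

test_that("prediction interface matches columns by name and validates them", {
  set.seed(57)
  x <- matrix(runif(30), 10, 3)
  colnames(x) <- c("s1", "s2", "s3")
  y <- runif(10, 20, 80)
  d <- make_model_tbl(x, y)
  fit <- fit_age_model(d, "linear")

  shuffled <- d[, c("s3", "age", "s1", "s2")]
  expect_equal(predict(fit, shuffled), predict(fit, d))

  expect_error(predict(fit, d[, c("age", "s1", "s2")]), "s3")

  rep1 <- prediction_report(fit, d)
  expect_equal(attr(rep1, "mad"), mean(abs(rep1$predicted - rep1$age)))
})

test_that("MAD is the mean absolute residual and permutation invariant", {
  expect_equal(mad_years(c(20, 40), c(25, 30)), 7.5)
  expect_equal(mad_years(c(20, 40), c(20, 40)), 0)
  set.seed(58)
  obs <- runif(20, 20, 80)
  pred <- obs + rnorm(20)
  perm <- sample(20)
  expect_equal(mad_years(obs, pred), mad_years(obs[perm], pred[perm]))
})

test_that("fitted models survive a JSON round trip with identical predictions", {
  set.seed(59)
  x <- matrix(runif(36), 12, 3)
  colnames(x) <- c("s1", "s2", "s3")
  y <- 20 + 40 * x[, 1] + rnorm(12, 0, 2)
  d <- make_model_tbl(x, y)
  for (fam in c("linear", "quadratic", "bpnn", "svr")) {
    fit <- fit_age_model(d, fam, seed = 3)
    path <- withr::local_tempfile(fileext = ".json")
    write_age_model(fit, path)
    back <- read_age_model(path)
    expect_equal(predict(back, d), predict(fit, d), tolerance = 1e-12)
  }
})
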