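# The four regression families compared for methylation-age prediction,
# behind one fit/predict contract. Model tables are wide: one row per
# sample, an age column, one numeric column per CpG site.

#' Fit an age-prediction model
#'
#' Fits one of the four regression families used for methylation-based age
#' prediction: multivariate linear regression, quadratic multiple
#' regression (pure squares added, no cross terms), a single-hidden-layer
#' back-propagation neural network, or epsilon-support-vector regression
#' with an RBF kernel (the package's own SMO solver; see Details).
#'
#' @details
#' **SVR.** The dual of the epsilon-insensitive problem is solved by
#' sequential minimal optimisation over the 2n-variable box-constrained QP
#' with the single equality constraint, to a KKT tolerance of `tol`
#' (default 1e-6). Features and the response are standardised internally
#' (the conventional default for RBF kernels, without which a fixed
#' `gamma` is meaningless across the beta and age scales); `epsilon`
#' applies on the standardised response and predictions are
#' de-standardised. A zero-variance response short-circuits to a constant
#' predictor. If no training point leaves the epsilon-tube the bias is the
#' midpoint of the optimal interval `[max(y) - epsilon, min(y) + epsilon]`.
#'
#' **BPNN.** One hidden layer of `hidden` sigmoid units with a linear
#' output, trained by full-batch gradient descent on standardised data for
#' exactly `max_epochs` epochs unless the loss plateaus; deterministic
#' given `seed`. The loss curve is retained in the fitted object.
#'
#' @param data Wide tibble: one row per sample, a numeric age column and
#'   one numeric column per site. No missing values.
#' @param family `"linear"`, `"quadratic"`, `"bpnn"`, or `"svr"`.
#' @param age Name of the age column (default `"age"`).
#' @param sites Character vector of site columns; default every numeric
#'   column except the age column.
#' @param cost,gamma,epsilon SVR hyperparameters (defaults 2, 0.1, 0.1).
#' @param tol SVR KKT tolerance (default 1e-6).
#' @param max_iter SVR maximum SMO iterations; non-convergence is an error.
#' @param hidden,learning_rate,max_epochs,plateau_tol,seed BPNN
#'   hyperparameters (defaults 3, 0.05, 1000, 1e-12, 1).
#' @return An object of class `c("<family>_age_model", "age_model")`
#'   supporting [predict()], [tidy()], [glance()], and
#'   [prediction_report()].
#' @examples
#' cohort <- simulate_validation_cohort(n_samples = 20, n_sites = 3, seed = 4)
#' m <- fit_age_model(cohort$data, family = "svr")
#' predict(m, cohort$data)[1:3]
#' @export
fit_age_model <- function(data, family = c("linear", "quadratic", "bpnn", "svr"),
                          age = "age", sites = NULL,
                          cost = 2, gamma = 0.1, epsilon = 0.1,
                          tol = 1e-6, max_iter = 1e5,
                          hidden = 3, learning_rate = 0.05, max_epochs = 1000,
                          plateau_tol = 1e-12, seed = 1) {
  family <- match.arg(family)
  check_columns(data, age, "model table")
  if (is.null(sites)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    sites <- setdiff(numeric_cols, age)
  } else {
    check_columns(data, sites, "model table")
  }
  if (length(sites) == 0 && family != "linear") {
    abort_field("at least one site column is required.", "sites")
  }
  x <- as.matrix(data[, sites, drop = FALSE])
  y <- data[[age]]
  if (anyNA(x) || anyNA(y)) {
    abort_field("model table contains missing values; impute or filter first.")
  }
  fit <- switch(family,
    linear = fit_linear_ls(x, y),
    quadratic = fit_quadratic_ls(x, y),
    bpnn = fit_bpnn_gd(x, y, hidden, learning_rate, max_epochs, plateau_tol, seed),
    svr = fit_svr_smo(x, y, cost, gamma, epsilon, tol, max_iter)
  )
  fit$family <- family
  fit$sites <- sites
  fit$age_col <- age
  fit$n <- nrow(x)
  class(fit) <- c(paste0(family, "_age_model"), "age_model")
  fit$train_mad <- mad_years(y, predict(fit, data))
  fit
}

# ---- linear / quadratic -----------------------------------------------------

solve_ls <- function(design, y, what) {
  n <- nrow(design)
  p <- ncol(design)
  if (n <= p) {
    abort_field(sprintf("%s needs n > %d samples for %d parameters.", what, p, p))
  }
  qrd <- qr(design)
  if (qrd$rank < p) {
    collinear <- colnames(design)[qrd$pivot[(qrd$rank + 1):p]]
    abort_field(sprintf(
      "%s design is rank deficient; collinear column(s): %s.",
      what, paste(collinear, collapse = ", ")
    ))
  }
  drop(qr.coef(qrd, y))
}

fit_linear_ls <- function(x, y) {
  design <- cbind(`(Intercept)` = 1, x)
  coefs <- solve_ls(design, y, "linear regression")
  list(coefficients = coefs[-1], intercept = unname(coefs[1]))
}

fit_quadratic_ls <- function(x, y) {
  sq <- x^2
  colnames(sq) <- paste0(colnames(x), "_sq")
  design <- cbind(`(Intercept)` = 1, x, sq)
  coefs <- solve_ls(design, y, "quadratic regression")
  list(
    coefficients = coefs[1 + seq_len(ncol(x))],
    sq_coefficients = coefs[1 + ncol(x) + seq_len(ncol(x))],
    intercept = unname(coefs[1])
  )
}

# ---- scaling helpers --------------------------------------------------------

scale_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

scale_apply <- function(x, s) sweep(sweep(x, 2, s$center), 2, s$scale, "/")

# ---- BPNN -------------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

fit_bpnn_gd <- function(x, y, hidden, learning_rate, max_epochs, plateau_tol, seed) {
  hidden <- check_count(hidden, "hidden", min = 1)
  max_epochs <- check_count(max_epochs, "max_epochs", min = 1)
  if (is.null(seed)) abort_field("bpnn requires an integer `seed`.", "seed")
  xs <- scale_fit(x)
  xm <- scale_apply(x, xs)
  y_center <- mean(y)
  y_scale <- sd(y)
  if (y_scale == 0) y_scale <- 1
  yv <- (y - y_center) / y_scale
  n <- nrow(xm)
  p <- ncol(xm)

  with_seed(derive_seed(seed, "bpnn"), {
    w1 <- matrix(runif(hidden * p, -0.5, 0.5), hidden, p)
    b1 <- runif(hidden, -0.5, 0.5)
    w2 <- runif(hidden, -0.5, 0.5)
    b2 <- 0
    loss_curve <- numeric(max_epochs)
    epochs_run <- 0
    for (epoch in seq_len(max_epochs)) {
      a1 <- tcrossprod(xm, w1)          # n x hidden pre-activations
      a1 <- sweep(a1, 2, b1, "+")
      h <- sigmoid(a1)
      pred <- drop(h %*% w2) + b2
      resid <- pred - yv
      loss <- mean(resid^2) / 2
      if (!is.finite(loss)) {
        abort_field(sprintf("bpnn training diverged (non-finite loss at epoch %d).", epoch))
      }
      loss_curve[epoch] <- loss
      epochs_run <- epoch
      if (epoch > 1 && abs(loss_curve[epoch - 1] - loss) < plateau_tol) break
      # full-batch gradients
      g_out <- resid / n                     # dL/dpred
      gw2 <- drop(crossprod(h, g_out))
      gb2 <- sum(g_out)
      gh <- outer(g_out, w2) * h * (1 - h)   # n x hidden
      gw1 <- crossprod(gh, xm)               # hidden x p
      gb1 <- colSums(gh)
      w2 <- w2 - learning_rate * gw2
      b2 <- b2 - learning_rate * gb2
      w1 <- w1 - learning_rate * gw1
      b1 <- b1 - learning_rate * gb1
    }
    list(
      w1 = w1, b1 = b1, w2 = w2, b2 = b2,
      x_scaling = xs, y_center = y_center, y_scale = y_scale,
      hidden = hidden, learning_rate = learning_rate, seed = seed,
      epochs_run = epochs_run, loss_curve = loss_curve[seq_len(epochs_run)]
    )
  })
}

# ---- SVR: SMO over the 2n-variable dual -------------------------------------

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# Solve min_a 1/2 a'Qa + p'a, 0 <= a <= C, z'a = 0 with
# Q[i,j] = z_i z_j K[idx(i), idx(j)], z = (+1^n, -1^n),
# p = (eps - y, eps + y). Returns beta = alpha - alpha*, bias, objective.
svr_solve_smo <- function(K, y, C, epsilon, tol = 1e-6, max_iter = 1e5) {
  n <- length(y)
  z <- c(rep(1, n), rep(-1, n))
  pvec <- c(epsilon - y, epsilon + y)
  idx <- c(seq_len(n), seq_len(n))
  a <- numeric(2 * n)
  G <- pvec
  kd <- diag(K)
  eps_a <- 1e-12
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    negzG <- -z * G
    up <- (z > 0 & a < C - eps_a) | (z < 0 & a > eps_a)
    low <- (z > 0 & a > eps_a) | (z < 0 & a < C - eps_a)
    m_val <- max(negzG[up])
    M_val <- min(negzG[low])
    if (m_val - M_val <= tol) {
      converged <- TRUE
      break
    }
    i <- which(up)[which.max(negzG[up])]
    j <- which(low)[which.min(negzG[low])]
    zz <- z[i] * z[j]
    g <- G[i] - zz * G[j]
    eta <- kd[idx[i]] + kd[idx[j]] - 2 * K[idx[i], idx[j]]
    if (eta <= 1e-12) eta <- 1e-12
    t_star <- -g / eta
    # feasible range for t = delta a_i, with delta a_j = -zz * t
    t_lo <- -a[i]
    t_hi <- C - a[i]
    if (zz > 0) { # a_j moves by -t
      t_lo <- max(t_lo, a[j] - C)
      t_hi <- min(t_hi, a[j])
    } else {      # a_j moves by +t
      t_lo <- max(t_lo, -a[j])
      t_hi <- min(t_hi, C - a[j])
    }
    t_step <- min(max(t_star, t_lo), t_hi)
    if (t_step == 0) break
    a[i] <- a[i] + t_step
    a[j] <- a[j] - zz * t_step
    qcol_i <- z * z[i] * K[idx, idx[i]]
    qcol_j <- z * z[j] * K[idx, idx[j]]
    G <- G + t_step * qcol_i + (-zz * t_step) * qcol_j
  }
  if (!converged) {
    negzG <- -z * G
    up <- (z > 0 & a < C - eps_a) | (z < 0 & a > eps_a)
    low <- (z > 0 & a > eps_a) | (z < 0 & a < C - eps_a)
    m_val <- max(negzG[up])
    M_val <- min(negzG[low])
    if (m_val - M_val > tol) {
      abort_field(sprintf(
        "SVR solver failed to converge in %d iterations (KKT gap %.3g).",
        max_iter, m_val - M_val
      ))
    }
  }
  beta <- a[seq_len(n)] - a[n + seq_len(n)]
  bias <- (m_val + M_val) / 2
  objective <- 0.5 * drop(crossprod(beta, K %*% beta)) - sum(y * beta) +
    epsilon * sum(abs(beta))
  list(beta = beta, bias = bias, objective = objective,
       iterations = it, kkt_gap = m_val - M_val)
}

fit_svr_smo <- function(x, y, cost, gamma, epsilon, tol, max_iter) {
  check_number(cost, "cost", min = 0, strict_min = TRUE)
  check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  check_number(epsilon, "epsilon", min = 0)
  if (nrow(x) < 2) abort_field("SVR needs at least 2 samples.")
  xs <- scale_fit(x)
  xm <- scale_apply(x, xs)
  y_center <- mean(y)
  y_scale <- sd(y)
  base <- list(
    x_train = xm, x_scaling = xs, y_center = y_center,
    y_scale = if (y_scale == 0) 1 else y_scale,
    cost = cost, gamma = gamma, epsilon = epsilon, tol = tol
  )
  if (y_scale == 0) {
    # constant response: optimal solution is the constant predictor
    return(c(base, list(
      dual_coefficients = numeric(nrow(x)), bias = 0, objective = 0,
      support_indices = integer(0), total_slack = 0, iterations = 0
    )))
  }
  yv <- (y - y_center) / y_scale
  K <- rbf_kernel(xm, xm, gamma)
  sol <- svr_solve_smo(K, yv, cost, epsilon, tol, max_iter)
  fitted_s <- drop(K %*% sol$beta) + sol$bias
  slack <- pmax(0, abs(fitted_s - yv) - epsilon)
  c(base, list(
    dual_coefficients = sol$beta, bias = sol$bias, objective = sol$objective,
    support_indices = which(abs(sol$beta) > 1e-8),
    total_slack = sum(slack), iterations = sol$iterations,
    kkt_gap = sol$kkt_gap
  ))
}

# ---- predict / report -------------------------------------------------------

#' Predict ages from a fitted model
#'
#' @param object A fitted `age_model`.
#' @param newdata Wide tibble containing the model's site columns (matched
#'   by name; column order is irrelevant).
#' @param ... Unused.
#' @return Numeric vector of predicted ages (years).
#' @export
predict.age_model <- function(object, newdata, ...) {
  missing_sites <- setdiff(object$sites, names(newdata))
  if (length(missing_sites) > 0) {
    abort_field(sprintf(
      "newdata lacks model site column(s): %s.",
      paste(missing_sites, collapse = ", ")
    ))
  }
  if (nrow(newdata) == 0) abort_field("`newdata` has no rows.")
  x <- as.matrix(newdata[, object$sites, drop = FALSE])
  switch(object$family,
    linear = drop(x %*% object$coefficients) + object$intercept,
    quadratic = drop(x %*% object$coefficients) +
      drop(x^2 %*% object$sq_coefficients) + object$intercept,
    bpnn = {
      xm <- scale_apply(x, object$x_scaling)
      h <- sigmoid(sweep(tcrossprod(xm, object$w1), 2, object$b1, "+"))
      (drop(h %*% object$w2) + object$b2) * object$y_scale + object$y_center
    },
    svr = {
      xm <- scale_apply(x, object$x_scaling)
      k <- rbf_kernel(xm, object$x_train, object$gamma)
      (drop(k %*% object$dual_coefficients) + object$bias) * object$y_scale +
        object$y_center
    }
  )
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf(
    "<age_model: %s> %d training samples, %d site(s); training MAD %.3f years\n",
    x$family, x$n, length(x$sites), x$train_mad
  ))
  invisible(x)
}

#' Mean absolute deviation between predicted and observed age
#'
#' @param observed,predicted Numeric vectors of ages (years).
#' @return The mean of `|predicted - observed|`, in years.
#' @examples
#' mad_years(c(20, 40), c(25, 30))
#' @export
mad_years <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  mean(abs(predicted - observed))
}

#' Per-sample prediction report
#'
#' Applies a fitted model to a labelled table and tabulates observed age,
#' predicted age and residual per sample, with the MAD as attribute
#' `"mad"` (also via `glance()`).
#'
#' @param model A fitted `age_model`.
#' @param data Wide tibble with the model's site columns and its age
#'   column; an optional `sample_id` column is carried through.
#' @return A tibble of class `"prediction_report"`: `sample_id`,
#'   `age`, `predicted`, `residual`.
#' @export
prediction_report <- function(model, data) {
  check_columns(data, model$age_col, "data")
  pred <- predict(model, data)
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(data)) data$sample_id else
      sprintf("S%03d", seq_len(nrow(data))),
    age = data[[model$age_col]],
    predicted = pred,
    residual = pred - data[[model$age_col]]
  )
  class(out) <- c("prediction_report", class(out))
  attr(out, "mad") <- mad_years(out$age, out$predicted)
  attr(out, "family") <- model$family
  out
}
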