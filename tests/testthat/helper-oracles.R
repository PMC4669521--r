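# Independent oracles used across the suite. Each is deliberately coded
# from first principles, on a different algorithmic route than the package
# implementation it checks.

# ---- dense-QP oracle for epsilon-SVR ----------------------------------------
# Solves the 2n-variable dual  min 1/2 a'Qa + p'a,  0 <= a <= C,  z'a = 0
# by FISTA with exact projection onto the box-hyperplane intersection
# (bisection on the hyperplane multiplier). Returns the equivalent
# beta = alpha - alpha*, the dual objective in beta form, and predictions.
oracle_svr_qp <- function(x, y, cost = 2, gamma = 0.1, epsilon = 0.1,
                          max_iter = 30000) {
  n <- length(y)
  d2 <- as.matrix(dist(x))^2
  K <- exp(-gamma * d2)
  z <- c(rep(1, n), rep(-1, n))
  pvec <- c(epsilon - y, epsilon + y)
  idx <- c(seq_len(n), seq_len(n))
  Q <- outer(z, z) * K[idx, idx]

  project <- function(v) {
    # find lambda with z' clip(v - lambda z, 0, C) = 0 (monotone decreasing)
    lo <- min(v * z) - cost
    hi <- max(v * z) + cost
    for (b in 1:60) {
      mid <- (lo + hi) / 2
      if (sum(z * pmin(cost, pmax(0, v - mid * z))) > 0) lo <- mid else hi <- mid
    }
    pmin(cost, pmax(0, v - ((lo + hi) / 2) * z))
  }

  L <- max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)) + 1e-9
  a <- numeric(2 * n)
  v <- a
  t_k <- 1
  f_prev <- Inf
  for (iter in seq_len(max_iter)) {
    grad <- drop(Q %*% v) + pvec
    a_new <- project(v - grad / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    v <- a_new + ((t_k - 1) / t_new) * (a_new - a)
    a <- a_new
    t_k <- t_new
    if (iter %% 500 == 0) {
      f_cur <- 0.5 * drop(crossprod(a, Q %*% a)) + sum(pvec * a)
      if (abs(f_prev - f_cur) < 1e-15) break
      f_prev <- f_cur
    }
  }
  beta <- a[seq_len(n)] - a[n + seq_len(n)]
  objective <- 0.5 * drop(crossprod(beta, K %*% beta)) - sum(y * beta) +
    epsilon * sum(abs(beta))
  # bias from the KKT interval of the final gradient
  G <- drop(Q %*% a) + pvec
  negzG <- -z * G
  tol_a <- 1e-9
  up <- (z > 0 & a < cost - tol_a) | (z < 0 & a > tol_a)
  low <- (z > 0 & a > tol_a) | (z < 0 & a < cost - tol_a)
  bias <- (max(negzG[up]) + min(negzG[low])) / 2
  fitted <- drop(K %*% beta) + bias
  list(beta = beta, bias = bias, objective = objective, fitted = fitted, K = K)
}

# ---- closed-form OLS oracle (normal equations) ------------------------------
oracle_ols <- function(design, y) {
  drop(solve(crossprod(design), crossprod(design, y)))
}

# ---- hand-coded BH step-up ---------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  # literal step-up definition: q_(i) = min_{j >= i} p_(j) * m / j
  for (i in seq_len(m)) q_sorted[i] <- min(p[o][i:m] * m / seq(i, m))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# ---- exhaustive hypergeometric two-sided Fisher p ---------------------------
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- brute-force per-site regression ----------------------------------------
oracle_site_lm <- function(beta, age) {
  fit <- lm(beta ~ age)
  ct <- suppressWarnings(cor.test(beta, age))
  list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    R = unname(ct$estimate), p = ct$p.value,
    t = unname(ct$statistic)
  )
}

# ---- brute-force KNN imputation per the documented rule ---------------------
oracle_knn_impute <- function(x, k) {
  n_samples <- ncol(x)
  out <- x
  for (i in seq_len(nrow(x))) {
    for (s in seq_len(n_samples)) {
      if (!is.na(x[i, s])) next
      d <- rep(Inf, nrow(x))
      for (j in seq_len(nrow(x))) {
        if (j == i) next
        mutual <- which(!is.na(x[i, ]) & !is.na(x[j, ]))
        if (length(mutual) == 0) next
        d[j] <- sqrt(sum((x[i, mutual] - x[j, mutual])^2) * n_samples / length(mutual))
      }
      elig <- which(is.finite(d) & !is.na(x[, s]))
      elig <- elig[order(d[elig])]
      nb <- elig[seq_len(min(k, length(elig)))]
      out[i, s] <- if (length(nb) > 0) mean(x[nb, s]) else mean(x[i, ], na.rm = TRUE)
    }
  }
  out
}

# ---- misc -------------------------------------------------------------------
make_model_tbl <- function(x, y) {
  d <- tibble::as_tibble(as.data.frame(x))
  names(d) <- colnames(x) %||% paste0("s", seq_len(ncol(x)))
  d$age <- y
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
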