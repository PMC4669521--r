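#' Leave-one-out cross-validation of an age model
#'
#' For each sample i the model is refit on the other n - 1 samples and
#' used to predict sample i; the per-sample predictions and the overall
#' leave-one-out MAD measure out-of-sample accuracy. Deterministic
#' families give deterministic reports; the BPNN is reseeded per fold as
#' `seed + fold index` so folds are independent but reproducible.
#'
#' @inheritParams fit_age_model
#' @param ... Passed to [fit_age_model()] (hyperparameters).
#' @return A `"prediction_report"` tibble (see [prediction_report()]) with
#'   the LOO MAD in attribute `"mad"`.
#' @examples
#' d <- tibble::tibble(age = c(1, 2, 3))
#' loo_cv(d, family = "linear", sites = character(0))
#' @export
loo_cv <- function(data, family = c("linear", "quadratic", "bpnn", "svr"),
                   age = "age", sites = NULL, seed = 1, ...) {
  family <- match.arg(family)
  check_columns(data, age, "model table")
  n <- nrow(data)
  if (n < 3) abort_field("leave-one-out needs at least 3 samples.")
  preds <- vapply(seq_len(n), function(i) {
    fit <- tryCatch(
      fit_age_model(data[-i, , drop = FALSE], family = family, age = age,
        sites = sites, seed = seed + i, ...),
      error = function(e) {
        abort_field(sprintf("leave-one-out fold %d failed: %s", i, conditionMessage(e)))
      }
    )
    predict(fit, data[i, , drop = FALSE])
  }, numeric(1))
  obs <- data[[age]]
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(data)) data$sample_id else
      sprintf("S%03d", seq_len(n)),
    age = obs,
    predicted = preds,
    residual = preds - obs
  )
  class(out) <- c("prediction_report", class(out))
  attr(out, "mad") <- mad_years(out$age, out$predicted)
  attr(out, "family") <- family
  out
}

#' Exhaustive leave-one-out subset search over CpG sites
#'
#' Evaluates the leave-one-out MAD of every subset of the candidate sites
#' at each requested subset size and records, per size, the minimal MAD
#' and its arg-min subset. This is the brute-force search used to find the
#' smallest site panel that predicts age as well as the full panel. Ties
#' in minimal MAD are broken by the lexicographically smallest site-id
#' tuple. The number of candidate sites is guarded (default 20) against
#' combinatorial blow-up; pass `allow_large = TRUE` to override.
#'
#' @inheritParams loo_cv
#' @param sizes Integer vector of subset sizes to evaluate (default
#'   `1:p`).
#' @param allow_large Override the `p <= 20` guard.
#' @param progress Emit a message per subset size.
#' @return An object of class `"subset_search"` with elements `by_size`
#'   (tibble: `size`, `mad`, `sites` list-column) and `table` (tibble of
#'   every evaluated subset: `size`, `sites`, `label`, `mad`), plus the
#'   family and hyperparameters used.
#' @export
exhaustive_subset_search <- function(data, family = c("linear", "quadratic", "bpnn", "svr"),
                                     age = "age", sites = NULL, sizes = NULL,
                                     allow_large = FALSE, progress = FALSE,
                                     seed = 1, ...) {
  family <- match.arg(family)
  check_columns(data, age, "model table")
  if (is.null(sites)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    sites <- setdiff(numeric_cols, age)
  }
  sites <- sort(sites)
  p <- length(sites)
  if (p == 0) abort_field("no candidate sites.", "sites")
  if (p > 20 && !allow_large) {
    abort_field(sprintf(
      "%d candidate sites would require %d subset evaluations; pass allow_large = TRUE to proceed.",
      p, sum(choose(p, seq_len(p)))
    ), "sites")
  }
  sizes <- sizes %||% seq_len(p)
  if (any(sizes < 1 | sizes > p)) {
    abort_field(sprintf("`sizes` must lie in 1..%d.", p), "sizes")
  }
  sizes <- sort(unique(as.integer(sizes)))

  rows <- list()
  for (k in sizes) {
    combos <- combn(sites, k, simplify = FALSE) # lexicographic given sorted sites
    mads <- vapply(combos, function(subset) {
      attr(loo_cv(data, family = family, age = age, sites = subset,
        seed = seed, ...), "mad")
    }, numeric(1))
    rows[[as.character(k)]] <- tibble::tibble(
      size = k, sites = combos,
      label = vapply(combos, paste, character(1), collapse = "+"),
      mad = mads
    )
    if (progress) {
      inform(sprintf("subset search: size %d done (%d subsets, min MAD %.3f).",
                     k, length(combos), min(mads)))
    }
  }
  table <- dplyr::bind_rows(rows)
  by_size <- dplyr::bind_rows(lapply(split(table, table$size), function(tt) {
    i <- which.min(tt$mad) # first minimum = lexicographically smallest subset
    tibble::tibble(size = tt$size[1], mad = tt$mad[i],
                   sites = tt$sites[i], label = tt$label[i])
  }))
  by_size <- dplyr::arrange(by_size, .data$size)
  structure(
    list(by_size = by_size, table = table, family = family,
         candidates = sites, hyperparameters = list(...)),
    class = "subset_search"
  )
}

#' @export
print.subset_search <- function(x, ...) {
  best <- x$by_size[which.min(x$by_size$mad), ]
  cat(sprintf(
    "<subset_search: %s> %d subsets over %d sites; global min LOO MAD %.3f years at k = %d (%s)\n",
    x$family, nrow(x$table), length(x$candidates), best$mad, best$size, best$label
  ))
  invisible(x)
}

#' Choose the final site panel from a subset search
#'
#' Formalises the accuracy-versus-panel-size balance: among subset sizes
#' whose minimal LOO MAD is within `tolerance` years of the global
#' minimum over all sizes, the smallest size wins; its arg-min subset is
#' the final panel. With `tolerance = 0` this returns the global
#' minimiser itself (smallest such size).
#'
#' @param result A [exhaustive_subset_search()] result.
#' @param tolerance Years of MAD allowed above the global minimum
#'   (default 0.05).
#' @return A one-row tibble: `size`, `mad`, `sites` (list-column),
#'   `label`.
#' @export
choose_final_subset <- function(result, tolerance = 0.05) {
  stopifnot(inherits(result, "subset_search"))
  check_number(tolerance, "tolerance", min = 0)
  bs <- result$by_size
  if (nrow(bs) == 0) abort_field("empty subset-search result.")
  global_min <- min(bs$mad)
  ok <- bs[bs$mad <= global_min + tolerance, ]
  ok[which.min(ok$size), c("size", "mad", "sites", "label")]
}

#' Training-fit versus leave-one-out comparison
#'
#' The over-fitting diagnostic at the heart of panel selection: a model
#' family's in-sample (training) MAD is compared with its leave-one-out
#' MAD on the same table. A large gap means the apparent accuracy of the
#' refit panel does not generalise.
#'
#' @inheritParams loo_cv
#' @return A one-row tibble: `family`, `n`, `p`, `train_mad`, `loo_mad`.
#' @export
compare_fit_loo <- function(data, family = c("linear", "quadratic", "bpnn", "svr"),
                            age = "age", sites = NULL, seed = 1, ...) {
  family <- match.arg(family)
  fit <- fit_age_model(data, family = family, age = age, sites = sites,
    seed = seed, ...)
  loo <- loo_cv(data, family = family, age = age, sites = fit$sites,
    seed = seed, ...)
  tibble::tibble(
    family = family, n = fit$n, p = length(fit$sites),
    train_mad = fit$train_mad, loo_mad = attr(loo, "mad")
  )
}
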