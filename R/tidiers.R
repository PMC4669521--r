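# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy a fitted age model
#'
#' @param x A fitted `age_model`.
#' @param ... Unused.
#' @return A tibble; its shape depends on the family. Linear and quadratic
#'   models give one row per term (`term`, `estimate`); the SVR gives one
#'   row per training sample (`sample`, `dual_coefficient`, `support`);
#'   the BPNN gives one row per weight (`layer`, `from`, `to`, `weight`).
#' @method tidy age_model
#' @export
tidy.age_model <- function(x, ...) {
  switch(x$family,
    linear = tibble::tibble(
      term = c("(Intercept)", names(x$coefficients)),
      estimate = c(x$intercept, unname(x$coefficients))
    ),
    quadratic = tibble::tibble(
      term = c("(Intercept)", names(x$coefficients), names(x$sq_coefficients)),
      estimate = c(x$intercept, unname(x$coefficients), unname(x$sq_coefficients))
    ),
    svr = tibble::tibble(
      sample = seq_along(x$dual_coefficients),
      dual_coefficient = x$dual_coefficients,
      support = seq_along(x$dual_coefficients) %in% x$support_indices
    ),
    bpnn = {
      w1 <- x$w1
      tibble::tibble(
        layer = c(
          rep("hidden", length(w1) + length(x$b1)),
          rep("output", length(x$w2) + 1)
        ),
        from = c(
          rep(colnames(w1) %||% x$sites, each = nrow(w1)),
          rep("(bias)", length(x$b1)),
          paste0("h", seq_along(x$w2)), "(bias)"
        ),
        to = c(
          paste0("h", rep(seq_len(nrow(w1)), ncol(w1))),
          paste0("h", seq_along(x$b1)),
          rep("age", length(x$w2) + 1)
        ),
        weight = c(as.vector(w1), x$b1, x$w2, x$b2)
      )
    }
  )
}

#' Glance at a fitted age model
#'
#' @param x A fitted `age_model`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `n`, `p`, `train_mad`, plus
#'   family-specific columns (SVR: `n_support`, `bias`, `objective`,
#'   `total_slack`, `cost`, `gamma`, `epsilon`; BPNN: `epochs_run`,
#'   `final_loss`, `hidden`).
#' @method glance age_model
#' @export
glance.age_model <- function(x, ...) {
  base <- tibble::tibble(
    family = x$family, n = x$n, p = length(x$sites), train_mad = x$train_mad
  )
  extra <- switch(x$family,
    svr = tibble::tibble(
      n_support = length(x$support_indices), bias = x$bias,
      objective = x$objective, total_slack = x$total_slack,
      cost = x$cost, gamma = x$gamma, epsilon = x$epsilon
    ),
    bpnn = tibble::tibble(
      epochs_run = x$epochs_run,
      final_loss = x$loss_curve[length(x$loss_curve)],
      hidden = x$hidden
    ),
    NULL
  )
  if (is.null(extra)) base else dplyr::bind_cols(base, extra)
}

#' Augment a model table with predictions
#'
#' @param x A fitted `age_model`.
#' @param data Wide model table.
#' @param ... Unused.
#' @return `data` with `.pred` (and `.resid` when the age column is
#'   present) appended.
#' @method augment age_model
#' @export
augment.age_model <- function(x, data, ...) {
  out <- tibble::as_tibble(data)
  out$.pred <- predict(x, data)
  if (x$age_col %in% names(data)) out$.resid <- out$.pred - data[[x$age_col]]
  out
}

#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"), estimate = c(x$intercept, x$slope)
  )
}

#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r2_fit = x$r2_fit, n = x$n)
}

#' @method tidy subset_search
#' @export
tidy.subset_search <- function(x, ...) x$by_size

#' @method glance subset_search
#' @export
glance.subset_search <- function(x, ...) {
  best <- x$by_size[which.min(x$by_size$mad), ]
  tibble::tibble(
    family = x$family, n_candidates = length(x$candidates),
    n_subsets = nrow(x$table), best_size = best$size, best_mad = best$mad,
    best_label = best$label
  )
}

#' @method glance prediction_report
#' @export
glance.prediction_report <- function(x, ...) {
  tibble::tibble(family = attr(x, "family") %||% NA_character_,
                 n = nrow(x), mad = attr(x, "mad"))
}
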