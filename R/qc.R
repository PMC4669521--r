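#' Fit a linear calibration from methylation standards
#'
#' Regresses the known methylation fraction of a standard series on its
#' measured value, `known = slope * measured + intercept` (ordinary least
#' squares), giving the correction line applied to cohort measurements.
#' With standards measured noiselessly through a linear platform
#' distortion this recovers the distortion's correction exactly.
#'
#' @param standards Tibble with columns `known` and `measured` (>= 2 rows,
#'   measured values not all equal).
#' @return An object of class `"calibration_model"` with fields `slope`,
#'   `intercept`, `r2_fit`, `n`, and the fitting data.
#' @examples
#' s <- simulate_standards(platform_distortion(2.285, -1.2176))
#' fit_calibration(s)
#' @export
fit_calibration <- function(standards) {
  check_columns(standards, c("known", "measured"), "standards")
  ok <- is.finite(standards$known) & is.finite(standards$measured)
  if (sum(ok) < 2) abort_field("need at least 2 complete standard levels.")
  x <- standards$measured[ok]
  y <- standards$known[ok]
  if (max(x) - min(x) == 0) {
    abort_field("measured standard values are constant; no calibration line exists.")
  }
  fit <- lm(y ~ x)
  r2 <- if (var(y) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r2_fit = r2, n = sum(ok),
      data = tibble::tibble(known = y, measured = x)
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> corrected = %.4f * measured %+.4f  (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r2_fit, x$n
  ))
  invisible(x)
}

#' Apply a calibration line to measured methylation values
#'
#' Maps measured values to corrected fractions,
#' `corrected = slope * measured + intercept`, then clips to \[0, 1\]
#' (beta values are fractions by definition; the correction line can map
#' extreme measurements slightly outside the unit interval). The number of
#' clipped values is reported in attribute `"n_clipped"` and via a
#' message. Missing cells stay missing.
#'
#' @param data Long beta table on the measured scale.
#' @param model A [fit_calibration()] result.
#' @param quiet Suppress the clipping message.
#' @return The tibble with `beta` replaced by corrected values.
#' @export
apply_calibration <- function(data, model, quiet = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  check_columns(data, c("site_id", "sample_id", "beta"), "beta table")
  raw <- model$slope * data$beta + model$intercept
  n_clipped <- sum(!is.na(raw) & (raw < 0 | raw > 1))
  if (n_clipped > 0 && !quiet) {
    inform(sprintf("apply_calibration: %d corrected value(s) clipped to [0, 1].", n_clipped))
  }
  data$beta <- clip01(raw)
  attr(data, "n_clipped") <- n_clipped
  data
}

#' Mask low-confidence methylation calls
#'
#' EpiTYPER assigns each methylation call a confidence score from 0 (low)
#' to 5 (high); calls are accepted only when the score is strictly above
#' the cutoff. Rejected calls become missing. The acceptance fraction
#' (accepted / scored calls) is attached as attribute
#' `"acceptance_fraction"`.
#'
#' @param data Long beta table with a `confidence` column.
#' @param confidence_min Acceptance cutoff (default 1.9).
#' @param quiet Suppress the acceptance message.
#' @return The filtered tibble.
#' @export
filter_confidence <- function(data, confidence_min = 1.9, quiet = FALSE) {
  check_columns(data, c("site_id", "sample_id", "beta"), "beta table")
  if (!"confidence" %in% names(data)) {
    abort_field("`data` has no `confidence` layer.", "confidence")
  }
  check_number(confidence_min, "confidence_min", min = 0)
  scored <- !is.na(data$beta) & !is.na(data$confidence)
  accepted <- scored & data$confidence > confidence_min
  frac <- if (sum(scored) > 0) sum(accepted) / sum(scored) else NA_real_
  data$beta[scored & !accepted] <- NA_real_
  if (!quiet) {
    inform(sprintf("filter_confidence: %.1f%% of calls accepted (confidence > %g).",
                   100 * frac, confidence_min))
  }
  attr(data, "acceptance_fraction") <- frac
  data
}

#' Drop sites and samples with excessive missingness
#'
#' Removes sites whose fraction of missing values is strictly greater than
#' `site_max`, then samples whose missing fraction *on the site-reduced
#' table* is strictly greater than `sample_max`. Sites are filtered first
#' because site-level artefacts (failed amplicons) should not drive sample
#' exclusion. The exclusions (ids and fractions) are attached as
#' attributes `"excluded_sites"` and `"excluded_samples"` and available
#' via [qc_exclusions()].
#'
#' @param data Long beta table.
#' @param site_max,sample_max Missing-fraction thresholds in (0, 1),
#'   default 0.70 for both.
#' @param quiet Suppress the exclusion message.
#' @return The reduced tibble.
#' @export
filter_missingness <- function(data, site_max = 0.70, sample_max = 0.70,
                               quiet = FALSE) {
  check_columns(data, c("site_id", "sample_id", "beta"), "beta table")
  check_number(site_max, "site_max", min = 0, max = 1, strict_min = TRUE, strict_max = TRUE)
  check_number(sample_max, "sample_max", min = 0, max = 1, strict_min = TRUE, strict_max = TRUE)

  site_frac <- dplyr::summarise(
    dplyr::group_by(data, .data$site_id),
    missing_frac = mean(is.na(.data$beta)), .groups = "drop"
  )
  excl_sites <- dplyr::filter(site_frac, .data$missing_frac > site_max)
  kept <- dplyr::filter(data, !(.data$site_id %in% excl_sites$site_id))

  sample_frac <- dplyr::summarise(
    dplyr::group_by(kept, .data$sample_id),
    missing_frac = mean(is.na(.data$beta)), .groups = "drop"
  )
  excl_samples <- dplyr::filter(sample_frac, .data$missing_frac > sample_max)
  kept <- dplyr::filter(kept, !(.data$sample_id %in% excl_samples$sample_id))

  if (nrow(kept) == 0) {
    abort_field("missingness filtering excluded every site or sample.")
  }
  if (!quiet && (nrow(excl_sites) > 0 || nrow(excl_samples) > 0)) {
    inform(sprintf(
      "filter_missingness: excluded %d site(s) [%s] and %d sample(s) [%s] (> %g missing).",
      nrow(excl_sites), paste(excl_sites$site_id, collapse = ", "),
      nrow(excl_samples), paste(excl_samples$sample_id, collapse = ", "),
      site_max
    ))
  }
  attr(kept, "excluded_sites") <- excl_sites
  attr(kept, "excluded_samples") <- excl_samples
  kept
}

#' @rdname filter_missingness
#' @param x A tibble returned by [filter_missingness()].
#' @export
qc_exclusions <- function(x) {
  list(
    sites = attr(x, "excluded_sites") %||%
      tibble::tibble(site_id = character(), missing_frac = numeric()),
    samples = attr(x, "excluded_samples") %||%
      tibble::tibble(sample_id = character(), missing_frac = numeric())
  )
}

#' Select age-associated sites by absolute Pearson correlation
#'
#' Validation-stage site selection: per-site Pearson correlation between
#' methylation and age on pairwise-complete observations (no imputation at
#' this stage), keeping sites with `|R|` strictly greater than
#' `abs_r_min`. Sites with fewer than 3 observations are excluded with a
#' warning rather than an error.
#'
#' @param data Long beta table.
#' @param metadata Metadata with `sample_id` and `age`.
#' @param abs_r_min Selection threshold on `|R|` (default 0.5).
#' @return A tibble of selected sites: `site_id`, `R`, `p`, `n_used`.
#' @export
select_by_abs_r <- function(data, metadata, abs_r_min = 0.5) {
  check_columns(metadata, c("sample_id", "age"), "metadata")
  check_number(abs_r_min, "abs_r_min", min = 0, max = 1, strict_max = TRUE)
  x <- beta_matrix(data)
  age <- metadata$age[match(colnames(x), metadata$sample_id)]
  if (anyNA(age)) {
    abort_field("some samples in `data` are absent from `metadata`.")
  }
  rows <- lapply(seq_len(nrow(x)), function(i) {
    ok <- !is.na(x[i, ])
    if (sum(ok) < 3) {
      warn(sprintf("site %s has fewer than 3 observations; excluded.", rownames(x)[i]))
      return(NULL)
    }
    rec <- site_association(x[i, ok], age[ok])
    tibble::tibble(site_id = rownames(x)[i], R = rec$R, p = rec$p, n_used = rec$n_used)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(tibble::tibble(site_id = character(), R = numeric(),
                                            p = numeric(), n_used = integer()))
  dplyr::filter(out, abs(.data$R) > abs_r_min)
}
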