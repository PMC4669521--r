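#' Mask beta values with poor detection p-values
#'
#' Array methylation calls come with a per-value detection p-value; calls
#' whose detection p-value exceeds the threshold are unreliable and are set
#' to missing before imputation. The comparison is strict: a value with
#' detection p exactly equal to the threshold is kept.
#'
#' @param data Long beta table with a `detection_p` column.
#' @param detection_p_max Threshold (default 0.01).
#' @return The input tibble with sub-threshold-quality `beta` set to `NA`.
#' @export
mask_low_detection <- function(data, detection_p_max = 0.01) {
  check_columns(data, c("site_id", "sample_id", "beta"), "beta table")
  if (!"detection_p" %in% names(data)) {
    abort_field("`data` has no `detection_p` layer; nothing to mask on.", "detection_p")
  }
  check_number(detection_p_max, "detection_p_max", min = 0, max = 1,
    strict_min = TRUE, strict_max = TRUE)
  data$beta[!is.na(data$detection_p) & data$detection_p > detection_p_max] <- NA_real_
  data
}

#' Impute missing beta values from the k nearest sites
#'
#' Each missing cell (site i, sample s) is replaced by the mean of sample
#' s's observed values at the k sites nearest to site i. Nearness is the
#' Euclidean distance between site rows over their mutually observed
#' samples, rescaled by the square root of the observed fraction
#' (`d = sqrt(ssd * n_samples / n_mutual)`) so distances computed on few
#' shared samples are comparable to fully observed ones. Candidate
#' neighbours missing in sample s are skipped; distance ties are broken by
#' site order in the table. Observed values are never altered. A site with
#' no eligible neighbour falls back to its own observed row mean.
#'
#' @param data Long beta table.
#' @param k Number of nearest sites (default 10, the usual choice for
#'   array imputation); must be smaller than the number of sites.
#' @return The completed tibble (no `NA` betas).
#' @export
impute_knn <- function(data, k = 10) {
  check_columns(data, c("site_id", "sample_id", "beta"), "beta table")
  k <- check_count(k, "k", min = 1)
  x <- beta_matrix(data)
  n_sites <- nrow(x)
  n_samples <- ncol(x)
  if (k >= n_sites) abort_field("`k` must be smaller than the number of sites.", "k")

  obs <- !is.na(x)
  dead <- rownames(x)[rowSums(obs) == 0]
  if (length(dead) > 0) {
    abort_field(sprintf(
      "site(s) with no observed values cannot be imputed: %s.",
      paste(dead, collapse = ", ")
    ))
  }
  if (all(obs)) return(data)

  xz <- x
  xz[!obs] <- 0
  o <- obs * 1
  xsq <- xz^2

  targets <- which(rowSums(!obs) > 0)
  for (i in targets) {
    oi <- o[i, ]
    xi <- xz[i, ]
    mutual <- drop(o %*% oi)
    ssd <- drop(xsq %*% oi) - 2 * drop(xz %*% (oi * xi)) + drop(o %*% (oi * xi^2))
    d <- sqrt(pmax(ssd, 0) * n_samples / pmax(mutual, 1))
    d[mutual == 0] <- Inf
    d[i] <- Inf
    ord <- order(d) # stable: ties broken by site order
    ord <- ord[is.finite(d[ord])]
    for (s in which(!obs[i, ])) {
      nb <- ord[obs[ord, s]]
      nb <- nb[seq_len(min(k, length(nb)))]
      x[i, s] <- if (length(nb) > 0) mean(x[nb, s]) else mean(xi[oi == 1])
    }
  }
  out <- data
  key <- match(paste(data$site_id, data$sample_id),
               paste(rep(rownames(x), ncol(x)), rep(colnames(x), each = nrow(x))))
  out$beta <- as.vector(x)[key]
  out
}

#' Per-site linear regression of methylation on age
#'
#' Ordinary least squares of a site's beta values on chronological age,
#' with the Pearson correlation R, the t statistic
#' `t = R * sqrt((n - 2) / (1 - R^2))`, and the two-sided p-value on
#' `n - 2` degrees of freedom. A perfectly linear site underflows to
#' `p = 0`; a zero-variance site (in beta or age) is returned as
#' `R = 0, p = 1, slope = 0` and flagged `degenerate` so record tables
#' stay complete and filterable.
#'
#' @param beta Numeric vector of beta values for one site.
#' @param age Numeric vector of ages (years), same length.
#' @return A one-row tibble: `slope`, `intercept`, `R`, `R2`, `t`, `p`,
#'   `n_used`, `degenerate`.
#' @examples
#' site_association(c(0.12, 0.13, 0.14, 0.16), c(20, 30, 40, 60))
#' @export
site_association <- function(beta, age) {
  stopifnot(length(beta) == length(age))
  ok <- is.finite(beta) & is.finite(age)
  n <- sum(ok)
  if (n < 3) abort_field("site regression needs at least 3 paired observations.")
  b <- beta[ok]
  a <- age[ok]
  sa <- sum((a - mean(a))^2)
  sb <- sum((b - mean(b))^2)
  if (sa == 0 || sb == 0) {
    return(tibble::tibble(
      slope = 0, intercept = mean(b), R = 0, R2 = 0, t = 0, p = 1,
      n_used = n, degenerate = TRUE
    ))
  }
  sab <- sum((a - mean(a)) * (b - mean(b)))
  slope <- sab / sa
  r <- sab / sqrt(sa * sb)
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 0))
  p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2)
  tibble::tibble(
    slope = slope, intercept = mean(b) - slope * mean(a), R = r, R2 = r^2,
    t = tstat, p = p, n_used = n, degenerate = FALSE
  )
}

#' Genome-scale association scan of beta values against age
#'
#' Runs the discovery-stage scan: optionally mask on detection p-values,
#' impute remaining missing values by [impute_knn()], then regress every
#' site's beta on age (vectorised closed-form OLS identical to
#' [site_association()]) and attach Benjamini-Hochberg FDR-adjusted
#' q-values.
#'
#' @param data Long beta table (with optional `detection_p` layer).
#' @param metadata Cohort metadata with `sample_id` and `age`; matched to
#'   the beta table by id, never by position.
#' @param detection_p_max Detection-p threshold; `NULL` skips masking.
#' @param knn_k Neighbour count for imputation (default 10).
#' @param impute Impute missing values before regression (default TRUE).
#' @return A tibble of association records, one row per site: `site_id`,
#'   `slope`, `intercept`, `R`, `R2`, `t`, `p`, `q`, `n_used`,
#'   `degenerate`.
#' @export
scan_associations <- function(data, metadata, detection_p_max = 0.01,
                              knn_k = 10, impute = TRUE) {
  check_columns(metadata, c("sample_id", "age"), "metadata")
  if (!is.null(detection_p_max) && "detection_p" %in% names(data)) {
    data <- mask_low_detection(data, detection_p_max)
  }
  if (impute && anyNA(data$beta)) data <- impute_knn(data, k = knn_k)
  x <- beta_matrix(data)
  missing_meta <- setdiff(colnames(x), metadata$sample_id)
  if (length(missing_meta) > 0) {
    abort_field(sprintf(
      "samples absent from metadata: %s.", paste(missing_meta, collapse = ", ")
    ))
  }
  age <- metadata$age[match(colnames(x), metadata$sample_id)]
  n <- length(age)
  if (n < 3) abort_field("the scan needs at least 3 samples.")

  ac <- age - mean(age)
  sa <- sum(ac^2)
  rm_ <- rowMeans(x)
  sab <- drop(x %*% ac)
  sb <- rowSums(x^2) - n * rm_^2
  degenerate <- sb <= .Machine$double.eps * n | sa == 0
  slope <- ifelse(degenerate, 0, sab / sa)
  r <- ifelse(degenerate, 0, sab / sqrt(pmax(sa * sb, .Machine$double.xmin)))
  r <- pmax(-1, pmin(1, r))
  tstat <- ifelse(degenerate, 0, r * sqrt((n - 2) / pmax(1 - r^2, 0)))
  p <- ifelse(degenerate, 1, ifelse(is.infinite(tstat), 0, 2 * pt(-abs(tstat), df = n - 2)))
  tibble::tibble(
    site_id = rownames(x), slope = unname(slope),
    intercept = unname(rm_ - slope * mean(age)),
    R = unname(r), R2 = unname(r^2), t = unname(tstat), p = unname(p),
    q = unname(adjust_bh(p)), n_used = n, degenerate = unname(degenerate)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_{j >= i} p_(j) * m / j`,
#' order-preserving with the input (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @examples
#' adjust_bh(c(0.001, 0.02, 0.03, 0.5))
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort_field("p-values must lie in [0, 1].", "p")
  }
  p.adjust(p, method = "BH")
}

#' Select age-associated sites by the loose and strict criteria
#'
#' Applies the two discovery-stage selection rules to a record table:
#' the *loose* rule `p < p_max & R2 > r2_min` (nominal significance plus
#' effect size) and the *strict* rule `q < fdr_max` (FDR control). All
#' comparisons are strict inequalities; records at the boundary are
#' excluded. Each selected record is labelled with its rule and the sign
#' of its slope.
#'
#' @param records Association record tibble from [scan_associations()].
#' @param p_max,r2_min,fdr_max Thresholds (defaults 0.01, 0.5, 0.01).
#' @return A tibble of selected records with added columns `rule`
#'   (`"loose"`/`"strict"`; a site passing both appears twice) and
#'   `direction` (`"positive"`/`"negative"`), sorted by rule then site id.
#' @export
select_sites <- function(records, p_max = 0.01, r2_min = 0.5, fdr_max = 0.01) {
  check_columns(records, c("site_id", "slope", "R2", "p", "q"), "records")
  for (thr in c(p_max = p_max, r2_min = r2_min, fdr_max = fdr_max)) {
    check_number(thr, "threshold", min = 0, max = 1, strict_min = TRUE, strict_max = TRUE)
  }
  loose <- dplyr::filter(records, .data$p < p_max, .data$R2 > r2_min)
  strict <- dplyr::filter(records, .data$q < fdr_max)
  out <- dplyr::bind_rows(loose = loose, strict = strict, .id = "rule")
  out$direction <- ifelse(out$slope > 0, "positive", "negative")
  dplyr::arrange(out, .data$rule, .data$site_id)
}

#' CpG-island enrichment of a selected site set
#'
#' Tests whether selected sites fall in CpG islands more often than the
#' remaining sites of the scanned universe, by a two-sided Fisher exact
#' test on the 2x2 table with rows (selected, universe \ selected) and
#' columns (island, non-island).
#'
#' @param selected Character vector of selected site ids (or a tibble with
#'   a `site_id` column). Must be non-empty and fully annotated.
#' @param annotation Tibble with `site_id` and logical `in_island`,
#'   defining the scan universe (a superset of `selected`).
#' @return A one-row tibble: counts of the 2x2 table, island proportions,
#'   `odds_ratio`, `p_value`; the table itself is in attribute
#'   `"contingency"`.
#' @export
test_island_enrichment <- function(selected, annotation) {
  if (is.data.frame(selected)) selected <- selected$site_id
  selected <- unique(selected)
  if (length(selected) == 0) abort_field("`selected` is empty; nothing to test.")
  check_columns(annotation, c("site_id", "in_island"), "annotation")
  unk <- setdiff(selected, annotation$site_id)
  if (length(unk) > 0) {
    abort_field(sprintf(
      "selected site(s) missing from the annotation: %s.",
      paste(head(unk, 5), collapse = ", ")
    ))
  }
  is_sel <- annotation$site_id %in% selected
  tab <- matrix(
    c(
      sum(is_sel & annotation$in_island), sum(is_sel & !annotation$in_island),
      sum(!is_sel & annotation$in_island), sum(!is_sel & !annotation$in_island)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("selected", "rest"), c("island", "non_island"))
  )
  ft <- fisher.test(tab, alternative = "two.sided")
  out <- tibble::tibble(
    n_selected_island = tab[1, 1], n_selected_non = tab[1, 2],
    n_rest_island = tab[2, 1], n_rest_non = tab[2, 2],
    prop_selected_island = tab[1, 1] / sum(tab[1, ]),
    prop_universe_island = sum(tab[, 1]) / sum(tab),
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
  attr(out, "contingency") <- tab
  out
}
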