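#' Convert between long beta tables and site-by-sample matrices
#'
#' The package's working representation of a methylation experiment is a
#' *long* tibble with one row per (site, sample) cell: columns `site_id`,
#' `sample_id`, `beta` (methylated fraction in \[0, 1\], `NA` when the cell
#' is missing) and, optionally, a same-shape auxiliary layer such as
#' `detection_p` (BeadChip detection p-values) or `confidence` (EpiTYPER
#' per-value confidence scores). The table is a complete site-by-sample
#' grid so missingness fractions are well defined. `beta_matrix()` pivots a
#' long table to the conventional sites-in-rows numeric matrix;
#' `as_beta_tbl()` is its inverse.
#'
#' @param data A long beta table (see Details).
#' @param value Name of the column to place in the matrix cells
#'   (default `"beta"`).
#' @param x A numeric matrix with site ids as row names and sample ids as
#'   column names.
#' @return `beta_matrix()` a numeric matrix (sites x samples);
#'   `as_beta_tbl()` a long tibble with columns `site_id`, `sample_id`,
#'   `beta`.
#' @examples
#' m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2,
#'   dimnames = list(c("cg01", "cg02"), c("S1", "S2"))
#' )
#' as_beta_tbl(m)
#' beta_matrix(as_beta_tbl(m))
#' @export
beta_matrix <- function(data, value = "beta") {
  check_columns(data, c("site_id", "sample_id", value), "beta table")
  sites <- unique(data$site_id)
  samples <- unique(data$sample_id)
  grid_ok <- nrow(data) == length(sites) * length(samples) &&
    !anyDuplicated(paste(data$site_id, data$sample_id))
  if (!grid_ok) {
    abort_field("beta table must be a complete site-by-sample grid with no duplicate cells.")
  }
  wide <- tidyr::pivot_wider(
    data[, c("site_id", "sample_id", value)],
    names_from = "sample_id", values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$site_id
  m[, samples, drop = FALSE]
}

#' @rdname beta_matrix
#' @export
as_beta_tbl <- function(x, value = "beta") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  tibble::tibble(
    site_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    !!value := as.vector(x)
  ) |>
    dplyr::arrange(match(.data$site_id, rownames(x)), match(.data$sample_id, colnames(x)))
}

# Validate beta values: in [0,1] or NA. Returns offending cells.
validate_beta_range <- function(data, what = "beta table") {
  bad <- which(!is.na(data$beta) & (data$beta < 0 | data$beta > 1))
  if (length(bad) > 0) {
    first <- bad[1]
    abort_field(sprintf(
      "%s has %d value(s) outside [0, 1]; first offender: site %s, sample %s, value %g.",
      what, length(bad), data$site_id[first], data$sample_id[first], data$beta[first]
    ))
  }
  invisible(data)
}
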