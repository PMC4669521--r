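#' Read and write dense beta-value tables
#'
#' The on-disk format is the dense tab-separated layout used for array
#' methylation matrices (e.g. tables extracted from GEO series): first
#' column `site_id`, one further column per sample, cells holding beta
#' fractions in \[0, 1\]. Missing cells are written as `NA`; on input the
#' tokens `""`, `NA`, `NaN` are accepted case-insensitively. Values are
#' written with shortest round-trip precision, so a write/read cycle is
#' bitwise faithful.
#'
#' @param path File path.
#' @param data Long beta table (see [beta_matrix()]).
#' @return `read_beta_tsv()` returns a long tibble with columns `site_id`,
#'   `sample_id`, `beta`; `write_beta_tsv()` returns `path` invisibly.
#' @export
read_beta_tsv <- function(path) {
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(0)
  )) # structural problems are re-raised below with line context
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort_field(sprintf(
      "parse error in %s at line %d, column %d: expected %s, got '%s'.",
      path, probs$row[1] + 1, probs$col[1], probs$expected[1], probs$actual[1]
    ))
  }
  check_columns(raw, "site_id", sprintf("'%s'", path))
  if (ncol(raw) < 2) abort_field(sprintf("'%s' has no sample columns.", path))
  # parse cells with strtod (correctly rounded, so writes round-trip
  # bitwise); "", "NA", "NaN" in any case are missing tokens
  for (j in seq(2, ncol(raw))) {
    cell <- trimws(raw[[j]])
    is_na <- is.na(cell) | tolower(cell) %in% c("", "na", "nan")
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & is.na(parsed))
    if (length(bad) > 0) {
      abort_field(sprintf(
        "parse error in %s at line %d, column %d: '%s' is not a number.",
        path, bad[1] + 1, j, cell[bad[1]]
      ))
    }
    parsed[is_na] <- NA_real_
    raw[[j]] <- parsed
  }
  if (anyDuplicated(raw$site_id)) {
    dup <- raw$site_id[duplicated(raw$site_id)][1]
    abort_field(sprintf("duplicate site id '%s' in %s.", dup, path))
  }
  if (anyDuplicated(names(raw))) {
    dup <- names(raw)[duplicated(names(raw))][1]
    abort_field(sprintf("duplicate sample id '%s' in %s.", dup, path))
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw$site_id
  out <- as_beta_tbl(m)
  validate_beta_range(out, sprintf("'%s'", path))
  out
}

#' @rdname read_beta_tsv
#' @export
write_beta_tsv <- function(data, path) {
  validate_beta_range(data)
  m <- beta_matrix(data)
  wide <- tibble::as_tibble(m, rownames = "site_id")
  # serialise doubles at full precision so a write/read cycle is bitwise exact
  wide[-1] <- lapply(wide[-1], function(col) {
    ifelse(is.na(col), NA_character_, sprintf("%.17g", col))
  })
  readr::write_tsv(wide, path, na = "NA")
  invisible(path)
}

#' Read EpiTYPER-style long-format methylation calls
#'
#' Mass-spectrometric methylation quantification (Sequenom EpiTYPER)
#' reports one row per (sample, site) call with a methylated fraction and
#' a per-value confidence score (0 = lowest to 5 = highest). This reader
#' expects a CSV with columns `sample_id`, `site_id`,
#' `methylation_fraction`, `confidence` and pivots it into the package's
#' complete-grid long beta table, carrying `confidence` as the auxiliary
#' layer. Cells absent from the file become missing.
#'
#' @param path CSV file path.
#' @return A long tibble with columns `site_id`, `sample_id`, `beta`,
#'   `confidence`.
#' @export
read_epityper_long <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), site_id = readr::col_character(),
    .default = readr::col_double()
  ))
  need <- c("sample_id", "site_id", "methylation_fraction", "confidence")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort_field(sprintf(
      "'%s' lacks required column(s): %s.", path,
      paste0("`", missing_cols, "`", collapse = ", ")
    ))
  }
  key <- paste(raw$sample_id, raw$site_id)
  if (anyDuplicated(key)) {
    dup <- strsplit(key[duplicated(key)][1], " ")[[1]]
    abort_field(sprintf(
      "duplicate (sample, site) record (%s, %s) in %s.", dup[1], dup[2], path
    ))
  }
  sites <- unique(raw$site_id)
  samples <- unique(raw$sample_id)
  grid <- tidyr::expand_grid(site_id = sites, sample_id = samples)
  out <- dplyr::left_join(grid, raw, by = c("site_id", "sample_id"))
  out <- dplyr::rename(out, beta = "methylation_fraction")
  validate_beta_range(out, sprintf("'%s'", path))
  tibble::as_tibble(out[, c("site_id", "sample_id", "beta", "confidence")])
}

#' @rdname read_epityper_long
#' @param data Long beta table with a `confidence` column.
#' @export
write_epityper_long <- function(data, path) {
  check_columns(data, c("site_id", "sample_id", "beta", "confidence"),
    "epityper table")
  out <- tibble::tibble(
    sample_id = data$sample_id, site_id = data$site_id,
    methylation_fraction = data$beta, confidence = data$confidence
  )
  out <- out[!is.na(out$methylation_fraction) | !is.na(out$confidence), ]
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Read and write cohort metadata
#'
#' Per-sample metadata: `sample_id` (unique), `age` in years (positive),
#' `sex`, `cohort`, and optional `pair_id` for twin pairs.
#'
#' @param path CSV file path.
#' @param data Metadata tibble.
#' @return `read_metadata_csv()` a tibble; `write_metadata_csv()` `path`,
#'   invisibly.
#' @export
read_metadata_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_double(), .default = readr::col_character()
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort_field(sprintf(
      "parse error in %s at line %d: expected %s, got '%s'.",
      path, probs$row[1] + 1, probs$expected[1], probs$actual[1]
    ))
  }
  check_columns(raw, c("sample_id", "age"), sprintf("'%s'", path))
  if (anyDuplicated(raw$sample_id)) {
    abort_field(sprintf(
      "duplicate sample id '%s' in %s.",
      raw$sample_id[duplicated(raw$sample_id)][1], path
    ))
  }
  if (any(is.na(raw$age)) || any(raw$age <= 0)) {
    bad <- raw$sample_id[which(is.na(raw$age) | raw$age <= 0)[1]]
    abort_field(sprintf("sample '%s' in %s has a non-positive or unparsable age.", bad, path))
  }
  if (!"pair_id" %in% names(raw)) raw$pair_id <- NA_character_
  tibble::as_tibble(raw)
}

#' @rdname read_metadata_csv
#' @export
write_metadata_csv <- function(data, path) {
  check_columns(data, c("sample_id", "age"), "metadata")
  readr::write_csv(data, path, na = "NA")
  invisible(path)
}
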