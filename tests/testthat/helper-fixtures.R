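# Shared fixture builders (all generated in code; no stored data).

# Small complete beta table with explicit values.
fixture_beta_tbl <- function(values, sites = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sites %||% sprintf("cg%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  methage::as_beta_tbl(m)
}

# Missingness pattern mirroring a targeted-platform QC worked example:
# 95 sites x 50 samples; five failed amplicon sites (82/74/74/72/74%
# missing), one failed sample missing 79 of 95 sites (83%).
fixture_qc_missingness <- function() {
  sites <- sprintf("X%02d", 1:95)
  samples <- sprintf("F%02d", 51:100)
  bad_sites <- c(X74 = 41, X75 = 37, X88 = 37, X89 = 36, X90 = 37) # of 50
  bad_sample <- "F91"
  m <- matrix(0.5, 95, 50, dimnames = list(sites, samples))
  # the failed sample misses the 5 failed sites plus 74 of the others
  other_sites <- setdiff(sites, names(bad_sites))
  m[c(names(bad_sites), other_sites[1:74]), bad_sample] <- NA
  for (s in names(bad_sites)) {
    others <- setdiff(samples, bad_sample)
    m[s, others[seq_len(bad_sites[[s]] - 1)]] <- NA # -1: bad sample already NA
  }
  methage::as_beta_tbl(m)
}

# A wide model table with a planted informative feature and noise features.
fixture_informative_table <- function(n = 24, p = 3, seed = 5) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    code
  }
  withr_seed({
    age <- runif(n, 20, 80)
    x1 <- age / 100 + rnorm(n, 0, 0.01)
    noise <- matrix(runif(n * (p - 1), 0, 1), n)
    d <- tibble::tibble(age = age, f1 = x1)
    for (j in seq_len(p - 1)) d[[paste0("f", j + 1)]] <- noise[, j]
    d
  })
}
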