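#' Simulate a study cohort with optional monozygotic twin pairs
#'
#' Generates per-sample metadata emulating the two cohort designs used for
#' methylation-age studies in blood: a discovery panel of monozygotic twin
#' pairs (each pair shares one chronological age) and an unrelated adult
#' validation panel spanning a wide age range. Ages are drawn uniformly on
#' `age_range`; members of a twin pair receive identical ages and a shared
#' `pair_id`.
#'
#' @param n_samples Number of samples (>= 2).
#' @param age_range Length-2 numeric, closed age interval in years
#'   (lower <= upper; a degenerate interval fixes every age).
#' @param twin_pairs Number of twin pairs; `2 * twin_pairs <= n_samples`.
#' @param seed Integer seed; the output is a deterministic function of it.
#' @param sex Sex label applied to all samples (default `"F"`).
#' @param cohort Cohort label (default `"discovery"`).
#' @param id_prefix Prefix for generated sample ids.
#' @return A tibble with columns `sample_id`, `age`, `sex`, `cohort`,
#'   `pair_id` (`NA` for unpaired samples).
#' @examples
#' simulate_cohort(16, c(21, 32), twin_pairs = 8, seed = 1)
#' @export
simulate_cohort <- function(n_samples, age_range = c(20, 80), twin_pairs = 0,
                            seed = 1, sex = "F", cohort = "discovery",
                            id_prefix = "S") {
  n_samples <- check_count(n_samples, "n_samples", min = 2)
  twin_pairs <- check_count(twin_pairs, "twin_pairs", min = 0)
  if (length(age_range) != 2 || !is.numeric(age_range)) {
    abort_field("`age_range` must be a numeric interval of length 2.", "age_range")
  }
  if (age_range[1] > age_range[2]) {
    abort_field("`age_range` lower bound exceeds the upper bound.", "age_range")
  }
  if (age_range[1] <= 0) {
    abort_field("`age_range` must be positive (ages in years).", "age_range")
  }
  if (2 * twin_pairs > n_samples) {
    abort_field("`twin_pairs` requires 2 * twin_pairs <= n_samples.", "twin_pairs")
  }

  with_seed(derive_seed(seed, "cohort"), {
    pair_ages <- runif(twin_pairs, age_range[1], age_range[2])
    single_ages <- runif(n_samples - 2 * twin_pairs, age_range[1], age_range[2])
    ages <- c(rep(pair_ages, each = 2), single_ages)
    pair_id <- c(
      rep(sprintf("P%02d", seq_len(twin_pairs)), each = 2),
      rep(NA_character_, n_samples - 2 * twin_pairs)
    )
    tibble::tibble(
      sample_id = sprintf("%s%03d", id_prefix, seq_len(n_samples)),
      age = ages,
      sex = sex,
      cohort = cohort,
      pair_id = pair_id
    )
  })
}

#' Simulate a methylome with planted age-associated CpG sites
#'
#' Generates a complete site-by-sample beta table in which `n_associated`
#' sites follow a linear age trend on the beta scale,
#' `beta = clip(b0 + s * age + e, 0, 1)` with `e ~ Normal(0, noise_sd)`,
#' and the remaining background sites are flat (`s = 0`). Value-level
#' missingness is independent Bernoulli(`missing_rate`); a matching
#' `detection_p` layer is emitted in which masked cells carry detection
#' p-values above 0.01 and observed cells below it, so detection-p masking
#' reproduces the planted mask. Each site is annotated as lying in a CpG
#' island or not, with a mildly higher island rate among associated sites
#' (emulating the island enrichment seen on 450K arrays).
#'
#' @param cohort Cohort metadata tibble from [simulate_cohort()].
#' @param n_sites,n_associated Total and associated site counts.
#' @param slope_range Interval of slope magnitudes (beta units per year);
#'   each associated site draws a magnitude and a random sign.
#' @param baseline_range Interval within \[0, 1\] from which each site's
#'   baseline level is drawn.
#' @param baseline_age Age (years) at which `baseline_range` applies; the
#'   intercept is `b0 = baseline - s * baseline_age`. The default 0 makes
#'   the baseline the intercept itself.
#' @param noise_sd Gaussian measurement noise on the beta scale (>= 0).
#' @param missing_rate Per-value missingness probability in \[0, 1).
#' @param island_rate Length-2 named or unnamed numeric: island probability
#'   for background and associated sites.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_methylome"` with elements
#'   `betas` (long beta table with `detection_p`), `truth` (per-site tibble:
#'   `site_id`, `associated`, `slope`, `baseline`, `in_island`), and
#'   `annotation` (`site_id`, `in_island`).
#' @examples
#' cohort <- simulate_cohort(8, c(20, 60), seed = 2)
#' sim <- simulate_betas(cohort, n_sites = 50, n_associated = 5, seed = 2)
#' head(sim$betas)
#' @export
simulate_betas <- function(cohort, n_sites = 10000, n_associated = 60,
                           slope_range = c(0.005, 0.02),
                           baseline_range = c(0.2, 0.8), baseline_age = 0,
                           noise_sd = 0.02, missing_rate = 0,
                           island_rate = c(0.647, 0.70), seed = 1) {
  check_columns(cohort, c("sample_id", "age"), "cohort metadata")
  if (nrow(cohort) < 1) abort_field("`cohort` must be non-empty.", "cohort")
  n_sites <- check_count(n_sites, "n_sites", min = 1)
  n_associated <- check_count(n_associated, "n_associated", min = 0)
  if (n_associated > n_sites) {
    abort_field("`n_associated` cannot exceed `n_sites`.", "n_associated")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(missing_rate, "missing_rate", min = 0, max = 1, strict_max = TRUE)
  if (any(baseline_range < 0) || any(baseline_range > 1)) {
    abort_field("`baseline_range` must lie within [0, 1].", "baseline_range")
  }

  n <- nrow(cohort)
  site_id <- sprintf("cg%08d", seq_len(n_sites))
  ages <- cohort$age

  truth <- with_seed(derive_seed(seed, "sites"), {
    associated <- c(rep(TRUE, n_associated), rep(FALSE, n_sites - n_associated))
    magnitude <- runif(n_sites, slope_range[1], slope_range[2])
    sign <- sample(c(-1, 1), n_sites, replace = TRUE)
    slope <- ifelse(associated, magnitude * sign, 0)
    baseline <- runif(n_sites, baseline_range[1], baseline_range[2])
    in_island <- runif(n_sites) < ifelse(associated, island_rate[2], island_rate[1])
    tibble::tibble(site_id, associated, slope, baseline, in_island)
  })

  values <- with_seed(derive_seed(seed, "betas"), {
    b0 <- truth$baseline - truth$slope * baseline_age
    mu <- outer(b0, rep(1, n)) + outer(truth$slope, ages)
    eps <- matrix(rnorm(n_sites * n, sd = noise_sd), n_sites, n)
    clip01(mu + eps)
  })
  dimnames(values) <- list(site_id, cohort$sample_id)

  masked <- with_seed(derive_seed(seed, "mask"), {
    matrix(runif(n_sites * n) < missing_rate, n_sites, n)
  })
  detection_p <- with_seed(derive_seed(seed, "detection"), {
    p <- matrix(runif(n_sites * n, 0, 0.01), n_sites, n)
    p[masked] <- runif(sum(masked), 0.0101, 1)
    p
  })
  values[masked] <- NA_real_

  betas <- as_beta_tbl(values)
  betas$detection_p <- as_beta_tbl(`dimnames<-`(detection_p, dimnames(values)),
    value = "detection_p"
  )$detection_p

  structure(
    list(betas = betas, truth = truth,
         annotation = truth[, c("site_id", "in_island")]),
    class = "synthetic_methylome"
  )
}

#' @export
print.synthetic_methylome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_methylome> %d sites x %d samples; %d age-associated; %.1f%% missing\n",
    length(unique(x$betas$site_id)), length(unique(x$betas$sample_id)),
    sum(x$truth$associated), 100 * mean(is.na(x$betas$beta))
  ))
  invisible(x)
}

#' Describe a linear platform distortion with methylation standards
#'
#' Mass-spectrometric methylation calls can be linearly distorted relative
#' to the true methylated fraction; laboratories quantify this with a
#' dilution series of DNA standards of known methylation (0-100% in steps
#' of 10%) and correct by regressing known on measured. This constructor
#' records the *correction* line `true = slope * measured + intercept`;
#' [distort_measurements()] applies its inverse to simulate the platform.
#'
#' @param slope,intercept Correction-line coefficients (`slope != 0`).
#' @param standard_levels Strictly increasing known methylation fractions of
#'   the standard series (>= 2 levels).
#' @param standard_noise_sd Gaussian noise s.d. added on the measured scale.
#' @return A list of class `"platform_distortion"`.
#' @examples
#' platform_distortion(2.285, -1.2176)
#' @export
platform_distortion <- function(slope = 2.285, intercept = -1.2176,
                                standard_levels = seq(0, 1, by = 0.1),
                                standard_noise_sd = 0) {
  if (!is.numeric(slope) || length(slope) != 1 || slope == 0 || !is.finite(slope)) {
    abort_field("`slope` must be a single finite nonzero number.", "slope")
  }
  check_number(intercept, "intercept")
  check_number(standard_noise_sd, "standard_noise_sd", min = 0)
  if (length(standard_levels) < 2 || any(diff(standard_levels) <= 0) ||
      any(standard_levels < 0) || any(standard_levels > 1)) {
    abort_field(
      "`standard_levels` must be >= 2 strictly increasing fractions in [0, 1].",
      "standard_levels"
    )
  }
  structure(
    list(slope = slope, intercept = intercept,
         standard_levels = standard_levels,
         standard_noise_sd = standard_noise_sd),
    class = "platform_distortion"
  )
}

#' Apply a platform distortion to true methylation values
#'
#' Maps true beta values to the *measured* scale by inverting the
#' correction line: `measured = (true - intercept) / slope + noise`.
#' Fitting a calibration on distorted standards and applying it with
#' [apply_calibration()] recovers the true values exactly when
#' `noise_sd = 0`. Measured-scale values are not clipped to \[0, 1\];
#' they live on the instrument's scale until calibrated.
#'
#' @param data Long beta table (column `beta` holds true fractions).
#' @param distortion A [platform_distortion()].
#' @param noise_sd Gaussian noise s.d. on the measured scale (defaults to
#'   the distortion's `standard_noise_sd`).
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @return The input tibble with `beta` replaced by measured values;
#'   missing cells stay missing.
#' @examples
#' d <- platform_distortion(2.285, -1.2176)
#' tbl <- tibble::tibble(site_id = "cg1", sample_id = "S1", beta = 1)
#' distort_measurements(tbl, d)
#' @export
distort_measurements <- function(data, distortion, noise_sd = NULL, seed = 1) {
  stopifnot(inherits(distortion, "platform_distortion"))
  check_columns(data, c("site_id", "sample_id", "beta"), "beta table")
  noise_sd <- noise_sd %||% distortion$standard_noise_sd
  measured <- (data$beta - distortion$intercept) / distortion$slope
  if (noise_sd > 0) {
    measured <- measured + with_seed(
      derive_seed(seed, "distort"),
      rnorm(length(measured), sd = noise_sd)
    )
  }
  data$beta <- ifelse(is.na(data$beta), NA_real_, measured)
  data
}

#' Simulate a measured methylation-standard series
#'
#' Produces the paired (known, measured) series a laboratory would obtain
#' by running the standard dilution series through the distorted platform.
#'
#' @param distortion A [platform_distortion()].
#' @param seed Integer seed for the measurement noise.
#' @return A tibble with columns `known` and `measured`, one row per level.
#' @examples
#' simulate_standards(platform_distortion(2.285, -1.2176))
#' @export
simulate_standards <- function(distortion, seed = 1) {
  stopifnot(inherits(distortion, "platform_distortion"))
  known <- distortion$standard_levels
  measured <- (known - distortion$intercept) / distortion$slope
  if (distortion$standard_noise_sd > 0) {
    measured <- measured + with_seed(
      derive_seed(seed, "standards"),
      rnorm(length(known), sd = distortion$standard_noise_sd)
    )
  }
  tibble::tibble(known = known, measured = measured)
}

#' Simulate an adult validation cohort with a nonlinear age signal
#'
#' Emulates the targeted-validation stage of a methylation clock study: a
#' wide-age-range cohort measured at a small panel of CpG sites whose
#' methylation tracks age along curved trajectories (change accelerating
#' or saturating toward the age extremes), as commonly observed for
#' age-associated CpGs. Each site follows
#' `beta = clip(m50 + s * (age - 50) + q * (age - 50)^2 + noise, 0, 1)`,
#' with the quadratic deflection at the cohort's age extremes comparable
#' in size to the linear span, so the signal is visibly but not wildly
#' nonlinear.
#'
#' @param n_samples Cohort size (default 49).
#' @param n_sites Number of CpG sites in the panel (default 11).
#' @param age_range Age interval in years.
#' @param noise_sd Beta-scale noise s.d.
#' @param curvature Magnitude scale of the quadratic term (beta per year^2).
#' @param seed Integer seed.
#' @return A list with `data` (wide tibble: `sample_id`, `age`, one column
#'   per site), `metadata`, and `betas` (the same values in long form).
#' @export
simulate_validation_cohort <- function(n_samples = 49, n_sites = 11,
                                       age_range = c(20, 80), noise_sd = 0.04,
                                       curvature = 3e-4, seed = 1) {
  cohort <- simulate_cohort(n_samples, age_range,
    twin_pairs = 0, seed = derive_seed(seed, "vcohort"),
    cohort = "validation", id_prefix = "F"
  )
  site_id <- sprintf("X%02d", 20 + seq_len(n_sites))
  pars <- with_seed(derive_seed(seed, "vsites"), {
    tibble::tibble(
      site_id = site_id,
      slope = sample(c(-1, 1), n_sites, TRUE) * runif(n_sites, 0.003, 0.006),
      curv = sample(c(-1, 1), n_sites, TRUE) * runif(n_sites, 0.5, 1.5) * curvature,
      level50 = runif(n_sites, 0.25, 0.75)
    )
  })
  values <- with_seed(derive_seed(seed, "vbetas"), {
    mu <- outer(pars$level50, rep(1, n_samples)) +
      outer(pars$slope, cohort$age - 50) +
      outer(pars$curv, (cohort$age - 50)^2)
    clip01(mu + matrix(rnorm(n_sites * n_samples, sd = noise_sd), n_sites))
  })
  dimnames(values) <- list(site_id, cohort$sample_id)
  betas <- as_beta_tbl(values)
  wide <- dplyr::bind_cols(
    cohort[, c("sample_id", "age")],
    tibble::as_tibble(t(values))
  )
  list(data = wide, metadata = cohort, betas = betas, sites = pars)
}
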