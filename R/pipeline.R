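#' Default configuration for the end-to-end synthetic pipeline
#'
#' Bundles the tunable parameters of every stage, mirroring the design of
#' a two-cohort methylation-clock study: a small twin discovery panel
#' scanned genome-wide, a wide-age validation cohort measured by a
#' calibrated targeted platform, site selection, and exhaustive subset
#' search with a final SVR model. Any element can be overridden through
#' `...` (named sub-lists are merged).
#'
#' @param ... Named overrides, e.g. `discovery = list(n_sites = 500)`.
#' @return A nested list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  base <- list(
    discovery = list(
      n_samples = 16, age_range = c(21, 32), twin_pairs = 8,
      n_sites = 2000, n_associated = 20, slope_range = c(0.012, 0.022),
      baseline_range = c(0.35, 0.65), baseline_age = 26.5,
      noise_sd = 0.02, missing_rate = 0.01
    ),
    scan = list(detection_p_max = 0.01, knn_k = 10, p_max = 0.01,
                r2_min = 0.5, fdr_max = 0.01),
    validation = list(
      n_samples = 50, age_range = c(20, 80), noise_sd = 0.03,
      slope_range = c(0.004, 0.007), level_range = c(0.3, 0.7),
      min_sites = 4, max_sites = 11,
      confidence_mean = 3.25, confidence_sd = 0.82
    ),
    distortion = list(slope = 2.285, intercept = -1.2176,
                      standard_noise_sd = 0.02),
    qc = list(confidence_min = 1.9, site_max = 0.70, sample_max = 0.70,
              abs_r_min = 0.5),
    model = list(family = "svr", cost = 2, gamma = 0.1, epsilon = 0.1),
    search = list(sizes = 1:2, tolerance = 0.05),
    blind = list(n_samples = 10)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- modifyList(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  structure(base, class = "pipeline_config")
}

# Simulate the targeted validation measurements for a panel of sites whose
# slope signs are inherited from the discovery truth. Trajectories are
# anchored at age 50 with gentler slopes than the twin-panel scale (a new
# platform, tissue-wide age range), plus planted high-missingness
# artefacts: one failed sample and one failed amplicon site, realised as
# confidence-0 calls.
simulate_validation_measurements <- function(panel_sites, panel_signs, cfg,
                                             distortion, seed, site_pars = NULL,
                                             plant_artifacts = TRUE) {
  v <- cfg$validation
  cohort <- simulate_cohort(v$n_samples, v$age_range, twin_pairs = 0,
    seed = derive_seed(seed, "valcohort"), cohort = "validation", id_prefix = "F")
  p <- length(panel_sites)
  pars <- site_pars %||% with_seed(derive_seed(seed, "valsites"), tibble::tibble(
    site_id = panel_sites,
    slope = panel_signs * runif(p, v$slope_range[1], v$slope_range[2]),
    level50 = runif(p, v$level_range[1], v$level_range[2])
  ))
  true <- with_seed(derive_seed(seed, "valbetas"), {
    mu <- outer(pars$level50, rep(1, v$n_samples)) + outer(pars$slope, cohort$age - 50)
    clip01(mu + matrix(rnorm(p * v$n_samples, sd = v$noise_sd), p))
  })
  dimnames(true) <- list(panel_sites, cohort$sample_id)
  betas <- as_beta_tbl(true)
  measured <- distort_measurements(betas, distortion, seed = derive_seed(seed, "valdist"))

  conf <- with_seed(derive_seed(seed, "valconf"), {
    matrix(pmin(5, pmax(0, rnorm(p * v$n_samples, v$confidence_mean,
      v$confidence_sd))), p, v$n_samples)
  })
  measured$confidence <- as_beta_tbl(
    `dimnames<-`(conf, dimnames(true)), value = "confidence")$confidence
  # planted detection failures: one failed sample (~83% of sites absent)
  # and one failed amplicon site (~80% of samples absent); these are
  # missing measurements, not low-confidence calls
  if (plant_artifacts) {
    fail <- with_seed(derive_seed(seed, "valfail"), {
      f <- matrix(FALSE, p, v$n_samples)
      f[sample.int(p, ceiling(0.83 * p)), v$n_samples] <- TRUE
      f[p, sample.int(v$n_samples, ceiling(0.80 * v$n_samples))] <- TRUE
      f
    })
    fail_long <- as_beta_tbl(`dimnames<-`(fail * 1, dimnames(true)),
      value = "fail")$fail > 0
    measured$beta[fail_long] <- NA_real_
    measured$confidence[fail_long] <- NA_real_
  }
  list(measured = measured, metadata = cohort, site_pars = pars)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the whole study shape end to end on synthetic data and writes
#' every stage output plus a provenance manifest into `out_dir`:
#'
#' 1. **simulate** - twin discovery cohort and methylome with planted
#'    age-associated sites; methylation standards through a distorted
#'    platform.
#' 2. **scan** - detection-p masking, KNN imputation, per-site regression,
#'    loose/strict selection, island enrichment.
#' 3. **qc** - validation-cohort measurement of the strict panel,
#'    confidence filter, missingness filter, calibration, |R| selection.
#' 4. **select** - exhaustive leave-one-out subset search over the
#'    selected panel.
#' 5. **train** - final model on the chosen panel, with the training-fit
#'    versus leave-one-out over-fitting report.
#' 6. **predict** - blind-cohort prediction with the final model.
#'
#' Deterministic given `seed`; re-running with the same config and seed
#' reproduces every output byte-for-byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (mandatory).
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir, seed, config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(seed) || is.null(seed)) {
    abort_field("`seed` is mandatory: the pipeline has stochastic stages.", "seed")
  }
  seed <- check_count(seed, "seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
        class = "methage_pipeline_error")
    })
  }
  paths <- character(0)
  keep <- function(p) { paths[[length(paths) + 1]] <<- p; p }

  # -- stage 1: simulate ------------------------------------------------------
  d <- config$discovery
  sim <- run_stage("simulate", {
    cohort <- simulate_cohort(d$n_samples, d$age_range, d$twin_pairs,
      seed = derive_seed(seed, "disc"))
    meth <- simulate_betas(cohort,
      n_sites = d$n_sites, n_associated = d$n_associated,
      slope_range = d$slope_range, baseline_range = d$baseline_range,
      baseline_age = d$baseline_age, noise_sd = d$noise_sd,
      missing_rate = d$missing_rate, seed = derive_seed(seed, "meth"))
    distortion <- platform_distortion(config$distortion$slope,
      config$distortion$intercept,
      standard_noise_sd = config$distortion$standard_noise_sd)
    standards <- simulate_standards(distortion, seed = derive_seed(seed, "std"))
    write_metadata_csv(cohort, keep(file.path(out_dir, "discovery_metadata.csv")))
    write_beta_tsv(meth$betas, keep(file.path(out_dir, "discovery_betas.tsv")))
    readr::write_tsv(meth$truth, keep(file.path(out_dir, "discovery_truth.tsv")))
    readr::write_csv(standards, keep(file.path(out_dir, "standards.csv")))
    list(cohort = cohort, meth = meth, distortion = distortion, standards = standards)
  })
  say("simulate: %d sites x %d samples, %d planted", d$n_sites, d$n_samples, d$n_associated)

  # -- stage 2: scan ----------------------------------------------------------
  sc <- config$scan
  scan <- run_stage("scan", {
    records <- scan_associations(sim$meth$betas, sim$cohort,
      detection_p_max = sc$detection_p_max, knn_k = sc$knn_k)
    selected <- select_sites(records, sc$p_max, sc$r2_min, sc$fdr_max)
    strict <- dplyr::filter(selected, .data$rule == "strict")
    loose <- dplyr::filter(selected, .data$rule == "loose")
    enrichment <- if (nrow(loose) > 0) {
      test_island_enrichment(loose$site_id, sim$meth$annotation)
    } else {
      NULL
    }
    readr::write_tsv(records, keep(file.path(out_dir, "scan_records.tsv")))
    readr::write_tsv(selected, keep(file.path(out_dir, "scan_selected.tsv")))
    summary <- list(
      n_loose = nrow(loose),
      n_loose_positive = sum(loose$direction == "positive"),
      n_loose_negative = sum(loose$direction == "negative"),
      n_strict = nrow(strict),
      island_p = if (!is.null(enrichment)) enrichment$p_value else NA
    )
    jsonlite::write_json(summary, keep(file.path(out_dir, "scan_summary.json")),
      auto_unbox = TRUE, digits = NA)
    list(records = records, loose = loose, strict = strict,
         enrichment = enrichment, summary = summary)
  })
  say("scan: %d loose (%d+/%d-), %d strict", scan$summary$n_loose,
    scan$summary$n_loose_positive, scan$summary$n_loose_negative, scan$summary$n_strict)

  # -- stage 3: qc ------------------------------------------------------------
  qcfg <- config$qc
  vcfg <- config$validation
  qc <- run_stage("qc", {
    # validation panel: strict sites (lowest q first), topped up from the
    # best remaining records if the strict set is small
    ranked <- dplyr::arrange(scan$records, .data$q, .data$site_id)
    panel <- head(scan$strict$site_id[order(
      scan$records$q[match(scan$strict$site_id, scan$records$site_id)])],
      vcfg$max_sites)
    if (length(panel) < vcfg$min_sites) {
      extra <- setdiff(ranked$site_id, panel)
      panel <- c(panel, head(extra, vcfg$min_sites - length(panel)))
    }
    signs <- sign(scan$records$slope[match(panel, scan$records$site_id)])
    signs[signs == 0] <- 1
    val <- simulate_validation_measurements(panel, signs, config,
      sim$distortion, seed)
    calib <- fit_calibration(sim$standards)
    filtered <- filter_confidence(val$measured, qcfg$confidence_min, quiet = TRUE)
    acceptance <- attr(filtered, "acceptance_fraction")
    reduced <- filter_missingness(filtered, qcfg$site_max, qcfg$sample_max,
      quiet = TRUE)
    excl <- qc_exclusions(reduced)
    corrected <- apply_calibration(reduced, calib, quiet = TRUE)
    kept_meta <- dplyr::filter(val$metadata,
      .data$sample_id %in% unique(corrected$sample_id))
    picked <- select_by_abs_r(corrected, kept_meta, qcfg$abs_r_min)
    write_metadata_csv(val$metadata,
      keep(file.path(out_dir, "validation_metadata.csv")))
    write_epityper_long(val$measured,
      keep(file.path(out_dir, "validation_epityper.csv")))
    write_beta_tsv(corrected, keep(file.path(out_dir, "qc_matrix.tsv")))
    report <- list(
      calibration = list(slope = calib$slope, intercept = calib$intercept,
        r2_fit = calib$r2_fit),
      acceptance_fraction = acceptance,
      excluded_sites = excl$sites, excluded_samples = excl$samples,
      n_clipped = attr(corrected, "n_clipped"),
      panel = panel, selected_sites = picked$site_id
    )
    jsonlite::write_json(report, keep(file.path(out_dir, "qc_report.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    list(panel = panel, corrected = corrected, metadata = kept_meta,
         calibration = calib, picked = picked, report = report,
         site_pars = val$site_pars)
  })
  say("qc: %d/%d panel sites selected by |R|; %d site(s), %d sample(s) excluded",
    nrow(qc$picked), length(qc$panel),
    nrow(qc$report$excluded_sites), nrow(qc$report$excluded_samples))

  # -- stage 4: select (subset search) ---------------------------------------
  mcfg <- config$model
  model_args <- mcfg[setdiff(names(mcfg), "family")]
  search <- run_stage("select", {
    sites_use <- qc$picked$site_id
    if (length(sites_use) < 2) {
      abort_field("fewer than 2 sites survived |R| selection; cannot search subsets.")
    }
    # model fitting needs a complete table: fill the sparse residual
    # missingness (scattered low-confidence calls) by KNN over the panel
    panel_data <- dplyr::filter(qc$corrected, .data$site_id %in% sites_use)
    if (anyNA(panel_data$beta)) {
      panel_data <- impute_knn(panel_data, k = min(5, length(sites_use) - 1))
    }
    wide <- make_model_table(panel_data, qc$metadata, sites_use)
    sizes <- config$search$sizes[config$search$sizes <= length(sites_use)]
    res <- do.call(exhaustive_subset_search, c(
      list(data = wide, family = mcfg$family, sites = sites_use,
        sizes = sizes, seed = derive_seed(seed, "search")),
      model_args
    ))
    final <- choose_final_subset(res, config$search$tolerance)
    tab <- res$table
    tab$sites <- NULL
    readr::write_tsv(tab, keep(file.path(out_dir, "search.tsv")))
    jsonlite::write_json(
      list(by_size = data.frame(size = res$by_size$size, mad = res$by_size$mad,
        label = res$by_size$label),
        final_size = final$size, final_sites = final$sites[[1]],
        final_loo_mad = final$mad),
      keep(file.path(out_dir, "search_summary.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    list(result = res, final = final, table = wide)
  })
  say("select: final panel k = %d (%s), LOO MAD %.2f y",
    search$final$size, search$final$label, search$final$mad)

  # -- stage 5: train ---------------------------------------------------------
  train <- run_stage("train", {
    final_sites <- search$final$sites[[1]]
    fit <- do.call(fit_age_model, c(
      list(data = search$table, family = mcfg$family, sites = final_sites,
        seed = derive_seed(seed, "train")),
      model_args
    ))
    overfit <- do.call(compare_fit_loo, c(
      list(data = search$table, family = mcfg$family, sites = final_sites,
        seed = derive_seed(seed, "train")),
      model_args
    ))
    write_age_model(fit, keep(file.path(out_dir, "model.json")))
    readr::write_tsv(overfit, keep(file.path(out_dir, "train_report.tsv")))
    list(fit = fit, overfit = overfit)
  })
  say("train: %s on %d sites; train MAD %.2f y, LOO MAD %.2f y",
    mcfg$family, length(search$final$sites[[1]]),
    train$overfit$train_mad, train$overfit$loo_mad)

  # -- stage 6: predict (blind cohort) ---------------------------------------
  blind <- run_stage("predict", {
    bcfg <- config$blind
    # blind samples are new individuals measured at the same panel: the
    # site trajectories are those of the validation cohort, only the
    # cohort draw and measurement noise are new
    bval <- simulate_validation_measurements(
      qc$panel, rep(1, length(qc$panel)),
      modifyList(config, list(validation = modifyList(config$validation,
        list(n_samples = bcfg$n_samples)))),
      sim$distortion, derive_seed(seed, "blind"), site_pars = qc$site_pars,
      plant_artifacts = FALSE)
    bcorr <- apply_calibration(bval$measured, qc$calibration, quiet = TRUE)
    bwide <- make_model_table(bcorr, bval$metadata, train$fit$sites)
    preds <- predict_ages(train$fit, bwide)
    preds$age <- bval$metadata$age[match(preds$sample_id, bval$metadata$sample_id)]
    readr::write_tsv(preds, keep(file.path(out_dir, "blind_predictions.tsv")))
    list(predictions = preds, mad = mad_years(preds$age, preds$predicted))
  })
  say("predict: blind MAD %.2f y over %d samples", blind$mad,
    nrow(blind$predictions))

  manifest <- list(
    package = as.character(packageVersion("methage")),
    r_version = R.version.string,
    seed = seed,
    config = unclass(config),
    stages = c("simulate", "scan", "qc", "select", "train", "predict"),
    outputs = lapply(setNames(paths, basename(unlist(paths))), file_hash_fnv)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)

  invisible(list(simulate = sim, scan = scan, qc = qc, select = search,
                 train = train, predict = blind, manifest = manifest))
}

#' Assemble a wide model table from a beta table and metadata
#'
#' Joins a (complete-case) long beta table with cohort ages into the wide
#' samples-by-sites layout the model fitters take: `sample_id`, `age`, one
#' numeric column per site.
#'
#' @param data Long beta table.
#' @param metadata Metadata with `sample_id` and `age`.
#' @param sites Sites to include (default: all in `data`).
#' @return A wide tibble.
#' @export
make_model_table <- function(data, metadata, sites = NULL) {
  check_columns(metadata, c("sample_id", "age"), "metadata")
  sites <- sites %||% unique(data$site_id)
  sub <- dplyr::filter(data, .data$site_id %in% sites)
  x <- beta_matrix(sub)
  wide <- tibble::as_tibble(t(x[sites, , drop = FALSE]))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(x)),
    tibble::tibble(age = metadata$age[match(colnames(x), metadata$sample_id)]),
    wide
  )
  tibble::as_tibble(out)
}

#' Predict ages for new samples with a fitted model
#'
#' @param model A fitted `age_model` (or a path to a model JSON written by
#'   [write_age_model()]).
#' @param data Wide tibble with `sample_id` and the model's site columns;
#'   column order is irrelevant. Missing site columns are an error.
#' @return A tibble: `sample_id`, `predicted`.
#' @export
predict_ages <- function(model, data) {
  if (is.character(model)) model <- read_age_model(model)
  stopifnot(inherits(model, "age_model"))
  tibble::tibble(
    sample_id = if ("sample_id" %in% names(data)) data$sample_id else
      sprintf("S%03d", seq_len(nrow(data))),
    predicted = predict(model, data)
  )
}
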