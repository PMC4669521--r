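#' Serialize fitted age models to and from JSON
#'
#' Writes a fitted model (any family) to a self-contained JSON document:
#' family, hyperparameters, scaling, coefficients or dual solution, and
#' the training site ids. `read_age_model()` restores an object with
#' identical predictions.
#'
#' @param model A fitted `age_model`.
#' @param path Output/input JSON path.
#' @return `write_age_model()` returns `path` invisibly;
#'   `read_age_model()` the restored model.
#' @export
write_age_model <- function(model, path) {
  stopifnot(inherits(model, "age_model"))
  payload <- unclass(model)
  for (nm in names(payload)) {
    if (is.matrix(payload[[nm]])) {
      payload[[nm]] <- list(
        .matrix = TRUE, data = as.vector(payload[[nm]]),
        nrow = nrow(payload[[nm]]), ncol = ncol(payload[[nm]]),
        dimnames = dimnames(payload[[nm]])
      )
    }
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(payload)) {
    el <- payload[[nm]]
    if (is.list(el) && isTRUE(el$.matrix)) {
      m <- matrix(el$data, el$nrow, el$ncol)
      if (!is.null(el$dimnames)) {
        dn <- el$dimnames
        dimnames(m) <- list(
          if (length(dn) >= 1 && length(dn[[1]])) dn[[1]] else NULL,
          if (length(dn) >= 2 && length(dn[[2]])) dn[[2]] else NULL
        )
      }
      payload[[nm]] <- m
    }
  }
  for (nm in c("coefficients", "sq_coefficients", "dual_coefficients", "w2",
               "b1", "support_indices")) {
    if (!is.null(payload[[nm]])) payload[[nm]] <- unlist(payload[[nm]])
  }
  for (nm in c("x_scaling")) {
    if (!is.null(payload[[nm]])) {
      payload[[nm]] <- lapply(payload[[nm]], unlist)
    }
  }
  payload$sites <- unlist(payload$sites)
  class(payload) <- c(paste0(payload$family, "_age_model"), "age_model")
  payload
}
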