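# Internal helpers: seed handling, validation, small numerics.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage sub-seed derived from one global seed, so each
# named stream (cohort, betas, mask, standards, ...) is independently
# reproducible. Stays below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  sid <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) %% 1000003) * 1009 + sid * 97 + 11) %% 2147483647L
}

abort_field <- function(msg, field = NULL) {
  abort(msg, class = "methage_error", field = field)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE,
                         strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_field(sprintf("`%s` must be a single finite number.", name), name)
  }
  low_ok <- if (strict_min) x > min else x >= min
  high_ok <- if (strict_max) x < max else x <= max
  if (!low_ok || !high_ok) {
    abort_field(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x, if (strict_min) "(" else "[", min, max,
      if (strict_max) ")" else "]"
    ), name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) {
    abort_field(sprintf("`%s` must be a whole number.", name), name)
  }
  invisible(as.integer(x))
}

check_columns <- function(data, cols, what = "data") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort_field(sprintf(
      "%s is missing required column(s): %s.",
      what, paste0("`", missing_cols, "`", collapse = ", ")
    ))
  }
  invisible(data)
}

clip01 <- function(x) {
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  x
}

# FNV-1a over a file's bytes; used for the pipeline manifest.
file_hash_fnv <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
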