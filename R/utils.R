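# Internal validation helpers shared across modules.

stop_domain <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nmrbind_domain_error")
}

stop_fit <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nmrbind_fit_error")
}

stop_schema <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nmrbind_schema_error")
}

# All arguments finite numerics; names used in the error message.
check_finite <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop_domain("`%s` must be finite numeric, got non-finite or missing values", nms[i])
    }
  }
  invisible(TRUE)
}

check_nonneg <- function(x, name) {
  check_finite_one(x, name)
  if (any(x < 0)) stop_domain("`%s` must be non-negative", name)
  invisible(TRUE)
}

check_positive <- function(x, name) {
  check_finite_one(x, name)
  if (any(x <= 0)) stop_domain("`%s` must be strictly positive", name)
  invisible(TRUE)
}

check_finite_one <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_domain("`%s` must be finite numeric, got non-finite or missing values", name)
  }
  invisible(TRUE)
}

# Require a data frame with the given columns, all-numeric where listed.
check_columns <- function(data, required, numeric_cols = required, what = "data") {
  if (!is.data.frame(data)) stop_schema("`%s` must be a data frame", what)
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop_schema("%s is missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  for (col in intersect(numeric_cols, required)) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      stop_schema("column `%s` of %s must be numeric", col, what)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v) | is.na(v))[1]
      stop_schema("column `%s` of %s has a non-finite value at row %d", col, what, bad)
    }
  }
  invisible(TRUE)
}

# Run body under a fixed RNG seed when one is given, untouched otherwise.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_domain("`seed` must be a single finite number or NULL")
  }
  withr::with_seed(as.integer(seed), force(code))
}
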