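#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

abort_validation <- function(msg, field = NULL) {
  cls <- c("ayapbpk_validation_error", "error", "condition")
  stop(structure(class = cls,
                 list(message = if (is.null(field)) msg
                      else sprintf("%s [field: %s]", msg, field),
                      call = NULL, field = field)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_positive <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    abort_validation(sprintf("'%s' must be a positive finite number", field),
                     field)
  invisible(x)
}

check_fraction <- function(x, field, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || any(!is.finite(x)) || any(!lo_ok) || any(x > 1))
    abort_validation(sprintf("'%s' must lie in %s", field,
                             if (allow_zero) "[0, 1]" else "(0, 1]"), field)
  invisible(x)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ayapbpk")
  if (path == "") abort_validation(sprintf("packaged data file '%s' not found", file))
  path
}

.table_cache <- new.env(parent = emptyenv())

read_pkg_table <- function(file) {
  if (is.null(.table_cache[[file]]))
    .table_cache[[file]] <- utils::read.delim(pkg_extdata(file),
                                              stringsAsFactors = FALSE)
  .table_cache[[file]]
}

#' Get or set a value inside a nested model specification by path
#'
#' Paths address nested list elements with `/` separators, e.g.
#' `"compounds/HRM/processes/cyp2d6/kcat_per_min"` or
#' `"physiology/gastric_emptying_h"`.  Used by [fit_parameters()] and
#' [local_sensitivity()] to perturb arbitrary scalar parameters.
#'
#' @param x nested list (a model specification).
#' @param path character scalar path.
#' @param value replacement value (for `config_set`).
#' @return `config_get` returns the addressed element; `config_set` returns
#'   the modified list.
#' @export
config_get <- function(x, path) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  for (k in keys) {
    idx <- suppressWarnings(as.integer(k))
    x <- if (!is.na(idx)) x[[idx]] else x[[k]]
    if (is.null(x))
      abort_validation(sprintf("path component '%s' not found in '%s'", k, path))
  }
  x
}

#' @rdname config_get
#' @export
config_set <- function(x, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (length(keys) == 1L) {
    idx <- suppressWarnings(as.integer(keys))
    if (!is.na(idx)) x[[idx]] <- value else x[[keys]] <- value
    return(x)
  }
  head <- keys[1L]
  rest <- paste(keys[-1L], collapse = "/")
  idx <- suppressWarnings(as.integer(head))
  if (!is.na(idx)) {
    x[[idx]] <- config_set(x[[idx]], rest, value)
  } else {
    if (is.null(x[[head]]))
      abort_validation(sprintf("path component '%s' not found", head))
    x[[head]] <- config_set(x[[head]], rest, value)
  }
  x
}

## Unit conversions. Internal amounts are micromol, volumes L, time h.
mg_to_umol <- function(mg, mw) mg / mw * 1000
umol_l_to_ng_ml <- function(conc_um, mw) conc_um * mw
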