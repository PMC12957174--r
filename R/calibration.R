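## calibration_sensitivity: bounded least-squares parameter identification
## against observed mean plasma profiles, and local (+/-50%) normalized
## sensitivity analysis.

#' Fit model parameters to an observed dataset
#'
#' Bounded trust-region least squares (Levenberg-Marquardt with box
#' constraints) on the residuals between simulated and observed mean
#' plasma concentrations.  Parameters flagged `log = TRUE` are estimated
#' on the log10 scale.  The default objective compares log concentrations
#' (`sse_log`), appropriate for data spanning orders of magnitude.
#'
#' @param model a [pbpk_model()].
#' @param observed an `observed_dataset` (see [generate_trial()]) or a
#'   data.frame with columns `time_h`, `compound`, `conc_ng_ml` of mean
#'   concentrations.
#' @param free list of free-parameter descriptors
#'   `list(path =, lower =, upper =, log = TRUE)`; paths address the model
#'   specification as in [config_get()].  Empty list returns the model
#'   unchanged with the residual evaluated.
#' @param regimen dosing regimen; defaults to the dataset's `dose_record`.
#' @param objective `"sse_log"` or `"sse_linear"`.
#' @param dt_out simulation output spacing, h.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return object of class `pbpk_fit`: the refitted model, `estimates`,
#'   `start`, `residual_norm`, `converged`, `rsstrace` (monotone
#'   non-increasing across accepted iterations).
#' @export
fit_parameters <- function(model, observed, free = list(), regimen = NULL,
                           objective = c("sse_log", "sse_linear"),
                           dt_out = 0.05, control = list(maxiter = 50)) {
  objective <- match.arg(objective)
  stopifnot(inherits(model, "pbpk_model"))
  obs <- if (inherits(observed, "observed_dataset")) {
    regimen <- regimen %||% observed$dose_record
    summarize_trial(observed)
  } else as.data.frame(observed)
  if (is.null(regimen)) abort_validation("a dosing regimen is required", "regimen")
  obs <- obs[is.finite(obs$conc_ng_ml) & obs$conc_ng_ml > 0, , drop = FALSE]
  if (!nrow(obs)) abort_validation("no usable observations", "observed")
  t_end <- max(obs$time_h)
  tms <- sort(unique(c(seq(0, t_end, by = dt_out), obs$time_h)))

  resid_fun <- function(spec) {
    m <- rebuild_model(spec)
    prof <- simulate_profile(m, regimen, t_end = t_end, times = tms)
    sim <- merge(obs, as.data.frame(prof)[, c("time_h", "compound", "conc_ng_ml")],
                 by = c("time_h", "compound"), suffixes = c("_obs", "_sim"))
    if (objective == "sse_log")
      log(pmax(sim$conc_ng_ml_sim, 1e-9)) - log(sim$conc_ng_ml_obs)
    else sim$conc_ng_ml_sim - sim$conc_ng_ml_obs
  }

  spec0 <- model$spec
  if (!length(free)) {
    r <- resid_fun(spec0)
    return(structure(list(model = model, estimates = numeric(0),
                          start = numeric(0), residual_norm = sum(r^2),
                          converged = TRUE, rsstrace = sum(r^2)),
                     class = "pbpk_fit"))
  }

  paths <- vapply(free, `[[`, "", "path")
  logf <- vapply(free, function(f) isTRUE(f$log %||% TRUE), logical(1))
  lower <- vapply(free, function(f) f$lower %||% -Inf, numeric(1))
  upper <- vapply(free, function(f) f$upper %||% Inf, numeric(1))
  if (any(logf & lower <= 0))
    abort_validation("log-scale parameters need a positive lower bound", "free")
  p0 <- vapply(paths, function(p) config_get(spec0, p), numeric(1))
  tr <- function(p) ifelse(logf, log10(p), p)
  itr <- function(th) ifelse(logf, 10^th, th)

  fn <- function(th) {
    p <- itr(th)
    spec <- spec0
    for (k in seq_along(paths)) spec <- config_set(spec, paths[k], p[k])
    resid_fun(spec)
  }
  fit <- minpack.lm::nls.lm(par = tr(p0), lower = tr(lower), upper = tr(upper),
                            fn = fn,
                            control = do.call(minpack.lm::nls.lm.control,
                                              control))
  est <- stats::setNames(itr(fit$par), paths)
  spec <- spec0
  for (k in seq_along(paths)) spec <- config_set(spec, paths[k], est[[k]])
  structure(list(model = rebuild_model(spec),
                 estimates = est, start = stats::setNames(p0, paths),
                 residual_norm = fit$deviance,
                 converged = fit$info %in% 1:4,
                 rsstrace = fit$rsstrace, info = fit$message),
            class = "pbpk_fit")
}

#' @export
coef.pbpk_fit <- function(object, ...) object$estimates

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("<pbpk_fit> %s, residual norm %.4g\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual_norm))
  if (length(x$estimates)) {
    df <- data.frame(start = x$start, estimate = x$estimates)
    print(df)
  }
  invisible(x)
}

#' Local sensitivity analysis with a +/-50% variation range
#'
#' Each parameter is perturbed one at a time to `p * (1 - v)` and
#' `p * (1 + v)` and the central normalized sensitivity coefficient
#' `S = (dM/M) / (dp/p)` is computed per metric (AUC, Cmax, Tmax of the
#' stated compound over the analysis window).  A failed simulation at a
#' perturbed point yields `NA` for that coefficient.
#'
#' @param model a [pbpk_model()].
#' @param regimen dosing regimen.
#' @param parameters character vector of specification paths (see
#'   [config_get()]).
#' @param compound metric compound.
#' @param metrics subset of `c("auc", "cmax", "tmax")`.
#' @param variation fraction in (0, 1); 0.5 is the +/-50% convention.
#' @param t_end,window,dt_out simulation horizon, NCA window, grid.
#' @return object of class `sensitivity_result`: data.frame with columns
#'   `parameter`, `metric`, `S`, sorted by |S| within metric.
#' @export
local_sensitivity <- function(model, regimen, parameters, compound,
                              metrics = c("auc", "cmax", "tmax"),
                              variation = 0.5, t_end, window = NULL,
                              dt_out = 0.05) {
  stopifnot(inherits(model, "pbpk_model"))
  if (variation <= 0 || variation >= 1)
    abort_validation("variation must lie in (0, 1)", "variation")
  metrics <- match.arg(metrics, several.ok = TRUE)

  eval_metrics <- function(spec) {
    m <- rebuild_model(spec)
    prof <- simulate_profile(m, regimen, t_end = t_end, dt_out = dt_out)
    nn <- nca(prof, compound = compound, window = window)
    c(auc = nn$auc_0_t, cmax = nn$cmax, tmax = nn$tmax)[metrics]
  }
  M0 <- eval_metrics(model$spec)

  rows <- list()
  for (path in parameters) {
    p0 <- config_get(model$spec, path)
    Mhi <- tryCatch(eval_metrics(config_set(model$spec, path, p0 * (1 + variation))),
                    error = function(e) rep(NA_real_, length(metrics)))
    Mlo <- tryCatch(eval_metrics(config_set(model$spec, path, p0 * (1 - variation))),
                    error = function(e) rep(NA_real_, length(metrics)))
    S <- (Mhi - Mlo) / M0 / (2 * variation)
    rows[[path]] <- data.frame(parameter = path, metric = metrics,
                               S = as.numeric(S), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res <- res[order(res$metric, -abs(res$S)), ]
  rownames(res) <- NULL
  structure(res, class = c("sensitivity_result", "data.frame"),
            variation = variation, compound = compound, baseline = M0)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> compound %s, variation +/-%.0f%%\n",
              attr(x, "compound"), 100 * attr(x, "variation")))
  print(as.data.frame(x))
  invisible(x)
}
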