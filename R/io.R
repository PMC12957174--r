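## interface_io: delimited-table I/O for profiles and observed datasets,
## and scenario orchestration tying the modules into one reproducible run.

#' Read and write concentration profiles and observed datasets
#'
#' Profiles are stored as tab-delimited long tables with columns `time_h`,
#' `compound`, `compartment`, `conc_ng_ml`; observed datasets with columns
#' `subject_id`, `time_h`, `compound`, `conc_ng_ml`.  Round-trips preserve
#' values to full precision; rows are canonically sorted on read.
#'
#' @param x profile or dataset (data.frame-compatible).
#' @param path file path.
#' @return the written path (write) or the object (read).
#' @name profile_io
NULL

write_table_checked <- function(df, path) {
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_checked <- function(path, need) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation(paste("file", path, "lacks required column(s):",
                           paste(miss, collapse = ", ")))
  df
}

#' @rdname profile_io
#' @export
write_profile <- function(x, path) {
  df <- as.data.frame(x)[, c("time_h", "compound", "compartment", "conc_ng_ml")]
  write_table_checked(df, path)
}

#' @rdname profile_io
#' @export
read_profile <- function(path) {
  df <- read_table_checked(path, c("time_h", "compound", "compartment",
                                   "conc_ng_ml"))
  df <- df[order(df$compound, df$compartment, df$time_h), ]
  rownames(df) <- NULL
  structure(df, class = c("concentration_profile", "data.frame"))
}

#' @rdname profile_io
#' @export
write_dataset <- function(x, path) {
  df <- if (inherits(x, "observed_dataset")) x$samples else as.data.frame(x)
  write_table_checked(df[, c("subject_id", "time_h", "compound",
                             "conc_ng_ml")], path)
}

#' @rdname profile_io
#' @export
read_dataset <- function(path) {
  df <- read_table_checked(path, c("subject_id", "time_h", "compound",
                                   "conc_ng_ml"))
  df <- df[order(df$subject_id, df$compound, df$time_h), ]
  rownames(df) <- NULL
  df
}

#' Run a complete simulation scenario
#'
#' Validates the configuration up front (no partial outputs on error),
#' builds the model, simulates the requested regimen or DDI protocol, and
#' writes profiles, NCA tables, DDI ratio tables and a JSON run manifest
#' (configuration echo, seed, package version) into `out_dir`.
#'
#' @param config list with entries `compounds` (character vector resolved
#'   from [default_compounds()], or a named list of [compound()] objects),
#'   `protocol` (a [ddi_protocol()] name) or `regimen` (a [regimen()]),
#'   `t_end` (h, for plain regimens), `seed`, and optional `physiology`,
#'   `options`, `outputs` (subset of `c("profiles", "nca", "ddi")`).
#' @param out_dir output directory (created).
#' @return invisible list with the in-memory results (`profile`, `nca`,
#'   `ddi`, `manifest`).
#' @export
run_scenario <- function(config, out_dir) {
  ## ---- validate everything before touching the disk
  cps <- config$compounds
  if (is.character(cps)) cps <- default_compounds(cps)
  if (is.null(cps) || !length(cps))
    abort_validation("config$compounds is required", "compounds")
  phys <- config$physiology %||% build_reference_individual()
  seed <- as.integer(config$seed %||% 1L)
  outputs <- config$outputs %||% c("profiles", "nca", "ddi")
  model <- pbpk_model(cps, phys, config$options %||% list())

  is_ddi <- !is.null(config$protocol) &&
    config$protocol %in% c("FL_5d", "FL_14d", "PR_5d", "PR_14d")
  if (!is_ddi && is.null(config$regimen) && is.null(config$protocol))
    abort_validation("config needs a 'protocol' or a 'regimen'")

  set.seed(seed)
  results <- list()
  if (is_ddi) {
    dd <- run_ddi(model, config$protocol,
                  body_weight = phys$body_weight)
    results$ddi <- do.call(rbind, lapply(dd, function(d) data.frame(
      victim = d$victim, perpetrator = d$perpetrator,
      duration_days = d$duration_days, auc_ratio = d$auc_ratio,
      cmax_ratio = d$cmax_ratio, classification = d$classification,
      stringsAsFactors = FALSE)))
  } else {
    reg <- config$regimen %||% ddi_protocol(config$protocol,
                                            body_weight = phys$body_weight)
    t_end <- config$t_end %||% (max(reg$events$time_h) + 12)
    prof <- simulate_profile(model, reg, t_end = t_end)
    results$profile <- prof
    results$nca <- do.call(rbind, lapply(unique(prof$compound), function(cp) {
      nn <- nca(prof, compound = cp)
      data.frame(compound = cp, auc_0_t = nn$auc_0_t, cmax = nn$cmax,
                 tmax = nn$tmax, stringsAsFactors = FALSE)
    }))
  }

  ## ---- write outputs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(results$profile) && "profiles" %in% outputs)
    write_profile(results$profile, file.path(out_dir, "profiles.tsv"))
  if (!is.null(results$nca) && "nca" %in% outputs)
    write_table_checked(results$nca, file.path(out_dir, "nca.tsv"))
  if (!is.null(results$ddi) && "ddi" %in% outputs)
    write_table_checked(results$ddi, file.path(out_dir, "ddi.tsv"))
  manifest <- list(
    package = "ayapbpk",
    version = as.character(utils::packageVersion("ayapbpk")),
    seed = seed,
    protocol = config$protocol %||% NA,
    compounds = names(cps),
    body_weight = phys$body_weight,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
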