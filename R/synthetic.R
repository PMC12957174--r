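## synthetic_clinic: synthetic clinical datasets emulating the oral
## ayahuasca volunteer study (n = 6, sampling pre-dose to 240 min), so that
## calibration, qualification and DDI stages are testable without real
## subject data.  Individual parameters get lognormal interindividual
## variability, observations a proportional residual error, and values
## below the assay quantification limit are censored.

#' Specify a synthetic trial design
#'
#' Defaults emulate the clinical study conditions: 6 volunteers (4 M / 2 F),
#' age 32 +/- 11 y, weight 75 +/- 11 kg (truncated normal), sampling at
#' pre-dose, 20, 40, 60, 90, 120, 180 and 240 min, 1 mL/kg oral ayahuasca
#' (1.77 mg/kg harmine, 0.67 mg/kg DMT), 20% proportional residual error
#' and a 0.1 ng/mL lower limit of quantification.
#'
#' @param n_subjects number of volunteers.
#' @param age_mean,age_sd,weight_mean,weight_sd demographic moments
#'   (truncated to the physiologically valid ranges).
#' @param n_males males among `n_subjects`.
#' @param sampling_times_h sampling grid (pre-dose mapped to 0).
#' @param iiv named lognormal CVs applied multiplicatively to model
#'   parameters; names are either enzyme names (scaling that enzyme's
#'   abundance) or specification paths.
#' @param residual_cv proportional residual error CV.
#' @param lloq ng/mL; observations below are censored (`NA`).
#' @param seed integer.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 6, age_mean = 32, age_sd = 11,
                         weight_mean = 75, weight_sd = 11, n_males = 4,
                         sampling_times_h = c(0, 20, 40, 60, 90, 120, 180,
                                              240) / 60,
                         iiv = c(CYP2D6 = 0.35, CYP_other = 0.35, MAOA = 0.2),
                         residual_cv = 0.2, lloq = 0.1, seed = 1L) {
  if (n_subjects < 1) abort_validation("n_subjects must be >= 1", "n_subjects")
  if (any(iiv < 0) || residual_cv < 0)
    abort_validation("CVs must be >= 0", "iiv")
  structure(list(n_subjects = as.integer(n_subjects), age_mean = age_mean,
                 age_sd = age_sd, weight_mean = weight_mean,
                 weight_sd = weight_sd, n_males = n_males,
                 sampling_times_h = sort(sampling_times_h), iiv = iiv,
                 residual_cv = residual_cv, lloq = lloq,
                 seed = as.integer(seed)),
            class = "trial_design")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic observed dataset from a ground-truth model
#'
#' Per subject: demographics are sampled, individual parameters drawn with
#' lognormal IIV (median 1), the individual's weight-scaled ayahuasca dose
#' simulated with the ground-truth model, concentrations evaluated at the
#' design sampling times, proportional residual error applied, and values
#' below the LLOQ censored.  Fully seed-deterministic.
#'
#' @param ground_truth_model a [pbpk_model()] containing DMT and HRM.
#' @param design a [trial_design()].
#' @param compounds compounds to sample (default DMT and HRM).
#' @return object of class `observed_dataset`: list with `subjects`
#'   (data.frame id/age/weight/sex), `samples` (long data.frame
#'   subject_id/time_h/compound/conc_ng_ml, censored values `NA`),
#'   `dose_record` (the mean-weight [regimen()]), `design`.
#' @export
generate_trial <- function(ground_truth_model, design = trial_design(),
                           compounds = c("DMT", "HRM")) {
  stopifnot(inherits(ground_truth_model, "pbpk_model"),
            inherits(design, "trial_design"))
  set.seed(design$seed)
  n <- design$n_subjects
  ages <- rnorm_trunc(n, design$age_mean, design$age_sd, 18, 80)
  wts <- rnorm_trunc(n, design$weight_mean, design$weight_sd, 40, 150)
  n_m <- min(design$n_males, n)
  sexes <- rep(c("M", "F"), c(n_m, n - n_m))
  subjects <- data.frame(id = seq_len(n), age = ages, weight = wts,
                         sex = sexes, stringsAsFactors = FALSE)

  t_end <- max(design$sampling_times_h)
  spec0 <- ground_truth_model$spec
  enzymes <- unique(unlist(lapply(spec0$compounds, function(cp)
    lapply(cp$processes, `[[`, "enzyme"))))

  samples <- list()
  for (i in seq_len(n)) {
    spec <- spec0
    ab <- spec$physiology$enzyme_abundance
    for (pn in names(design$iiv)) {
      mult <- rlnorm_cv(1, design$iiv[[pn]])
      if (pn %in% enzymes) {
        ab[[pn]] <- (if (pn %in% names(ab)) ab[[pn]] else 1) * mult
      } else {
        spec <- config_set(spec, pn, config_get(spec, pn) * mult)
      }
    }
    spec$physiology <- physiology(
      organs = build_reference_individual(age = ages[i], weight = wts[i],
                                          sex = sexes[i])$organs,
      cardiac_output = REF_CARDIAC_OUTPUT_L_H * (wts[i] / REF_WEIGHT_KG)^0.75,
      body_weight = wts[i], age = ages[i], sex = sexes[i],
      hematocrit = spec$physiology$hematocrit,
      gastric_emptying_h = spec$physiology$gastric_emptying_h,
      enzyme_abundance = ab)
    m_i <- rebuild_model(spec)
    reg_i <- regimen(data.frame(
      compound = c("HRM", "DMT"), route = "oral",
      amount_mg = c(1.77, 0.67) * wts[i], time_h = 0,
      stringsAsFactors = FALSE), sprintf("subject %d ayahuasca", i))
    prof <- simulate_profile(m_i, reg_i, t_end = t_end,
                             times = sort(unique(c(seq(0, t_end, by = 0.05),
                                                   design$sampling_times_h))))
    pdf <- as.data.frame(prof)
    for (cp in compounds) {
      sub <- pdf[pdf$compound == cp & pdf$compartment == "venous_plasma", ]
      idx <- match(round(design$sampling_times_h, 9), round(sub$time_h, 9))
      conc <- sub$conc_ng_ml[idx]
      if (design$residual_cv > 0)
        conc <- conc * (1 + stats::rnorm(length(conc), 0, design$residual_cv))
      conc <- pmax(conc, 0)
      conc[conc < design$lloq] <- NA_real_
      samples[[length(samples) + 1L]] <- data.frame(
        subject_id = i, time_h = design$sampling_times_h, compound = cp,
        conc_ng_ml = conc, stringsAsFactors = FALSE)
    }
  }
  dose_record <- regimen(data.frame(
    compound = c("HRM", "DMT"), route = "oral",
    amount_mg = c(1.77, 0.67) * design$weight_mean, time_h = 0,
    stringsAsFactors = FALSE), "mean-weight ayahuasca dose")
  structure(list(subjects = subjects,
                 samples = do.call(rbind, samples),
                 dose_record = dose_record, design = design),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat(sprintf("<observed_dataset> %d subjects, %d samples (%d censored), compounds: %s\n",
              nrow(x$subjects), nrow(x$samples), sum(is.na(x$samples$conc_ng_ml)),
              paste(unique(x$samples$compound), collapse = ", ")))
  invisible(x)
}

#' Mean +/- SEM profile of an observed dataset
#'
#' Arithmetic mean and standard error over non-censored values per time
#' point and compound (censored/below-LLOQ values are excluded, the
#' standard below-quantification-limit convention here).
#'
#' @param dataset an `observed_dataset`, or a data.frame with columns
#'   `subject_id`, `time_h`, `compound`, `conc_ng_ml`.
#' @return data.frame with `time_h`, `compound`, `conc_ng_ml` (mean),
#'   `sem`, `n`.
#' @export
summarize_trial <- function(dataset) {
  df <- if (inherits(dataset, "observed_dataset")) dataset$samples
        else as.data.frame(dataset)
  sp <- split(df, list(df$compound, df$time_h), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    v <- g$conc_ng_ml[!is.na(g$conc_ng_ml)]
    data.frame(time_h = g$time_h[1], compound = g$compound[1],
               conc_ng_ml = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$compound, out$time_h), ]
  rownames(out) <- NULL
  out
}
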