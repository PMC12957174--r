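## physiology: reference human anatomy/physiology and virtual populations.
##
## The shipped reference table (inst/extdata/reference_physiology.tsv) holds
## ICRP-style adult organ volumes and regional blood flow fractions for a
## 75 kg adult.  Organ volumes scale linearly with body weight; blood flows
## scale with cardiac output, which follows allometric weight^0.75 scaling.

REF_WEIGHT_KG <- 75
REF_CARDIAC_OUTPUT_L_H <- 390   # ~6.5 L/min adult male

#' Build a reference virtual individual
#'
#' Returns the anatomy and physiology of one virtual adult: organ volumes
#' (L), regional blood flows (L/h), cardiac output, hematocrit, relative
#' enzyme abundances and gastric emptying time.  Volumes are scaled linearly
#' in body weight from the shipped 75 kg reference table; flows scale with
#' cardiac output as weight^0.75.
#'
#' @param age years, in \[18, 80\].
#' @param weight kg, in \[40, 150\].
#' @param sex `"M"` or `"F"`.
#' @param hematocrit fraction of blood volume occupied by red cells.
#' @param gastric_emptying_h first-order gastric emptying time (h).
#' @param enzyme_abundance named numeric vector of relative enzyme
#'   abundances (1 = reference).  Unnamed enzymes default to 1.
#' @return An object of class `physiology`: a list with elements
#'   `body_weight`, `age`, `sex`, `organs` (data.frame of volumes/flows),
#'   `cardiac_output`, `hematocrit`, `enzyme_abundance`,
#'   `gastric_emptying_h`.
#' @examples
#' phys <- build_reference_individual(32, 75, "M")
#' sum(phys$organs$volume_L)
#' @export
build_reference_individual <- function(age = 32, weight = 75, sex = c("M", "F"),
                                       hematocrit = 0.45,
                                       gastric_emptying_h = 0.25,
                                       enzyme_abundance = numeric(0)) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1L || age < 18 || age > 80)
    abort_validation("age must lie in [18, 80] years", "age")
  if (!is.numeric(weight) || length(weight) != 1L || weight < 40 || weight > 150)
    abort_validation("weight must lie in [40, 150] kg", "weight")
  check_fraction(hematocrit, "hematocrit", allow_zero = FALSE)
  check_positive(gastric_emptying_h, "gastric_emptying_h")

  ref <- read_pkg_table("reference_physiology.tsv")
  wf <- weight / REF_WEIGHT_KG
  co <- REF_CARDIAC_OUTPUT_L_H * wf^0.75
  organs <- data.frame(
    organ = ref$organ,
    volume_L = ref$volume_L * wf,
    blood_flow_L_h = ifelse(is.na(ref$flow_frac_co), NA_real_,
                            ref$flow_frac_co * co),
    stringsAsFactors = FALSE
  )
  phys <- structure(list(
    body_weight = weight, age = age, sex = sex,
    organs = organs, cardiac_output = co, hematocrit = hematocrit,
    enzyme_abundance = enzyme_abundance,
    gastric_emptying_h = gastric_emptying_h
  ), class = "physiology")
  validate_physiology(phys)
  phys
}

validate_physiology <- function(phys) {
  org <- phys$organs
  if (any(org$volume_L <= 0)) abort_validation("organ volumes must be positive", "organs")
  fl <- org$blood_flow_L_h[!is.na(org$blood_flow_L_h) & org$organ != "lung"]
  if (any(fl <= 0)) abort_validation("blood flows must be positive", "organs")
  if (sum(fl) > phys$cardiac_output + 1e-9)
    abort_validation("regional blood flows exceed cardiac output", "organs")
  vtot <- sum(org$volume_L)
  lo <- 0.8 * phys$body_weight / 1.05
  hi <- 1.05 * phys$body_weight / 1.05
  if (vtot < lo || vtot > hi)
    abort_validation(sprintf("total organ volume %.1f L outside [%.1f, %.1f] L",
                             vtot, lo, hi), "organs")
  invisible(phys)
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, %.0f y, %.1f kg; CO %.0f L/h; Hct %.2f\n",
              x$sex, x$age, x$body_weight, x$cardiac_output, x$hematocrit))
  cat(sprintf("  total organ volume %.1f L; gastric emptying %.2f h\n",
              sum(x$organs$volume_L), x$gastric_emptying_h))
  if (length(x$enzyme_abundance))
    cat("  enzyme abundance:",
        paste(sprintf("%s=%.2f", names(x$enzyme_abundance), x$enzyme_abundance),
              collapse = ", "), "\n")
  invisible(x)
}

#' Specify a virtual population
#'
#' @param n number of individuals.
#' @param age_range,weight_range numeric length-2 (min, max).
#' @param sex_ratio fraction of males.
#' @param variability named numeric vector of lognormal coefficients of
#'   variation per enzyme (median 1); default 35% for the CYPs and none for
#'   MAO-A, reflecting the large interindividual spread of CYP activity.
#' @param seed integer RNG seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n = 100, age_range = c(20, 59),
                            weight_range = c(60, 80), sex_ratio = 0.5,
                            variability = c(CYP2D6 = 0.35, CYP_other = 0.35,
                                            MAOA = 0),
                            seed = 1L) {
  if (!is.numeric(n) || n < 1) abort_validation("n must be >= 1", "n")
  if (diff(age_range) < 0) abort_validation("age_range must be ordered", "age_range")
  if (diff(weight_range) < 0) abort_validation("weight_range must be ordered", "weight_range")
  check_fraction(sex_ratio, "sex_ratio")
  if (any(variability < 0)) abort_validation("CVs must be >= 0", "variability")
  structure(list(n = as.integer(n), age_range = age_range,
                 weight_range = weight_range, sex_ratio = sex_ratio,
                 variability = variability, seed = as.integer(seed)),
            class = "population_spec")
}

## lognormal with median 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Sample a virtual population
#'
#' Draws `spec$n` individuals with age and weight uniform inside the stated
#' ranges, sex per `sex_ratio`, and per-enzyme relative abundances drawn
#' lognormally (median 1) with the stated CVs.  Identical seeds give
#' identical populations.
#'
#' @param spec a [population_spec()].
#' @return list of `physiology` objects.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n
  ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  wts <- stats::runif(n, spec$weight_range[1], spec$weight_range[2])
  sexes <- ifelse(stats::runif(n) < spec$sex_ratio, "M", "F")
  enz <- names(spec$variability)
  draws <- vapply(spec$variability, function(cv) rlnorm_cv(n, cv), numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, enz))
  lapply(seq_len(n), function(i) {
    ab <- if (length(enz)) stats::setNames(draws[i, ], enz) else numeric(0)
    build_reference_individual(age = ages[i], weight = wts[i], sex = sexes[i],
                               enzyme_abundance = ab)
  })
}
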