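## compound: physicochemical, kinetic and inhibition definitions of one
## molecular species, plus the shipped parameterizations of the five drugs
## in the ayahuasca/SSRI interaction network (DMT, harmine, fluoxetine,
## norfluoxetine, paroxetine).
##
## Metabolic processes are tagged with the enzyme that carries them so that
## inhibition specs couple perpetrators to victims through shared enzyme
## pools (site-specific: liver or gut wall).

#' Define a compound
#'
#' @param name compound identifier (used in regimens and outputs).
#' @param MW molecular weight, g/mol.
#' @param logP octanol:water log partition coefficient.
#' @param pKa numeric vector of ionization constants.
#' @param pKa_type character vector, `"base"`/`"acid"` per pKa.
#' @param fu unbound fraction in plasma, (0, 1].
#' @param blood_plasma_ratio blood:plasma concentration ratio.
#' @param solubility mg/mL (recorded; dissolution is not modelled).
#' @param compound_type `"neutral"`, `"base"`, `"acid"` or `"zwitterion"`.
#' @param partition_method `"rodgers_rowland"` or `"schmitt"`.
#' @param ka first-order absorption rate (1/h), or `NULL` to derive it from
#'   lipophilicity via [ka_from_logP()] (so absorption responds to logP, as
#'   in permeability-based absorption models).
#' @param fabs fraction of drug leaving the gut lumen that enters the gut
#'   wall (the remainder is counted unabsorbed).
#' @param processes named list of [process_mm()], [process_linear()],
#'   [process_renal()] elimination/biotransformation routes.
#' @param inhibition named list of [inhibition_competitive()],
#'   [inhibition_tdi()] specs exerted *by* this compound on enzyme pools.
#' @param kp_override scalar or tissue-named numeric vector of partition
#'   coefficients bypassing the prediction methods (used for reduced
#'   verification models).
#' @return object of class `compound`.
#' @export
compound <- function(name, MW, logP, pKa = numeric(0),
                     pKa_type = character(0), fu, blood_plasma_ratio = 1,
                     solubility = NA_real_,
                     compound_type = c("base", "neutral", "acid", "zwitterion"),
                     partition_method = c("rodgers_rowland", "schmitt"),
                     ka = NULL, fabs = 0.9,
                     processes = list(), inhibition = list(),
                     kp_override = NULL) {
  compound_type <- match.arg(compound_type)
  partition_method <- match.arg(partition_method)
  obj <- structure(list(
    name = name, MW = MW, logP = logP, pKa = pKa, pKa_type = pKa_type,
    fu = fu, blood_plasma_ratio = blood_plasma_ratio,
    solubility = solubility, compound_type = compound_type,
    partition_method = partition_method, ka = ka, fabs = fabs,
    processes = processes, inhibition = inhibition,
    kp_override = kp_override
  ), class = "compound")
  validate_compound(obj)
  obj
}

validate_compound <- function(x) {
  check_positive(x$MW, "MW")
  check_fraction(x$fu, "fu_plasma", allow_zero = FALSE)
  check_positive(x$blood_plasma_ratio, "blood_plasma_ratio")
  if (length(x$pKa) != length(x$pKa_type))
    abort_validation("pKa and pKa_type lengths differ", "pKa")
  if (length(x$pKa_type) && !all(x$pKa_type %in% c("acid", "base")))
    abort_validation("pKa_type entries must be 'acid' or 'base'", "pKa_type")
  if (x$compound_type %||% "base" == "base" && length(x$pKa) &&
      !any(x$pKa_type == "base"))
    abort_validation("compound_type 'base' requires a basic pKa", "compound_type")
  check_fraction(x$fabs %||% 0.9, "fabs", allow_zero = FALSE)
  for (p in x$processes) stopifnot(inherits(p, "process_spec"))
  for (i in x$inhibition) stopifnot(inherits(i, "inhibition_spec"))
  invisible(x)
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s: MW %.1f, logP %.2f, fu %.3f, %s/%s\n",
              x$name, x$MW, x$logP, x$fu, x$compound_type, x$partition_method))
  if (length(x$processes))
    cat("  processes:", paste(names(x$processes), collapse = ", "), "\n")
  if (length(x$inhibition))
    cat("  inhibits:", paste(vapply(x$inhibition, function(i)
      sprintf("%s (%s)", i$enzyme, i$mode), ""), collapse = ", "), "\n")
  invisible(x)
}

#' Absorption rate constant from lipophilicity
#'
#' Saturable permeability correlation `ka = ka_max * L / (1 + L)` with
#' `L = 10^(slope * (logP - logP_ref))`.  Keeps absorption monotone in
#' logP while bounded above, mirroring permeability-limited oral uptake.
#'
#' @param logP compound lipophilicity.
#' @param ka_max maximal absorption rate, 1/h.
#' @param slope,logP_ref correlation shape parameters.
#' @return ka in 1/h.
#' @export
ka_from_logP <- function(logP, ka_max = 1.6, slope = 0.55, logP_ref = 2.6) {
  L <- 10^(slope * (logP - logP_ref))
  ka_max * L / (1 + L)
}

## Process specs ------------------------------------------------------------

#' Metabolic and excretion process specifications
#'
#' `process_mm()` is a Michaelis-Menten enzymatic route
#' (`v = kcat * E * Cu / (Km + Cu)`, driven by the unbound tissue
#' concentration at the site); `process_linear()` an unbound intrinsic
#' clearance (`v = CLint_u * Cu`), optionally enzyme-tagged so it can be
#' inhibited; `process_renal()` a linear renal clearance referenced to
#' kidney venous-equilibrium plasma.
#'
#' @param enzyme enzyme pool name (e.g. `"CYP2D6"`, `"MAOA"`), or `NULL`
#'   for a non-inhibitable route.
#' @param site `"liver"` or `"gut_wall"`.
#' @param Km Michaelis constant, umol/L (unbound).
#' @param kcat_per_min turnover number, 1/min.
#' @param enzyme_conc_um enzyme concentration in the site tissue, umol/L.
#' @param CLint_u unbound intrinsic clearance, L/h.
#' @param CL_renal_L_h renal plasma clearance, L/h.
#' @param fraction_to_metabolite fraction of the metabolic flux that forms
#'   `metabolite` (a compound name co-simulated in the same model).
#' @param metabolite compound name receiving the formed mass, or `NULL`.
#' @return object of class `process_spec`.
#' @name process_spec
NULL

#' @rdname process_spec
#' @export
process_mm <- function(enzyme, site = c("liver", "gut_wall"), Km,
                       kcat_per_min, enzyme_conc_um,
                       fraction_to_metabolite = 0, metabolite = NULL) {
  site <- match.arg(site)
  check_positive(Km, "Km"); check_positive(kcat_per_min, "kcat")
  check_positive(enzyme_conc_um, "enzyme_conc")
  check_fraction(fraction_to_metabolite, "fraction_to_metabolite")
  structure(list(kind = "enzymatic_mm", enzyme = enzyme, site = site,
                 Km = Km, kcat_per_min = kcat_per_min,
                 enzyme_conc_um = enzyme_conc_um,
                 fraction_to_metabolite = fraction_to_metabolite,
                 metabolite = metabolite),
            class = "process_spec")
}

#' @rdname process_spec
#' @export
process_linear <- function(CLint_u, enzyme = NULL,
                           site = c("liver", "gut_wall"),
                           fraction_to_metabolite = 0, metabolite = NULL) {
  site <- match.arg(site)
  check_positive(CLint_u, "CLint")
  check_fraction(fraction_to_metabolite, "fraction_to_metabolite")
  structure(list(kind = "linear_intrinsic", enzyme = enzyme, site = site,
                 CLint_u = CLint_u,
                 fraction_to_metabolite = fraction_to_metabolite,
                 metabolite = metabolite),
            class = "process_spec")
}

#' @rdname process_spec
#' @export
process_renal <- function(CL_renal_L_h) {
  check_positive(CL_renal_L_h, "CL_renal")
  structure(list(kind = "renal_linear", enzyme = NULL, site = "kidney",
                 CL_renal_L_h = CL_renal_L_h,
                 fraction_to_metabolite = 0, metabolite = NULL),
            class = "process_spec")
}

## Inhibition specs ---------------------------------------------------------

#' Enzyme inhibition specifications
#'
#' `inhibition_competitive()` scales the apparent Km (or divides a linear
#' intrinsic clearance) by `1 + sum(Cu_I / Ki)`; reversible MAO-A inhibition
#' by harmine is this mechanism applied to the MAO-A pools
#' (`inhibition_maoa()` is an explicit alias).  `inhibition_tdi()` is
#' mechanism-based inactivation: the enzyme pool obeys
#' `dE/dt = kdeg * (1 - E) - kinact * Cu / (KI + Cu) * E`.
#'
#' @param enzyme enzyme pool attacked.
#' @param Ki reversible inhibition constant, umol/L (unbound).
#' @param KI half-maximal inactivation concentration, umol/L (unbound).
#' @param kinact_per_h maximal inactivation rate, 1/h.
#' @param kdeg_per_h enzyme degradation/resynthesis rate, 1/h (default
#'   corresponds to the ~51 h CYP2D6 turnover half-life).
#' @return object of class `inhibition_spec`.
#' @name inhibition_spec
NULL

#' @rdname inhibition_spec
#' @export
inhibition_competitive <- function(enzyme, Ki) {
  check_positive(Ki, "Ki")
  structure(list(mode = "competitive", enzyme = enzyme, Ki = Ki),
            class = "inhibition_spec")
}

#' @rdname inhibition_spec
#' @export
inhibition_maoa <- function(Ki) {
  out <- inhibition_competitive("MAOA", Ki)
  out$mode <- "reversible_maoa"
  out
}

#' @rdname inhibition_spec
#' @export
inhibition_tdi <- function(enzyme, KI, kinact_per_h, kdeg_per_h = 0.0136) {
  check_positive(KI, "KI"); check_positive(kinact_per_h, "kinact")
  check_positive(kdeg_per_h, "kdeg")
  structure(list(mode = "mechanism_based", enzyme = enzyme, KI = KI,
                 kinact_per_h = kinact_per_h, kdeg_per_h = kdeg_per_h),
            class = "inhibition_spec")
}

## Shipped compound library -------------------------------------------------

#' Shipped compound definitions for the ayahuasca/SSRI interaction network
#'
#' Physicochemistry from public compound databases; inhibition constants
#' from the in-vitro/in-vivo DDI literature; metabolic intrinsic clearances
#' and the harmine CYP2D6 turnover calibrated against observed oral
#' ayahuasca plasma exposure (see the methods vignette).  All values are
#' plain list entries and can be edited with [config_set()].
#'
#' DMT is cleared overwhelmingly by MAO-A in the gut wall and liver
#' (oral inactivity without inhibitor), secondarily by CYP2D6.  Harmine is
#' a high-extraction CYP substrate (CYP2D6 fraction ~0.2) and a potent
#' reversible MAO-A inhibitor.  Fluoxetine is a competitive CYP2D6
#' inhibitor and substrate forming norfluoxetine (shared-pool
#' auto-inhibition gives nonlinear accumulation); paroxetine is a
#' mechanism-based CYP2D6 inactivator.
#'
#' @param names subset of compounds to return.
#' @return named list of `compound` objects.
#' @export
default_compounds <- function(names = c("DMT", "HRM", "FL", "NFL", "PR")) {
  lib <- list(
    DMT = compound(
      name = "DMT", MW = 188.27, logP = 2.57,
      pKa = 8.68, pKa_type = "base", fu = 0.35, blood_plasma_ratio = 1.0,
      solubility = 1.0, compound_type = "base",
      partition_method = "rodgers_rowland", ka = NULL, fabs = 0.9,
      processes = list(
        maoa_gut = process_linear(CLint_u = 3800, enzyme = "MAOA",
                                  site = "gut_wall"),
        maoa_liver = process_linear(CLint_u = 4400, enzyme = "MAOA",
                                    site = "liver"),
        cyp2d6 = process_linear(CLint_u = 1400, enzyme = "CYP2D6",
                                site = "liver"),
        renal = process_renal(CL_renal_L_h = 5)
      )
    ),
    HRM = compound(
      name = "HRM", MW = 212.25, logP = 3.5,
      pKa = 7.7, pKa_type = "base", fu = 0.25, blood_plasma_ratio = 1.0,
      solubility = 0.04, compound_type = "base",
      partition_method = "rodgers_rowland", ka = NULL, fabs = 0.85,
      processes = list(
        ## CYP2D6 O-demethylation: kcat optimized from the 29.7 1/min
        ## literature start against observed oral exposure
        cyp2d6 = process_mm(enzyme = "CYP2D6", site = "liver", Km = 0.9,
                            kcat_per_min = 55, enzyme_conc_um = 0.50),
        cyp_other = process_linear(CLint_u = 6700, enzyme = "CYP_other",
                                   site = "liver"),
        renal = process_renal(CL_renal_L_h = 2)
      ),
      inhibition = list(
        maoa = inhibition_maoa(Ki = 0.005)
      )
    ),
    FL = compound(
      name = "FL", MW = 309.33, logP = 4.05,
      pKa = 9.8, pKa_type = "base", fu = 0.056, blood_plasma_ratio = 1.0,
      solubility = 0.014, compound_type = "base",
      partition_method = "schmitt", ka = 0.7, fabs = 0.85,
      processes = list(
        cyp2d6 = process_linear(CLint_u = 1500, enzyme = "CYP2D6",
                                site = "liver",
                                fraction_to_metabolite = 0.9,
                                metabolite = "NFL"),
        cyp_other = process_linear(CLint_u = 500, enzyme = "CYP_other",
                                   site = "liver",
                                   fraction_to_metabolite = 0.5,
                                   metabolite = "NFL")
      ),
      inhibition = list(
        cyp2d6 = inhibition_competitive("CYP2D6", Ki = 0.01)
      )
    ),
    NFL = compound(
      name = "NFL", MW = 295.30, logP = 3.9,
      pKa = 9.8, pKa_type = "base", fu = 0.06, blood_plasma_ratio = 1.0,
      solubility = 0.02, compound_type = "base",
      partition_method = "schmitt", ka = 0.7, fabs = 0.85,
      processes = list(
        cyp2d6 = process_linear(CLint_u = 250, enzyme = "CYP2D6",
                                site = "liver"),
        cyp_other = process_linear(CLint_u = 120, enzyme = "CYP_other",
                                   site = "liver")
      ),
      inhibition = list(
        cyp2d6 = inhibition_competitive("CYP2D6", Ki = 0.008)
      )
    ),
    PR = compound(
      name = "PR", MW = 329.37, logP = 3.6,
      pKa = 9.9, pKa_type = "base", fu = 0.05, blood_plasma_ratio = 1.0,
      solubility = 0.035, compound_type = "base",
      partition_method = "rodgers_rowland", ka = 1.0, fabs = 0.9,
      processes = list(
        cyp2d6 = process_mm(enzyme = "CYP2D6", site = "liver", Km = 0.5,
                            kcat_per_min = 30, enzyme_conc_um = 0.30),
        cyp3a4 = process_linear(CLint_u = 2000, enzyme = "CYP_other",
                                site = "liver"),
        renal = process_renal(CL_renal_L_h = 1)
      ),
      inhibition = list(
        cyp2d6_rev = inhibition_competitive("CYP2D6", Ki = 0.34),
        cyp2d6_tdi = inhibition_tdi("CYP2D6", KI = 0.34,
                                    kinact_per_h = 19)
      )
    )
  )
  missing <- setdiff(names, names(lib))
  if (length(missing))
    abort_validation(paste("unknown compound(s):", paste(missing, collapse = ", ")))
  lib[names]
}
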