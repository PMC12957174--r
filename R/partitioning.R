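## partitioning: tissue:plasma partition coefficient (Kp) prediction from
## physicochemistry, and steady-state distribution volume.
##
## Two mechanistic methods are provided:
##   * rodgers_rowland_kp(): the Rodgers & Rowland tissue-composition
##     equations.  Moderate-to-strong bases (basic pKa > 7, the harmine and
##     paroxetine case) partition into acidic phospholipids with an affinity
##     back-calculated from blood-cell binding; neutrals/acids/weak bases use
##     the extracellular-protein (albumin-ratio) term instead.
##   * schmitt_kp(): a Schmitt-type membrane-composition model in which the
##     neutral species partitions into neutral lipid with P = 10^logP, the
##     ionized species with a 20-fold lower affinity, cations bind acidic
##     phospholipids with enhanced (20x) affinity, and the whole unbound
##     tissue affinity is referenced to plasma through fu.
## Both are pure functions of (compound, tissue composition).

#' Load the shipped tissue composition table
#'
#' Water/lipid/phospholipid fractions, acidic phospholipid content,
#' tissue-to-plasma albumin ratios and intracellular pH per tissue, plus
#' `blood_cells` and `plasma` rows used to anchor the methods.
#'
#' @return data.frame, one row per tissue.
#' @export
tissue_composition <- function() {
  tc <- read_pkg_table("tissue_composition.tsv")
  stopifnot(all(tc$f_ew >= 0 & tc$f_ew <= 1), all(tc$f_iw >= 0 & tc$f_iw <= 1))
  tc
}

## Fraction ionized / Henderson-Hasselbalch helpers -------------------------

ionization_terms <- function(compound, pH) {
  ## returns X = 1 + sum of 10^(pKa - pH) for bases + 10^(pH - pKa) for acids
  x <- 1
  pka <- compound$pKa
  typ <- compound$pKa_type
  if (length(pka)) {
    for (i in seq_along(pka)) {
      x <- x + if (typ[i] == "base") 10^(pka[i] - pH) else 10^(pH - pka[i])
    }
  }
  x
}

strongest_basic_pka <- function(compound) {
  b <- compound$pKa[compound$pKa_type == "base"]
  if (length(b)) max(b) else -Inf
}

#' Tissue:plasma partition coefficients by the Rodgers-Rowland method
#'
#' @param compound a [compound()] definition.
#' @param tissues tissue composition table (defaults to the shipped one).
#' @param tissue_names tissues to compute; default all body tissues.
#' @param pH_p,pH_iw,pH_bc plasma, intracellular and blood-cell pH.
#' @param hematocrit fraction, used to back-calculate blood-cell binding.
#' @return object of class `partition_set`: list with `method`, `kp`
#'   (named numeric, tissue:plasma), and the inputs used.
#' @export
rodgers_rowland_kp <- function(compound, tissues = tissue_composition(),
                               tissue_names = NULL,
                               pH_p = 7.4, pH_iw = 7.0, pH_bc = 7.22,
                               hematocrit = 0.45) {
  validate_compound(compound)
  tc <- tissues
  body <- setdiff(tc$tissue, c("blood_cells", "plasma"))
  tissue_names <- tissue_names %||% body
  missing <- setdiff(tissue_names, tc$tissue)
  if (length(missing))
    abort_validation(paste("no tissue composition for:",
                           paste(missing, collapse = ", ")), "tissues")

  P <- 10^compound$logP
  fu <- compound$fu
  bp <- compound$blood_plasma_ratio
  pka_b <- strongest_basic_pka(compound)
  moderate_base <- is.finite(pka_b) && pka_b > 7

  Y <- ionization_terms(compound, pH_p)     # plasma
  lipid_term <- function(f_nl, f_np) (P * f_nl + (0.3 * P + 0.7) * f_np) / Y

  plasma <- tc[tc$tissue == "plasma", ]
  bc <- tc[tc$tissue == "blood_cells", ]

  if (moderate_base) {
    ## acidic-phospholipid association constant from blood-cell partitioning
    X_bc <- ionization_terms(compound, pH_bc)
    kpu_bc <- (bp - (1 - hematocrit)) / (hematocrit * fu)
    if (kpu_bc <= 0)
      abort_validation("blood:plasma ratio inconsistent with hematocrit/fu",
                       "blood_plasma_ratio")
    ka_ap <- (kpu_bc - (X_bc / Y) * bc$f_iw - lipid_term(bc$f_nl, bc$f_np)) *
      Y / (bc$ap_mg_g * 10^(pka_b - pH_bc))
    ka_ap <- max(ka_ap, 0)
  }

  kp <- vapply(tissue_names, function(tn) {
    t <- tc[tc$tissue == tn, ]
    X_iw <- ionization_terms(compound, t$pH)
    base_terms <- t$f_ew + (X_iw / Y) * t$f_iw + lipid_term(t$f_nl, t$f_np)
    if (moderate_base) {
      kpu <- base_terms + ka_ap * t$ap_mg_g * 10^(pka_b - t$pH) / Y
    } else {
      ## extracellular protein (albumin) term for neutrals/acids/weak bases
      prot <- (1 / fu - 1 - lipid_term(plasma$f_nl, plasma$f_np)) * t$alb_ratio
      kpu <- base_terms + max(prot, 0)
    }
    kpu * fu
  }, numeric(1))

  new_partition_set("rodgers_rowland", kp, compound)
}

#' Tissue:plasma partition coefficients by a Schmitt-type membrane model
#'
#' @inheritParams rodgers_rowland_kp
#' @param ion_lipid_factor affinity of the ionized species for neutral lipid
#'   relative to the neutral species.
#' @param cation_ap_factor electrostatic enhancement of cation binding to
#'   acidic phospholipids.
#' @return object of class `partition_set`.
#' @export
schmitt_kp <- function(compound, tissues = tissue_composition(),
                       tissue_names = NULL, pH_p = 7.4,
                       ion_lipid_factor = 0.05, cation_ap_factor = 20) {
  validate_compound(compound)
  tc <- tissues
  body <- setdiff(tc$tissue, c("blood_cells", "plasma"))
  tissue_names <- tissue_names %||% body
  missing <- setdiff(tissue_names, tc$tissue)
  if (length(missing))
    abort_validation(paste("no tissue composition for:",
                           paste(missing, collapse = ", ")), "tissues")

  P <- 10^compound$logP
  fu <- compound$fu

  frac_species <- function(pH) {
    ## fractions (neutral, cation, anion) from the strongest pKa of each type
    pka_b <- strongest_basic_pka(compound)
    pka_a <- { a <- compound$pKa[compound$pKa_type == "acid"]
               if (length(a)) min(a) else Inf }
    rb <- if (is.finite(pka_b)) 10^(pka_b - pH) else 0
    ra <- if (is.finite(pka_a)) 10^(pH - pka_a) else 0
    tot <- 1 + rb + ra
    c(n = 1 / tot, cat = rb / tot, an = ra / tot)
  }

  kp <- vapply(tissue_names, function(tn) {
    t <- tc[tc$tissue == tn, ]
    fs <- frac_species(t$pH)
    k_nl <- P * (fs["n"] + ion_lipid_factor * (fs["cat"] + fs["an"]))
    k_np <- 0.3 * k_nl + 0.7
    k_ap <- k_np * (fs["n"] + cation_ap_factor * fs["cat"] +
                    ion_lipid_factor * fs["an"])
    f_ap <- t$ap_mg_g / 1000          # mg/g ~ volume fraction
    kpu <- (t$f_ew + t$f_iw) + k_nl * t$f_nl + k_np * t$f_np + k_ap * f_ap
    unname(kpu * fu)
  }, numeric(1))

  new_partition_set("schmitt", kp, compound)
}

new_partition_set <- function(method, kp, compound) {
  if (any(!is.finite(kp)) || any(kp <= 0))
    abort_validation("computed Kp values must be positive and finite", "kp")
  structure(list(method = method, kp = kp, compound = compound$name),
            class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> %s, method %s\n", x$compound, x$method))
  print(round(x$kp, 3))
  invisible(x)
}

#' Steady-state volume of distribution from a partition set
#'
#' `Vss = sum(V_t * Kp_t) + V_plasma`, with plasma volume taken as the
#' non-cellular fraction of blood volume.
#'
#' @param partition a `partition_set`.
#' @param phys a `physiology`.
#' @return Vss in litres.
#' @export
vss_from_kps <- function(partition, phys) {
  stopifnot(inherits(partition, "partition_set"), inherits(phys, "physiology"))
  org <- phys$organs
  v_blood <- sum(org$volume_L[org$organ %in% c("arterial", "venous", "portal")])
  v_plasma <- v_blood * (1 - phys$hematocrit)
  tn <- names(partition$kp)
  vt <- org$volume_L[match(tn, org$organ)]
  if (any(is.na(vt)))
    abort_validation(paste("physiology lacks organs:",
                           paste(tn[is.na(vt)], collapse = ", ")), "organs")
  sum(vt * partition$kp) + v_plasma
}
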