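## Reduced verification anatomies and toy compounds used across the suite.

## A physiology whose tissues mix with blood on a ~2 s timescale, so the
## whole body behaves as one well-stirred compartment (V_eff = total
## volume); flows are large enough that flow-limited errors are < 0.1%.
one_comp_phys <- function(gastric_emptying_h = 0) {
  organs <- data.frame(
    organ = c("lung", "adipose", "bone", "brain", "gut", "heart", "kidney",
              "liver", "muscle", "skin", "spleen", "arterial", "venous",
              "portal"),
    volume_L = c(rep(5.65, 11), 1.8, 3.4, 0.6),
    blood_flow_L_h = c(NA, rep(1e4, 10), NA, NA, NA),
    stringsAsFactors = FALSE)
  physiology(organs, cardiac_output = 1e5, body_weight = 75,
             gastric_emptying_h = gastric_emptying_h, validate = FALSE)
}

one_comp_volume <- function(phys = one_comp_phys()) sum(phys$organs$volume_L)

## Linear toy compound: unit partitioning, no binding, renal clearance only.
toy_compound <- function(name = "TOY", CL = NULL, ka = 1, MW = 100,
                         fabs = 1, processes = NULL, inhibition = list()) {
  if (is.null(processes))
    processes <- list(renal = process_renal(CL %||% 7))
  compound(name = name, MW = MW, logP = 1, pKa = 9, pKa_type = "base",
           fu = 1, blood_plasma_ratio = 1, ka = ka, fabs = fabs,
           processes = processes, inhibition = inhibition, kp_override = 1)
}

iv_regimen <- function(compound, amount_mg, time_h = 0) {
  regimen(data.frame(compound = compound, route = "iv",
                     amount_mg = amount_mg, time_h = time_h,
                     stringsAsFactors = FALSE))
}

oral_regimen <- function(compound, amount_mg, time_h = 0) {
  regimen(data.frame(compound = compound, route = "oral",
                     amount_mg = amount_mg, time_h = time_h,
                     stringsAsFactors = FALSE))
}

## geometric output grid: resolves the fast venous mixing transient after
## an IV bolus so trapezoidal AUCs are accurate
geom_times <- function(t_end, t0 = 1e-5, n = 800) {
  sort(unique(c(0, exp(seq(log(t0), log(t_end), length.out = n)))))
}

## constant-inhibitor model: no-clearance IV inhibitor in a one-compartment
## collapse keeps Cu exactly constant after mixing
constant_inhibitor_model <- function(Ki = NULL, tdi = NULL, victim_CLint = 20) {
  vict <- toy_compound(name = "VIC", processes = list(
    p = process_linear(victim_CLint, enzyme = "E1", site = "liver")))
  inh <- compound(name = "INH", MW = 100, logP = 1, pKa = 9,
                  pKa_type = "base", fu = 1, ka = 1,
                  kp_override = 1,
                  inhibition = c(
                    if (!is.null(Ki)) list(k = inhibition_competitive("E1", Ki)),
                    if (!is.null(tdi)) list(t = tdi)))
  pbpk_model(list(VIC = vict, INH = inh), one_comp_phys())
}

aya_model <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- pbpk_model(default_compounds(c("DMT", "HRM")))
    val
  }
})
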