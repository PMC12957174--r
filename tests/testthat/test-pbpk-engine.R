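test_that("mass balance holds to well below 1e-6 on a full co-simulation", {
  prof <- simulate_profile(aya_model(), ddi_protocol("ayahuasca_only", 75),
                           t_end = 12, dt_out = 0.1)
  mb <- check_mass_balance(prof)
  expect_true(all(mb$max_rel_residual < 1e-6))
  ## non-negativity of reported concentrations
  expect_true(all(prof$conc_ng_ml >= 0))
})

test_that("IV bolus with linear clearance gives AUC = Dose/CL within 0.1%", {
  CL <- 7
  m <- pbpk_model(list(TOY = toy_compound(CL = CL)), one_comp_phys())
  prof <- simulate_profile(m, iv_regimen("TOY", 100), t_end = 120,
                           times = geom_times(120))
  auc <- nca(prof, "TOY", extrapolate_to = 1000)$auc_extrapolated
  ## dose 100 mg = 1000 umol at MW 100; AUC in ng.h/mL = ug.h/L
  expect_equal(auc, 100e3 / CL, tolerance = 1e-3)
})

test_that("oral one-compartment collapse reproduces the Bateman Tmax", {
  ka <- 1
  phys <- one_comp_phys(gastric_emptying_h = 0)   # dose straight to lumen
  V <- one_comp_volume(phys)
  ke <- 0.1
  m <- pbpk_model(list(TOY = toy_compound(CL = ke * V, ka = ka)), phys)
  prof <- simulate_profile(m, oral_regimen("TOY", 50), t_end = 12,
                           dt_out = 0.01)
  tmax_pred <- log(ka / ke) / (ka - ke)       # 2.558 h
  expect_equal(nca(prof, "TOY")$tmax, tmax_pred, tolerance = 0.01)
})

test_that("doubling the dose doubles concentrations in an all-linear model", {
  m <- pbpk_model(list(TOY = toy_compound(CL = 10)), one_comp_phys(0.25))
  p1 <- simulate_profile(m, oral_regimen("TOY", 20), t_end = 24, dt_out = 0.25)
  p2 <- simulate_profile(m, oral_regimen("TOY", 40), t_end = 24, dt_out = 0.25)
  i <- p1$conc_ng_ml > 1e-6
  expect_equal(p2$conc_ng_ml[i] / p1$conc_ng_ml[i],
               rep(2, sum(i)), tolerance = 1e-6)
})

test_that("QD multidose equals superposed shifted single doses (linearity)", {
  m <- pbpk_model(list(TOY = toy_compound(CL = 10)), one_comp_phys(0.25))
  multi <- regimen(data.frame(compound = "TOY", route = "oral",
                              amount_mg = 20, time_h = c(0, 24, 48)))
  pm <- simulate_profile(m, multi, t_end = 72, dt_out = 0.25)
  ps <- simulate_profile(m, oral_regimen("TOY", 20), t_end = 72, dt_out = 0.25)
  sm <- pm$conc_ng_ml
  tt <- pm$time_h
  single <- function(t) {
    out <- numeric(length(t))
    ok <- t >= 0
    out[ok] <- ps$conc_ng_ml[match(round(t[ok], 6), round(ps$time_h, 6))]
    out
  }
  super <- single(tt) + single(tt - 24) + single(tt - 48)
  i <- super > 1e-3 * max(super)
  expect_equal(sm[i], super[i], tolerance = 1e-3)
})

test_that("Michaelis-Menten at Km >> Cu with kcat*E/Km fixed matches the linear model", {
  phys <- one_comp_phys(0.25)
  CLint <- 40
  Km <- 1e5; Econc <- 1; Vliver <- 5.65
  kcat_min <- CLint * Km / (60 * Econc * Vliver)
  mm <- toy_compound(processes = list(
    p = process_mm("E1", site = "liver", Km = Km, kcat_per_min = kcat_min,
                   enzyme_conc_um = Econc)))
  lin <- toy_compound(processes = list(
    p = process_linear(CLint, enzyme = "E1", site = "liver")))
  p_mm <- simulate_profile(pbpk_model(list(TOY = mm), phys),
                           oral_regimen("TOY", 20), t_end = 24, dt_out = 0.25)
  p_lin <- simulate_profile(pbpk_model(list(TOY = lin), phys),
                            oral_regimen("TOY", 20), t_end = 24, dt_out = 0.25)
  i <- p_lin$conc_ng_ml > 1e-3 * max(p_lin$conc_ng_ml)
  expect_equal(p_mm$conc_ng_ml[i], p_lin$conc_ng_ml[i], tolerance = 5e-3)
})

test_that("zero dose yields an all-zero profile and dangling references error", {
  m <- pbpk_model(list(TOY = toy_compound(CL = 10)), one_comp_phys())
  prof <- simulate_profile(m, regimen(data.frame(
    compound = character(0), route = character(0), amount_mg = numeric(0),
    time_h = numeric(0))), t_end = 10, dt_out = 0.5)
  expect_true(all(prof$conc_ng_ml == 0))

  bad <- toy_compound(processes = list(
    p = process_linear(10, site = "liver", fraction_to_metabolite = 0.5,
                       metabolite = "GHOST")))
  expect_error(pbpk_model(list(TOY = bad), one_comp_phys()), "GHOST")
})

test_that("suppressing MAO-A clearance uncovers oral DMT exposure (>= 10-fold)", {
  cps <- default_compounds("DMT")
  reg <- oral_regimen("DMT", 50)
  m1 <- pbpk_model(cps)
  spec <- m1$spec
  for (p in c("compounds/DMT/processes/maoa_gut/CLint_u",
              "compounds/DMT/processes/maoa_liver/CLint_u"))
    spec <- config_set(spec, p, 1e-6)
  m0 <- rebuild_model(spec)
  auc1 <- nca(simulate_profile(m1, reg, 12, dt_out = 0.05), "DMT")$auc_0_t
  auc0 <- nca(simulate_profile(m0, reg, 12, dt_out = 0.05), "DMT")$auc_0_t
  expect_gt(auc0 / auc1, 10)
})

test_that("metabolite formation transfers mass stoichiometrically", {
  phys <- one_comp_phys(0.25)
  parent <- toy_compound(name = "PAR", processes = list(
    p = process_linear(30, site = "liver", fraction_to_metabolite = 0.6,
                       metabolite = "MET")))
  met <- toy_compound(name = "MET", CL = 5)
  m <- pbpk_model(list(PAR = parent, MET = met), phys)
  prof <- simulate_profile(m, oral_regimen("PAR", 10), t_end = 200,
                           dt_out = 0.5)
  st <- attr(prof, "state")
  last <- st[nrow(st), ]
  ## at completion, formed metabolite = 0.6 * eliminated parent
  expect_equal(unname(last["MET.formed"]),
               unname(0.6 * last["PAR.elim"]), tolerance = 1e-6)
  mb <- check_mass_balance(prof)
  expect_true(all(mb$max_rel_residual < 1e-6))
})
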