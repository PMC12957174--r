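test_that("competitive factor and MAO-A coupling match their definitions", {
  expect_equal(competitive_rate_factor(0, 1), 1)
  expect_equal(competitive_rate_factor(2, 2), 2)
  ## two inhibitors at I1 = Ki1 and I2 = 2*Ki2 -> factor 4
  expect_equal(competitive_rate_factor(c(1, 4), c(1, 2)), 4)
  expect_equal(maoa_coupling(0, 0.005), 1)
  expect_equal(maoa_coupling(0.005, 0.005), 0.5)
})

test_that("TDI dynamics: baseline steady state and closed-form E_ss", {
  expect_equal(tdi_enzyme_dynamics(1, 0, 1, 2, 0.1), 0)
  ## kinact = kdeg and I >> KI -> E_ss = 0.5
  expect_equal(tdi_steady_state(1e6, 1, 0.1, 0.1), 0.5, tolerance = 1e-5)
  ## derivative is zero at the closed-form steady state
  ess <- tdi_steady_state(0.5, 0.3, 2, 0.05)
  expect_equal(tdi_enzyme_dynamics(ess, 0.5, 0.3, 2, 0.05), 0)
})

test_that("victim AUC ratio equals 1 + Iu/Ki under constant competitive inhibition", {
  Ki <- 0.5
  m <- constant_inhibitor_model(Ki = Ki)
  V <- one_comp_volume()
  dose_mg <- 0.75 * V * 100 / 1000    # gives Cu = 0.75 umol/L everywhere
  both <- regimen(data.frame(compound = c("INH", "VIC"), route = "iv",
                             amount_mg = c(dose_mg, 10), time_h = 0))
  alone <- iv_regimen("VIC", 10)
  p1 <- simulate_profile(m, both, t_end = 400, times = geom_times(400))
  p0 <- simulate_profile(m, alone, t_end = 400, times = geom_times(400))
  auc1 <- nca(p1, "VIC", extrapolate_to = 5000)$auc_extrapolated
  auc0 <- nca(p0, "VIC", extrapolate_to = 5000)$auc_extrapolated
  expect_equal(auc1 / auc0, 1 + 0.75 / Ki, tolerance = 0.02)
})

test_that("enzyme pool reaches the closed-form steady state under constant exposure", {
  kinact <- 2; KI <- 0.3; kdeg <- 0.05
  m <- constant_inhibitor_model(
    tdi = inhibition_tdi("E1", KI = KI, kinact_per_h = kinact,
                         kdeg_per_h = kdeg))
  V <- one_comp_volume()
  Cu <- 0.6
  reg <- iv_regimen("INH", Cu * V * 100 / 1000)
  prof <- simulate_profile(m, reg, t_end = 300, dt_out = 1)
  st <- attr(prof, "state")
  e_end <- st[nrow(st), "pool.E1.liver"]
  expect_equal(unname(e_end), tdi_steady_state(Cu, KI, kinact, kdeg),
               tolerance = 5e-3)
})

test_that("enzyme recovers with rate kdeg after inactivator washout", {
  kdeg <- 0.08
  vict <- toy_compound(name = "VIC", processes = list(
    p = process_linear(20, enzyme = "E1", site = "liver")))
  ## rapidly cleared inactivator: exposure step then washout
  inh <- compound(name = "INH", MW = 100, logP = 1, pKa = 9,
                  pKa_type = "base", fu = 1, ka = 2, kp_override = 1,
                  processes = list(renal = process_renal(300)),
                  inhibition = list(t = inhibition_tdi(
                    "E1", KI = 0.05, kinact_per_h = 5, kdeg_per_h = kdeg)))
  m <- pbpk_model(list(VIC = vict, INH = inh), one_comp_phys())
  prof <- simulate_profile(m, iv_regimen("INH", 40), t_end = 60, dt_out = 0.5)
  st <- attr(prof, "state")
  tt <- st[, "time"]; ee <- st[, "pool.E1.liver"]
  ## inhibitor t1/2 ~ 0.16 h: by t = 10 h washout is complete
  i1 <- which(tt == 20); i2 <- which(tt == 40)
  slope <- (log(1 - ee[i2]) - log(1 - ee[i1])) / (tt[i2] - tt[i1])
  expect_equal(unname(-slope), kdeg, tolerance = 0.01)
})

test_that("removing inhibition specs reproduces victim-alone kinetics", {
  ## perpetrator defined but never dosed -> baseline identical to a model
  ## with the inhibition specs stripped
  m_full <- aya_model()
  spec <- m_full$spec
  spec$compounds$HRM$inhibition <- list()
  m_stripped <- rebuild_model(spec)
  reg <- ddi_protocol("ayahuasca_only", 75)
  p1 <- simulate_profile(m_full, reg, 12, dt_out = 0.1)
  p2 <- simulate_profile(m_stripped, reg, 12, dt_out = 0.1)
  ## HRM does not inhibit its own pathways: identical HRM profile
  h1 <- p1$conc_ng_ml[p1$compound == "HRM"]
  h2 <- p2$conc_ng_ml[p2$compound == "HRM"]
  expect_equal(h1, h2, tolerance = 1e-6)
  ## DMT differs strongly (MAO-A no longer inhibited)
  d1 <- nca(p1, "DMT")$auc_0_t
  d2 <- nca(p2, "DMT")$auc_0_t
  expect_gt(d1 / d2, 5)
})

test_that("DMT exposure is monotone in harmine dose", {
  m <- aya_model()
  aucs <- vapply(c(40, 90, 132.75, 200), function(hd) {
    reg <- regimen(data.frame(compound = c("HRM", "DMT"), route = "oral",
                              amount_mg = c(hd, 50.25), time_h = 0))
    nca(simulate_profile(m, reg, 12, dt_out = 0.1), "DMT")$auc_0_t
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
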