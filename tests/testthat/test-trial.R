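test_that("protocol regimens encode the published dosing design", {
  r <- ddi_protocol("PR_14d", 75)
  ev <- r$events
  pr <- ev[ev$compound == "PR", ]
  expect_equal(nrow(pr), 14)
  expect_equal(pr$amount_mg, rep(20, 14))
  expect_equal(pr$time_h, (0:13) * 24)
  expect_equal(ev$amount_mg[ev$compound == "HRM"], 1.77 * 75)   # 132.75 mg
  expect_equal(ev$amount_mg[ev$compound == "DMT"], 0.67 * 75)   # 50.25 mg
  expect_equal(unique(ev$time_h[ev$compound %in% c("HRM", "DMT")]), 13 * 24)

  r0 <- ddi_protocol("ayahuasca_only", 75)
  expect_true(all(r0$events$compound %in% c("HRM", "DMT")))

  ## perpetrator dose independent of weight, substrate scaled by mg/kg
  r60 <- ddi_protocol("FL_5d", 60); r80 <- ddi_protocol("FL_5d", 80)
  expect_equal(r60$events$amount_mg[r60$events$compound == "FL"],
               r80$events$amount_mg[r80$events$compound == "FL"])
  expect_equal(r60$events$amount_mg[r60$events$compound == "DMT"] /
                 r80$events$amount_mg[r80$events$compound == "DMT"], 60 / 80)
  expect_error(ddi_protocol("XX_5d"))
})

test_that("nca reproduces trapezoid geometry and closed forms", {
  tri <- data.frame(time_h = c(0, 1, 2), conc_ng_ml = c(0, 10, 0))
  r <- nca(tri)
  expect_equal(r$auc_0_t, 10)
  expect_equal(r$cmax, 10)
  expect_equal(r$tmax, 1)

  const <- data.frame(time_h = 0:4, conc_ng_ml = rep(5, 5))
  expect_equal(nca(const)$auc_0_t, 20)

  tt <- seq(0, 12, by = 0.01)
  mono <- data.frame(time_h = tt, conc_ng_ml = 10 * exp(-0.5 * tt))
  expect_equal(nca(mono)$auc_0_t, (10 / 0.5) * (1 - exp(-6)), tolerance = 0.01)

  ## terminal extrapolation recovers the full integral of an exponential
  short <- data.frame(time_h = seq(0, 6, 0.05),
                      conc_ng_ml = 10 * exp(-0.5 * seq(0, 6, 0.05)))
  expect_equal(nca(short, extrapolate_to = 100)$auc_extrapolated, 20,
               tolerance = 0.01)

  ## invariant to redundant collinear points
  base <- data.frame(time_h = c(0, 2, 4), conc_ng_ml = c(0, 8, 0))
  dense <- data.frame(time_h = c(0, 1, 2, 3, 4), conc_ng_ml = c(0, 4, 8, 4, 0))
  expect_equal(nca(base)$auc_0_t, nca(dense)$auc_0_t)

  expect_error(nca(data.frame(time_h = c(0, 1), conc_ng_ml = c(1, 1))),
               "3 time points")
})

test_that("ddi ratios: identity, reciprocity and classification", {
  tt <- seq(0, 12, 0.05)
  a <- data.frame(time_h = tt, conc_ng_ml = 10 * exp(-0.4 * tt) *
                    (1 - exp(-2 * tt)))
  b <- a; b$conc_ng_ml <- 2.13 * a$conc_ng_ml

  same <- ddi_ratios(a, a, compound = NULL)
  expect_equal(same$auc_ratio, 1)
  expect_equal(same$cmax_ratio, 1)
  expect_equal(same$classification, "none")

  up <- ddi_ratios(b, a, compound = NULL)
  dn <- ddi_ratios(a, b, compound = NULL)
  expect_equal(up$auc_ratio * dn$auc_ratio, 1)
  expect_equal(up$cmax_ratio * dn$cmax_ratio, 1)
  expect_equal(up$auc_ratio, 2.13)
  expect_equal(up$classification, "moderate")

  expect_equal(classify_ddi(c(1.1, 1.27, 2.13, 7)),
               c("none", "weak", "moderate", "strong"))
})

test_that("mean fold error arithmetic and qualification window", {
  expect_equal(round(mfe(42.79, 49.16), 2), 0.87)
  expect_equal(floor(mfe(59.51, 38.49) * 100) / 100, 1.54)  # printed (truncated)
  expect_equal(round(mfe(822.96, 424.18), 2), 1.94)
  expect_equal(round(mfe(181.49, 111.79), 2), 1.62)
  expect_equal(mfe(3.7, 3.7), 1)
  expect_error(mfe(1, 0), "observed")

  q <- qualification_table(data.frame(
    compound = c("A", "B"), dataset = "d",
    predicted_auc = c(10, 30), observed_auc = c(10, 10),
    predicted_cmax = c(1, 1), observed_cmax = c(1, 1)))
  expect_equal(q$pass, c(TRUE, FALSE))
})
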