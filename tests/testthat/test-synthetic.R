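test_that("zero-noise, collapsed-demographics trial equals the ground truth", {
  m <- aya_model()
  d0 <- trial_design(n_subjects = 3, age_sd = 0, weight_sd = 0,
                     iiv = c(CYP2D6 = 0), residual_cv = 0, seed = 9)
  tr <- generate_trial(m, d0)
  prof <- simulate_profile(m, tr$dose_record, t_end = 4,
                           times = sort(unique(c(seq(0, 4, 0.05),
                                                 d0$sampling_times_h))))
  pdf <- as.data.frame(prof)
  for (cp in c("DMT", "HRM")) {
    truth <- pdf$conc_ng_ml[pdf$compound == cp][
      match(d0$sampling_times_h, pdf$time_h[pdf$compound == cp])]
    truth[truth < d0$lloq] <- NA
    for (s in 1:3) {
      obs <- tr$samples[tr$samples$compound == cp &
                          tr$samples$subject_id == s, ]
      expect_equal(obs$conc_ng_ml, truth, tolerance = 1e-8)
    }
  }
  ## mean-profile NCA on the zero-noise dataset equals ground-truth NCA
  sm <- summarize_trial(tr)
  smd <- sm[sm$compound == "DMT" & !is.na(sm$conc_ng_ml), ]
  auc_obs <- nca(smd[, c("time_h", "conc_ng_ml")])$auc_0_t
  auc_truth <- nca(prof, "DMT",
                   window = c(min(smd$time_h), max(smd$time_h)))$auc_0_t
  expect_equal(auc_obs, auc_truth, tolerance = 0.05)  # grid coarseness only
})

test_that("default design produces the clinical sampling layout, deterministically", {
  m <- aya_model()
  d <- trial_design(seed = 5)
  tr <- generate_trial(m, d)
  expect_equal(nrow(tr$subjects), 6)
  expect_equal(table(tr$subjects$sex)[["M"]], 4)
  expect_equal(nrow(tr$samples), 6 * 8 * 2)
  expect_equal(sort(unique(tr$samples$time_h)),
               c(0, 20, 40, 60, 90, 120, 180, 240) / 60)
  ## pre-dose and sub-LLOQ values are censored, everything else positive
  expect_true(all(is.na(tr$samples$conc_ng_ml) |
                    tr$samples$conc_ng_ml >= d$lloq))
  tr2 <- generate_trial(m, d)
  expect_identical(tr$samples, tr2$samples)
  expect_identical(tr$subjects, tr2$subjects)
})

test_that("summarize_trial computes mean and SEM per time point", {
  df <- data.frame(subject_id = c(1, 2), time_h = 1, compound = "DMT",
                   conc_ng_ml = c(8, 12))
  sm <- summarize_trial(df)
  expect_equal(sm$conc_ng_ml, 10)
  expect_equal(sm$sem, 2)
  one <- summarize_trial(df[1, ])
  expect_equal(one$conc_ng_ml, 8)
  expect_equal(one$sem, 0)
})

test_that("noisy mean profile stays within 3 SEM of the ground truth", {
  m <- aya_model()
  d <- trial_design(age_sd = 0, weight_sd = 0, iiv = c(CYP2D6 = 0),
                    residual_cv = 0.2, seed = 21)
  tr <- generate_trial(m, d)
  sm <- summarize_trial(tr)
  prof <- simulate_profile(m, tr$dose_record, t_end = 4,
                           times = sort(unique(c(seq(0, 4, 0.05),
                                                 d$sampling_times_h))))
  pdf <- as.data.frame(prof)
  sm <- sm[!is.na(sm$conc_ng_ml) & sm$n >= 4, ]
  for (k in seq_len(nrow(sm))) {
    truth <- pdf$conc_ng_ml[pdf$compound == sm$compound[k] &
                              abs(pdf$time_h - sm$time_h[k]) < 1e-9]
    expect_lt(abs(sm$conc_ng_ml[k] - truth), 3 * max(sm$sem[k], 1e-6))
  }
})
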