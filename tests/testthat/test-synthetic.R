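test_that("cohorts are reproducible bit for bit", {
  cfg <- quick_config(seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$meta, c2$meta)
  expect_identical(c1$recordings[[1]]$signals, c2$recordings[[1]]$signals)
  expect_identical(c1$layout, c2$layout)
})

test_that("the default cohort composition is 23 migraineurs (10 MwA) + 23 controls", {
  meta <- cohort_metadata(cohort_config(seed = 2))
  expect_equal(nrow(meta), 46)
  expect_equal(sum(meta$subgroup == "MwA"), 10)
  expect_equal(sum(meta$subgroup == "MwoA"), 13)
  expect_equal(sum(meta$group == "control"), 23)
  # subgroup is none exactly for controls
  expect_identical(meta$subgroup == "none", meta$group == "control")
})

test_that("a minimal two-subject cohort gets subgroups MwoA and none", {
  cfg <- cohort_config(n_migraine = 1, n_mwa = 0, n_control = 1,
                       n_channels = 8, sampling_rate = 200, duration_s = 2,
                       seed = 1)
  ch <- simulate_cohort(cfg)
  expect_equal(nrow(ch$meta), 2)
  expect_equal(ch$meta$subgroup, c("MwoA", "none"))
})

test_that("clinical covariates stay inside the demographic ranges", {
  meta <- cohort_metadata(cohort_config(seed = 5))
  mig <- meta[meta$group == "migraine", ]
  expect_true(all(meta$age >= 20 & meta$age <= 40))
  expect_true(all(mig$history >= 2 & mig$history <= 30))
  expect_true(all(mig$attack_frequency >= 1 & mig$attack_frequency <= 4))
  expect_true(all(mig$duration >= 1 & mig$duration <= 72))
  expect_true(all(mig$pain_intensity >= 3 & mig$pain_intensity <= 8))
  expect_true(all(mig$onset_to_scan >= 0))
  ctrl <- meta[meta$group == "control", ]
  expect_true(all(is.na(ctrl$history)))
})

test_that("earlier subjects are unchanged when the cohort grows", {
  small <- cohort_metadata(cohort_config(n_migraine = 3, n_mwa = 1,
                                         n_control = 2, seed = 9))
  big <- cohort_metadata(cohort_config(n_migraine = 3, n_mwa = 1,
                                       n_control = 10, seed = 9))
  expect_identical(small, big[seq_len(nrow(small)), ])
})

test_that("background noise follows the configured 1/f slope", {
  set.seed(4)
  fs <- 600; dur <- 64
  x <- megnet:::shaped_noise(dur * fs, 2, fs, exponent = 1, rms = 100)
  # Welch periodogram, 4 s segments
  nper <- 4 * fs
  starts <- seq(1, dur * fs - nper + 1, by = nper)
  psd <- 0
  for (s in starts) {
    seg <- x[s:(s + nper - 1), 1]
    psd <- psd + Mod(fft(seg * 0.5 * (1 - cos(2 * pi * seq_len(nper) / nper))))^2
  }
  f <- (seq_len(nper) - 1) * fs / nper
  keep <- f >= 1 & f <= 100
  fit <- lm(log(psd[keep]) ~ log(f[keep]))
  expect_lt(abs(coef(fit)[2] + 1), 0.2)
})

test_that("couplings raise within-region connectivity monotonically", {
  lay <- make_sensor_layout(10, seed = 2)
  res <- sapply(c(0.5, 1.5, 3), function(strength) {
    vals <- sapply(1:5, function(s) {
      cfg <- cohort_config(n_migraine = 1, n_mwa = 0, n_control = 0,
                           n_channels = 10, sampling_rate = 600,
                           duration_s = 12,
                           coupling_specs = list(
                             coupling_spec("theta", "frontal", 1, strength, 1)),
                           seed = s)
      rec <- simulate_subject(lay, cohort_metadata(cfg)[1, ], cfg, seed = s)
      cm <- pairwise_connectivity(bandpass(remove_dc(rec), "theta"))
      fr <- which(lay$regions == "frontal")
      wf <- cm$weights[fr, fr]
      mean(wf[upper.tri(wf)])
    })
    mean(vals)
  })
  expect_true(all(diff(res) >= 0))
})

test_that("without couplings channels are mutually independent", {
  cfg <- cohort_config(n_migraine = 1, n_mwa = 0, n_control = 0,
                       n_channels = 8, sampling_rate = 600,
                       duration_s = 40, seed = 3)
  lay <- make_sensor_layout(8, 3)
  rec <- simulate_subject(lay, cohort_metadata(cfg)[1, ], cfg, seed = 3)
  cm <- pairwise_connectivity(bandpass(remove_dc(rec), "alpha"))
  expect_lt(mean(abs(cm$weights[upper.tri(cm$weights)])), 0.45)
  # coherence shrinks as duration grows (more Welch segments)
  cfg2 <- cfg; cfg2$duration_s <- 10
  rec2 <- simulate_subject(lay, cohort_metadata(cfg2)[1, ], cfg2, seed = 3)
  cm2 <- pairwise_connectivity(bandpass(remove_dc(rec2), "alpha"))
  expect_lt(mean(abs(cm$weights[upper.tri(cm$weights)])),
            mean(abs(cm2$weights[upper.tri(cm2$weights)])))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_migraine = 2, n_mwa = 3), "n_mwa")
  expect_error(cohort_config(duration_s = 0), "duration")
  expect_error(coupling_spec("theta", "frontal", sign = 2), "sign")
  expect_error(coupling_spec("theta", "nowhere"), "unknown region")
  expect_error(coupling_spec("theta", "frontal", prevalence = 1.2),
               "prevalence")
  # sampling rate must support the coupling band
  expect_error(
    cohort_config(sampling_rate = 400,
                  coupling_specs = list(coupling_spec("ripple", "frontal"))),
    "sampling rate too low")
})
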