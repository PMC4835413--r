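# hand-built cohort tables for the statistical battery
toy_tables <- function(n_mig = 23, n_ctl = 23, seed = 1) {
  set.seed(seed)
  ids <- sprintf("sub-%03d", seq_len(n_mig + n_ctl))
  clinical <- data.frame(
    subject_id = ids,
    group = rep(c("migraine", "control"), c(n_mig, n_ctl)),
    subgroup = c(rep("MwA", 10), rep("MwoA", n_mig - 10),
                 rep("none", n_ctl)),
    age = sample(20:40, n_mig + n_ctl, TRUE),
    history = c(runif(n_mig, 2, 30), rep(NA, n_ctl)),
    attack_frequency = c(runif(n_mig, 1, 4), rep(NA, n_ctl)),
    duration = c(runif(n_mig, 1, 72), rep(NA, n_ctl)),
    pain_intensity = c(sample(3:8, n_mig, TRUE), rep(NA, n_ctl)),
    onset_to_scan = c(sample(3:20, n_mig, TRUE), rep(NA, n_ctl)),
    stringsAsFactors = FALSE)
  metrics <- data.frame(
    subject_id = rep(ids, each = 1), band = "slow",
    strength = runif(n_mig + n_ctl, 0.2, 0.4),
    path_length = runif(n_mig + n_ctl, 2, 4),
    clustering = runif(n_mig + n_ctl, 0.1, 0.3),
    stringsAsFactors = FALSE)
  patterns <- data.frame(
    subject_id = rep(ids, each = 1), band = "slow", roi = "frontal",
    excitatory = c(rep(TRUE, 17), rep(FALSE, n_mig - 17),
                   rep(TRUE, 2), rep(FALSE, n_ctl - 2)),
    inhibitory = FALSE, stringsAsFactors = FALSE)
  power <- data.frame(subject_id = ids, band = "slow",
                      power = runif(n_mig + n_ctl, 500, 1500),
                      stringsAsFactors = FALSE)
  list(clinical = clinical, metrics = metrics, patterns = patterns,
       power = power)
}

test_that("a strong prevalence difference is detected by the Fisher test", {
  tb <- toy_tables()
  res <- run_group_analysis(tb$metrics, tb$patterns, tb$clinical, tb$power)
  ft <- res$pattern_tests
  row <- ft[ft$roi == "frontal" & ft$connection_type == "excitatory" &
              ft$comparison == "migraine_vs_control", ]
  expect_equal(row$present1, 17)
  expect_equal(row$present2, 2)
  expect_lt(row$p_value, 0.05)
  expect_true(row$significant)
})

test_that("metric t-tests report the Bonferroni-corrected decision", {
  tb <- toy_tables(seed = 2)
  res <- run_group_analysis(tb$metrics, tb$patterns, tb$clinical)
  mt <- res$metric_tests
  expect_setequal(mt$metric, c("strength", "path_length", "clustering"))
  expect_true(all(mt$alpha_corrected == 0.05 / 3))
  expect_identical(mt$significant, mt$p_value < 0.05 / 3)
})

test_that("band-power ANOVA runs per band when a power table is given", {
  tb <- toy_tables(seed = 3)
  res <- run_group_analysis(tb$metrics, tb$patterns, tb$clinical, tb$power)
  expect_equal(nrow(res$power_anova), 1)
  expect_true(res$power_anova$p_value >= 0 && res$power_anova$p_value <= 1)
  res2 <- run_group_analysis(tb$metrics, tb$patterns, tb$clinical)
  expect_null(res2$power_anova)
})

test_that("clinical correlations cover covariates against metrics and patterns", {
  tb <- toy_tables(seed = 4)
  # make one deterministic association: strength increases with history
  mig <- tb$clinical$group == "migraine"
  tb$metrics$strength[mig] <-
    tb$clinical$history[mig] / 40
  res <- run_group_analysis(tb$metrics, tb$patterns, tb$clinical)
  cc <- res$clinical_correlations
  row <- cc[cc$covariate == "history" & cc$parameter == "strength", ]
  expect_equal(row$rho, 1)
  expect_true(row$significant)
  expect_true(any(grepl("frontal", cc$parameter)))
})

test_that("subjects missing from the clinical table abort with their ids", {
  tb <- toy_tables()
  tb$clinical <- tb$clinical[-c(1, 2), ]
  expect_error(run_group_analysis(tb$metrics, tb$patterns, tb$clinical),
               "sub-001.*sub-002")
})

test_that("MwA vs MwoA comparisons are emitted alongside group comparisons", {
  tb <- toy_tables(seed = 5)
  # plant an aura-specific pattern difference
  aura <- tb$clinical$subgroup[match(tb$patterns$subject_id,
                                     tb$clinical$subject_id)]
  tb$patterns$inhibitory <- aura == "MwoA"
  res <- run_group_analysis(tb$metrics, tb$patterns, tb$clinical)
  ft <- res$pattern_tests
  row <- ft[ft$comparison == "MwA_vs_MwoA" &
              ft$connection_type == "inhibitory", ]
  expect_equal(row$n1, 10)
  expect_equal(row$n2, 13)
  expect_lt(row$p_value, 0.05)
})
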