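#' Full group statistical battery
#'
#' Runs, per frequency band, the study's statistics on cohort-level
#' tables: Fisher's exact tests on every regional pattern boolean
#' (migraineurs vs controls, and MwA vs MwoA), two-tailed pooled-variance
#' t-tests on the three network parameters with Bonferroni correction
#' (`alpha / n_comparisons`), one-way ANOVA on band power, and Spearman
#' correlations of the clinical covariates against metrics and pattern
#' presences within the migraine group.  Pattern tests are reported at the
#' uncorrected level.
#'
#' @param metrics Data frame from the metrics stage: `subject_id`, `band`,
#'   `strength`, `path_length`, `clustering` (plus anything else).
#' @param patterns Long data frame: `subject_id`, `band`, `roi`,
#'   `excitatory`, `inhibitory`.
#' @param clinical Cohort metadata (see [cohort_metadata()]): must contain
#'   `subject_id`, `group`, `subgroup` and the clinical covariates.
#' @param power Optional data frame `subject_id`, `band`, `power` for the
#'   band-power ANOVA.
#' @param alpha Nominal two-tailed level (default 0.05).
#' @param n_comparisons Bonferroni divisor for the metric t-tests
#'   (default 3, one per network parameter).
#' @return List of data frames: `pattern_tests`, `metric_tests`,
#'   `power_anova` (NULL if no power table), `clinical_correlations`.
#' @export
run_group_analysis <- function(metrics, patterns, clinical, power = NULL,
                               alpha = 0.05, n_comparisons = 3L) {
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(nm, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  need(metrics, c("subject_id", "band", "strength", "path_length",
                  "clustering"), "metrics")
  need(patterns, c("subject_id", "band", "roi", "excitatory",
                   "inhibitory"), "patterns")
  need(clinical, c("subject_id", "group", "subgroup"), "clinical")

  extra <- setdiff(unique(c(metrics$subject_id, patterns$subject_id)),
                   clinical$subject_id)
  if (length(extra))
    stop("subject id(s) missing from the clinical table: ",
         paste(extra, collapse = ", "))

  grp <- clinical$group[match(metrics$subject_id, clinical$subject_id)]
  sub <- clinical$subgroup[match(patterns$subject_id, clinical$subject_id)]
  pgrp <- clinical$group[match(patterns$subject_id, clinical$subject_id)]

  ## --- Fisher tests on pattern prevalence -------------------------------
  comparisons <- list(
    migraine_vs_control = function() list(a = pgrp == "migraine",
                                          b = pgrp == "control"),
    MwA_vs_MwoA = function() list(a = sub == "MwA", b = sub == "MwoA")
  )
  rows <- list()
  for (band in unique(patterns$band)) {
    for (roi in unique(patterns$roi)) {
      sel <- patterns$band == band & patterns$roi == roi
      for (type in c("excitatory", "inhibitory")) {
        pres <- patterns[[type]][sel]
        for (cmp in names(comparisons)) {
          gg <- comparisons[[cmp]]()
          ia <- gg$a[sel]; ib <- gg$b[sel]
          if (!any(ia) || !any(ib)) next
          tab <- matrix(c(sum(pres[ia]), sum(!pres[ia]),
                          sum(pres[ib]), sum(!pres[ib])),
                        2, 2, byrow = TRUE)
          ft <- fisher_exact(tab)
          rows[[length(rows) + 1L]] <- data.frame(
            band = band, roi = roi, connection_type = type,
            comparison = cmp, n1 = sum(ia), n2 = sum(ib),
            present1 = sum(pres[ia]), present2 = sum(pres[ib]),
            odds_ratio = ft$odds_ratio, p_value = ft$p_value,
            significant = ft$p_value < alpha,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pattern_tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame()

  ## --- t-tests on the three network parameters --------------------------
  rows <- list()
  for (band in unique(metrics$band)) {
    sel <- metrics$band == band
    for (m in c("strength", "path_length", "clustering")) {
      va <- metrics[[m]][sel & grp == "migraine"]
      vb <- metrics[[m]][sel & grp == "control"]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      if (length(va) < 2 || length(vb) < 2) next
      tt <- ttest_two_sample(va, vb, alpha = alpha,
                             n_comparisons = n_comparisons)
      rows[[length(rows) + 1L]] <- data.frame(
        band = band, metric = m, n_migraine = length(va),
        n_control = length(vb),
        mean_migraine = mean(va), mean_control = mean(vb),
        statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
        alpha_corrected = tt$alpha_corrected,
        significant = tt$significant, stringsAsFactors = FALSE)
    }
  }
  metric_tests <- if (length(rows)) do.call(rbind, rows) else data.frame()

  ## --- ANOVA on band power ----------------------------------------------
  power_anova <- NULL
  if (!is.null(power)) {
    need(power, c("subject_id", "band", "power"), "power")
    wgrp <- clinical$group[match(power$subject_id, clinical$subject_id)]
    rows <- list()
    for (band in unique(power$band)) {
      sel <- power$band == band
      gl <- list(migraine = power$power[sel & wgrp == "migraine"],
                 control = power$power[sel & wgrp == "control"])
      if (any(vapply(gl, length, 1L) < 2)) next
      av <- anova_oneway(gl)
      rows[[length(rows) + 1L]] <- data.frame(
        band = band, statistic = av$statistic, p_value = av$p_value,
        df_between = av$df_between, df_within = av$df_within,
        significant = av$p_value < alpha, stringsAsFactors = FALSE)
    }
    power_anova <- if (length(rows)) do.call(rbind, rows) else data.frame()
  }

  ## --- Spearman clinical correlations (migraineurs only) ----------------
  covariates <- intersect(c("age", "history", "attack_frequency",
                            "duration", "pain_intensity", "onset_to_scan"),
                          names(clinical))
  mig <- clinical[clinical$group == "migraine", , drop = FALSE]
  rows <- list()
  add_corr <- function(band, parameter, xv, yv) {
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < 3) return()
    res <- tryCatch(spearman_corr(xv[ok], yv[ok]), error = function(e) NULL)
    if (is.null(res)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      band = band, parameter = parameter, covariate = cov,
      n = res$n, rho = res$rho, p_value = res$p_value,
      significant = res$p_value < alpha, stringsAsFactors = FALSE)
  }
  for (cov in covariates) {
    for (band in unique(metrics$band)) {
      sel <- metrics$band == band & grp == "migraine"
      sub_ids <- metrics$subject_id[sel]
      xv <- mig[[cov]][match(sub_ids, mig$subject_id)]
      for (m in c("strength", "path_length", "clustering"))
        add_corr(band, m, as.numeric(xv), metrics[[m]][sel])
    }
    for (band in unique(patterns$band)) {
      for (roi in unique(patterns$roi)) {
        sel <- patterns$band == band & patterns$roi == roi &
          pgrp == "migraine"
        sub_ids <- patterns$subject_id[sel]
        xv <- mig[[cov]][match(sub_ids, mig$subject_id)]
        for (type in c("excitatory", "inhibitory"))
          add_corr(band, paste(roi, type),
                   as.numeric(xv), as.numeric(patterns[[type]][sel]))
      }
    }
  }
  clinical_correlations <-
    if (length(rows)) do.call(rbind, rows) else data.frame()

  structure(list(pattern_tests = pattern_tests,
                 metric_tests = metric_tests,
                 power_anova = power_anova,
                 clinical_correlations = clinical_correlations),
            class = "meg_group_results")
}
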