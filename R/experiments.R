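#' Type-I-error calibration on null cohorts
#'
#' Repeatedly simulates cohorts with no group difference (no planted
#' couplings), runs the full per-band analysis -- filtering, signed
#' coherence, thresholding, graph metrics, pattern classification and the
#' group statistics -- and collects the p-values of the frontal
#' excitatory-pattern Fisher test and of the three network-parameter
#' t-tests.  Their rejection rates at a nominal level estimate the
#' procedure's actual size.
#'
#' @param n_seeds Number of independent null cohorts.
#' @param n_per_group Subjects per group (migraine / control).
#' @param n_channels,sampling_rate,duration_s Recording geometry.
#' @param band Analysis band name (default `"slow"`, the band of the
#'   primary group contrast).
#' @param tau Connectivity threshold (default 0.5).
#' @param base_seed Seed of the first replicate.
#' @return Data frame with one row per seed: `p_fisher_frontal`,
#'   `p_strength`, `p_path_length`, `p_clustering`.
#' @export
null_calibration <- function(n_seeds = 150, n_per_group = 12,
                             n_channels = 16, sampling_rate = 1200,
                             duration_s = 30, band = "slow", tau = 0.5,
                             base_seed = 1) {
  band <- as_band(band)
  layout <- make_sensor_layout(n_channels, base_seed)
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_config(n_migraine = n_per_group, n_mwa = 0,
                         n_control = n_per_group,
                         n_channels = n_channels,
                         sampling_rate = sampling_rate,
                         duration_s = duration_s,
                         seed = (base_seed + 7919 * s) %% 2147483647)
    res <- analyse_cohort_bands(cfg, layout, band, tau)
    gr <- run_group_analysis(res$metrics, res$patterns, res$clinical)
    pt <- gr$pattern_tests
    frontal <- pt[pt$roi == "frontal" & pt$connection_type == "excitatory" &
                    pt$comparison == "migraine_vs_control", ]
    mt <- gr$metric_tests
    out[[s]] <- data.frame(
      seed = cfg$seed,
      p_fisher_frontal = frontal$p_value[1],
      p_strength = mt$p_value[mt$metric == "strength"][1],
      p_path_length = mt$p_value[mt$metric == "path_length"][1],
      p_clustering = mt$p_value[mt$metric == "clustering"][1])
  }
  do.call(rbind, out)
}

#' Planted-effect recovery experiment
#'
#' Simulates cohorts mirroring the reference findings -- a frontal
#' slow-wave excitatory coupling far more prevalent in migraineurs than
#' in controls, and a bilateral-occipital theta inhibitory coupling
#' prevalent in MwoA and controls but rare in MwA -- and measures, per
#' seed, the Fisher p-values of the two pattern contrasts and the mean
#' slow-band connection strength per group.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param n_migraine,n_mwa,n_control Cohort composition.
#' @param n_channels,sampling_rate,duration_s Recording geometry.
#' @param prevalence_case,prevalence_control Frontal slow-wave coupling
#'   prevalences in migraineurs and controls.
#' @param occ_prevalence_mwoa,occ_prevalence_mwa Bilateral-occipital theta
#'   coupling prevalences in MwoA (and controls) and MwA.
#' @param strength Coupling strength (shared-source amplitude over
#'   background RMS).
#' @param tau Connectivity threshold.
#' @param base_seed Seed of the first replicate.
#' @return Data frame with one row per seed: `p_frontal_slow`,
#'   `p_occipital_theta`, `strength_slow_migraine`,
#'   `strength_slow_control`.
#' @export
planted_effect_experiment <- function(n_seeds = 100, n_migraine = 23,
                                      n_mwa = 10, n_control = 23,
                                      n_channels = 16, sampling_rate = 600,
                                      duration_s = 20,
                                      prevalence_case = 0.75,
                                      prevalence_control = 0.05,
                                      occ_prevalence_mwoa = 0.9,
                                      occ_prevalence_mwa = 0.05,
                                      strength = 2, tau = 0.5,
                                      base_seed = 1) {
  bands <- rbind(as_band("slow"), as_band("theta"))
  layout <- make_sensor_layout(n_channels, base_seed)
  specs <- list(
    coupling_spec("slow", "frontal", +1, strength, prevalence_case,
                  "migraine"),
    coupling_spec("slow", "frontal", +1, strength, prevalence_control,
                  "control"),
    coupling_spec("theta", c("occipital_L", "occipital_R"), -1, strength,
                  occ_prevalence_mwoa, "MwoA"),
    coupling_spec("theta", c("occipital_L", "occipital_R"), -1, strength,
                  occ_prevalence_mwoa, "control"),
    coupling_spec("theta", c("occipital_L", "occipital_R"), -1, strength,
                  occ_prevalence_mwa, "MwA"))
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_config(n_migraine = n_migraine, n_mwa = n_mwa,
                         n_control = n_control, n_channels = n_channels,
                         sampling_rate = sampling_rate,
                         duration_s = duration_s, coupling_specs = specs,
                         seed = (base_seed + 104729 * s) %% 2147483647)
    res <- analyse_cohort_bands(cfg, layout, bands, tau)
    gr <- run_group_analysis(res$metrics, res$patterns, res$clinical)
    pt <- gr$pattern_tests
    frontal <- pt[pt$band == "slow" & pt$roi == "frontal" &
                    pt$connection_type == "excitatory" &
                    pt$comparison == "migraine_vs_control", ]
    occ <- pt[pt$band == "theta" & pt$roi == "occipital_bilateral" &
                pt$connection_type == "inhibitory" &
                pt$comparison == "MwA_vs_MwoA", ]
    m <- res$metrics
    grp <- res$clinical$group[match(m$subject_id, res$clinical$subject_id)]
    out[[s]] <- data.frame(
      seed = cfg$seed,
      p_frontal_slow = frontal$p_value[1],
      p_occipital_theta = occ$p_value[1],
      strength_slow_migraine =
        mean(m$strength[m$band == "slow" & grp == "migraine"]),
      strength_slow_control =
        mean(m$strength[m$band == "slow" & grp == "control"]))
  }
  do.call(rbind, out)
}

# Shared driver: simulate every subject of a cohort and analyse the given
# bands, returning the metrics / patterns / clinical tables.
analyse_cohort_bands <- function(cfg, layout, bands, tau) {
  meta <- cohort_metadata(cfg)
  metrics <- vector("list", nrow(meta) * nrow(bands))
  patterns <- vector("list", nrow(meta) * nrow(bands))
  k <- 0L
  for (i in seq_len(nrow(meta))) {
    rec <- simulate_subject(layout, meta[i, ], cfg,
                            seed = subject_seed(cfg$seed, i, 2L))
    rec <- remove_dc(rec)
    for (b in seq_len(nrow(bands))) {
      filt <- trim_edges(bandpass(rec, bands[b, ]))
      cm <- pairwise_connectivity(filt)
      k <- k + 1L
      metrics[[k]] <- network_metrics(cm, tau)
      patterns[[k]] <- classify_pattern(apply_threshold(cm, tau), layout)
    }
  }
  list(metrics = do.call(rbind, metrics[seq_len(k)]),
       patterns = do.call(rbind, patterns[seq_len(k)]),
       clinical = meta)
}
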