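#' Specify a planted regional coupling
#'
#' A coupling is a band-limited source shared by all sensors of one region
#' (or a pair of regions), expressed by a random subset of the subjects of
#' a target group.  Couplings with `sign = +1` raise positively signed
#' ("excitatory") connectivity; `sign = -1` inverts the source on the
#' second region so the two regions' band-limited amplitudes become
#' anti-correlated ("inhibitory").  For a within-region inhibitory
#' coupling the region's channels are split in half with opposite signs.
#'
#' @param band Band name or specification (see [as_band()]).
#' @param regions Character vector of one or two region labels.
#' @param sign `+1` (excitatory) or `-1` (inhibitory).
#' @param strength Amplitude of the shared source as a multiple of the
#'   background RMS (dimensionless, >= 0).
#' @param prevalence Probability that a subject of the target group
#'   expresses the coupling, in `[0, 1]`.
#' @param group Target group: `"migraine"`, `"control"`, `"MwA"`,
#'   `"MwoA"` or `"all"`.
#' @return A `coupling_spec` object.
#' @examples
#' coupling_spec("slow", "frontal", sign = +1, strength = 2, prevalence = 0.75)
#' @export
coupling_spec <- function(band, regions, sign = 1L, strength = 2,
                          prevalence = 1, group = "migraine") {
  band <- as_band(band)
  regions <- as.character(regions)
  if (!length(regions) %in% 1:2)
    stop("regions must name one or two regions")
  if (length(regions) == 1L) regions <- rep(regions, 2L)
  unknown <- setdiff(regions, REGIONS)
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (!is.numeric(strength) || strength < 0) stop("strength must be >= 0")
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stop("prevalence must be in [0, 1]")
  group <- match.arg(group, c("migraine", "control", "MwA", "MwoA", "all"))
  structure(list(band = band, regions = regions, sign = as.integer(sign),
                 strength = strength, prevalence = prevalence, group = group),
            class = "coupling_spec")
}

#' Configure a synthetic resting-state cohort
#'
#' Defaults mirror the reference study design: 23 migraineurs (10 with
#' aura) and 23 matched controls, at the package's desk simulation scale
#' of 64 channels, 1200 Hz and 60 s.  The full 275-channel, 6000 Hz, 120 s
#' scale is available by argument.  Background activity is 1/f-shaped
#' noise (exponent `noise_exponent`, RMS `background_rms` fT per channel);
#' group differences are planted through `coupling_specs`.
#'
#' @param n_migraine,n_mwa,n_control Cohort sizes; `n_mwa <= n_migraine`.
#' @param n_channels Number of sensors (>= 8).
#' @param sampling_rate Hz; must exceed twice the highest band edge used
#'   by any coupling.
#' @param duration_s Recording duration in seconds.
#' @param noise_exponent 1/f slope of the background (power ~ f^-exponent).
#' @param background_rms Background RMS per channel in fT.
#' @param coupling_specs List of [coupling_spec()] objects.
#' @param seed Integer master seed; per-subject streams are derived from
#'   `(seed, subject index)` so earlier subjects are unaffected by cohort
#'   growth.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_migraine = 23L, n_mwa = 10L, n_control = 23L,
                          n_channels = 64L, sampling_rate = 1200,
                          duration_s = 60, noise_exponent = 1,
                          background_rms = 100, coupling_specs = list(),
                          seed = 1L) {
  if (n_mwa > n_migraine) stop("n_mwa must not exceed n_migraine")
  if (n_migraine < 0 || n_control < 0) stop("cohort counts must be >= 0")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (n_channels < 8) stop("n_channels must be >= 8")
  for (cs in coupling_specs) {
    if (!inherits(cs, "coupling_spec"))
      stop("coupling_specs must be coupling_spec objects")
    if (sampling_rate <= 2 * cs$band$hi)
      stop("sampling rate too low for coupling band '", cs$band$name,
           "' (need > ", 2 * cs$band$hi, " Hz)")
  }
  structure(list(n_migraine = as.integer(n_migraine),
                 n_mwa = as.integer(n_mwa),
                 n_control = as.integer(n_control),
                 n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, duration_s = duration_s,
                 noise_exponent = noise_exponent,
                 background_rms = background_rms,
                 coupling_specs = coupling_specs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Derived per-subject, per-purpose RNG seeds, kept below 2^31.
subject_seed <- function(seed, idx, stream = 0L) {
  as.integer((abs(as.numeric(seed)) * 48271 + idx * 10007 + stream * 101) %%
               2147483647)
}

# 1/f-shaped Gaussian noise synthesised in the frequency domain: every
# non-DC bin gets an independent complex-Gaussian coefficient with
# amplitude f^(-exponent/2); one inverse FFT per channel block.  Exact
# per-channel RMS.  Returns n samples x nch channels.
shaped_noise <- function(n, nch, fs, exponent, rms) {
  nh <- floor((n - 1) / 2)                  # bins strictly below Nyquist
  amp <- ((1:nh) * fs / n)^(-exponent / 2)
  F <- noise_half_spectrum(n, nch, amp, (fs / 2)^(-exponent / 2))
  x <- Re(mvfft(F, inverse = TRUE))
  sc <- rms / sqrt(colMeans(x^2))
  x * rep(sc, each = n)
}

# Band-limited Gaussian noise: complex-Gaussian coefficients on the
# in-band bins only, inverse FFT, exact RMS.
band_limited_noise <- function(n, fs, lo, hi, rms) {
  k <- seq_len(floor((n - 1) / 2))
  k <- k[k * fs / n >= lo & k * fs / n <= hi]
  if (!length(k)) stop("no frequency bins inside the band")
  coef <- complex(real = rnorm(length(k)), imaginary = rnorm(length(k)))
  F <- complex(real = numeric(n))
  F[1 + k] <- coef
  F[n + 1 - k] <- Conj(coef)
  x <- Re(fft(F, inverse = TRUE))
  x * rms / sqrt(mean(x^2))
}

#' Simulate one subject's recording
#'
#' Independent 1/f background per channel plus, for each coupling spec
#' applicable to the subject's group and expressed by a Bernoulli draw at
#' its prevalence, a shared band-limited source added to the channels of
#' the coupled regions (negated on the second region when `sign = -1`).
#'
#' @param layout A [make_sensor_layout()] layout.
#' @param meta One-row data frame (or list) with at least `subject_id`,
#'   `group`, `subgroup`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this subject's RNG stream.
#' @return A [meg_recording()].
#' @export
simulate_subject <- function(layout, meta, config, seed) {
  validate_layout(layout)
  stopifnot(inherits(config, "cohort_config"))
  fs <- config$sampling_rate
  n <- round(config$duration_s * fs)
  set.seed(as.integer(seed))

  specs <- Filter(function(cs) {
    cs$group == "all" || cs$group == meta$group || cs$group == meta$subgroup
  }, config$coupling_specs)
  expressed <- vapply(specs, function(cs) runif(1) < cs$prevalence, logical(1))

  x <- t(shaped_noise(n, length(layout$channel_ids), fs,
                      config$noise_exponent, config$background_rms))
  for (cs in specs[expressed]) {
    if (fs <= 2 * cs$band$hi)
      stop("sampling rate too low for coupling band '", cs$band$name, "'")
    src <- band_limited_noise(n, fs, cs$band$lo, cs$band$hi,
                              cs$strength * config$background_rms)
    a <- which(layout$regions == cs$regions[1])
    b <- which(layout$regions == cs$regions[2])
    if (cs$regions[1] == cs$regions[2]) {
      if (cs$sign < 0) {
        half <- a[seq_len(floor(length(a) / 2))]
        x[half, ] <- x[half, ] + rep(src, each = length(half))
        rest <- setdiff(a, half)
        x[rest, ] <- x[rest, ] - rep(src, each = length(rest))
      } else {
        x[a, ] <- x[a, ] + rep(src, each = length(a))
      }
    } else {
      x[a, ] <- x[a, ] + rep(src, each = length(a))
      x[b, ] <- x[b, ] + cs$sign * rep(src, each = length(b))
    }
  }
  meg_recording(x, fs, channel_ids = layout$channel_ids,
                subject_id = as.character(meta$subject_id))
}

#' Deterministic cohort metadata
#'
#' Builds the subject table for a cohort configuration: the first
#' `n_migraine` subjects are migraineurs (the first `n_mwa` of them with
#' aura), the rest controls.  Clinical covariates are drawn independently
#' and uniformly within the reference demographic ranges (age 20--40 y,
#' history 2--30 y, attack frequency 1--4 per month, attack duration
#' 1--72 h, pain intensity 3--8, onset-to-scan 3--20 days); controls carry
#' `NA` for migraine-specific fields.  Each subject's covariates come from
#' its own derived RNG stream, so the table is reproducible and stable
#' under cohort growth.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per subject.
#' @export
cohort_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ntot <- config$n_migraine + config$n_control
  rows <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    migraine <- i <= config$n_migraine
    subgroup <- if (!migraine) "none"
                else if (i <= config$n_mwa) "MwA" else "MwoA"
    set.seed(subject_seed(config$seed, i, stream = 1L))
    rows[[i]] <- data.frame(
      subject_id = sprintf("sub-%03d", i),
      group = if (migraine) "migraine" else "control",
      subgroup = subgroup,
      sex = if (runif(1) < 15 / 23) "F" else "M",
      age = sample(20:40, 1),
      history = if (migraine) round(runif(1, 2, 30), 1) else NA_real_,
      attack_frequency = if (migraine) round(runif(1, 1, 4), 1) else NA_real_,
      duration = if (migraine) round(runif(1, 1, 72), 1) else NA_real_,
      pain_intensity = if (migraine) sample(3:8, 1) else NA_integer_,
      onset_to_scan = if (migraine) sample(3:20, 1) else NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate a full cohort
#'
#' @param config A [cohort_config()].
#' @param layout Optional [make_sensor_layout()] layout; by default one is
#'   generated from `(config$n_channels, config$seed)`.
#' @return A `meg_cohort`: list with `layout`, `meta` (data frame) and
#'   `recordings` (list of [meg_recording()], one per subject, in table
#'   order).
#' @examples
#' cfg <- cohort_config(n_migraine = 1, n_mwa = 0, n_control = 1,
#'                      n_channels = 8, sampling_rate = 200,
#'                      duration_s = 2, seed = 1)
#' ch <- simulate_cohort(cfg)
#' ch$meta$subgroup
#' @export
simulate_cohort <- function(config, layout = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(layout))
    layout <- make_sensor_layout(config$n_channels, config$seed)
  validate_layout(layout)
  meta <- cohort_metadata(config)
  recs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    recs[[i]] <- simulate_subject(layout, meta[i, ], config,
                                  seed = subject_seed(config$seed, i, 2L))
  }
  names(recs) <- meta$subject_id
  structure(list(layout = layout, meta = meta, recordings = recs),
            class = "meg_cohort")
}
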