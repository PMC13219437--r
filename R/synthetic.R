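# Feature families the generator can plant a class effect in. Each family is
# driven by one dedicated knob so that planted features respond more strongly
# than unrelated ones: the alpha-oscillation amplitude drives the amplitude
# family, the broadband (white) component drives the derivative family, and a
# DC offset drives the mean. Latency and shape features (ppt, lmin, lmax,
# skew, kurt) have no class-effect mechanism and cannot be planted.
PLANT_AMPLITUDE <- c(
  "std", "pp", "pps", "amp_max", "amp_min", "alar", "lar",
  "energy", "energy_norm"
)
PLANT_DERIVATIVE <- c("mdif1", "mdif2", "mdif1norm", "mdif2norm", "entropy")
PLANT_MEAN <- "mean"

#' Simulation parameters for a synthetic stress cohort
#'
#' Defines the study conditions the generator emulates: a resting cohort with
#' a 4-electrode prefrontal/temporoparietal montage, EEG-like spectra (1/f
#' background plus alpha- and beta-band oscillations and broadband noise),
#' PSQ scores whose pooled mean and SD match 30.20 and 15.52, and a class
#' effect of standardized size `effect_size` planted in a designated subset
#' of the 20 time-domain features.
#'
#' Per-channel component amplitudes vary log-normally with a subject-shared
#' part (`subject_log_amp_sd`) and a channel-specific part
#' (`channel_log_amp_sd`); the stressed class shifts the log-amplitude of the
#' knob component by `effect_size` times the total log-amplitude SD, so the
#' planted features differ between classes by about `effect_size` pooled SDs
#' per column.
#'
#' @param n_subjects Cohort size (>= 1; downstream evaluation needs both
#'   classes present).
#' @param channels Electrode names. Default AF7, AF8, TP7, TP8.
#' @param fs Sampling rate in Hz. Default 250 (2500 supported).
#' @param duration_s Recording length in seconds. Default 480.
#' @param stress_prevalence Probability a subject is in the stressed class.
#' @param psq_mean_by_class Named or ordered pair `(non_stressed, stressed)`
#'   of class-conditional PSQ means. The defaults (18, 45.1) with
#'   `psq_sd = 7.7` and prevalence 0.45 give pooled moments matching the
#'   reference cohort (mean 30.2, SD 15.5).
#' @param psq_sd Class-conditional PSQ standard deviation.
#' @param psq_range Admissible PSQ range; scores are drawn from the truncated
#'   normal on this interval. Default `c(0, 100)`.
#' @param effect_size Standardized between-class difference planted in the
#'   designated features. 0 means no class effect anywhere.
#' @param planted_features Subset of [feature_names()] carrying the effect.
#'   Default `c("std", "energy", "energy_norm")` — the variance-family
#'   descriptors that read out the alpha-amplitude manipulation most
#'   directly.
#' @param noise_spectrum List of signal-model parameters: `sd_background`,
#'   `bg_exponent` (1/f^alpha slope), `sd_alpha`, `f_alpha`, `sd_beta`,
#'   `f_beta`, `sd_white`, `phase_jitter` (rad/sample SD of the oscillator
#'   phase random walk), `sd_dc`, `subject_log_amp_sd`, `channel_log_amp_sd`.
#' @param seed Integer cohort seed; the cohort is a pure function of the
#'   full parameter set including this seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 120L,
                       channels = c("AF7", "AF8", "TP7", "TP8"),
                       fs = 250,
                       duration_s = 480,
                       stress_prevalence = 0.45,
                       psq_mean_by_class = c(non_stressed = 18, stressed = 45.1),
                       psq_sd = 7.7,
                       psq_range = c(0, 100),
                       effect_size = 1.5,
                       planted_features = c("std", "energy", "energy_norm"),
                       noise_spectrum = list(),
                       seed = 1L) {
  if (n_subjects < 1) stop_input("n_subjects must be >= 1")
  if (stress_prevalence <= 0 || stress_prevalence >= 1) {
    stop_input("stress_prevalence must be strictly inside (0, 1)")
  }
  if (fs <= 0 || duration_s <= 0) stop_input("fs and duration_s must be > 0")
  if (psq_sd <= 0) stop_input("psq_sd must be > 0")
  unknown <- setdiff(planted_features, feature_names())
  if (length(unknown) > 0) {
    stop_input(
      "planted_features not among the 20 feature names: ",
      paste(unknown, collapse = ", ")
    )
  }
  unplantable <- setdiff(
    planted_features,
    c(PLANT_AMPLITUDE, PLANT_DERIVATIVE, PLANT_MEAN)
  )
  if (length(unplantable) > 0) {
    stop_input(
      "no class-effect mechanism for feature(s): ",
      paste(unplantable, collapse = ", "),
      " (latency and shape features cannot be planted)"
    )
  }
  ns_defaults <- list(
    sd_background = 4, bg_exponent = 1,
    sd_alpha = 8.5, f_alpha = 10,
    sd_beta = 2.8, f_beta = 20,
    sd_white = 3, phase_jitter = 0.1,
    sd_dc = 0.5,
    subject_log_amp_sd = 0.05, channel_log_amp_sd = 0.15
  )
  bad_ns <- setdiff(names(noise_spectrum), names(ns_defaults))
  if (length(bad_ns) > 0) {
    stop_input("unknown noise_spectrum fields: ", paste(bad_ns, collapse = ", "))
  }
  ns <- utils::modifyList(ns_defaults, noise_spectrum)
  structure(
    list(
      n_subjects = as.integer(n_subjects), channels = channels, fs = fs,
      duration_s = duration_s, stress_prevalence = stress_prevalence,
      psq_mean_by_class = psq_mean_by_class, psq_sd = psq_sd,
      psq_range = psq_range, effect_size = effect_size,
      planted_features = planted_features, noise_spectrum = ns,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

# 1/f^alpha background noise, unit SD, via spectral shaping of white noise.
pink_noise <- function(n, exponent = 1) {
  w <- stats::fft(stats::rnorm(n))
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))
  scale <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(stats::fft(w * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Unit-variance narrowband oscillation: sinusoid with random initial phase
# and a per-sample random-walk phase jitter.
jittered_oscillation <- function(n, fs, f0, jitter_sd) {
  phase <- 2 * pi * f0 * seq_len(n) / fs +
    stats::runif(1, 0, 2 * pi) +
    cumsum(stats::rnorm(n, 0, jitter_sd))
  sqrt(2) * sin(phase)
}

# Truncated-normal draw via inverse-CDF sampling (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  mean + sd * stats::qnorm(stats::runif(n, p_lo, p_hi))
}

# Which knobs the planted feature set activates.
active_knobs <- function(planted) {
  c(
    amplitude = any(planted %in% PLANT_AMPLITUDE),
    derivative = any(planted %in% PLANT_DERIVATIVE),
    dc = any(planted %in% PLANT_MEAN)
  )
}

#' Simulate one subject
#'
#' Draws one subject's multichannel EEG-like recording and PSQ score as a
#' pure function of `(true_class, params, subject_seed)`. Each channel is the
#' sum of a 1/f background, alpha- and beta-band phase-jittered oscillations,
#' broadband noise and a small DC offset; component amplitudes carry
#' log-normal subject- and channel-level variability, and the stressed class
#' shifts the log-amplitude of the planted-feature knob component (alpha
#' amplitude for amplitude-type features, broadband amplitude for
#' derivative-type features, the DC mean for `mean`) by
#' `effect_size * total log-amplitude SD`, split symmetrically between the
#' classes. The PSQ score is drawn from the class-conditional normal
#' truncated to `params$psq_range`.
#'
#' @param true_class `"stressed"` or `"non_stressed"`.
#' @param params A [sim_params()] object.
#' @param subject_seed Integer seed for this subject's draws.
#' @return List with `recording` (an [eeg_recording()]) and `psq_score`.
#' @export
simulate_subject <- function(true_class, params, subject_seed) {
  stopifnot(inherits(params, "sim_params"))
  true_class <- match.arg(true_class, c("stressed", "non_stressed"))
  ns <- params$noise_spectrum
  n <- round(params$fs * params$duration_s)
  tau <- sqrt(ns$subject_log_amp_sd^2 + ns$channel_log_amp_sd^2)
  delta <- params$effect_size * tau
  half <- if (true_class == "stressed") delta / 2 else -delta / 2
  knobs <- active_knobs(params$planted_features)

  with_seed(subject_seed, {
    # subject-shared log-amplitude deviations, one per signal component
    subj_dev <- stats::rnorm(4, 0, ns$subject_log_amp_sd)
    names(subj_dev) <- c("bg", "alpha", "beta", "white")
    sig <- matrix(0, nrow = length(params$channels), ncol = n,
      dimnames = list(params$channels, NULL)
    )
    for (ci in seq_along(params$channels)) {
      chan_dev <- stats::rnorm(4, 0, ns$channel_log_amp_sd)
      amp <- function(base_sd, comp, shift) {
        base_sd * exp(subj_dev[comp] + chan_dev[match(comp, names(subj_dev))] + shift)
      }
      x <- amp(ns$sd_background, "bg", 0) * pink_noise(n, ns$bg_exponent) +
        amp(ns$sd_alpha, "alpha", if (knobs["amplitude"]) half else 0) *
          jittered_oscillation(n, params$fs, ns$f_alpha, ns$phase_jitter) +
        amp(ns$sd_beta, "beta", 0) *
          jittered_oscillation(n, params$fs, ns$f_beta, ns$phase_jitter) +
        amp(ns$sd_white, "white", if (knobs["derivative"]) half else 0) *
          stats::rnorm(n)
      dc_mean <- if (knobs["dc"]) {
        sign(half) * params$effect_size * ns$sd_dc / 2
      } else {
        0
      }
      x <- x + stats::rnorm(1, dc_mean, ns$sd_dc)
      sig[ci, ] <- x
    }
    class_means <- params$psq_mean_by_class
    m <- if (true_class == "stressed") class_means[[2]] else class_means[[1]]
    psq <- rtruncnorm(1, m, params$psq_sd, params$psq_range[1], params$psq_range[2])
    list(
      recording = eeg_recording(
        subject_id = paste0("seed", subject_seed), samples = sig, fs = params$fs
      ),
      psq_score = psq
    )
  })
}

#' Simulate a synthetic cohort
#'
#' Assigns each subject to the stressed class with probability
#' `stress_prevalence`, then simulates every subject with a per-subject seed
#' derived from the cohort seed by a deterministic counter scheme
#' (`(seed + 7919 * i) mod (2^31 - 1)`), so any subject can be regenerated
#' independently of the others.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `synthetic_cohort`: `recordings` (named list of
#'   [eeg_recording()]), `participants` (tibble `subject_id`, `psq_score`,
#'   `true_class`) and `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_subjects
  classes <- with_seed(
    params$seed,
    ifelse(stats::rbinom(n, 1, params$stress_prevalence) == 1,
      "stressed", "non_stressed"
    )
  )
  ids <- sprintf("sub-%03d", seq_len(n))
  seeds <- (as.numeric(params$seed) + 7919 * seq_len(n)) %% 2147483647
  recordings <- vector("list", n)
  psq <- numeric(n)
  for (i in seq_len(n)) {
    subj <- simulate_subject(classes[i], params, subject_seed = seeds[i])
    subj$recording$subject_id <- ids[i]
    recordings[[i]] <- subj$recording
    psq[i] <- subj$psq_score
  }
  names(recordings) <- ids
  structure(
    list(
      recordings = recordings,
      participants = tibble::tibble(
        subject_id = ids, psq_score = psq, true_class = classes
      ),
      params = params
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort>", x$params$n_subjects, "subjects,",
    length(x$params$channels), "channels @", x$params$fs, "Hz,",
    x$params$duration_s, "s; effect", x$params$effect_size, "in [",
    paste(x$params$planted_features, collapse = ", "), "]\n"
  )
  invisible(x)
}
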