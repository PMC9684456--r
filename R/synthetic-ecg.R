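#' Rhythm specification for synthetic ECG segments
#'
#' Describes the beat statistics and morphology of one rhythm. Sinus rhythm
#' has nearly regular RR intervals (low coefficient of variation) and a
#' visible P-wave before each QRS complex; atrial fibrillation (AF) has
#' highly irregular RR intervals, no P-wave, and a low-amplitude
#' fibrillatory baseline oscillation. A paced-like template (narrow pacing
#' spike, broadened QRS) is used for the out-of-distribution class.
#'
#' @param heart_rate_bpm Mean heart rate in beats per minute (20-250).
#' @param rr_cv Coefficient of variation of the RR (beat-to-beat) intervals.
#'   RR intervals are drawn from a log-normal distribution with this mean
#'   and CV (positive and right-skewed).
#' @param p_wave_amplitude P-wave amplitude in mV relative to a 1 mV R-peak;
#'   0 disables the P-wave entirely.
#' @param fibrillatory_amplitude Amplitude (mV) of the irregular 4-9 Hz
#'   baseline oscillation that replaces organised atrial activity in AF.
#' @param paced If `TRUE`, each beat is preceded by a narrow high-slope
#'   pacing spike and the QRS is broadened (out-of-distribution morphology).
#' @param label Rhythm class label: `"sinus"`, `"af"` or `"ood"`. Defaults
#'   to `"sinus"` when a P-wave is present and `"af"` otherwise.
#' @param seed Optional integer seed making segment generation deterministic.
#'
#' @return A `rhythm_spec` list.
#' @seealso [sinus_rhythm()], [af_rhythm()], [ood_rhythm()],
#'   [generate_segment()]
#' @export
rhythm_spec <- function(heart_rate_bpm, rr_cv, p_wave_amplitude,
                        fibrillatory_amplitude = 0, paced = FALSE,
                        label = NULL, seed = NULL) {
  check_number(heart_rate_bpm, "heart_rate_bpm", 20, 250)
  check_number(rr_cv, "rr_cv", 0, 2)
  check_number(p_wave_amplitude, "p_wave_amplitude", 0, 2)
  check_number(fibrillatory_amplitude, "fibrillatory_amplitude", 0, 2)
  label <- label %||% if (p_wave_amplitude > 0) "sinus" else "af"
  label <- rlang::arg_match0(label, c("sinus", "af", "ood"))
  structure(
    list(
      heart_rate_bpm = heart_rate_bpm, rr_cv = rr_cv,
      p_wave_amplitude = p_wave_amplitude,
      fibrillatory_amplitude = fibrillatory_amplitude,
      paced = paced, label = label, seed = seed
    ),
    class = "rhythm_spec"
  )
}

#' @rdname rhythm_spec
#' @param ... Overrides passed on to [rhythm_spec()].
#' @export
sinus_rhythm <- function(...) {
  args <- utils::modifyList(
    list(heart_rate_bpm = 75, rr_cv = 0.02, p_wave_amplitude = 0.15,
         fibrillatory_amplitude = 0, label = "sinus"),
    list(...)
  )
  do.call(rhythm_spec, args)
}

#' @rdname rhythm_spec
#' @export
af_rhythm <- function(...) {
  args <- utils::modifyList(
    list(heart_rate_bpm = 100, rr_cv = 0.25, p_wave_amplitude = 0,
         fibrillatory_amplitude = 0.1, label = "af"),
    list(...)
  )
  do.call(rhythm_spec, args)
}

#' @rdname rhythm_spec
#' @export
ood_rhythm <- function(...) {
  args <- utils::modifyList(
    list(heart_rate_bpm = 70, rr_cv = 0.03, p_wave_amplitude = 0,
         fibrillatory_amplitude = 0, paced = TRUE, label = "ood"),
    list(...)
  )
  do.call(rhythm_spec, args)
}

# Add a Gaussian bump centred at `center` (s) with width `width` (s) and
# amplitude `amp` (mV) to waveform `x` sampled at times `t`. Only touches
# the +/- 4 sd window for speed.
add_bump <- function(x, t, center, width, amp) {
  if (amp == 0) return(x)
  fs <- 1 / (t[2] - t[1])
  lo <- max(1L, floor((center - 4 * width) * fs) + 1L)
  hi <- min(length(t), ceiling((center + 4 * width) * fs) + 1L)
  if (lo > hi) return(x)
  idx <- lo:hi
  x[idx] <- x[idx] + amp * exp(-0.5 * ((t[idx] - center) / width)^2)
  x
}

#' Generate one synthetic multi-lead ECG segment
#'
#' Synthesises a fixed-duration, multi-lead ECG-like waveform from a beat
#' template model: each beat contributes Gaussian bumps for the P, Q, R, S
#' and T deflections, beat times follow RR intervals drawn from a log-normal
#' distribution with the mean rate and CV in `spec`, and AF specs add an
#' irregular fibrillatory baseline. Leads are correlated copies of a common
#' cardiac source with per-lead gain and independent measurement noise.
#'
#' @param spec A [rhythm_spec()].
#' @param fs Sampling rate in Hz.
#' @param duration Segment duration in seconds.
#' @param leads Number of leads (rows of the signal matrix).
#' @param seed Integer seed; defaults to `spec$seed`. The segment is a pure
#'   function of the spec, the sampling parameters and this seed.
#'
#' @return An `ecg_segment`: a list with `signal` (leads x samples matrix,
#'   mV), `fs`, `duration`, `patient_id`, `timestamp`, `true_rhythm`,
#'   `noisy`, `dropoff` and the accumulated `noise_fraction`.
#' @export
generate_segment <- function(spec, fs = 240, duration = 10, leads = 4,
                             seed = spec$seed) {
  if (!inherits(spec, "rhythm_spec")) abort("`spec` must be a rhythm_spec.")
  check_number(fs, "fs", 1, Inf)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    abort("`duration` must be a positive number of seconds.",
          class = "afuq_parameter_error")
  }
  check_number(leads, "leads", 1, Inf)

  with_seed(seed, {
    n <- round(fs * duration)
    t <- (seq_len(n) - 1) / fs
    mean_rr <- 60 / spec$heart_rate_bpm

    # log-normal RR intervals with the requested mean and CV
    cv <- max(spec$rr_cv, 1e-6)
    s2 <- log(1 + cv^2)
    mu <- log(mean_rr) - s2 / 2
    n_beats <- ceiling((duration + 2) / mean_rr) + 4
    rr <- rlnorm(n_beats, meanlog = mu, sdlog = sqrt(s2))
    beat_times <- cumsum(c(runif(1, 0.05, mean_rr), rr))
    beat_times <- beat_times[beat_times < duration + 0.5]

    base <- numeric(n)
    qrs_w <- if (spec$paced) 0.030 else 0.014
    for (tb in beat_times) {
      if (spec$p_wave_amplitude > 0) {
        base <- add_bump(base, t, tb - 0.17, 0.045, spec$p_wave_amplitude)
      }
      if (spec$paced) {
        base <- add_bump(base, t, tb - 0.05, 0.004, 2.2) # pacing spike
      }
      base <- add_bump(base, t, tb - 0.035, 0.012, -0.12)
      base <- add_bump(base, t, tb, qrs_w, 1.0)
      base <- add_bump(base, t, tb + 0.04, 0.016, -0.20)
      base <- add_bump(base, t, tb + 0.27, 0.060, 0.30)
    }

    if (spec$fibrillatory_amplitude > 0) {
      freqs <- runif(3, 4, 9)
      phases <- runif(3, 0, 2 * pi)
      amps <- spec$fibrillatory_amplitude * c(1, 0.6, 0.4)
      for (k in 1:3) base <- base + amps[k] * sin(2 * pi * freqs[k] * t + phases[k])
    }

    gains <- rep(c(1, 0.85, 0.7, 0.55), length.out = leads)
    signal <- matrix(0, nrow = leads, ncol = n)
    for (l in seq_len(leads)) {
      signal[l, ] <- gains[l] * base + rnorm(n, sd = 0.01)
    }
    new_ecg_segment(signal, fs = fs, duration = duration,
                    true_rhythm = spec$label)
  })
}

new_ecg_segment <- function(signal, fs, duration, true_rhythm,
                            patient_id = NA_character_,
                            timestamp = NA_real_, noisy = FALSE,
                            dropoff = FALSE, noise_fraction = 0) {
  structure(
    list(signal = signal, fs = fs, duration = duration,
         patient_id = patient_id, timestamp = timestamp,
         true_rhythm = true_rhythm, noisy = noisy, dropoff = dropoff,
         noise_fraction = noise_fraction),
    class = "ecg_segment"
  )
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf(
    "<ecg_segment> %s | %d leads x %d samples @ %g Hz | noisy=%s dropoff=%s\n",
    x$true_rhythm, nrow(x$signal), ncol(x$signal), x$fs, x$noisy, x$dropoff
  ))
  invisible(x)
}

#' Noise specification
#'
#' Describes one artifact injection. `hf_artifact` is broadband additive
#' noise (motion/muscle artifact), `baseline_wander` a low-frequency
#' (<= 1 Hz) additive drift, and `dropoff` a flat (constant) run emulating
#' sensor disconnection. A segment is flagged noisy when the total affected
#' fraction of the record reaches 1/4, mirroring the annotation criterion
#' that at least a quarter of the recording must contain artifact or wander.
#'
#' @param kind One of `"hf_artifact"`, `"baseline_wander"`, `"dropoff"`.
#' @param fraction Fraction of the record affected, in \[0, 1\].
#' @param amplitude Artifact amplitude in mV (ignored for `dropoff`).
#' @param seed Optional integer seed.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(kind = c("hf_artifact", "baseline_wander", "dropoff"),
                       fraction, amplitude = 0.5, seed = NULL) {
  kind <- match.arg(kind)
  check_fraction(fraction, "fraction")
  check_number(amplitude, "amplitude", 0, Inf)
  structure(list(kind = kind, fraction = fraction, amplitude = amplitude,
                 seed = seed),
            class = "noise_spec")
}

#' Inject an artifact into an ECG segment
#'
#' Applies the artifact described by `spec` to a contiguous, randomly
#' positioned window covering `spec$fraction` of the record. The rest of
#' the signal is unchanged. The segment's cumulative affected fraction is
#' tracked across repeated injections, and the `noisy` flag is set exactly
#' when that total reaches 0.25 (the at-least-1/4-of-the-recording
#' annotation criterion). A `dropoff` injection flattens the window to a
#' constant and sets the `dropoff` flag.
#'
#' @param segment An `ecg_segment`.
#' @param spec A [noise_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return The modified `ecg_segment`.
#' @export
inject_noise <- function(segment, spec, seed = spec$seed) {
  if (!inherits(segment, "ecg_segment")) abort("`segment` must be an ecg_segment.")
  if (!inherits(spec, "noise_spec")) abort("`spec` must be a noise_spec.")
  if (spec$fraction == 0) return(segment)

  with_seed(seed, {
    sig <- segment$signal
    n <- ncol(sig)
    leads <- nrow(sig)
    n_aff <- max(1L, round(spec$fraction * n))
    start <- if (n_aff >= n) 1L else sample.int(n - n_aff + 1L, 1L)
    idx <- start:(start + n_aff - 1L)

    if (spec$kind == "hf_artifact") {
      sig[, idx] <- sig[, idx] +
        matrix(rnorm(leads * n_aff, sd = spec$amplitude), nrow = leads)
    } else if (spec$kind == "baseline_wander") {
      f <- runif(1, 0.15, 0.9) # Hz, below the 1 Hz wander ceiling
      ph <- runif(1, 0, 2 * pi)
      tt <- (idx - 1) / segment$fs
      drift <- spec$amplitude * sin(2 * pi * f * tt + ph)
      # taper so the drift enters and leaves smoothly
      w <- sin(pi * seq_along(idx) / length(idx))^2
      sig[, idx] <- sweep(sig[, idx, drop = FALSE], 2, drift * w, "+")
    } else { # dropoff: hold the value at window start
      sig[, idx] <- sig[, idx[1]]
      segment$dropoff <- TRUE
    }

    segment$signal <- sig
    segment$noise_fraction <- min(1, segment$noise_fraction + spec$fraction)
    segment$noisy <- segment$noise_fraction >= 0.25
    segment
  })
}

#' Domain-shift parameters for cohort generation
#'
#' Emulates the gap between a clean diagnostic-ECG source domain and noisier
#' ICU telemetry: a global amplitude rescaling, an added broadband noise
#' floor, and a shift of the heart-rate distribution.
#'
#' @param amplitude_scale Multiplicative gain applied to every signal.
#' @param noise_floor Standard deviation (mV) of white noise added to every
#'   sample.
#' @param hr_shift Offset (bpm) added to the mean heart rate of both rhythm
#'   classes.
#' @return A `domain_shift` list.
#' @export
domain_shift <- function(amplitude_scale = 1, noise_floor = 0, hr_shift = 0) {
  check_number(amplitude_scale, "amplitude_scale", 0, Inf)
  check_number(noise_floor, "noise_floor", 0, Inf)
  check_number(hr_shift, "hr_shift", -100, 100)
  structure(list(amplitude_scale = amplitude_scale, noise_floor = noise_floor,
                 hr_shift = hr_shift),
            class = "domain_shift")
}

#' Generate a synthetic ECG cohort
#'
#' Builds a tibble of synthetic ECG segments with per-patient structure
#' (hourly-spaced timestamps), a configurable rhythm class mix, injected
#' noise on a fraction of segments, and an out-of-distribution (OOD) class
#' emulating recordings on which expert annotators would abstain
#' (paced-like morphology buried in severe artifact). The default mix
#' mirrors an ICU telemetry test population: 14% AF among in-distribution
#' segments, 27% of segments noisy, 9% OOD.
#'
#' @param n_patients Number of patients (must be >= 1).
#' @param segments_per_patient Segment count per patient: a single count or
#'   a vector of length `n_patients`.
#' @param class_mix Named proportions for the in-distribution classes,
#'   `c(sinus = ..., af = ...)`; must sum to 1.
#' @param noise_rate Fraction of non-OOD segments receiving an artifact
#'   injection large enough to be flagged noisy.
#' @param ood_rate Fraction of segments drawn from the OOD generator.
#' @param dropoff_rate Fraction of segments with a sensor drop-off run.
#' @param shift A [domain_shift()] or `NULL` for none.
#' @param seed Integer master seed; cohorts are bitwise reproducible.
#' @param fs,duration,leads Sampling parameters per segment.
#' @param segment_spacing Minimum spacing (s) between a patient's segments.
#'
#' @return A tibble with one row per segment: `segment_id`, `patient_id`,
#'   `timestamp`, `true_rhythm`, `y_true` (1 = AF, 0 = sinus, `NA` = OOD),
#'   `noisy`, `dropoff`, `ood`, `noise_fraction` and the `signal` matrix in
#'   a list-column.
#' @export
generate_cohort <- function(n_patients, segments_per_patient = 5,
                            class_mix = c(sinus = 0.86, af = 0.14),
                            noise_rate = 0.27, ood_rate = 0.09,
                            dropoff_rate = 0, shift = NULL, seed = 1,
                            fs = 240, duration = 10, leads = 4,
                            segment_spacing = 3600) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort("`n_patients` must be a positive count.", class = "afuq_parameter_error")
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    abort("`class_mix` proportions must sum to 1.", class = "afuq_parameter_error")
  }
  check_fraction(noise_rate, "noise_rate")
  check_fraction(ood_rate, "ood_rate")
  check_fraction(dropoff_rate, "dropoff_rate")
  shift <- shift %||% domain_shift()
  n_patients <- as.integer(n_patients)
  counts <- rep_len(as.integer(segments_per_patient), n_patients)
  p_af <- unname(class_mix[["af"]])

  with_seed(seed, {
    rows <- vector("list", sum(counts))
    r <- 0L
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%04d", p)
      ts <- 0
      for (k in seq_len(counts[p])) {
        ts <- ts + segment_spacing + runif(1, 0, 0.2 * segment_spacing)
        u <- runif(1)
        if (u < ood_rate) {
          spec <- ood_rhythm(heart_rate_bpm = min(
            250, max(40, rnorm(1, 70 + shift$hr_shift, 8))))
        } else if (runif(1) < p_af) {
          spec <- af_rhythm(
            heart_rate_bpm = min(250, max(40, rnorm(1, 100 + shift$hr_shift, 15))),
            rr_cv = runif(1, 0.18, 0.35),
            fibrillatory_amplitude = runif(1, 0.06, 0.15)
          )
        } else {
          spec <- sinus_rhythm(
            heart_rate_bpm = min(250, max(40, rnorm(1, 75 + shift$hr_shift, 10))),
            rr_cv = runif(1, 0.01, 0.04),
            p_wave_amplitude = runif(1, 0.10, 0.20)
          )
        }
        seg <- generate_segment(spec, fs = fs, duration = duration,
                                leads = leads, seed = NULL)
        seg$patient_id <- pid
        seg$timestamp <- ts

        if (shift$amplitude_scale != 1) seg$signal <- seg$signal * shift$amplitude_scale
        if (shift$noise_floor > 0) {
          seg$signal <- seg$signal +
            matrix(rnorm(length(seg$signal), sd = shift$noise_floor),
                   nrow = nrow(seg$signal))
        }

        if (spec$label == "ood") {
          # the abstain-analog class: severe artifact on top of odd morphology
          seg <- inject_noise(seg, noise_spec("hf_artifact",
                                              fraction = runif(1, 0.4, 0.8),
                                              amplitude = runif(1, 0.5, 1.0)),
                              seed = NULL)
        } else if (runif(1) < noise_rate) {
          kind <- sample(c("hf_artifact", "baseline_wander"), 1)
          amp <- if (kind == "hf_artifact") runif(1, 0.25, 0.8) else runif(1, 0.4, 1.2)
          seg <- inject_noise(seg, noise_spec(kind,
                                              fraction = runif(1, 0.25, 0.8),
                                              amplitude = amp),
                              seed = NULL)
        }
        if (runif(1) < dropoff_rate) {
          seg <- inject_noise(seg, noise_spec("dropoff",
                                              fraction = runif(1, 0.05, 0.3)),
                              seed = NULL)
        }

        r <- r + 1L
        rows[[r]] <- tibble(
          patient_id = pid, timestamp = ts, true_rhythm = spec$label,
          y_true = if (spec$label == "af") 1L else if (spec$label == "sinus") 0L else NA_integer_,
          noisy = seg$noisy, dropoff = seg$dropoff,
          ood = spec$label == "ood", noise_fraction = seg$noise_fraction,
          fs = fs, duration = duration, signal = list(seg$signal)
        )
      }
    }
    out <- bind_rows(rows)
    out$segment_id <- sprintf("S%05d", seq_len(nrow(out)))
    dplyr::relocate(out, "segment_id")
  })
}

#' Label corruption model
#'
#' A 2x2 row-stochastic flip matrix: `flip[a + 1, b + 1]` is the probability
#' that a true label `a` is observed as `b`. Used to inject controlled
#' weak-label error so the cleaning machinery can be validated against known
#' corruption.
#'
#' @param flip 2x2 row-stochastic matrix, or `NULL` to build a symmetric one.
#' @param flip_rate Symmetric flip probability used when `flip` is `NULL`.
#' @param seed Optional integer seed.
#' @return A `label_noise_model` list.
#' @export
label_noise_model <- function(flip = NULL, flip_rate = 0.2, seed = NULL) {
  if (is.null(flip)) {
    check_fraction(flip_rate, "flip_rate")
    flip <- matrix(c(1 - flip_rate, flip_rate, flip_rate, 1 - flip_rate),
                   2, 2, byrow = TRUE)
  }
  if (!is.matrix(flip) || !all(dim(flip) == c(2, 2)) ||
      any(flip < 0) || any(flip > 1) ||
      any(abs(rowSums(flip) - 1) > 1e-12)) {
    abort("`flip` must be a 2x2 row-stochastic matrix (rows sum to 1).",
          class = "afuq_parameter_error")
  }
  structure(list(flip = flip, seed = seed), class = "label_noise_model")
}

#' Corrupt binary labels with a known flip model
#'
#' Flips each label independently according to the model's row-stochastic
#' flip matrix. Deterministic given the seed.
#'
#' @param labels Binary (0/1) vector of true labels.
#' @param model A [label_noise_model()].
#' @param seed Integer seed; defaults to `model$seed`.
#' @return A tibble with columns `truth`, `observed` and `flipped`; the
#'   flipped index set is `which(out$flipped)`.
#' @export
corrupt_labels <- function(labels, model, seed = model$seed) {
  if (!inherits(model, "label_noise_model")) {
    abort("`model` must be a label_noise_model.", class = "afuq_parameter_error")
  }
  if (!all(labels %in% c(0, 1))) {
    abort("`labels` must be binary (0/1).", class = "afuq_parameter_error")
  }
  labels <- as.integer(labels)
  with_seed(seed, {
    p_flip <- ifelse(labels == 0, model$flip[1, 2], model$flip[2, 1])
    flipped <- runif(length(labels)) < p_flip
    tibble(truth = labels,
           observed = ifelse(flipped, 1L - labels, labels),
           flipped = flipped)
  })
}
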