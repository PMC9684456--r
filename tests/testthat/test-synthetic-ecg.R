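# Synthetic ECG generator: rhythm specs, segments, noise injection,
# cohorts and label corruption.

test_that("generate_segment produces the expected shape", {
  seg <- generate_segment(sinus_rhythm(), fs = 240, duration = 10, leads = 4,
                          seed = 1)
  expect_s3_class(seg, "ecg_segment")
  expect_identical(dim(seg$signal), c(4L, 2400L))
  expect_true(all(is.finite(seg$signal)))
  expect_identical(seg$true_rhythm, "sinus")
  expect_false(seg$noisy)
})

test_that("a 60 bpm sinus segment carries about 10 R-peaks", {
  seg <- generate_segment(sinus_rhythm(heart_rate_bpm = 60), seed = 7)
  pk <- oracle_peaks(seg$signal[1, ], seg$fs)
  expect_gte(length(pk), 9)
  expect_lte(length(pk), 11)
})

test_that("AF segments have more irregular detected RR than sinus", {
  cvs <- function(spec_fun, seeds) {
    vapply(seeds, function(s) {
      seg <- generate_segment(spec_fun(), seed = s)
      pk <- oracle_peaks(seg$signal[1, ], seg$fs)
      rr <- diff(pk)
      sd(rr) / mean(rr)
    }, numeric(1))
  }
  seeds <- 1:25
  expect_gt(mean(cvs(af_rhythm, seeds)), mean(cvs(sinus_rhythm, seeds)))
})

test_that("P-wave bumps appear iff p_wave_amplitude > 0", {
  # generate with identical RNG stream; the only difference is the P bump
  with_p <- generate_segment(rhythm_spec(60, 0.02, 0.3), seed = 3)
  without_p <- generate_segment(rhythm_spec(60, 0.02, 0), seed = 3)
  diff_sig <- with_p$signal[1, ] - without_p$signal[1, ]
  expect_gt(max(abs(diff_sig)), 0.2) # P bumps present
  # the difference is localised (bumps), not a global offset
  expect_lt(stats::median(abs(diff_sig)), 0.02)
})

test_that("segment generation is deterministic given seed", {
  a <- generate_segment(af_rhythm(), seed = 11)
  b <- generate_segment(af_rhythm(), seed = 11)
  expect_identical(a$signal, b$signal)
  c <- generate_segment(af_rhythm(), seed = 12)
  expect_false(identical(a$signal, c$signal))
})

test_that("rhythm parameter validation errors", {
  expect_error(rhythm_spec(10, 0.02, 0.1), class = "afuq_parameter_error")
  expect_error(rhythm_spec(300, 0.02, 0.1), class = "afuq_parameter_error")
  expect_error(generate_segment(sinus_rhythm(), duration = -1),
               class = "afuq_parameter_error")
})

test_that("inject_noise with fraction 0 is the identity", {
  seg <- generate_segment(sinus_rhythm(), seed = 1)
  out <- inject_noise(seg, noise_spec("hf_artifact", fraction = 0), seed = 1)
  expect_identical(out$signal, seg$signal)
  expect_false(out$noisy)
})

test_that("hf artifact raises variance only inside the affected window", {
  seg <- generate_segment(sinus_rhythm(), seed = 2)
  out <- inject_noise(seg, noise_spec("hf_artifact", fraction = 0.5,
                                      amplitude = 5), seed = 9)
  changed <- which(out$signal[1, ] != seg$signal[1, ])
  unchanged <- setdiff(seq_len(ncol(seg$signal)), changed)
  expect_equal(length(changed), 1200)
  expect_identical(out$signal[, unchanged], seg$signal[, unchanged])
  expect_gt(var(out$signal[1, changed]), var(out$signal[1, unchanged]))
})

test_that("noisy flag implements the >= 1/4-of-record criterion exactly", {
  seg <- generate_segment(sinus_rhythm(), seed = 3)
  below <- inject_noise(seg, noise_spec("hf_artifact", fraction = 0.24), seed = 1)
  at <- inject_noise(seg, noise_spec("hf_artifact", fraction = 0.25), seed = 1)
  expect_false(below$noisy)
  expect_true(at$noisy)
  # cumulative across injections
  twice <- inject_noise(below, noise_spec("hf_artifact", fraction = 0.01),
                        seed = 2)
  expect_true(twice$noisy)
})

test_that("dropoff flattens a run and sets the flag", {
  seg <- generate_segment(sinus_rhythm(), seed = 4)
  out <- inject_noise(seg, noise_spec("dropoff", fraction = 0.3), seed = 5)
  expect_true(out$dropoff)
  changed <- which(out$signal[1, ] != seg$signal[1, ])
  expect_true(length(unique(out$signal[1, min(changed):max(changed)])) <= 4)
})

test_that("baseline wander is low-frequency", {
  seg <- generate_segment(sinus_rhythm(), seed = 5)
  out <- inject_noise(seg, noise_spec("baseline_wander", fraction = 1,
                                      amplitude = 2), seed = 6)
  drift <- out$signal[1, ] - seg$signal[1, ]
  spec <- Mod(stats::fft(drift))[2:200]
  freqs <- (1:199) / 10 # Hz, for a 10 s record
  peak_freq <- freqs[which.max(spec)]
  expect_lte(peak_freq, 1)
})

test_that("generate_cohort bookkeeping and determinism", {
  co <- generate_cohort(10, 5, ood_rate = 0, noise_rate = 0, seed = 42)
  expect_equal(nrow(co), 50)
  expect_false(any(co$ood))
  expect_equal(dplyr::n_distinct(co$patient_id), 10)
  co2 <- generate_cohort(10, 5, ood_rate = 0, noise_rate = 0, seed = 42)
  expect_identical(co, co2)
  # per-patient timestamps spaced at least one hour apart
  gaps <- co |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(min_gap = min(diff(timestamp)))
  expect_true(all(gaps$min_gap >= 3600))
  expect_error(generate_cohort(0), class = "afuq_parameter_error")
})

test_that("cohort class mix is binomially plausible", {
  co <- generate_cohort(200, 5, class_mix = c(sinus = 0.87, af = 0.13),
                        ood_rate = 0, noise_rate = 0, seed = 7)
  n_af <- sum(co$y_true == 1)
  expect_lt(abs(n_af - 1000 * 0.13), 3 * sqrt(1000 * 0.13 * 0.87))
})

test_that("a simple RR-CV threshold separates the default clean presets", {
  co <- generate_cohort(100, 5, ood_rate = 0, noise_rate = 0, seed = 10)
  co <- classify_by_rr_cv(co)
  expect_gte(mean(co$rr_pred == co$y_true), 0.95)
})

test_that("corrupt_labels respects the flip model", {
  y <- rep(c(0L, 1L), 50)
  ident <- label_noise_model(flip = diag(2))
  out <- corrupt_labels(y, ident, seed = 1)
  expect_identical(out$observed, y)
  expect_false(any(out$flipped))

  forced <- label_noise_model(flip = matrix(c(0, 1, 1, 0), 2, 2))
  out2 <- corrupt_labels(y, forced, seed = 1)
  expect_identical(out2$observed, 1L - y)
  expect_true(all(out2$flipped))

  y_big <- rep(c(0L, 1L), 500)
  out3 <- corrupt_labels(y_big, label_noise_model(flip_rate = 0.2), seed = 3)
  expect_lt(abs(sum(out3$flipped) - 200), 3 * sqrt(1000 * 0.2 * 0.8))
  expect_error(label_noise_model(flip = matrix(c(0.5, 0.2, 0.3, 0.7), 2, 2)),
               class = "afuq_parameter_error")
})
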