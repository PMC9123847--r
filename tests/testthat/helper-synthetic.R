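# shared fixture builders (all programmatic; no files)

tone_recording <- function(freqs, amps = rep(1, length(freqs)), fs = 200,
                           duration_s = 30, n_channels = 1, noise_sd = 0,
                           labels = NULL, units = "uV", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq_len(round(duration_s * fs)) / fs
  base <- rowSums(vapply(seq_along(freqs),
                         function(i) amps[i] * sin(2 * pi * freqs[i] * tt),
                         numeric(length(tt))))
  x <- vapply(seq_len(n_channels),
              function(ch) base + stats::rnorm(length(tt), 0, noise_sd),
              numeric(length(tt)))
  time_series_recording(x, fs, labels, units = units)
}

# noise-free pairs generated exactly from a given coefficient vector, so the
# fitted model reproduces beta to numerical precision
exact_pairs <- function(beta, n_subjects = 10, n_per_subject = 3, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    d1 <- runif(1, 0.2, 0.8)
    age <- runif(1, 1, 20)
    ivi <- sort(runif(n_per_subject, 0.1, 5))
    data.frame(subject_id = paste0("S", i), delta_initial = d1,
               delta_subsequent = beta[1] + beta[2] * d1 +
                 beta[3] * log10(age) * ivi,
               age_initial = age, ivi = ivi)
  })
  do.call(rbind, rows)
}

fit_quiet <- function(...) suppressWarnings(fit_natural_history(...))

small_mouse_cohort <- function(treatment_effect = 1e-3, seed = 1) {
  make_mouse_cohort(mouse_cohort_spec(treatment_effect = treatment_effect),
                    seed = seed)
}
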