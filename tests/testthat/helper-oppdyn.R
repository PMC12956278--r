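# shared fixtures built in code

tiny_design <- function(n_blocks = 1, v = 6, i = 2, ctrl = 2, catch = 0) {
  design_config(n_blocks = n_blocks, n_valid_per_leading = v,
                n_invalid_per_leading = i, n_control_per_trailing = ctrl,
                catch_fraction = catch)
}

quiet_noise <- function() {
  noise_spec(noise_sd = 0, blink_rate_hz = 0, line_noise_amp = 0,
             eog_noise_sd = 0)
}

# a small noiseless recording with flat (no expectation) effects
tiny_recording <- function(seed = 1, fs = 256, n_ch = 16, base_gain = 4,
                           design = tiny_design(), noise = quiet_noise(),
                           sharpening = 0, dampening = 0, memory = 0) {
  tm <- build_transition_matrix(assignment_seed = seed)
  sq <- generate_session(tm, design, seed = seed)
  eff <- effect_spec(c(tm$leading_labels, tm$trailing_labels),
                     default_channel_labels(n_ch), base_gain = base_gain,
                     sharpening_gain = sharpening, dampening_gain = dampening,
                     memory_gain = memory, pattern_seed = seed + 1)
  list(tm = tm, seq = sq, effects = eff,
       rec = simulate_recording(sq, eff, noise, fs_hz = fs, seed = seed + 2))
}

# synthetic epochs with class-specific constant patterns plus noise
synth_epochs <- function(n_per_class, classes, sep, noise, seed,
                         n_ch = 6, n_tp = 5) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  arr <- array(rnorm(n_tp * n_ch * n, sd = noise), c(n_tp, n_ch, n))
  for (k in seq_along(classes)) {
    pat <- numeric(n_ch); pat[k] <- sep
    for (i in which(labels == classes[k]))
      arr[, , i] <- arr[, , i] + outer(rep(1, n_tp), pat)
  }
  meta <- data.frame(index = seq_len(n) - 1L,
                     leading_cat = rep(rep(c("L1", "L2"),
                                           length.out = length(classes)),
                                       each = n_per_class),
                     trailing_cat = labels,
                     stringsAsFactors = FALSE)
  structure(list(data = arr, times_s = seq_len(n_tp) / 100, fs_hz = 100,
                 channel_labels = paste0("ch", seq_len(n_ch)),
                 metadata = meta, rejected_mask = rep(FALSE, n),
                 time_lock = "leading"),
            class = "eeg_epochs")
}

# hand-built decoding_result for the learning-dynamics module
fake_decoding_result <- function(correct, index, times, validity = "valid") {
  structure(list(accuracy = colMeans(correct, na.rm = TRUE),
                 times_s = times, per_trial_correct = correct,
                 metadata = data.frame(index = index),
                 chance_level = 0.5, n_components_used = 1,
                 n_folds = 1, analysis = "sensory_trailing",
                 validity = validity, subject_id = 1,
                 time_lock = "trailing_onset"),
            class = "decoding_result")
}

fast_cfg <- function(...) pipeline_config(n_perm = 200, ...)

window_idx_pkg <- function(times, window) {
  which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
}
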