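#' Scalp and EOG channel labels
#'
#' Standard 10/20-extended electrode names. The list is ordered so that
#' truncating it to the first `n_scalp` labels still yields a sensible
#' whole-head montage including the occipital channels `Oz`, `O1`, `O2`
#' (used by the ERP region of interest) and the frontopolar channels
#' that pick up blink activity.
#'
#' @param n_scalp number of scalp channels (4 to 64).
#' @return character vector of `n_scalp` scalp labels
#'   (`eog_channel_labels()` returns the 4 EOG labels).
#' @export
default_channel_labels <- function(n_scalp = 64) {
  base <- c("Oz", "O1", "O2", "Fp1", "Fp2", "POz", "PO3", "PO4", "Pz",
            "P3", "P4", "P7", "P8", "CPz", "CP1", "CP2", "Cz", "C3",
            "C4", "T7", "T8", "FCz", "FC1", "FC2", "Fz", "F3", "F4",
            "F7", "F8", "AFz", "AF3", "AF4",
            "PO7", "PO8", "P1", "P2", "P5", "P6", "CP3", "CP4", "CP5",
            "CP6", "C1", "C2", "C5", "C6", "FC3", "FC4", "FC5", "FC6",
            "F1", "F2", "F5", "F6", "FT7", "FT8", "TP7", "TP8", "AF7",
            "AF8", "F9", "F10", "TP9", "TP10")
  stopifnot(n_scalp >= 4, n_scalp <= length(base))
  base[seq_len(n_scalp)]
}

#' @rdname default_channel_labels
#' @export
eog_channel_labels <- function() c("VEOGU", "VEOGL", "HEOGL", "HEOGR")

#' Biphasic visual evoked response template
#'
#' A smooth, band-limited time course emulating an occipital visual
#' evoked response: a small negativity near 90 ms, a broad positivity
#' peaking near 165 ms and a later negativity near 290 ms, so that both
#' the early (123-180 ms) and late (280-296 ms) analysis windows carry
#' signal. Returns a function of time (s, relative to stimulus onset)
#' that is zero outside `[0, 0.45]`.
#'
#' @return function mapping a numeric time vector to amplitudes (peak 1).
#' @export
evoked_template <- function() {
  function(t) {
    a <- -0.5 * exp(-((t - 0.09) / 0.025)^2) +
          1.0 * exp(-((t - 0.165) / 0.055)^2) -
          1.0 * exp(-((t - 0.29) / 0.04)^2)
    a[t < 0 | t > 0.45] <- 0
    a
  }
}

#' Logarithmic across-trial gain profiles
#'
#' Gain functions of the trial index `t` used to let expectation effects
#' emerge or decay over the course of a session.
#' `log_growth_gain` rises from 0 to `g_inf` as
#' `g_inf * min(1, log(1 + t/tau) / log(1 + t_max/tau))`;
#' `log_decay_gain` is its complement, falling from `g0` to 0 by trial
#' `t_max`. `constant_gain` is a flat profile.
#'
#' @param g_inf,g0,g asymptotic / initial / constant gain (>= 0).
#' @param tau curvature time constant in trials.
#' @param t_max trial index at which the profile saturates.
#' @return function of a trial-index vector.
#' @export
log_growth_gain <- function(g_inf, tau = 60, t_max = 864) {
  stopifnot(g_inf >= 0, tau > 0, t_max > 0)
  function(t) g_inf * pmin(1, log(1 + t / tau) / log(1 + t_max / tau))
}

#' @rdname log_growth_gain
#' @export
log_decay_gain <- function(g0, tau = 60, t_max = 864) {
  stopifnot(g0 >= 0, tau > 0, t_max > 0)
  function(t) g0 * (1 - pmin(1, log(1 + t / tau) / log(1 + t_max / tau)))
}

#' @rdname log_growth_gain
#' @export
constant_gain <- function(g) {
  stopifnot(is.finite(g), g >= 0)
  function(t) rep(g, length(t))
}

#' Specification of the simulated evoked effects
#'
#' Defines the category-specific spatial patterns, the evoked time
#' course, and the expectation-dependent gain modulations injected by
#' [simulate_recording()]. Patterns are unit-norm random topographies
#' with posterior emphasis (visual responses are strongest over
#' occipito-parietal channels). Within the sharpening window of valid
#' trials the trailing-category pattern is scaled by
#' `1 + sharpening_gain(trial)`; within the dampening window of invalid
#' trials by `1 + dampening_gain(trial)`. On valid trials the leading
#' category's pattern is additionally re-embedded at low gain during the
#' trailing response (a memory trace of the predictive context).
#'
#' The default gain profiles encode the across-trial study conditions:
#' the dampening modulation starts at full strength and decays
#' logarithmically to zero by mid-session, while the sharpening
#' modulation grows logarithmically from zero over the same range.
#' Pass [constant_gain()] profiles for stationary within-trial effects.
#'
#' @param categories character vector of all category names.
#' @param channel_labels scalp channel labels receiving the patterns.
#' @param base_gain evoked amplitude in microvolts at the template peak.
#' @param sharpening_gain,dampening_gain scalar or function of trial
#'   index; scalars are wrapped with [constant_gain()].
#' @param memory_gain gain of the leading-category pattern re-embedded
#'   during the trailing epoch of valid trials, relative to `base_gain`.
#' @param sharpening_window_s,dampening_window_s modulation windows in
#'   seconds relative to trailing onset.
#' @param template evoked time-course function, see [evoked_template()].
#' @param pattern_seed seed for the random category topographies.
#' @return list of class `"effect_spec"`.
#' @export
effect_spec <- function(categories,
                        channel_labels = default_channel_labels(64),
                        base_gain = 5,
                        sharpening_gain = log_growth_gain(1),
                        dampening_gain = log_decay_gain(1),
                        memory_gain = 0.4,
                        sharpening_window_s = c(0.123, 0.180),
                        dampening_window_s = c(0.280, 0.296),
                        template = evoked_template(),
                        pattern_seed = 99L) {
  stopifnot(length(categories) >= 2, base_gain >= 0, memory_gain >= 0,
            sharpening_window_s[1] < sharpening_window_s[2],
            dampening_window_s[1] < dampening_window_s[2])
  if (is.numeric(sharpening_gain)) sharpening_gain <- constant_gain(sharpening_gain)
  if (is.numeric(dampening_gain)) dampening_gain <- constant_gain(dampening_gain)
  probe <- c(sharpening_gain(c(1, 500, 2000)), dampening_gain(c(1, 500, 2000)))
  if (!all(is.finite(probe)) || any(probe < 0))
    stop("gain functions must be finite and non-negative")

  rng <- local_rng(pattern_seed)
  n_ch <- length(channel_labels)
  posterior <- grepl("^(O|PO)", channel_labels)
  parietal <- grepl("^P[0-9z]", channel_labels)
  w <- 1 + 1.5 * posterior + 0.5 * parietal
  patterns <- sapply(categories, function(cc) {
    p <- rnorm(n_ch) * w
    p / sqrt(sum(p^2))
  })
  rownames(patterns) <- channel_labels

  structure(list(categories = categories,
                 channel_labels = channel_labels,
                 pattern_per_category = patterns,
                 base_gain = base_gain,
                 sharpening_gain = sharpening_gain,
                 dampening_gain = dampening_gain,
                 memory_gain = memory_gain,
                 sharpening_window_s = sharpening_window_s,
                 dampening_window_s = dampening_window_s,
                 template = template),
            class = "effect_spec")
}

#' Specification of the simulated noise
#'
#' @param noise_sd sensor-noise standard deviation in microvolts.
#' @param spatial_corr uniform between-channel correlation of the sensor
#'   noise (0 = independent channels).
#' @param blink_rate_hz mean rate of eye blinks (Poisson onsets).
#' @param blink_amp blink amplitude in microvolts on the upper vertical
#'   EOG; blinks also appear, attenuated, on frontal scalp channels.
#' @param line_noise_amp amplitude (microvolts) of 50 Hz mains noise.
#' @param eog_noise_sd sensor noise on the EOG channels.
#' @return list of class `"noise_spec"`.
#' @export
noise_spec <- function(noise_sd = 8, spatial_corr = 0.3,
                       blink_rate_hz = 0.12, blink_amp = 150,
                       line_noise_amp = 2, eog_noise_sd = 4) {
  stopifnot(noise_sd >= 0, spatial_corr >= 0, spatial_corr < 1,
            blink_rate_hz >= 0, blink_amp >= 0, line_noise_amp >= 0,
            eog_noise_sd >= 0)
  structure(list(noise_sd = noise_sd, spatial_corr = spatial_corr,
                 blink_rate_hz = blink_rate_hz, blink_amp = blink_amp,
                 line_noise_amp = line_noise_amp,
                 eog_noise_sd = eog_noise_sd),
            class = "noise_spec")
}

blink_projection <- function(labels) {
  proj <- numeric(length(labels))
  proj[labels == "VEOGU"] <- 1
  proj[labels == "VEOGL"] <- -0.7
  proj[labels %in% c("HEOGL", "HEOGR")] <- 0.08
  proj[grepl("^Fp", labels)] <- 0.45
  proj[grepl("^AF", labels)] <- 0.25
  proj[grepl("^F[0-9z]", labels)] <- 0.12
  proj[grepl("^(FC|FT)", labels)] <- 0.05
  proj
}

#' Simulate a continuous EEG recording from a trial sequence
#'
#' Forward model: for every trial the leading category's spatial pattern
#' times the evoked template is added at the leading onset and the
#' trailing category's pattern at the trailing onset. Expectation
#' modulations scale the trailing pattern inside the sharpening window
#' (valid trials) or the dampening window (invalid trials) by
#' `1 + gain(trial index)`; valid trials additionally carry a low-gain
#' copy of the leading pattern during the trailing response (memory
#' signal). Blink artifacts (stereotyped deflection on the vertical EOG
#' and, attenuated, on frontal channels, Poisson onsets), 50 Hz line
#' noise and spatially correlated Gaussian sensor noise are added on
#' top. Deterministic for a given `seed`.
#'
#' @param seq a [generate_session()] trial sequence.
#' @param effects an [effect_spec()]; its `channel_labels` define the
#'   scalp montage.
#' @param noise a [noise_spec()].
#' @param fs_hz sampling rate in Hz (native acquisition default 2048).
#' @param seed integer seed.
#' @param pad_s silent padding (s) appended after the last trial.
#'
#' @return an object of class `"eeg_recording"`: list with `data`
#'   (samples x channels matrix, microvolts), `fs_hz`, `channel_labels`
#'   (scalp then 4 EOG), `is_eog`, `events` (data frame with columns
#'   `sample`, `trial_index`, `marker`), `seq` (the trial metadata) and
#'   `blink_onsets_s` (ground-truth injected blink times).
#' @examples
#' tm <- build_transition_matrix(assignment_seed = 1)
#' seq <- generate_session(tm, design_config(n_blocks = 0), seed = 1)
#' @export
simulate_recording <- function(seq, effects, noise = noise_spec(),
                               fs_hz = 2048, seed = 1L, pad_s = 1) {
  stopifnot(inherits(effects, "effect_spec"), inherits(noise, "noise_spec"))
  if (nrow(seq) == 0L) stop("empty trial sequence")
  miss <- setdiff(unique(c(seq$leading_cat, seq$trailing_cat)),
                  effects$categories)
  if (length(miss))
    stop("categories missing from effect_spec: ", paste(miss, collapse = ", "))
  rng <- local_rng(seed)

  scalp <- effects$channel_labels
  labels <- c(scalp, eog_channel_labels())
  n_scalp <- length(scalp)
  n_ch <- length(labels)
  dur <- max(seq$trailing_onset_s) + pad_s
  n <- ceiling(dur * fs_hz)

  # sensor noise, optionally with uniform spatial correlation over scalp
  data <- matrix(rnorm(n * n_ch), n, n_ch)
  if (noise$spatial_corr > 0 && noise$noise_sd > 0) {
    sigma <- matrix(noise$spatial_corr, n_scalp, n_scalp)
    diag(sigma) <- 1
    data[, seq_len(n_scalp)] <- data[, seq_len(n_scalp)] %*% chol(sigma)
  }
  data[, seq_len(n_scalp)] <- data[, seq_len(n_scalp)] * noise$noise_sd
  data[, n_scalp + 1:4] <- data[, n_scalp + 1:4] * noise$eog_noise_sd

  tvec <- seq_len(n) / fs_hz
  if (noise$line_noise_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    line <- noise$line_noise_amp * sin(2 * pi * 50 * tvec + phase)
    amp_jitter <- runif(n_scalp, 0.5, 1.5)
    data[, seq_len(n_scalp)] <- data[, seq_len(n_scalp)] +
      outer(line, amp_jitter)
  }

  # blinks: Poisson onsets, stereotyped squared-sine deflection
  blink_onsets <- numeric(0)
  if (noise$blink_rate_hz > 0 && noise$blink_amp > 0) {
    t_cur <- runif(1, 0, 2 / noise$blink_rate_hz)
    while (t_cur < dur - 0.5) {
      blink_onsets <- c(blink_onsets, t_cur)
      t_cur <- t_cur + max(0.5, rexp_(1 / noise$blink_rate_hz))
    }
    if (length(blink_onsets)) {
      bt <- seq(0, 0.35, by = 1 / fs_hz)
      btpl <- noise$blink_amp * sin(pi * bt / 0.35)^2
      proj <- blink_projection(labels)
      onset_samples <- round(blink_onsets * fs_hz) + 1L
      onset_samples <- onset_samples[onset_samples + length(btpl) - 1L <= n]
      # blinks are >= 0.5 s apart so their segments never overlap
      idx <- as.vector(outer(0:(length(btpl) - 1L), onset_samples, "+"))
      data[idx, ] <- data[idx, ] +
        matrix(rep(btpl, length(onset_samples)), ncol = 1) %*% t(proj)
    }
  }

  # evoked responses; within a category the patches never overlap
  # (template 0.45 s, trial spacing >= 2.3 s), so contributions can be
  # injected with one vectorized assignment per category and role
  tpl_t <- seq(0, 0.45, by = 1 / fs_hz)
  tpl <- effects$template(tpl_t)
  ltpl <- length(tpl)
  sharp_idx <- window_idx(tpl_t, effects$sharpening_window_s)
  damp_idx <- window_idx(tpl_t, effects$dampening_window_s)
  pat <- effects$pattern_per_category
  g <- effects$base_gain
  s_lead <- round(seq$leading_onset_s * fs_hz) + 1L
  s_trail <- round(seq$trailing_onset_s * fs_hz) + 1L
  events <- data.frame(sample = as.vector(rbind(s_lead, s_trail)),
                       trial_index = rep(seq$index, each = 2),
                       marker = rep(c("leading_onset", "trailing_onset"),
                                    nrow(seq)))
  scalp_cols <- seq_len(n_scalp)
  inject <- function(onsets, waves, pattern) {
    # onsets: sample indices; waves: ltpl x length(onsets) matrix
    ok <- onsets >= 1 & onsets + ltpl - 1L <= n
    if (!any(ok)) return(invisible(NULL))
    idx <- as.vector(outer(0:(ltpl - 1L), onsets[ok], "+"))
    data[idx, scalp_cols] <<- data[idx, scalp_cols] +
      matrix(waves[, ok], ncol = 1) %*% t(pattern)
    invisible(NULL)
  }
  trial_pos <- seq$index + 1  # 1-based trial position for gain profiles
  for (cat in unique(seq$leading_cat)) {
    sel <- seq$leading_cat == cat
    inject(s_lead[sel], matrix(rep(g * tpl, sum(sel)), ltpl), pat[, cat])
  }
  # trailing responses with per-trial gain modulation
  for (cat in unique(seq$trailing_cat)) {
    sel <- which(seq$trailing_cat == cat)
    waves <- matrix(rep(g * tpl, length(sel)), ltpl)
    for (j in seq_along(sel)) {
      i <- sel[j]
      if (seq$validity[i] == "valid") {
        waves[sharp_idx, j] <- waves[sharp_idx, j] *
          (1 + effects$sharpening_gain(trial_pos[i]))
      } else if (seq$validity[i] == "invalid") {
        waves[damp_idx, j] <- waves[damp_idx, j] *
          (1 + effects$dampening_gain(trial_pos[i]))
      }
    }
    inject(s_trail[sel], waves, pat[, cat])
  }
  # memory trace of the leading category on valid trials
  if (effects$memory_gain > 0) {
    for (cat in unique(seq$leading_cat)) {
      sel <- seq$leading_cat == cat & seq$validity == "valid"
      if (any(sel))
        inject(s_trail[sel],
               matrix(rep(g * effects$memory_gain * tpl, sum(sel)), ltpl),
               pat[, cat])
    }
  }

  structure(list(data = data, fs_hz = fs_hz, channel_labels = labels,
                 is_eog = labels %in% eog_channel_labels(),
                 events = events, seq = seq,
                 blink_onsets_s = blink_onsets),
            class = "eeg_recording")
}

# exponential draw via runif so that one seeded stream drives everything
rexp_ <- function(mean) -mean * log(runif(1))

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              ncol(x$data), nrow(x$data), x$fs_hz,
              nrow(x$data) / x$fs_hz, nrow(x$events)))
  invisible(x)
}

#' Reaction-time parameters and simulation for the categorisation task
#'
#' Reaction times are drawn from condition-specific log-normal
#' distributions; the defaults make valid trials ~25 ms faster than
#' invalid and neutral trials, emulating implicit learning of the
#' category transitions.
#'
#' @param valid_median_ms,invalid_median_ms,neutral_median_ms per
#'   condition median RT in milliseconds.
#' @param sdlog log-scale standard deviation (0 gives exactly the
#'   medians).
#' @return `rt_params()` returns a parameter list; `simulate_rts()`
#'   returns a data frame with columns `subject`, `trial`, `condition`,
#'   `rt_ms` (one row per non-catch trial).
#' @export
rt_params <- function(valid_median_ms = 599, invalid_median_ms = 624,
                      neutral_median_ms = 625, sdlog = 0.15) {
  if (valid_median_ms <= 0 || invalid_median_ms <= 0 ||
      neutral_median_ms <= 0 || sdlog < 0)
    stop("rt_params: scale parameters must be positive")
  list(valid = valid_median_ms, invalid = invalid_median_ms,
       neutral = neutral_median_ms, sdlog = sdlog)
}

#' @rdname rt_params
#' @param seq a trial sequence.
#' @param params an [rt_params()] list.
#' @param seed integer seed.
#' @param subject subject identifier copied into the table.
#' @export
simulate_rts <- function(seq, params = rt_params(), seed = 1L, subject = 1L) {
  rng <- local_rng(seed)
  keep <- !seq$is_catch
  cond <- seq$validity[keep]
  med <- unlist(params[cond])
  rt <- med * exp(params$sdlog * rnorm(sum(keep)))
  data.frame(subject = subject, trial = seq$index[keep],
             condition = cond, rt_ms = as.numeric(rt))
}
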