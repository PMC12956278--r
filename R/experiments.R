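# Simulation studies exercising the full pipeline at reduced scale.
# These are the package's reproducible computational experiments: effect
# recovery, type-I calibration, learning-curve recovery and mixed-model
# power, each driven by a single seed.

#' Reduced-scale study configuration
#'
#' The pipeline parameters used by the simulation studies: 32 scalp
#' channels, 256 Hz acquisition downsampled to 128 Hz, one block of 240
#' trials at the full design ratios (52 trials per 2:1 leading category,
#' 39 valid + 13 invalid, and 16 control trials per control trailing
#' category), epochs spanning the leading-to-trailing pair, decoding over
#' 0.05-0.35 s after trailing onset with 8 cross-validation folds per
#' validity. The pipeline is scale-agnostic; these sizes keep a
#' 20-cohort recovery study tractable on a single core while preserving
#' every structural property of the full-scale design.
#'
#' @return list with `cfg` (a [pipeline_config()]), `design`
#'   (a [design_config()]), `n_channels` and `fs_hz`.
#' @export
reduced_scale_config <- function() {
  list(cfg = pipeline_config(fs_down_hz = 128, dss_n_keep = 12,
                             epoch_window_s = c(-0.2, 1.4),
                             decode_window_s = c(0.05, 0.35),
                             max_folds = 8, n_perm = 1000),
       design = design_config(n_blocks = 1, n_valid_per_leading = 39,
                              n_invalid_per_leading = 13,
                              n_control_per_trailing = 16),
       n_channels = 32, fs_hz = 256)
}

#' Simulate and decode one subject end to end
#'
#' Generates a randomized session, synthesizes the EEG recording with
#' the requested expectation gains, preprocesses it with the full chain
#' and runs the trailing-image sensory decoding analysis split by
#' validity.
#'
#' @param seed integer seed (drives design randomization, simulation
#'   noise, subject-specific spatial patterns and fold assignment).
#' @param sharpening_gain,dampening_gain gain (scalar or function of
#'   trial index) applied to the trailing pattern inside the early
#'   window of valid trials / the late window of invalid trials.
#' @param scale a [reduced_scale_config()]-style list.
#' @param assignment_seed seed of the category-pair assignment (shared
#'   across the subjects of a cohort: one experiment, one design).
#' @param base_gain,noise_sd evoked amplitude and sensor noise (microvolts).
#' @param memory_gain see [effect_spec()].
#' @param analysis decoding analysis to run.
#' @return the [run_decoding_suite()] result (elements `valid` and
#'   `invalid`).
#' @export
simulate_study_subject <- function(seed, sharpening_gain = 0,
                                   dampening_gain = 0,
                                   scale = reduced_scale_config(),
                                   assignment_seed = 1L,
                                   base_gain = 4, noise_sd = 4,
                                   memory_gain = 0,
                                   analysis = "sensory_trailing") {
  tm <- build_transition_matrix(assignment_seed = assignment_seed)
  seq <- generate_session(tm, scale$design, seed = child_seed(seed, 1))
  eff <- effect_spec(categories = c(tm$leading_labels, tm$trailing_labels),
                     channel_labels = default_channel_labels(scale$n_channels),
                     base_gain = base_gain,
                     sharpening_gain = sharpening_gain,
                     dampening_gain = dampening_gain,
                     memory_gain = memory_gain,
                     sharpening_window_s = scale$cfg$sharpening_window_s,
                     dampening_window_s = scale$cfg$dampening_window_s,
                     pattern_seed = child_seed(seed, 2))
  rec <- simulate_recording(seq, eff, noise_spec(noise_sd = noise_sd),
                            fs_hz = scale$fs_hz, seed = child_seed(seed, 3))
  ep <- preprocess_pipeline(rec, scale$cfg)
  run_decoding_suite(ep, analysis = analysis, cfg = scale$cfg,
                     seed = child_seed(seed, 4), subject_id = seed)
}

cluster_overlaps <- function(clusters, window, sign, alpha = 0.05) {
  if (!nrow(clusters)) return(FALSE)
  hit <- clusters$sign == sign & clusters$p_fwe < alpha &
    clusters$end_s >= window[1] & clusters$start_s <= window[2]
  any(hit)
}

#' Within-trial effect-recovery study
#'
#' Simulates replicate cohorts with a constant sharpening gain injected
#' in the early window of valid trials and a constant dampening gain in
#' the late window of invalid trials, runs the full pipeline and the
#' paired group cluster test per cohort, and records whether an early
#' valid > invalid cluster and a late invalid > valid cluster (each
#' significant at cluster-level p < 0.05 and overlapping its injected
#' window) are recovered.
#'
#' The default injected gains are width-compensated: the late window
#' (16 ms) is about 3.6 times narrower than the early one (57 ms), and
#' equal injected effect mass (gain times window width) requires the
#' gain ratio to match the width ratio, so the late injection is 3.5
#' times the early one.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param seed master seed.
#' @param sharpening_gain,dampening_gain injected gains.
#' @param scale a [reduced_scale_config()]-style list.
#' @param verbose print per-cohort progress.
#' @return list with `per_cohort` (data frame: cohort, early_recovered,
#'   late_recovered), `early_rate`, `late_rate`, `both_rate`.
#' @export
run_effect_recovery_study <- function(n_cohorts = 20, n_subjects = 12,
                                      seed = 1L,
                                      sharpening_gain = 2,
                                      dampening_gain = 7,
                                      scale = reduced_scale_config(),
                                      verbose = FALSE) {
  cfg <- scale$cfg
  rows <- vector("list", n_cohorts)
  for (co in seq_len(n_cohorts)) {
    acc_v <- acc_i <- NULL
    times <- NULL
    for (su in seq_len(n_subjects)) {
      res <- simulate_study_subject(
        seed = child_seed(seed, 1000 * co + su),
        sharpening_gain = sharpening_gain,
        dampening_gain = dampening_gain,
        scale = scale, assignment_seed = child_seed(seed, co))
      acc_v <- rbind(acc_v, res$valid$accuracy)
      acc_i <- rbind(acc_i, res$invalid$accuracy)
      times <- res$valid$times_s
    }
    gs <- group_decoding_stats(acc_v, acc_i, times, chance = 0.5,
                               cfg = cfg, seed = child_seed(seed, 500 + co))
    early <- cluster_overlaps(gs$paired$clusters, cfg$sharpening_window_s,
                              sign = 1)
    late <- cluster_overlaps(gs$paired$clusters, cfg$dampening_window_s,
                             sign = -1)
    rows[[co]] <- data.frame(cohort = co, early_recovered = early,
                             late_recovered = late)
    if (verbose)
      message(sprintf("cohort %d/%d: early %s late %s", co, n_cohorts,
                      early, late))
  }
  per_cohort <- do.call(rbind, rows)
  list(per_cohort = per_cohort,
       early_rate = mean(per_cohort$early_recovered),
       late_rate = mean(per_cohort$late_recovered),
       both_rate = mean(per_cohort$early_recovered &
                        per_cohort$late_recovered))
}

#' Type-I calibration of the paired cluster test
#'
#' Estimates the cluster-level family-wise error rate of the paired
#' valid-vs-invalid cluster test under the null of zero expectation
#' effects. Each simulated cohort consists of per-subject valid and
#' invalid accuracy time series drawn from the same null model
#' (chance-level accuracy plus temporally smoothed sampling noise, the
#' structure produced by decoding gain-free data), so the two conditions
#' are exchangeable by construction; a cohort counts as a false positive
#' if any cluster reaches p_fwe below `alpha`.
#'
#' @param n_sims number of simulated null cohorts.
#' @param n_subjects subjects per cohort.
#' @param n_tp time points per accuracy series.
#' @param chance chance level of the emulated analysis.
#' @param acc_sd standard deviation of the per-time-point accuracy noise
#'   (sampling noise of a fold-averaged accuracy estimate).
#' @param smooth_k temporal smoothing (samples) of the accuracy noise.
#' @param alpha nominal cluster-level threshold.
#' @param seed master seed.
#' @param cfg a [pipeline_config()] (`n_perm`, `forming_alpha`).
#' @return list with `fwe_rate`, `n_sims`, `alpha`.
#' @export
run_null_calibration <- function(n_sims = 200, n_subjects = 12, n_tp = 40,
                                 chance = 0.5, acc_sd = 0.07, smooth_k = 3,
                                 alpha = 0.05, seed = 1L,
                                 cfg = pipeline_config(n_perm = 500)) {
  local_rng(seed)
  null_series <- function() {
    z <- matrix(rnorm(n_subjects * n_tp), n_subjects, n_tp)
    t(apply(z, 1, moving_average, k = smooth_k)) * acc_sd + chance
  }
  hits <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    v <- null_series()
    i <- null_series()
    gs <- group_decoding_stats(v, i, seq_len(n_tp), chance, cfg,
                               seed = child_seed(seed, s))
    hits[s] <- nrow(gs$paired$clusters) > 0 &&
      any(gs$paired$clusters$p_fwe < alpha)
  }
  list(fwe_rate = mean(hits), n_sims = n_sims, alpha = alpha)
}

#' Recovery of the logarithmic learning fit
#'
#' Two-part oracle study for [fit_log_stabilization()]: (1) a noiseless
#' series `a + b log(t)` must return the generating coefficients to
#' numerical precision and a stabilization index equal to the analytic
#' solution computed from the generating curve; (2) with binomial
#' sampling noise on the grid, the stabilization index should stay close
#' to the noiseless index (the study reports the median absolute index
#' error as a fraction of the series length).
#'
#' @param a,b generating coefficients.
#' @param n series length (trial grid).
#' @param n_sims noisy replicates.
#' @param binom_size number of Bernoulli trials behind each grid point.
#' @param seed master seed.
#' @param cfg a [pipeline_config()] (`log_tol`).
#' @return list with `coef_error` (max abs error of the noiseless fit),
#'   `index_match` (noiseless index equals the analytic index),
#'   `analytic_index`, `median_index_error_frac`.
#' @export
run_logfit_recovery <- function(a = 0.1, b = 0.05, n = 200, n_sims = 100,
                                binom_size = 30, seed = 1L,
                                cfg = pipeline_config()) {
  t <- seq_len(n)
  curve <- a + b * log(t)
  fit0 <- fit_log_stabilization(curve, cfg)
  coef_error <- max(abs(c(fit0$a - a, fit0$b - b)))
  # analytic index from the generating curve itself
  rel <- abs(b * log(1 + 1 / t[-n])) /
    ifelse(curve[-n] == 0, 1, abs(curve[-n]))
  rel[curve[-n] == 0] <- abs(b * log(1 + 1 / t[-n]))[curve[-n] == 0]
  analytic <- which(rel < cfg$log_tol)[1]

  local_rng(seed)
  errs <- vapply(seq_len(n_sims), function(s) {
    p <- pmin(pmax(0.5 + curve, 0.01), 0.99)
    y <- rbinom(n, binom_size, p) / binom_size - 0.5
    fit <- fit_log_stabilization(y, cfg)
    idx <- if (fit$stabilized) fit$stabilization_index else n
    abs(idx - analytic)
  }, numeric(1))
  list(coef_error = coef_error,
       index_match = identical(as.integer(fit0$stabilization_index),
                               as.integer(analytic)),
       analytic_index = analytic,
       median_index_error_frac = median(errs) / n)
}

#' Power and null calibration of the validity-by-bin mixed model
#'
#' Simulates bin-table cohorts with a pure crossover interaction (no
#' validity difference in bin 1, `effect` in bin 2) on top of
#' subject-level random intercepts and residual noise, fits
#' [fit_validity_bin_lme()] and counts detections of the interaction
#' (Holm-adjusted across the three fixed effects, p < 0.05). With
#' `effect = 0` the same machinery estimates the false-detection rate.
#'
#' @param n_sims simulated cohorts.
#' @param n_subjects subjects per cohort.
#' @param effect valid-minus-invalid accuracy difference in bin 2.
#' @param base mean accuracy.
#' @param subject_sd random-intercept standard deviation.
#' @param resid_sd residual (cell-level) standard deviation.
#' @param seed master seed.
#' @param cfg a [pipeline_config()].
#' @return list with `detection_rate`, `n_sims`, `effect`.
#' @export
run_lme_power_study <- function(n_sims = 100, n_subjects = 24,
                                effect = 0.06, base = 0.55,
                                subject_sd = 0.03, resid_sd = 0.03,
                                seed = 1L, cfg = pipeline_config()) {
  local_rng(seed)
  detect <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    subj <- rep(seq_len(n_subjects), each = 4)
    validity <- rep(c("valid", "invalid"), times = 2 * n_subjects)
    bin <- rep(rep(1:2, each = 2), times = n_subjects)
    mu <- base + ifelse(validity == "valid" & bin == 2, effect, 0)
    intercepts <- rnorm(n_subjects, 0, subject_sd)
    acc <- mu + intercepts[subj] + rnorm(length(mu), 0, resid_sd)
    tab <- data.frame(subject = as.character(subj), window_id = "early",
                      validity = validity, bin = bin, mean_accuracy = acc)
    res <- suppressWarnings(fit_validity_bin_lme(tab, cfg))
    fx <- res$fixed[res$fixed$term != "(Intercept)", ]
    p_adj <- p.adjust(fx$p, method = "holm")
    detect[s] <- p_adj[grepl(":", fx$term)] < 0.05
  }
  list(detection_rate = mean(detect), n_sims = n_sims, effect = effect)
}

#' Preprocessing oracle measurements
#'
#' Small deterministic measurements used to validate the preprocessing
#' chain: the attenuation of a pure 50 Hz sinusoid by the notch filter,
#' the sample shift of a symmetric pulse's peak after filtering
#' (zero-phase implies 0), the correlation between the DSS-denoised
#' evoked response and the injected ground-truth evoked signal on
#' noiseless data, and whether RMS rejection removes exactly a single
#' 100-fold-scaled epoch.
#'
#' @param fs_hz sampling rate for the filter probes.
#' @param seed seed for the DSS simulation.
#' @return list with `notch_attenuation_db`, `pulse_peak_shift_samples`,
#'   `dss_recovery_r`, `rms_rejection_exact`.
#' @export
measure_preprocessing_oracles <- function(fs_hz = 256, seed = 1L) {
  cfg <- pipeline_config()
  # 50 Hz attenuation
  n <- fs_hz * 10
  t <- seq_len(n) / fs_hz
  s50 <- sin(2 * pi * 50 * t)
  out <- fft_apply_gain(matrix(s50), fs_hz, function(f)
    butter_gain_hp(f, cfg$hp_hz, cfg$filter_order) *
      butter_gain_bandstop(f, cfg$notch_band_hz, cfg$filter_order))
  mid <- seq(round(n * 0.2), round(n * 0.8))
  att_db <- 20 * log10(sqrt(mean(s50[mid]^2)) / sqrt(mean(out[mid, 1]^2)))

  # zero-phase pulse
  pulse <- exp(-((seq_len(n) - n / 2) / (0.05 * fs_hz))^2)
  outp <- fft_apply_gain(matrix(pulse), fs_hz, function(f)
    butter_gain_hp(f, cfg$hp_hz, cfg$filter_order) *
      butter_gain_bandstop(f, cfg$notch_band_hz, cfg$filter_order))
  shift <- which.max(outp[, 1]) - which.max(pulse)

  # DSS recovery on noiseless epochs
  scale <- reduced_scale_config()
  tm <- build_transition_matrix(assignment_seed = seed)
  dcfg <- design_config(n_blocks = 1, n_valid_per_leading = 6,
                        n_invalid_per_leading = 2,
                        n_control_per_trailing = 2, catch_fraction = 0)
  sq <- generate_session(tm, dcfg, seed = seed)
  eff <- effect_spec(c(tm$leading_labels, tm$trailing_labels),
                     default_channel_labels(16), base_gain = 4,
                     sharpening_gain = 0, dampening_gain = 0,
                     memory_gain = 0, pattern_seed = seed)
  rec <- simulate_recording(sq, eff,
                            noise_spec(noise_sd = 0, blink_rate_hz = 0,
                                       line_noise_amp = 0, eog_noise_sd = 0),
                            fs_hz = 256, seed = seed)
  ep <- epoch_recording(rec, window = c(-0.1, 0.5), time_lock = "leading")
  # ground truth: average re-referenced evoked response at each channel
  truth <- apply(ep$data, c(1, 2), mean)
  truth <- truth - rowMeans(truth)
  den <- dss_denoise(ep, n_keep = 1)
  rec_avg <- apply(den$data, c(1, 2), mean)
  dss_r <- cor(as.numeric(truth), as.numeric(rec_avg))

  # RMS rejection of a single gross outlier
  local_rng(seed)
  arr <- array(rnorm(50 * 4 * 12), c(50, 4, 12))
  arr[, , 5] <- arr[, , 5] * 100
  epo <- structure(list(data = arr, times_s = seq_len(50) / 100, fs_hz = 100,
                        channel_labels = paste0("ch", 1:4),
                        metadata = data.frame(index = 0:11),
                        rejected_mask = rep(FALSE, 12),
                        time_lock = "leading"),
                   class = "eeg_epochs")
  rej <- reject_epochs(epo, cfg)
  exact <- identical(which(rej$rejected_mask), 5L)

  list(notch_attenuation_db = att_db,
       pulse_peak_shift_samples = as.integer(shift),
       dss_recovery_r = dss_r,
       rms_rejection_exact = exact)
}

#' Decoding oracle measurements
#'
#' Deterministic checks of the decoding stack on constructed data:
#' accuracy on perfectly separable two-class data (expected 1.0), mean
#' accuracy under label permutation for 2-class and 4-class problems
#' (expected at chance), and whether leave-one-per-cell folds partition
#' the trials with exactly one test trial per design cell.
#'
#' @param seed master seed.
#' @param n_sims label-permutation replicates.
#' @return list with `separable_accuracy`, `null_accuracy_2way`,
#'   `null_accuracy_4way`, `folds_partition_ok`.
#' @export
measure_decoding_oracles <- function(seed = 1L, n_sims = 20) {
  cfg <- pipeline_config(snr_cutoff_db = -Inf, selection = "global")
  make_ep <- function(n_per_class, classes, sep, noise, seed, n_ch = 6,
                      n_tp = 5) {
    local_rng(seed)
    n <- n_per_class * length(classes)
    labels <- rep(classes, each = n_per_class)
    arr <- array(rnorm(n_tp * n_ch * n, sd = noise), c(n_tp, n_ch, n))
    for (k in seq_along(classes)) {
      pat <- numeric(n_ch); pat[k] <- sep
      idx <- which(labels == classes[k])
      for (i in idx) arr[, , i] <- arr[, , i] +
          outer(rep(1, n_tp), pat)
    }
    meta <- data.frame(index = seq_len(n) - 1L,
                       leading_cat = rep(rep(c("L1", "L2"),
                                             length.out = length(classes)),
                                         each = n_per_class),
                       trailing_cat = labels)
    structure(list(data = arr, times_s = seq_len(n_tp) / 100, fs_hz = 100,
                   channel_labels = paste0("ch", seq_len(n_ch)),
                   metadata = meta, rejected_mask = rep(FALSE, n),
                   time_lock = "leading"),
              class = "eeg_epochs")
  }
  # perfectly separable two classes, no noise
  ep <- make_ep(10, c("A", "B"), sep = 5, noise = 1e-6, seed = seed)
  folds <- make_cv_folds(ep$metadata, seed = seed)
  res <- decode_timecourse(ep, ep$metadata$trailing_cat, folds, cfg,
                           signal_window = c(0, 1),
                           baseline_window = c(0, 1))
  sep_acc <- mean(res$accuracy)

  null_acc <- function(classes) {
    mean(vapply(seq_len(n_sims), function(s) {
      epn <- make_ep(8, classes, sep = 0, noise = 1, seed = child_seed(seed, s))
      f <- make_cv_folds(epn$metadata, seed = child_seed(seed, 100 + s))
      r <- decode_timecourse(epn, epn$metadata$trailing_cat, f, cfg,
                             signal_window = c(0, 1),
                             baseline_window = c(0, 1))
      mean(r$accuracy)
    }, numeric(1)))
  }
  null2 <- null_acc(c("A", "B"))
  null4 <- null_acc(c("A", "B", "C", "D"))

  # fold structure on an 8-cell design
  meta <- expand.grid(leading_cat = paste0("L", 1:4),
                      trailing_cat = paste0("T", 1:2),
                      rep = 1:10, stringsAsFactors = FALSE)[, 1:2]
  f8 <- make_cv_folds(meta, seed = seed)
  per_fold_ok <- all(vapply(seq_len(f8$n_folds), function(k) {
    test <- which(f8$fold == k)
    length(test) == 8 &&
      !any(duplicated(paste(meta$leading_cat[test], meta$trailing_cat[test])))
  }, logical(1)))
  partition_ok <- per_fold_ok && f8$n_folds == 10 &&
    all(!is.na(f8$fold)) && all(table(f8$fold) == 8)

  list(separable_accuracy = sep_acc,
       null_accuracy_2way = null2,
       null_accuracy_4way = null4,
       folds_partition_ok = partition_ok)
}
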