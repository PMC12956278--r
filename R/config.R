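#' Pipeline configuration
#'
#' Collects every numeric parameter used by the preprocessing, decoding,
#' statistics and learning-dynamics stages in one place. Call with no
#' arguments for the full-scale defaults; override any subset by name.
#'
#' @param hp_hz high-pass cutoff in Hz applied to continuous data.
#' @param notch_band_hz two-element band (Hz) removed to suppress mains
#'   interference.
#' @param filter_order Butterworth order; filters are applied zero-phase
#'   (forward-backward response).
#' @param fs_down_hz target sampling rate (Hz) after downsampling.
#' @param blink_epoch_s window (s) around each detected blink onset used
#'   for SVD-based blink removal.
#' @param n_blink_pcs number of spatial principal components removed from
#'   blink segments.
#' @param blink_z robust z-score threshold on the vertical EOG used for
#'   blink detection.
#' @param blink_refractory_s minimum separation (s) between detected
#'   blink onsets.
#' @param baseline_s baseline window (s) relative to the leading stimulus
#'   onset; its mean is subtracted per epoch and channel.
#' @param dss_n_keep number of denoising-source-separation components
#'   retained when reconstructing sensor data.
#' @param rms_reject_sd epochs whose root-mean-square amplitude exceeds
#'   the median by this many standard deviations are rejected.
#' @param lp_hz low-pass cutoff (Hz) applied to trial-averaged data only
#'   (the ERP branch); single-trial decoding uses unfiltered epochs.
#' @param lp_order Butterworth order of the ERP low-pass (steeper than
#'   the high-pass/notch order so that mains-adjacent frequencies are
#'   suppressed below 5% despite the cutoff sitting at 48 Hz).
#' @param snr_cutoff_db principal components whose evoked signal-to-noise
#'   ratio is at least this many dB are retained as decoding features.
#' @param sharpening_window_s early window (s, relative to trailing
#'   stimulus onset) in which expectation is predicted to increase
#'   decodability of the expected category.
#' @param dampening_window_s late window (s, relative to trailing onset)
#'   in which expectation is predicted to decrease decodability.
#' @param epoch_window_s epoch limits (s) relative to the leading onset.
#' @param decode_window_s time range (s, relative to the locked onset)
#'   over which time-resolved decoding is run.
#' @param decode_step decode every `decode_step`-th sample of the epoch
#'   time grid (1 = every sample).
#' @param svm_cost linear SVM regularization constant C.
#' @param selection `"per_fold"` fits the PCA/SNR feature selection on
#'   training folds only (leakage-safe); `"global"` fits it once on all
#'   trials before cross-validation.
#' @param max_folds cap on the number of cross-validation folds; trials
#'   beyond the cap's per-cell allocation are used for training only.
#' @param surplus `"train"` keeps trials beyond complete folds in the
#'   training sets; `"discard"` drops them.
#' @param forming_alpha uncorrected two-tailed alpha forming clusters.
#' @param n_perm number of permutations for cluster-level inference.
#' @param cluster_stat cluster score, `"mass"` (sum of the statistic) or
#'   `"extent"` (number of time points).
#' @param n_bins number of consecutive trial bins for learning analyses.
#' @param benefit_grid length of the fixed trial grid onto which the
#'   trial-wise decoding-benefit series is resampled.
#' @param smoothing_k width (trials) of the centred moving average used
#'   to smooth per-trial correctness before computing the benefit.
#' @param log_tol relative per-trial change of the fitted logarithmic
#'   curve below which decoding is considered stabilized (0.001 = 0.1%).
#' @param cooks_sd rows whose Cook's distance exceeds the mean by this
#'   many SDs are removed before refitting the mixed model.
#' @param rt_outlier_sd reaction times beyond this many SDs from the
#'   pooled mean are excluded.
#' @param ... ignored; present so configs can be built from lists.
#'
#' @return a list of class `"oppdyn_config"`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$fs_down_hz
#' small <- pipeline_config(fs_down_hz = 128, dss_n_keep = 6)
#' @export
pipeline_config <- function(hp_hz = 0.1,
                            notch_band_hz = c(48, 52),
                            filter_order = 5,
                            fs_down_hz = 300,
                            blink_epoch_s = c(-0.2, 0.4),
                            n_blink_pcs = 2,
                            blink_z = 4,
                            blink_refractory_s = 0.3,
                            baseline_s = c(-0.2, 0),
                            dss_n_keep = 10,
                            rms_reject_sd = 2,
                            lp_hz = 48,
                            lp_order = 8,
                            snr_cutoff_db = 8,
                            sharpening_window_s = c(0.123, 0.180),
                            dampening_window_s = c(0.280, 0.296),
                            epoch_window_s = c(-0.2, 2.6),
                            decode_window_s = c(0, 0.4),
                            decode_step = 1,
                            svm_cost = 1,
                            selection = c("per_fold", "global"),
                            max_folds = Inf,
                            surplus = c("train", "discard"),
                            forming_alpha = 0.05,
                            n_perm = 1000,
                            cluster_stat = c("mass", "extent"),
                            n_bins = 4,
                            benefit_grid = 200,
                            smoothing_k = 21,
                            log_tol = 0.001,
                            cooks_sd = 3,
                            rt_outlier_sd = 2,
                            ...) {
  cfg <- list(
    hp_hz = hp_hz, notch_band_hz = sort(notch_band_hz),
    filter_order = filter_order, fs_down_hz = fs_down_hz,
    blink_epoch_s = blink_epoch_s, n_blink_pcs = n_blink_pcs,
    blink_z = blink_z, blink_refractory_s = blink_refractory_s,
    baseline_s = baseline_s, dss_n_keep = dss_n_keep,
    rms_reject_sd = rms_reject_sd, lp_hz = lp_hz,
    lp_order = lp_order, snr_cutoff_db = snr_cutoff_db,
    sharpening_window_s = sharpening_window_s,
    dampening_window_s = dampening_window_s,
    epoch_window_s = epoch_window_s,
    decode_window_s = decode_window_s, decode_step = decode_step,
    svm_cost = svm_cost, selection = match.arg(selection),
    max_folds = max_folds, surplus = match.arg(surplus),
    forming_alpha = forming_alpha, n_perm = n_perm,
    cluster_stat = match.arg(cluster_stat),
    n_bins = n_bins, benefit_grid = benefit_grid,
    smoothing_k = smoothing_k, log_tol = log_tol,
    cooks_sd = cooks_sd, rt_outlier_sd = rt_outlier_sd
  )
  stopifnot(
    cfg$hp_hz > 0, length(cfg$notch_band_hz) == 2,
    cfg$notch_band_hz[1] < cfg$notch_band_hz[2],
    cfg$filter_order >= 1, cfg$fs_down_hz > 0,
    cfg$blink_epoch_s[1] < cfg$blink_epoch_s[2],
    cfg$n_blink_pcs >= 1, cfg$baseline_s[1] < cfg$baseline_s[2],
    cfg$rms_reject_sd > 0, cfg$lp_hz > 0, cfg$lp_order >= 1,
    cfg$sharpening_window_s[1] < cfg$sharpening_window_s[2],
    cfg$dampening_window_s[1] < cfg$dampening_window_s[2],
    cfg$epoch_window_s[1] < cfg$epoch_window_s[2],
    cfg$decode_step >= 1, cfg$svm_cost > 0,
    cfg$forming_alpha > 0, cfg$forming_alpha < 1,
    cfg$n_perm >= 100, cfg$n_bins >= 2, cfg$benefit_grid >= 10,
    cfg$smoothing_k >= 1, cfg$log_tol > 0, cfg$cooks_sd > 0,
    cfg$rt_outlier_sd > 0
  )
  class(cfg) <- "oppdyn_config"
  cfg
}

#' @export
print.oppdyn_config <- function(x, ...) {
  cat("<oppdyn_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                paste(format(v, digits = 4), collapse = ", ")))
  }
  invisible(x)
}
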