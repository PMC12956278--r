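# ---- zero-phase frequency-domain filtering -------------------------------
#
# A 5th-order Butterworth high-pass at 0.1 Hz has poles so close to the
# unit circle at EEG sampling rates that time-domain forward-backward
# filtering in transfer-function form is numerically unstable. The
# forward-backward (zero-phase) response of a Butterworth filter is its
# squared magnitude, so the package applies that response directly in
# the frequency domain: the data are evenly extended (mirror padding,
# continuous at every boundary), transformed, multiplied by the
# two-pass magnitude response and transformed back. This is exactly
# zero-phase and stable at any sampling rate.

# two-pass (forward-backward) Butterworth magnitude responses
butter_gain_hp <- function(f, fc, order) {
  g <- numeric(length(f))
  nz <- f != 0
  g[nz] <- 1 / (1 + (fc / f[nz])^(2 * order))
  g
}

butter_gain_lp <- function(f, fc, order) {
  1 / (1 + (f / fc)^(2 * order))
}

butter_gain_bandstop <- function(f, band, order) {
  f0sq <- band[1] * band[2]
  bw <- band[2] - band[1]
  g <- numeric(length(f))
  on_center <- abs(f^2 - f0sq) < 1e-12
  ok <- !on_center
  g[ok] <- 1 / (1 + (f[ok] * bw / (f0sq - f[ok]^2))^(2 * order))
  g  # zero exactly at the band center
}

# mirror-pad a matrix on both sides (P rows) and extend to m rows
pad_mirror <- function(x, P, m) {
  n <- nrow(x)
  xp <- rbind(x[P:1, , drop = FALSE], x, x[n:(n - P + 1L), , drop = FALSE])
  if (m > nrow(xp))
    xp <- rbind(xp, matrix(rep(xp[nrow(xp), ], each = m - nrow(xp)),
                           m - nrow(xp)))
  xp
}

fft_freqs <- function(m, fs) {
  c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) * fs / m
}

# apply a frequency-response gain to every column of x (zero phase);
# mirror padding (default 30 s, enough for the 0.1 Hz high-pass ringing)
# keeps boundary transients away from the data
fft_apply_gain <- function(x, fs, gain_fn, pad_s = 30) {
  x <- as.matrix(x)
  n <- nrow(x)
  P <- max(1L, min(n - 1L, round(pad_s * fs)))
  m <- stats::nextn(n + 2L * P, c(2, 3, 5))
  xp <- pad_mirror(x, P, m)
  g <- gain_fn(abs(fft_freqs(m, fs)))
  X <- stats::mvfft(xp)
  out <- Re(stats::mvfft(X * g, inverse = TRUE)) / m
  out[P + seq_len(n), , drop = FALSE]
}

# fused zero-phase filtering + resampling in a single FFT round trip;
# both operators are diagonal in the frequency domain, so this matches
# fft_apply_gain followed by fft_resample up to boundary-padding detail.
# Requires an integer-length mapping of the padded signal; callers fall
# back to the sequential path otherwise.
fft_filter_resample <- function(x, fs, gain_fn, fs_new, pad_s = 30) {
  x <- as.matrix(x)
  n <- nrow(x)
  P <- max(1L, min(n - 1L, round(pad_s * fs)))
  # the data must start on an exact sample of the new grid
  k <- fs / gcd_int(fs, fs_new)
  P <- (P %/% k) * k
  if (P < 1) return(NULL)
  m <- stats::nextn(n + 2L * P, c(2, 3, 5))
  if ((m * fs_new) %% fs != 0) return(NULL)
  m2 <- m * fs_new / fs
  xp <- pad_mirror(x, P, m)
  g <- gain_fn(abs(fft_freqs(m, fs)))
  X <- stats::mvfft(xp) * g
  half <- (min(m, m2) - 1L) %/% 2L
  Y <- matrix(0 + 0i, m2, ncol(x))
  Y[1:(half + 1), ] <- X[1:(half + 1), , drop = FALSE]
  if (half > 0)
    Y[(m2 - half + 1):m2, ] <- X[(m - half + 1):m, , drop = FALSE]
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / m
  n_new <- round(n * fs_new / fs)
  p_new <- round(P * fs_new / fs)
  out[p_new + seq_len(n_new), , drop = FALSE]
}

#' High-pass and notch filter a continuous recording
#'
#' Applies the zero-phase (forward-backward) response of a 5th-order
#' Butterworth high-pass at `cfg$hp_hz` and band-stop over
#' `cfg$notch_band_hz`, removing drift/DC and mains interference.
#' Event samples are unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [pipeline_config()].
#' @return the filtered `eeg_recording`.
#' @export
filter_continuous <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs_hz <= 2 * cfg$notch_band_hz[2])
    stop("sampling rate too low for the notch band")
  ord <- cfg$filter_order
  hp <- cfg$hp_hz
  band <- cfg$notch_band_hz
  rec$data <- fft_apply_gain(rec$data, rec$fs_hz, function(f) {
    butter_gain_hp(f, hp, ord) * butter_gain_bandstop(f, band, ord)
  })
  rec
}

# FFT-domain resampling (ideal anti-aliasing for band-limited data)
fft_resample <- function(x, n_new) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_new == n) return(x)
  X <- stats::mvfft(x)
  half <- (min(n, n_new) - 1L) %/% 2L
  Y <- matrix(0 + 0i, n_new, ncol(x))
  Y[1:(half + 1), ] <- X[1:(half + 1), , drop = FALSE]
  if (half > 0)
    Y[(n_new - half + 1):n_new, ] <- X[(n - half + 1):n, , drop = FALSE]
  Re(stats::mvfft(Y, inverse = TRUE)) / n
}

#' Downsample a recording
#'
#' Resamples every channel to `cfg$fs_down_hz` in the frequency domain
#' (exact anti-aliased resampling for band-limited signals) and remaps
#' event samples to the nearest new sample. Duration is preserved to
#' within one sample.
#'
#' @inheritParams filter_continuous
#' @return the downsampled `eeg_recording`.
#' @export
downsample_recording <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs_new <- cfg$fs_down_hz
  if (fs_new > rec$fs_hz) stop("target rate exceeds source rate")
  if (fs_new == rec$fs_hz) return(rec)
  n <- nrow(rec$data)
  n_new <- round(n * fs_new / rec$fs_hz)
  rec$data <- fft_resample(rec$data, n_new)
  rec$events$sample <- pmin(pmax(round((rec$events$sample - 1) *
                                       fs_new / rec$fs_hz) + 1L, 1L), n_new)
  rec$fs_hz <- fs_new
  rec
}

#' Detect and remove eye blinks by segment-wise SVD
#'
#' Blink onsets are detected on the bipolar vertical EOG (upper minus
#' lower; falls back to the first EOG channel) as robust z-score
#' threshold crossings with a refractory period. A window of
#' `cfg$blink_epoch_s` (default -200 to 400 ms) around each onset is
#' extracted, the concatenated segments are decomposed by singular value
#' decomposition, and the top `cfg$n_blink_pcs` spatial components are
#' projected out of those segments only; data outside blink segments are
#' untouched.
#'
#' @inheritParams filter_continuous
#' @return a list with `recording` (cleaned) and `report` (class
#'   `"blink_report"`: `onsets_s`, `n_blinks`, `variance_removed`).
#' @export
remove_blinks <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  eog <- which(rec$is_eog)
  if (!length(eog)) stop("no EOG channel present")
  lab <- rec$channel_labels
  if (all(c("VEOGU", "VEOGL") %in% lab)) {
    v <- rec$data[, lab == "VEOGU"] - rec$data[, lab == "VEOGL"]
  } else {
    v <- rec$data[, eog[1]]
  }
  med <- median(v)
  s <- 1.4826 * median(abs(v - med))
  if (s <= 0) s <- sd(v)
  z <- (v - med) / s
  above <- z > cfg$blink_z
  onsets <- which(diff(c(FALSE, above)) == 1L)
  if (length(onsets)) {  # refractory period
    sel <- onsets[1]
    for (o in onsets[-1]) {
      if (o - sel[length(sel)] > cfg$blink_refractory_s * rec$fs_hz)
        sel <- c(sel, o)
    }
    onsets <- sel
  }
  report <- structure(list(onsets_s = (onsets - 1) / rec$fs_hz,
                           n_blinks = length(onsets),
                           variance_removed = 0),
                      class = "blink_report")
  if (!length(onsets)) return(list(recording = rec, report = report))

  i0 <- round(cfg$blink_epoch_s[1] * rec$fs_hz)
  i1 <- round(cfg$blink_epoch_s[2] * rec$fs_hz)
  n <- nrow(rec$data)
  seg_idx <- unique(unlist(lapply(onsets, function(o) {
    idx <- (o + i0):(o + i1)
    idx[idx >= 1 & idx <= n]
  })))
  seg <- rec$data[seg_idx, , drop = FALSE]
  sv <- svd(seg, nu = 0, nv = cfg$n_blink_pcs)
  v_k <- sv$v
  clean <- seg - (seg %*% v_k) %*% t(v_k)
  report$variance_removed <- 1 - sum(clean^2) / sum(seg^2)
  rec$data[seg_idx, ] <- clean
  list(recording = rec, report = report)
}

#' @export
print.blink_report <- function(x, ...) {
  cat(sprintf("<blink_report> %d blinks, %.1f%% of blink-segment variance removed\n",
              x$n_blinks, 100 * x$variance_removed))
  invisible(x)
}

#' Epoch a continuous recording
#'
#' Extracts one epoch per trial, time-locked to the leading or trailing
#' stimulus onset. Trials whose window falls outside the recording are
#' dropped with a warning. EOG channels are excluded from the epochs
#' (they exist for blink handling on the continuous data).
#'
#' @param rec an `eeg_recording`.
#' @param window epoch limits in seconds relative to the locked onset.
#' @param time_lock `"leading"` or `"trailing"` onset.
#' @param baseline `NULL` for none, or a window (s) whose per-trial,
#'   per-channel mean is subtracted.
#' @return an object of class `"eeg_epochs"`: list with `data` (time x
#'   channel x trial array), `times_s`, `fs_hz`, `channel_labels`,
#'   `metadata` (trial records), `rejected_mask` and `time_lock`.
#' @export
epoch_recording <- function(rec, window = c(-0.2, 2.6),
                            time_lock = c("leading", "trailing"),
                            baseline = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  time_lock <- match.arg(time_lock)
  if (!nrow(rec$events)) stop("recording has no events")
  marker <- paste0(time_lock, "_onset")
  ev <- rec$events[rec$events$marker == marker, ]
  i0 <- round(window[1] * rec$fs_hz)
  i1 <- round(window[2] * rec$fs_hz)
  times <- (i0:i1) / rec$fs_hz
  n <- nrow(rec$data)
  ok <- ev$sample + i0 >= 1 & ev$sample + i1 <= n
  if (any(!ok))
    warning(sprintf("%d trial(s) dropped: epoch window outside recording", sum(!ok)))
  ev <- ev[ok, ]
  ch <- which(!rec$is_eog)
  arr <- array(0, c(length(times), length(ch), nrow(ev)))
  for (k in seq_len(nrow(ev)))
    arr[, , k] <- rec$data[(ev$sample[k] + i0):(ev$sample[k] + i1), ch]
  meta <- rec$seq[match(ev$trial_index, rec$seq$index), , drop = FALSE]
  rownames(meta) <- NULL
  ep <- structure(list(data = arr, times_s = times, fs_hz = rec$fs_hz,
                       channel_labels = rec$channel_labels[ch],
                       metadata = meta,
                       rejected_mask = rep(FALSE, nrow(ev)),
                       time_lock = time_lock),
                  class = "eeg_epochs")
  if (!is.null(baseline)) ep <- apply_baseline(ep, baseline)
  ep
}

#' Baseline-correct epochs
#'
#' Subtracts the per-trial, per-channel mean over the baseline window.
#'
#' @param ep an `eeg_epochs` object.
#' @param window baseline window in seconds (epoch time axis).
#' @return the corrected `eeg_epochs`.
#' @export
apply_baseline <- function(ep, window = c(-0.2, 0)) {
  idx <- window_idx(ep$times_s, window)
  if (!length(idx)) stop("baseline window outside epoch")
  bl <- colMeans(ep$data[idx, , , drop = FALSE])  # channel x trial
  ep$data <- ep$data - rep(bl, each = dim(ep$data)[1])
  ep
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, %s-locked [%g, %g] s\n",
              d[3], d[2], d[1], x$fs_hz, x$time_lock,
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Denoising source separation (DSS)
#'
#' Linear denoising that maximises the trial-to-trial reproducibility of
#' the evoked response. Epochs are first re-referenced to the average of
#' all channels. The data are whitened on the total (single-trial)
#' covariance, the covariance of the trial-averaged data is
#' eigen-decomposed in the whitened space, components are ranked by
#' their bias score (evoked power after whitening), and the sensor data
#' are reconstructed from the `n_keep` most reproducible components.
#'
#' @param ep an `eeg_epochs` object with at least 2 trials.
#' @param n_keep number of DSS components retained (clipped to the data
#'   rank with a warning).
#' @param rank_tol relative eigenvalue cutoff defining the data rank.
#' @return the denoised `eeg_epochs`; attribute `"dss"` carries the bias
#'   scores and retained count.
#' @export
dss_denoise <- function(ep, n_keep = 10, rank_tol = 1e-10) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  if (d[3] < 2) stop("DSS needs at least 2 trials")
  # average re-reference: subtract the across-channel mean per sample
  for (tr in seq_len(d[3])) {
    x <- ep$data[, , tr]
    ep$data[, , tr] <- x - rowMeans(x)
  }
  # total covariance over single trials and biased (evoked) covariance
  xm <- matrix(aperm(ep$data, c(1, 3, 2)), d[1] * d[3], d[2])
  xm <- sweep(xm, 2, colMeans(xm))
  c0 <- crossprod(xm) / nrow(xm)
  avg <- rowMeans(ep$data, dims = 2)
  avg <- sweep(avg, 2, colMeans(avg))
  c1 <- crossprod(avg) / nrow(avg)

  e0 <- eigen(c0, symmetric = TRUE)
  keep <- e0$values > rank_tol * max(e0$values)
  r <- sum(keep)
  wmat <- diag(1 / sqrt(e0$values[keep]), r) %*% t(e0$vectors[, keep, drop = FALSE])
  bmat <- wmat %*% c1 %*% t(wmat)
  e1 <- eigen(bmat, symmetric = TRUE)
  unmix <- t(e1$vectors) %*% wmat                    # components x channels
  mixing <- e0$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e0$values[keep]), r) %*% e1$vectors    # channels x components
  if (n_keep > r) {
    warning(sprintf("n_keep = %d exceeds data rank %d; clipped", n_keep, r))
    n_keep <- r
  }
  k <- seq_len(n_keep)
  proj <- mixing[, k, drop = FALSE] %*% unmix[k, , drop = FALSE]
  for (tr in seq_len(d[3]))
    ep$data[, , tr] <- ep$data[, , tr] %*% t(proj)
  attr(ep, "dss") <- list(bias = e1$values, n_keep = n_keep,
                          unmix = unmix, mixing = mixing)
  ep
}

#' Reject epochs with outlying RMS amplitude
#'
#' Computes the root-mean-square amplitude of every epoch over all
#' channels and samples and removes epochs whose RMS strictly exceeds
#' the median by `cfg$rms_reject_sd` standard deviations of the RMS
#' distribution (so with identical epochs nothing is rejected).
#'
#' @param ep an `eeg_epochs` object with at least 3 epochs.
#' @param cfg a [pipeline_config()].
#' @return the pruned `eeg_epochs`; `rejected_mask` marks, per input
#'   trial, which epochs were removed, and attribute `"rms"` carries the
#'   per-epoch RMS values.
#' @export
reject_epochs <- function(ep, cfg = pipeline_config()) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  if (d[3] < 3) stop("need at least 3 epochs for RMS rejection")
  rms <- sqrt(colMeans(matrix(ep$data^2, d[1] * d[2], d[3])))
  thr <- median(rms) + cfg$rms_reject_sd * sd(rms)
  bad <- rms > thr
  if (all(bad)) stop("all epochs rejected")
  ep$rejected_mask <- bad
  ep$data <- ep$data[, , !bad, drop = FALSE]
  ep$metadata <- ep$metadata[!bad, , drop = FALSE]
  rownames(ep$metadata) <- NULL
  attr(ep, "rms") <- rms
  ep
}

#' Per-condition trial averages (ERP branch)
#'
#' Averages epochs within each level of a metadata column and applies a
#' zero-phase low-pass at `cfg$lp_hz` to the averages. This is the ERP
#' branch only: single-trial decoding never sees this filter.
#'
#' @param ep an `eeg_epochs` object.
#' @param group_by name of a metadata column (e.g. `"validity"`).
#' @param cfg a [pipeline_config()].
#' @return named list of time x channel matrices, one per level, with
#'   the epoch time axis as attribute `"times_s"`.
#' @export
erp_average <- function(ep, group_by = "validity", cfg = pipeline_config()) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (!group_by %in% names(ep$metadata))
    stop("unknown metadata column: ", group_by)
  levels <- unique(ep$metadata[[group_by]])
  ord <- cfg$lp_order
  lp <- cfg$lp_hz
  out <- lapply(levels, function(lv) {
    idx <- which(ep$metadata[[group_by]] == lv)
    if (!length(idx)) stop("empty condition: ", lv)
    avg <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
    fft_apply_gain(avg, ep$fs_hz, function(f) butter_gain_lp(f, lp, ord))
  })
  names(out) <- levels
  attr(out, "times_s") <- ep$times_s
  out
}

#' Full preprocessing chain
#'
#' Runs the continuous-to-epochs pipeline in its canonical order:
#' high-pass + notch filtering, downsampling, blink removal, average
#' re-referencing with DSS denoising, epoching time-locked to the
#' leading onset, baseline correction, and RMS-based epoch rejection.
#' Catch trials are dropped before analysis.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [pipeline_config()].
#' @param drop_catch remove catch trials from the epochs.
#' @return an `eeg_epochs` object; attribute `"steps"` records the
#'   executed stage order and attribute `"blink_report"` the blink
#'   removal report.
#' @export
preprocess_pipeline <- function(rec, cfg = pipeline_config(),
                                drop_catch = TRUE) {
  steps <- c("filter", "downsample", "blinks", "rereference_dss",
             "epoch", "baseline", "reject")
  if (rec$fs_hz <= 2 * cfg$notch_band_hz[2])
    stop("sampling rate too low for the notch band")
  ord <- cfg$filter_order
  gain_fn <- function(f) butter_gain_hp(f, cfg$hp_hz, ord) *
    butter_gain_bandstop(f, cfg$notch_band_hz, ord)
  fused <- if (cfg$fs_down_hz < rec$fs_hz)
    fft_filter_resample(rec$data, rec$fs_hz, gain_fn, cfg$fs_down_hz)
  else NULL
  if (is.null(fused)) {
    rec <- filter_continuous(rec, cfg)
    rec <- downsample_recording(rec, cfg)
  } else {
    n_new <- nrow(fused)
    rec$events$sample <- pmin(pmax(round((rec$events$sample - 1) *
                                         cfg$fs_down_hz / rec$fs_hz) + 1L,
                                   1L), n_new)
    rec$data <- fused
    rec$fs_hz <- cfg$fs_down_hz
  }
  br <- remove_blinks(rec, cfg)
  rec <- br$recording
  ep <- epoch_recording(rec, window = cfg$epoch_window_s,
                        time_lock = "leading", baseline = NULL)
  ep <- dss_denoise(ep, n_keep = cfg$dss_n_keep)
  ep <- apply_baseline(ep, cfg$baseline_s)
  ep <- reject_epochs(ep, cfg)
  if (drop_catch) {
    keep <- !ep$metadata$is_catch
    ep$data <- ep$data[, , keep, drop = FALSE]
    ep$metadata <- ep$metadata[keep, , drop = FALSE]
    rownames(ep$metadata) <- NULL
  }
  attr(ep, "steps") <- steps
  attr(ep, "blink_report") <- br$report
  ep
}
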