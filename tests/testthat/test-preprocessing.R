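make_rec <- function(data, fs, labels = NULL, events = NULL, seq = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(data)))
  structure(list(data = data, fs_hz = fs, channel_labels = labels,
                 is_eog = labels %in% eog_channel_labels(),
                 events = if (is.null(events))
                   data.frame(sample = integer(0), trial_index = integer(0),
                              marker = character(0)) else events,
                 seq = seq, blink_onsets_s = numeric(0)),
            class = "eeg_recording")
}

test_that("filtering removes DC and mains with zero phase", {
  fs <- 256
  t <- seq_len(fs * 20) / fs
  s50 <- sin(2 * pi * 50 * t)
  const <- rep(3, length(t))
  pulse <- exp(-((seq_along(t) - length(t) / 2) / (0.05 * fs))^2)
  rec <- make_rec(cbind(s50, const, pulse), fs)
  out <- filter_continuous(rec, pipeline_config())$data
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  # 50 Hz residual under 1% RMS (>= 40 dB attenuation)
  expect_lt(sqrt(mean(out[mid, 1]^2)) / sqrt(mean(s50[mid]^2)), 0.01)
  # constant channel goes to zero
  expect_lt(max(abs(out[mid, 2])), 1e-6)
  # symmetric pulse peaks at the same sample (no group delay)
  expect_equal(which.max(out[, 3]), which.max(pulse))
  # too-low sampling rate is rejected
  expect_error(filter_continuous(make_rec(cbind(s50), 100),
                                 pipeline_config()), "too low")
})

test_that("downsampling preserves duration, amplitude and event timing", {
  fs <- 2048
  n <- fs * 10
  t <- seq_len(n) / fs
  x <- sin(2 * pi * 5 * t)
  ev <- data.frame(sample = round(1.0 * fs) + 1L, trial_index = 0L,
                   marker = "leading_onset")
  rec <- make_rec(cbind(x, x), fs, events = ev)
  out <- downsample_recording(rec, pipeline_config(fs_down_hz = 300))
  expect_equal(out$fs_hz, 300)
  expect_true(abs(nrow(out$data) - 3000) <= 1)
  mid <- 500:2500
  expect_equal(sqrt(mean(out$data[mid, 1]^2)), sqrt(0.5), tolerance = 0.01)
  # event lands at t = 1.0 s on the new grid
  expect_equal((out$events$sample - 1) / out$fs_hz, 1.0, tolerance = 1 / 300)
  expect_error(downsample_recording(out, pipeline_config(fs_down_hz = 2048)),
               "exceeds")
})

test_that("fused filter+resample matches the sequential path", {
  # band-limited input: differences between the two paths then reflect
  # implementation, not sub-Nyquist content cut with different padding
  fs <- 256
  set.seed(4)
  t <- seq_len(fs * 40) / fs
  x <- sapply(1:3, function(ch) {
    freqs <- runif(40, 0.5, 40)
    colSums(matrix(rnorm(40), 40, 1)[, 1] * sin(outer(freqs, t) + runif(40, 0, 2 * pi)))
  })
  cfg <- pipeline_config(fs_down_hz = 128)
  rec <- make_rec(x, fs)
  seq_path <- downsample_recording(filter_continuous(rec, cfg), cfg)$data
  ord <- cfg$filter_order
  gain <- function(f) oppdyn:::butter_gain_hp(f, cfg$hp_hz, ord) *
    oppdyn:::butter_gain_bandstop(f, cfg$notch_band_hz, ord)
  fused <- oppdyn:::fft_filter_resample(x, fs, gain, 128)
  mid <- seq(200, nrow(fused) - 200)
  expect_lt(max(abs(fused[mid, ] - seq_path[mid, ])),
            1e-3 * max(abs(seq_path[mid, ])))
})

test_that("blink removal detects injected blinks and cleans frontal channels", {
  des <- tiny_design(n_blocks = 2)
  x <- tiny_recording(seed = 8, fs = 256, n_ch = 16, design = des,
                      noise = noise_spec(noise_sd = 3, blink_rate_hz = 0.1,
                                         line_noise_amp = 0))
  rec <- x$rec
  truth <- rec$blink_onsets_s
  expect_gt(length(truth), 5)
  br <- remove_blinks(rec, pipeline_config())
  det <- br$report$onsets_s
  hits <- vapply(truth, function(on) any(abs(det - on) < 0.05), logical(1))
  expect_gte(mean(hits), 0.9)
  # frontal-VEOG coupling inside blink segments drops by at least half
  fp <- which(rec$channel_labels == "Fp1")
  ve <- which(rec$channel_labels == "VEOGU")
  seg <- unlist(lapply(round(truth * 256) + 1, function(s) s:(s + 90)))
  seg <- seg[seg <= nrow(rec$data)]
  r_before <- cor(rec$data[seg, fp], rec$data[seg, ve])
  r_after <- cor(br$recording$data[seg, fp], br$recording$data[seg, ve])
  expect_lt(abs(r_after), 0.5 * abs(r_before))
  expect_gt(br$report$variance_removed, 0)
})

test_that("blink removal is the identity when no blinks occur", {
  x <- tiny_recording(seed = 9, fs = 256, n_ch = 8,
                      noise = noise_spec(noise_sd = 2, blink_rate_hz = 0))
  br <- remove_blinks(x$rec, pipeline_config())
  expect_identical(br$recording$data, x$rec$data)
  expect_equal(br$report$n_blinks, 0)
  no_eog <- x$rec
  no_eog$is_eog[] <- FALSE
  expect_error(remove_blinks(no_eog, pipeline_config()), "EOG")
})

test_that("epoching and baseline correction behave by construction", {
  x <- tiny_recording(seed = 10, fs = 256, n_ch = 8)
  rec <- x$rec
  rec$data[] <- 7   # constant recording
  ep <- epoch_recording(rec, window = c(-0.2, 0.6), baseline = c(-0.2, 0))
  expect_equal(dim(ep$data)[3], nrow(x$seq))
  expect_lt(max(abs(ep$data)), 1e-9)
  # baseline window mean is zero per epoch and channel
  x2 <- tiny_recording(seed = 11, fs = 256, n_ch = 8,
                       noise = noise_spec(noise_sd = 5, blink_rate_hz = 0))
  ep2 <- epoch_recording(x2$rec, window = c(-0.2, 0.6),
                         baseline = c(-0.2, 0))
  bidx <- window_idx_pkg(ep2$times_s, c(-0.2, 0))
  bl <- apply(ep2$data[bidx, , , drop = FALSE], c(2, 3), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # metadata follows the trials that produced each epoch
  expect_equal(ep2$metadata$index, x2$seq$index)
  no_ev <- rec; no_ev$events <- rec$events[0, ]
  expect_error(epoch_recording(no_ev), "no events")
})

test_that("DSS recovers the evoked subspace and is complete at full rank", {
  x <- tiny_recording(seed = 12, fs = 256, n_ch = 12)
  ep <- epoch_recording(x$rec, window = c(-0.1, 0.5))
  # noiseless: one retained component reconstructs the evoked response
  truth <- apply(ep$data, c(1, 2), mean)
  truth <- truth - rowMeans(truth)
  den1 <- dss_denoise(ep, n_keep = 1)
  r <- cor(as.numeric(truth), as.numeric(apply(den1$data, c(1, 2), mean)))
  expect_gt(r, 0.99)
  # full rank: output equals the average-re-referenced input
  reref <- ep
  for (tr in seq_len(dim(ep$data)[3]))
    reref$data[, , tr] <- ep$data[, , tr] - rowMeans(ep$data[, , tr])
  expect_warning(den_full <- dss_denoise(ep, n_keep = 99), "clipped")
  expect_equal(den_full$data, reref$data, tolerance = 1e-6)
  # average reference: channel mean is zero at every sample
  expect_lt(max(abs(apply(den_full$data, c(1, 3), mean))), 1e-9)
})

test_that("evoked SNR does not decrease as noise components are discarded", {
  x <- tiny_recording(seed = 13, fs = 256, n_ch = 12,
                      design = tiny_design(v = 9, i = 3, ctrl = 3),
                      noise = noise_spec(noise_sd = 6, blink_rate_hz = 0,
                                         line_noise_amp = 0))
  ep <- epoch_recording(x$rec, window = c(-0.1, 0.5))
  snr_of <- function(n_keep) {
    den <- dss_denoise(ep, n_keep = n_keep)
    avg <- apply(den$data, c(1, 2), mean)
    resid <- sweep(den$data, c(1, 2), avg)
    sum(avg^2) / (sum(resid^2) / dim(ep$data)[3])
  }
  snrs <- vapply(c(11, 6, 3, 1), snr_of, numeric(1))
  expect_true(all(diff(snrs) >= -1e-9))
})

test_that("RMS rejection removes gross outliers and only them", {
  set.seed(3)
  arr <- array(rnorm(40 * 5 * 15), c(40, 5, 15))
  arr[, , 9] <- arr[, , 9] * 100
  ep <- structure(list(data = arr, times_s = seq_len(40) / 100, fs_hz = 100,
                       channel_labels = paste0("c", 1:5),
                       metadata = data.frame(index = 0:14),
                       rejected_mask = rep(FALSE, 15), time_lock = "leading"),
                  class = "eeg_epochs")
  rej <- reject_epochs(ep, pipeline_config())
  expect_identical(which(rej$rejected_mask), 9L)
  expect_equal(rej$metadata$index, setdiff(0:14, 8))
  # identical epochs: SD = 0, strict ">" keeps everything
  same <- ep
  for (tr in seq_len(15)) same$data[, , tr] <- ep$data[, , 1]
  expect_equal(sum(reject_epochs(same, pipeline_config())$rejected_mask), 0)
  expect_error(reject_epochs(structure(list(data = arr[, , 1:2, drop = FALSE],
                                            metadata = ep$metadata[1:2, ]),
                                       class = "eeg_epochs"),
                             pipeline_config()), "at least 3")
})

test_that("RMS rejection rate matches a Monte-Carlo oracle on Gaussian epochs", {
  # oracle: empirical P(RMS > median + 2 SD) for this epoch geometry
  set.seed(14)
  n_ep <- 24; shape <- c(30, 4)
  draw_frac <- function() {
    rms <- vapply(seq_len(n_ep), function(i)
      sqrt(mean(rnorm(prod(shape))^2)), numeric(1))
    mean(rms > median(rms) + 2 * sd(rms))
  }
  oracle <- mean(replicate(300, draw_frac()))
  fracs <- replicate(120, {
    arr <- array(rnorm(prod(shape) * n_ep), c(shape, n_ep))
    ep <- structure(list(data = arr, times_s = seq_len(shape[1]) / 100,
                         fs_hz = 100, channel_labels = paste0("c", 1:4),
                         metadata = data.frame(index = seq_len(n_ep) - 1),
                         rejected_mask = rep(FALSE, n_ep),
                         time_lock = "leading"),
                    class = "eeg_epochs")
    mean(reject_epochs(ep, pipeline_config())$rejected_mask)
  })
  expect_lt(abs(mean(fracs) - oracle), 0.01)
})

test_that("ERP averaging low-passes trial means only", {
  x <- tiny_recording(seed = 15, fs = 256, n_ch = 8)
  ep <- epoch_recording(x$rec, window = c(-0.1, 0.5))
  # two identical trials average to either trial
  two <- subset_epochs(ep, 1:2)
  two$data[, , 2] <- two$data[, , 1]
  two$metadata$validity <- "valid"
  avg <- erp_average(two, "validity", pipeline_config())
  expect_equal(avg$valid, two$data[, , 1], tolerance = 0.05,
               ignore_attr = TRUE)
  # injected 60 Hz ripple disappears after the 48 Hz low-pass
  rip <- ep
  ripple <- sin(2 * pi * 60 * ep$times_s)
  for (tr in seq_len(dim(rip$data)[3]))
    rip$data[, 1, tr] <- rip$data[, 1, tr] + ripple
  avg_r <- erp_average(rip, "validity", pipeline_config())
  resid <- avg_r[["valid"]][, 1] -
    erp_average(ep, "validity", pipeline_config())[["valid"]][, 1]
  # measured away from the short epoch's boundary transients
  mid <- seq(round(length(resid) * 0.2), round(length(resid) * 0.8))
  expect_lt(sqrt(mean(resid[mid]^2)), 0.05 * sqrt(0.5))
  expect_error(erp_average(ep, "nope"), "nope")
})

test_that("the pipeline preserves trial identity end to end", {
  des <- tiny_design(n_blocks = 2, catch = 0.05)
  x <- tiny_recording(seed = 16, fs = 256, n_ch = 16, design = des,
                      noise = noise_spec(noise_sd = 4))
  cfg <- pipeline_config(fs_down_hz = 128, dss_n_keep = 6,
                         epoch_window_s = c(-0.2, 1.4))
  ep <- preprocess_pipeline(x$rec, cfg)
  expect_false(any(ep$metadata$is_catch))
  # surviving epochs carry the trial records whose onsets produced them
  expect_true(all(ep$metadata$index %in% x$seq$index))
  kept <- x$seq[match(ep$metadata$index, x$seq$index), ]
  expect_equal(ep$metadata$leading_cat, kept$leading_cat)
  expect_equal(ep$metadata$validity, kept$validity)
  expect_equal(attr(ep, "steps"),
               c("filter", "downsample", "blinks", "rereference_dss",
                 "epoch", "baseline", "reject"))
  expect_equal(ep$fs_hz, 128)
})
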