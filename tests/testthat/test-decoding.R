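test_that("SNR component selection isolates a single evoked pattern", {
  # one pattern, no noise: exactly one component, matching the template
  n_tp <- 60; n_ch <- 8; n_tr <- 20
  times <- seq(-0.2, 0.39, by = 0.01)
  tpl <- c(rep(0, 20), sin(seq(0, pi, length.out = 40)))
  pat <- rnorm(n_ch); pat <- pat / sqrt(sum(pat^2))
  arr <- array(0, c(n_tp, n_ch, n_tr))
  for (tr in seq_len(n_tr)) arr[, , tr] <- outer(tpl, pat)
  ep <- structure(list(data = arr, times_s = times, fs_hz = 100,
                       channel_labels = paste0("c", seq_len(n_ch)),
                       metadata = data.frame(index = seq_len(n_tr) - 1),
                       rejected_mask = rep(FALSE, n_tr),
                       time_lock = "leading"),
                  class = "eeg_epochs")
  # tiny jitter so the covariance is not exactly rank one
  set.seed(1)
  ep$data <- ep$data + array(rnorm(length(ep$data), sd = 1e-6), dim(ep$data))
  sel <- select_components_snr(ep, pipeline_config(), signal_window = c(0, 0.39),
                               baseline_window = c(-0.2, 0))
  expect_equal(sel$n_components, 1)
  proj_tc <- apply(ep$data, c(1, 2), mean) %*% sel$projection[, 1]
  expect_gt(abs(cor(proj_tc[21:60], tpl[21:60])), 0.99)
})

test_that("a permissive SNR threshold keeps a complete, invertible basis", {
  ep <- synth_epochs(10, c("A", "B"), sep = 1, noise = 1, seed = 2,
                     n_ch = 5, n_tp = 30)
  ep$times_s <- seq(-0.1, 0.19, by = 0.01)
  sel <- select_components_snr(ep, pipeline_config(snr_cutoff_db = -Inf),
                               signal_window = c(0, 0.19),
                               baseline_window = c(-0.1, 0))
  expect_equal(sel$n_components, 5)
  # round trip through the complete basis
  x <- ep$data[3, , 1]
  expect_lt(max(abs(sel$projection %*% crossprod(sel$projection, x) - x)),
            1e-9)
})

test_that("pure-noise epochs rarely yield components above the cutoff", {
  retained <- vapply(1:30, function(s) {
    ep <- synth_epochs(10, c("A", "B"), sep = 0, noise = 1, seed = 100 + s,
                       n_ch = 6, n_tp = 40)
    ep$times_s <- seq(-0.2, 0.19, by = 0.01)
    sel <- suppressWarnings(
      select_components_snr(ep, pipeline_config(), signal_window = c(0, 0.19),
                            baseline_window = c(-0.2, 0)))
    # a warning-backed single component counts as zero passing
    if (max(sel$snr_db) < 8) 0L else sel$n_components
  }, integer(1))
  expect_lte(mean(retained), 1.5)
  expect_lte(median(retained), 1)
})

test_that("cross-validation folds hold one trial per design cell", {
  meta <- expand.grid(leading_cat = paste0("L", 1:4),
                      trailing_cat = paste0("T", 1:2),
                      rep = 1:10, stringsAsFactors = FALSE)[, 1:2]
  f <- make_cv_folds(meta, seed = 1)
  expect_equal(f$n_folds, 10)
  expect_true(all(!is.na(f$fold)))           # partition: every trial tested
  expect_true(all(table(f$fold) == 8))       # 8 test trials per fold
  for (k in 1:10) {
    test <- which(f$fold == k)
    cells <- paste(meta$leading_cat[test], meta$trailing_cat[test])
    expect_equal(length(unique(cells)), 8)   # one per cell
    expect_length(intersect(test, which(f$fold != k)), 0)
  }
})

test_that("unbalanced cells give complete folds plus training-only surplus", {
  meta <- do.call(rbind, lapply(1:8, function(cell) {
    n <- if (cell == 8) 7 else 10
    data.frame(leading_cat = paste0("L", (cell - 1) %% 4 + 1),
               trailing_cat = paste0("T", (cell - 1) %/% 4 + 1),
               stringsAsFactors = FALSE)[rep(1, n), ]
  }))
  f <- make_cv_folds(meta, seed = 2)
  expect_equal(f$n_folds, 7)
  expect_equal(sum(is.na(f$fold)), nrow(meta) - 7 * 8)
  # error pathways: an absent cell is named, small cells are rejected
  expect_error(make_cv_folds(meta,
                             cells = c(sort(unique(paste(meta$leading_cat,
                                                         meta$trailing_cat,
                                                         sep = ":"))),
                                       "L9:T9")),
               "L9:T9")
  one <- meta[c(1, 8, 15, 22, 29, 36, 43, 50), ]
  expect_error(make_cv_folds(one), "at least 2")
})

test_that("perfectly separable classes decode at 100%", {
  ep <- synth_epochs(10, c("A", "B"), sep = 5, noise = 1e-6, seed = 3)
  f <- make_cv_folds(ep$metadata, seed = 3)
  res <- decode_timecourse(ep, ep$metadata$trailing_cat, f,
                           pipeline_config(snr_cutoff_db = -Inf,
                                           selection = "global"),
                           signal_window = c(0, 1), baseline_window = c(0, 1))
  expect_true(all(res$accuracy == 1))
  expect_equal(res$chance_level, 0.5)
  # accuracy is the column mean of per-trial correctness
  expect_equal(res$accuracy, colMeans(res$per_trial_correct, na.rm = TRUE))
})

test_that("label-permutation nulls sit at chance for 2- and 4-way decoding", {
  orc <- measure_decoding_oracles(seed = 11, n_sims = 15)
  se2 <- sqrt(0.25 / (15 * 32))
  se4 <- sqrt(0.25 * 0.75 / (15 * 32))
  expect_lt(abs(orc$null_accuracy_2way - 0.5), 4 * se2 + 0.01)
  expect_lt(abs(orc$null_accuracy_4way - 0.25), 4 * se4 + 0.01)
  expect_equal(orc$separable_accuracy, 1)
  expect_true(orc$folds_partition_ok)
})

test_that("decoding is invariant to channel order and deterministic", {
  ep <- synth_epochs(8, c("A", "B"), sep = 1.2, noise = 1, seed = 4)
  cfg <- pipeline_config(snr_cutoff_db = -Inf, selection = "global")
  f <- make_cv_folds(ep$metadata, seed = 5)
  r1 <- decode_timecourse(ep, ep$metadata$trailing_cat, f, cfg,
                          signal_window = c(0, 1), baseline_window = c(0, 1))
  perm <- c(4, 2, 6, 1, 3, 5)
  ep2 <- ep
  ep2$data <- ep$data[, perm, ]
  ep2$channel_labels <- ep$channel_labels[perm]
  r2 <- decode_timecourse(ep2, ep2$metadata$trailing_cat, f, cfg,
                          signal_window = c(0, 1), baseline_window = c(0, 1))
  expect_equal(r2$accuracy, r1$accuracy)
  r3 <- decode_timecourse(ep, ep$metadata$trailing_cat, f, cfg,
                          signal_window = c(0, 1), baseline_window = c(0, 1))
  expect_identical(r1$per_trial_correct, r3$per_trial_correct)
})

test_that("accuracy never falls as the injected separation grows", {
  cfg <- pipeline_config(snr_cutoff_db = -Inf, selection = "global")
  accs <- vapply(c(0, 1, 2.5, 5), function(sep) {
    ep <- synth_epochs(8, c("A", "B"), sep = sep, noise = 1, seed = 6)
    f <- make_cv_folds(ep$metadata, seed = 6)
    mean(decode_timecourse(ep, ep$metadata$trailing_cat, f, cfg,
                           signal_window = c(0, 1),
                           baseline_window = c(0, 1))$accuracy)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("single-class training folds are rejected", {
  ep <- synth_epochs(6, c("A", "B"), sep = 1, noise = 1, seed = 7)
  f <- make_cv_folds(ep$metadata, seed = 7)
  expect_error(decode_timecourse(ep, rep("A", 12), f,
                                 pipeline_config(snr_cutoff_db = -Inf),
                                 signal_window = c(0, 1),
                                 baseline_window = c(0, 1)),
               "single class")
})

test_that("the decoding suite wires analyses, locks and chance levels", {
  des <- tiny_design(n_blocks = 1, v = 9, i = 3, ctrl = 3, catch = 0)
  x <- tiny_recording(seed = 17, fs = 256, n_ch = 16, design = des,
                      noise = noise_spec(noise_sd = 4, blink_rate_hz = 0,
                                         line_noise_amp = 0),
                      memory = 0.5)
  cfg <- pipeline_config(fs_down_hz = 128, dss_n_keep = 6,
                         epoch_window_s = c(-0.2, 1.4),
                         decode_window_s = c(0.05, 0.35), max_folds = 3)
  ep <- preprocess_pipeline(x$rec, cfg)
  st <- suppressWarnings(run_decoding_suite(ep, "sensory_trailing", cfg, seed = 1))
  expect_equal(st$valid$chance_level, 0.5)
  expect_equal(st$valid$validity, "valid")
  expect_equal(st$valid$time_lock, "trailing_onset")
  expect_true(all(st$valid$times_s >= 0.05 - 1e-9 &
                  st$valid$times_s <= 0.35 + 1e-9))
  mem <- suppressWarnings(run_decoding_suite(ep, "memory", cfg, seed = 2))
  expect_equal(mem$valid$chance_level, 0.25)
  expect_equal(mem$invalid$chance_level, 0.25)
  # anticipated-trailing variant: trailing labels from leading-locked data
  pr <- suppressWarnings(run_decoding_suite(ep, "prediction", cfg, seed = 3))
  expect_equal(pr$valid$chance_level, 0.5)
  expect_equal(pr$valid$time_lock, "leading_onset")
  expect_error(run_decoding_suite(ep, "nope", cfg), "arg")
})
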