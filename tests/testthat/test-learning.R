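test_that("trialwise benefit reflects the correctness series exactly", {
  n <- 120
  times <- seq(0.1, 0.2, by = 0.01)
  idx_v <- seq(0, 2 * n - 1, by = 2)
  idx_i <- seq(1, 2 * n - 1, by = 2)
  cfg <- pipeline_config(smoothing_k = 5, benefit_grid = 50)
  # identical correctness: benefit is identically zero
  cm <- matrix(1, n, length(times))
  v <- fake_decoding_result(cm, idx_v, times, "valid")
  i <- fake_decoding_result(cm, idx_i, times, "invalid")
  b0 <- trialwise_benefit(v, i, c(0.1, 0.2), cfg)
  expect_true(all(abs(b0$benefit) < 1e-12))
  expect_equal(nrow(b0), 50)
  # valid always right, invalid always wrong: benefit is one everywhere
  i1 <- fake_decoding_result(matrix(0, n, length(times)), idx_i, times,
                             "invalid")
  b1 <- trialwise_benefit(v, i1, c(0.1, 0.2), cfg)
  expect_true(all(abs(b1$benefit - 1) < 1e-12))
  expect_error(trialwise_benefit(v, i, c(5, 6), cfg), "outside")
})

test_that("a ramped success probability appears in the late benefit", {
  # binomial oracle: P(correct | valid) = 0.5 + 0.2 * min(1, t/100)
  set.seed(6)
  n <- 400
  times <- seq(0.1, 0.14, by = 0.01)
  p_v <- 0.5 + 0.2 * pmin(1, seq_len(n) / 100)
  reps <- replicate(60, {
    cv <- matrix(rbinom(n * 5, 1, rep(p_v, 5)), n, 5)
    ci <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
    v <- fake_decoding_result(cv, seq_len(n) * 2 - 2, times, "valid")
    i <- fake_decoding_result(ci, seq_len(n) * 2 - 1, times, "invalid")
    b <- trialwise_benefit(v, i, c(0.1, 0.14),
                           pipeline_config(smoothing_k = 21,
                                           benefit_grid = 200))
    mean(b$benefit[151:200])
  })
  expect_lt(abs(mean(reps) - 0.2), 0.02)
})

test_that("the logarithmic fit matches its closed-form normal equations", {
  set.seed(7)
  n <- 150
  t <- seq_len(n)
  y <- 0.07 + 0.03 * log(t) + rnorm(n, 0, 0.01)
  fit <- fit_log_stabilization(y, pipeline_config())
  X <- cbind(1, log(t))
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$a, beta[1], tolerance = 1e-10)
  expect_equal(fit$b, beta[2], tolerance = 1e-10)
})

test_that("noiseless log series recover coefficients and the analytic index", {
  cfg <- pipeline_config()
  a <- 0.1; b <- 0.05; n <- 200
  t <- seq_len(n)
  fit <- fit_log_stabilization(a + b * log(t), cfg)
  expect_lt(abs(fit$a - a), 1e-6)
  expect_lt(abs(fit$b - b), 1e-6)
  # analytic index: first t with |b log(1+1/t)| / |a + b log t| < 0.001
  rel <- abs(b * log(1 + 1 / t[-n])) / abs(a + b * log(t[-n]))
  expect_equal(fit$stabilization_index, which(rel < cfg$log_tol)[1])
  # constant series stabilizes immediately with zero slope
  cfit <- fit_log_stabilization(rep(0.3, 50), cfg)
  expect_equal(cfit$b, 0)
  expect_equal(cfit$stabilization_index, 1L)
  # decaying benefit: negative slope, finite index (brute-force scan)
  dfit <- fit_log_stabilization(0.4 - 0.06 * log(t), cfg)
  expect_lt(dfit$b, 0)
  fitv <- dfit$a + dfit$b * log(t)
  scan <- which(abs(diff(fitv)) / abs(fitv[-n]) < cfg$log_tol)[1]
  expect_equal(dfit$stabilization_index, scan)
  expect_error(fit_log_stabilization(1:5, cfg), "too short")
})

test_that("binning splits the session into equal consecutive parts", {
  n <- 432 * 4
  times <- seq(0.1, 0.13, by = 0.01)
  cm_v <- matrix(1, n / 2, length(times))
  cm_i <- matrix(rep(c(1, 0), length.out = n / 2 * length(times)),
                 n / 2, length(times))
  v <- fake_decoding_result(cm_v, seq(0, n - 1, by = 2), times, "valid")
  i <- fake_decoding_result(cm_i, seq(1, n - 1, by = 2), times, "invalid")
  tab <- bin_decoding(list(s1 = list(valid = v, invalid = i)),
                      list(early = c(0.1, 0.13)), pipeline_config())
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$mean_accuracy[tab$validity == "valid"] == 1))
  # alternating correctness averages to one half in every bin
  expect_true(all(abs(tab$mean_accuracy[tab$validity == "invalid"] - 0.5)
                  < 0.01))
  # bins are invariant to within-bin trial order (means by enumeration)
  expect_equal(unique(table(rep(1:4, each = n / 8))), n / 8)
})

test_that("the crossover mixed model detects interactions and flags outliers", {
  set.seed(8)
  n_sub <- 24
  mk <- function(effect, shift_row = NULL) {
    subj <- rep(sprintf("s%02d", 1:n_sub), each = 4)
    validity <- rep(c("valid", "invalid"), times = 2 * n_sub)
    bin <- rep(rep(1:2, each = 2), times = n_sub)
    mu <- 0.55 + ifelse(validity == "valid" & bin == 2, effect, 0)
    acc <- mu + rep(rnorm(n_sub, 0, 0.03), each = 4) +
      rnorm(4 * n_sub, 0, 0.03)
    d <- data.frame(subject = subj, window_id = "early",
                    validity = validity, bin = bin, mean_accuracy = acc)
    if (!is.null(shift_row)) d$mean_accuracy[shift_row] <-
        d$mean_accuracy[shift_row] + 10 * 0.03
    d
  }
  res <- fit_validity_bin_lme(mk(0.1), pipeline_config())
  inter <- res$fixed[grepl(":", res$fixed$term), ]
  expect_lt(inter$p, 0.05)
  expect_gt(res$cohens_f, 0)
  expect_equal(nrow(res$posthoc), 4)
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p))
  # Holm adjustment is monotone in the raw p values
  ord <- order(res$posthoc$p)
  expect_true(all(diff(res$posthoc$p_adj[ord]) >= -1e-12))
  # a 10-SD-shifted cell is flagged by the Cook's-distance rule
  res_out <- suppressWarnings(fit_validity_bin_lme(mk(0.1, shift_row = 7),
                                                   pipeline_config()))
  expect_true(7 %in% res_out$removed_outliers)
})

test_that("flat tables produce null effects", {
  subj <- rep(sprintf("s%02d", 1:10), each = 4)
  tab <- data.frame(subject = subj, window_id = "early",
                    validity = rep(c("valid", "invalid"), 20),
                    bin = rep(rep(1:2, each = 2), 10),
                    mean_accuracy = 0.5)
  res <- suppressWarnings(fit_validity_bin_lme(tab, pipeline_config()))
  fx <- res$fixed[res$fixed$term != "(Intercept)", ]
  expect_true(all(fx$p > 0.99))
  expect_lt(res$cohens_f, 1e-6)
})
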