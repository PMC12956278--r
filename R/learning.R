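#' Trial-wise decoding-benefit series
#'
#' Builds the across-trial time series of the decoding benefit of valid
#' over invalid trials within a post-stimulus window: per-trial
#' correctness is averaged over the window's time points, each validity
#' series is smoothed with a centred moving average (edges truncated)
#' along its own trial positions, both are aligned on the session trial
#' index by linear interpolation, and their difference is resampled onto
#' a fixed-length grid spanning the session.
#'
#' @param valid_result,invalid_result `decoding_result` objects from the
#'   same subject and analysis.
#' @param window_s window (s, decoding time axis) over which per-trial
#'   correctness is averaged.
#' @param cfg a [pipeline_config()] (`smoothing_k`, `benefit_grid`).
#' @return data frame with `grid_index` (1..`benefit_grid`),
#'   `session_trial` (interpolated session trial index) and `benefit`.
#' @export
trialwise_benefit <- function(valid_result, invalid_result, window_s,
                              cfg = pipeline_config()) {
  widx <- window_idx(valid_result$times_s, window_s)
  if (!length(widx)) stop("window outside the decoded time range")
  series_of <- function(res) {
    pc <- res$per_trial_correct[, widx, drop = FALSE]
    tested <- rowSums(!is.na(pc)) > 0
    val <- rowMeans(pc[tested, , drop = FALSE], na.rm = TRUE)
    pos <- res$metadata$index[tested]   # session trial index (0-based)
    ord <- order(pos)
    list(pos = pos[ord], val = moving_average(val[ord], cfg$smoothing_k))
  }
  v <- series_of(valid_result)
  i <- series_of(invalid_result)
  lo <- max(min(v$pos), min(i$pos))
  hi <- min(max(v$pos), max(i$pos))
  grid <- seq(lo, hi, length.out = cfg$benefit_grid)
  benefit <- approx(v$pos, v$val, xout = grid, rule = 2)$y -
             approx(i$pos, i$val, xout = grid, rule = 2)$y
  data.frame(grid_index = seq_along(grid), session_trial = grid,
             benefit = benefit)
}

#' Logarithmic learning-curve fit with stabilization index
#'
#' Least-squares fit of `benefit(t) = a + b * log(t)` over trial index
#' `t = 1..n`, and the stabilization index: the first trial at which the
#' relative per-trial change of the fitted curve,
#' `|fit(t+1) - fit(t)| / |fit(t)|`, drops below `cfg$log_tol` (0.1% by
#' default). Where the fitted value is zero the absolute change is used.
#' A constant series yields `b = 0` and stabilization at trial 1.
#'
#' @param benefit numeric series (length >= 10) on a trial grid, or the
#'   data frame returned by [trialwise_benefit()].
#' @param cfg a [pipeline_config()].
#' @return object of class `"learning_fit"`: `a`, `b`, `r_squared`,
#'   `stabilization_index` (trial index, `NA` if never reached),
#'   `stabilized` (logical), `n`.
#' @export
fit_log_stabilization <- function(benefit, cfg = pipeline_config()) {
  if (is.data.frame(benefit)) benefit <- benefit$benefit
  n <- length(benefit)
  if (n < 10) stop("series too short for a learning-curve fit")
  t <- seq_len(n)
  if (var(benefit) == 0) {
    fitv <- rep(benefit[1], n)
    a <- benefit[1]; b <- 0; r2 <- 1
  } else {
    fit <- lm(benefit ~ log(t))
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
    fitv <- unname(fitted(fit))
    r2 <- 1 - sum((benefit - fitv)^2) / sum((benefit - mean(benefit))^2)
  }
  change <- abs(diff(fitv))
  denom <- abs(fitv[-n])
  rel <- ifelse(denom == 0, change, change / denom)
  idx <- which(rel < cfg$log_tol)
  stab <- if (length(idx)) idx[1] else NA_integer_
  structure(list(a = a, b = b, r_squared = r2,
                 stabilization_index = stab,
                 stabilized = !is.na(stab), n = n),
            class = "learning_fit")
}

#' @export
print.learning_fit <- function(x, ...) {
  cat(sprintf("<learning_fit> benefit ~ %.4g + %.4g log(t), R2 = %.3f; stabilizes at trial %s of %d\n",
              x$a, x$b, x$r_squared,
              if (x$stabilized) x$stabilization_index else "— (not reached)",
              x$n))
  invisible(x)
}

#' Bin window-averaged decoding accuracy over the session
#'
#' Splits the session trials (by session order) into `n_bins`
#' consecutive equal-count bins (remainder trials going to the earlier
#' bins) and averages window-averaged per-trial correctness within each
#' bin, validity and window.
#'
#' @param results named list of subjects, each a list with `valid` and
#'   `invalid` `decoding_result` elements (as returned by
#'   [run_decoding_suite()]).
#' @param windows named list of windows (s), e.g.
#'   `list(early = c(0.123, 0.180), late = c(0.280, 0.296))`.
#' @param cfg a [pipeline_config()].
#' @return data frame of class `"bin_table"` with columns `subject`,
#'   `window_id`, `validity`, `bin`, `mean_accuracy`.
#' @export
bin_decoding <- function(results, windows, cfg = pipeline_config()) {
  n_bins <- cfg$n_bins
  rows <- list()
  for (s in seq_along(results)) {
    subj <- names(results)[s]
    if (is.null(subj) || subj == "") subj <- as.character(s)
    for (w in seq_along(windows)) {
      for (v in c("valid", "invalid")) {
        res <- results[[s]][[v]]
        widx <- window_idx(res$times_s, windows[[w]])
        if (!length(widx)) stop("window outside the decoded time range")
        pc <- res$per_trial_correct[, widx, drop = FALSE]
        tested <- rowSums(!is.na(pc)) > 0
        if (sum(tested) < n_bins)
          stop("fewer tested trials than bins for validity ", v)
        val <- rowMeans(pc[tested, , drop = FALSE], na.rm = TRUE)
        pos <- res$metadata$index[tested]
        ord <- order(pos)
        val <- val[ord]
        # equal-count consecutive bins, remainder to earlier bins
        m <- length(val)
        base <- m %/% n_bins
        sizes <- rep(base, n_bins) + c(rep(1, m %% n_bins),
                                       rep(0, n_bins - m %% n_bins))
        bin <- rep(seq_len(n_bins), times = sizes)
        for (b in seq_len(n_bins)) {
          rows[[length(rows) + 1]] <- data.frame(
            subject = subj, window_id = names(windows)[w], validity = v,
            bin = b, mean_accuracy = mean(val[bin == b]))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bin_table", "data.frame")
  out
}

# Cohen's f for a (mixed) linear model from marginal R^2:
# f = sqrt(R2 / (1 - R2)), R2 = var(fixed-effect fit) over total variance.
cohens_f_lmm <- function(fit) {
  if (inherits(fit, "merMod")) {
    fe <- lme4::fixef(fit)
    X <- lme4::getME(fit, "X")
    var_f <- var(as.numeric(X %*% fe))
    vc <- lme4::VarCorr(fit)
    var_r <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
    var_e <- attr(vc, "sc")^2
    r2 <- var_f / (var_f + var_r + var_e)
  } else {
    r2 <- summary(fit)$r.squared
  }
  sqrt(r2 / max(1e-12, 1 - r2))
}

paired_t_row <- function(a, b, label) {
  tt <- t.test(a, b, paired = TRUE)
  n <- length(a)
  d <- unname(tt$statistic) / sqrt(n)
  data.frame(contrast = label, t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             cohens_f = abs(d) / 2)
}

#' Mixed-effects model of binned decoding accuracy
#'
#' Fits `mean_accuracy ~ validity * bin + (1 | subject)` to the first
#' two trial bins of a [bin_decoding()] table (the learning phase),
#' removes rows whose Cook's distance exceeds the mean by `cfg$cooks_sd`
#' standard deviations, refits once, and reports the fixed effects
#' (Satterthwaite t, df, p), Cohen's f for the full model, and
#' Holm-Bonferroni-adjusted post hoc paired contrasts (valid vs invalid
#' within each bin; bin 1 vs bin 2 within each validity). If the random
#' intercept makes the fit singular the model falls back to a
#' fixed-effects linear model with a warning.
#'
#' @param table a [bin_decoding()] table restricted to one window.
#' @param cfg a [pipeline_config()].
#' @param bins which bins to analyse (default 1:2).
#' @return object of class `"lme_result"`: `fixed` (data frame with
#'   `term`, `estimate`, `t`, `df`, `p`), `cohens_f`,
#'   `removed_outliers` (row ids of the input table), `posthoc`
#'   (data frame with Holm-adjusted `p_adj`), `model`.
#' @export
fit_validity_bin_lme <- function(table, cfg = pipeline_config(), bins = 1:2) {
  stopifnot(all(c("subject", "validity", "bin", "mean_accuracy") %in%
                names(table)))
  if (length(unique(table$window_id)) > 1)
    stop("restrict the table to a single window before fitting")
  dat <- table[table$bin %in% bins, , drop = FALSE]
  dat$row_id <- seq_len(nrow(dat))
  if (length(unique(dat$subject)) < 2) stop("need at least 2 subjects")
  dat$validity <- factor(dat$validity, levels = c("invalid", "valid"))
  dat$bin_c <- dat$bin - mean(bins)   # centred bin covariate

  if (var(dat$mean_accuracy) < 1e-18) {
    # degenerate table: no variance, no effects
    terms <- c("(Intercept)", "validityvalid", "bin_c",
               "validityvalid:bin_c")
    fixed <- data.frame(term = terms,
                        estimate = c(mean(dat$mean_accuracy), 0, 0, 0),
                        t = 0, df = NA_real_, p = c(0, 1, 1, 1))
    fixed$p[1] <- NA_real_
    ph <- data.frame(contrast = c(sprintf("valid-invalid@bin%d", bins),
                                  sprintf("bin%d-bin%d@%s", bins[1],
                                          bins[2], c("valid", "invalid"))),
                     t = 0, df = NA_real_, p = 1, cohens_f = 0, p_adj = 1)
    return(structure(list(fixed = fixed, cohens_f = 0,
                          removed_outliers = integer(0), posthoc = ph,
                          model = NULL),
                     class = "lme_result"))
  }

  fit_once <- function(d) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(mean_accuracy ~ validity * bin_c + (1 | subject),
                     data = d, REML = TRUE)))
    if (lme4::isSingular(fit)) {
      warning("singular random-intercept fit; falling back to fixed effects")
      fit <- lm(mean_accuracy ~ validity * bin_c, data = d)
    }
    fit
  }
  fit <- fit_once(dat)
  cd <- cooks.distance(fit)
  cd[!is.finite(cd)] <- 0
  thr <- mean(cd) + cfg$cooks_sd * sd(cd)
  out_rows <- dat$row_id[cd > thr]
  dat2 <- if (length(out_rows)) dat[!(dat$row_id %in% out_rows), ] else dat
  fit <- fit_once(dat2)

  if (inherits(fit, "merMod")) {
    sm <- summary(fit)$coefficients
    fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        t = sm[, "t value"], df = sm[, "df"],
                        p = sm[, "Pr(>|t|)"], row.names = NULL)
  } else {
    sm <- summary(fit)$coefficients
    fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        t = sm[, "t value"], df = fit$df.residual,
                        p = sm[, "Pr(>|t|)"], row.names = NULL)
  }

  # post hoc paired contrasts on subject cell means (complete pairs)
  cell <- function(v, b) {
    sub <- dat2[dat2$validity == v & dat2$bin == b, ]
    setNames(sub$mean_accuracy, sub$subject)
  }
  ph <- list()
  for (b in bins) {
    a <- cell("valid", b); z <- cell("invalid", b)
    common <- intersect(names(a), names(z))
    ph[[length(ph) + 1]] <- paired_t_row(a[common], z[common],
                                         sprintf("valid-invalid@bin%d", b))
  }
  for (v in c("valid", "invalid")) {
    a <- cell(v, bins[1]); z <- cell(v, bins[2])
    common <- intersect(names(a), names(z))
    ph[[length(ph) + 1]] <- paired_t_row(a[common], z[common],
                                         sprintf("bin%d-bin%d@%s",
                                                 bins[1], bins[2], v))
  }
  posthoc <- do.call(rbind, ph)
  posthoc$p_adj <- p.adjust(posthoc$p, method = "holm")

  structure(list(fixed = fixed, cohens_f = cohens_f_lmm(fit),
                 removed_outliers = out_rows, posthoc = posthoc,
                 model = fit),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat("<lme_result> fixed effects:\n")
  print(x$fixed, digits = 4)
  cat(sprintf("Cohen's f (full model): %.3f; %d outlying row(s) removed\n",
              x$cohens_f, length(x$removed_outliers)))
  cat("post hoc (Holm-adjusted):\n")
  print(x$posthoc, digits = 4)
  invisible(x)
}
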