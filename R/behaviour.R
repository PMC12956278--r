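#' Reaction-time analysis of the categorisation task
#'
#' Removes outlying reaction times (beyond `cfg$rt_outlier_sd` standard
#' deviations from the pooled mean across subjects, on the raw scale),
#' log-transforms the remainder, averages per subject and condition
#' (imputing a subject's empty cell with the across-subject mean of that
#' condition), and runs a repeated-measures ANOVA over the three
#' conditions plus paired t tests for each condition pair with Cohen's
#' d effect sizes.
#'
#' @param table data frame with columns `subject`, `condition`
#'   (`valid`/`invalid`/`neutral`) and `rt_ms` (> 0), e.g. from
#'   [simulate_rts()].
#' @param cfg a [pipeline_config()].
#' @return object of class `"rt_analysis"`: `anova` (F, df, p, partial
#'   eta squared), `pairwise` (paired t tests with Cohen's d),
#'   `condition_stats` (per-condition mean and SEM of the raw-scale
#'   subject means, ms), `subject_means` (log scale, imputed cells
#'   flagged), `n_outliers_removed`.
#' @export
analyze_rts <- function(table, cfg = pipeline_config()) {
  stopifnot(all(c("subject", "condition", "rt_ms") %in% names(table)),
            all(table$rt_ms > 0))
  conds <- c("valid", "invalid", "neutral")
  if (length(unique(table$subject)) < 2) stop("need at least 2 subjects")
  for (cc in conds)
    if (!any(table$condition == cc))
      stop("condition empty for all subjects: ", cc)

  mu <- mean(table$rt_ms)
  s <- sd(table$rt_ms)
  keep <- abs(table$rt_ms - mu) <= cfg$rt_outlier_sd * s
  n_out <- sum(!keep)
  tab <- table[keep, , drop = FALSE]
  tab$log_rt <- log(tab$rt_ms)

  subjects <- unique(table$subject)
  grid <- expand.grid(subject = subjects, condition = conds,
                      stringsAsFactors = FALSE)
  agg <- aggregate(log_rt ~ subject + condition, data = tab, FUN = mean)
  sm <- merge(grid, agg, all.x = TRUE)
  sm$imputed <- is.na(sm$log_rt)
  for (cc in conds) {
    sel <- sm$condition == cc
    if (all(is.na(sm$log_rt[sel])))
      stop("condition empty for all subjects after outlier removal: ", cc)
    sm$log_rt[sel & is.na(sm$log_rt)] <- mean(sm$log_rt[sel], na.rm = TRUE)
  }
  sm$subject <- factor(sm$subject)
  sm$condition <- factor(sm$condition, levels = conds)

  av <- aov(log_rt ~ condition + Error(subject / condition), data = sm)
  avs <- summary(av)[["Error: subject:condition"]][[1]]
  ss_c <- avs["condition", "Sum Sq"]
  ss_e <- avs["Residuals", "Sum Sq"]
  anova_res <- data.frame(F = avs["condition", "F value"],
                          df1 = avs["condition", "Df"],
                          df2 = avs["Residuals", "Df"],
                          p = avs["condition", "Pr(>F)"],
                          partial_eta_sq = ss_c / (ss_c + ss_e))

  wide <- reshape_cells(sm)
  pair_list <- list(c("valid", "invalid"), c("valid", "neutral"),
                    c("invalid", "neutral"))
  pairwise <- do.call(rbind, lapply(pair_list, function(pr) {
    tt <- t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    diffs <- wide[[pr[1]]] - wide[[pr[2]]]
    data.frame(contrast = paste(pr, collapse = "-"),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohens_d = mean(diffs) / sd(diffs))
  }))

  raw_means <- aggregate(rt_ms ~ subject + condition, data = tab, FUN = mean)
  cond_stats <- do.call(rbind, lapply(conds, function(cc) {
    v <- raw_means$rt_ms[raw_means$condition == cc]
    data.frame(condition = cc, mean_ms = mean(v),
               sem_ms = sd(v) / sqrt(length(v)))
  }))

  structure(list(anova = anova_res, pairwise = pairwise,
                 condition_stats = cond_stats, subject_means = sm,
                 n_outliers_removed = n_out),
            class = "rt_analysis")
}

reshape_cells <- function(sm) {
  subjects <- levels(sm$subject)
  out <- lapply(levels(sm$condition), function(cc) {
    v <- sm$log_rt[sm$condition == cc]
    v[match(subjects, sm$subject[sm$condition == cc])]
  })
  names(out) <- levels(sm$condition)
  out
}

#' @export
print.rt_analysis <- function(x, ...) {
  cat("<rt_analysis>\n")
  cat(sprintf("  ANOVA: F(%d,%d) = %.3f, p = %.4f, partial eta^2 = %.3f\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p,
              x$anova$partial_eta_sq))
  print(x$pairwise, digits = 4)
  print(x$condition_stats, digits = 5)
  invisible(x)
}

#' Brain-behaviour correlations
#'
#' Pearson correlations between each subject's reaction-time expectation
#' effect (invalid minus valid) and their decoding-accuracy expectation
#' effect in each analysis window.
#'
#' @param rt_effects named numeric vector, one value per subject.
#' @param decoding_effects data frame or matrix with one row per subject
#'   (same order) and one column per window.
#' @return data frame with `window`, `r`, `df`, `p` (two-tailed).
#' @export
brain_behaviour_correlation <- function(rt_effects, decoding_effects) {
  decoding_effects <- as.data.frame(decoding_effects)
  n <- length(rt_effects)
  if (n < 3 || nrow(decoding_effects) != n)
    stop("need at least 3 paired observations per window")
  if (sd(rt_effects) == 0) stop("undefined correlation: zero variance")
  do.call(rbind, lapply(names(decoding_effects), function(w) {
    y <- decoding_effects[[w]]
    if (sd(y) == 0) stop("undefined correlation: zero variance in ", w)
    ct <- cor.test(rt_effects, y, method = "pearson")
    data.frame(window = w, r = unname(ct$estimate),
               df = unname(ct$parameter), p = ct$p.value)
  }))
}
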