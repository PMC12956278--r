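#' SNR-based PCA feature selection
#'
#' Fits a principal component decomposition to the channel covariance of
#' the single-trial epochs and scores each component by its evoked
#' signal-to-noise ratio: `10 * log10` of the variance of the
#' trial-averaged projection inside the post-stimulus signal window over
#' its variance inside the baseline window. Components at or above
#' `cfg$snr_cutoff_db` are retained in descending SNR order; if none
#' pass, the single best component is kept with a warning.
#'
#' @param ep an `eeg_epochs` object.
#' @param cfg a [pipeline_config()].
#' @param signal_window,baseline_window windows (s, epoch time axis)
#'   defining evoked signal and baseline variance.
#' @param trials optional trial indices (e.g. training folds) used to
#'   fit the decomposition; projections can then be applied to held-out
#'   trials without leakage.
#' @return list with `projection` (channels x k matrix), `snr_db`
#'   (all components, descending) and `n_components`.
#' @export
select_components_snr <- function(ep, cfg = pipeline_config(),
                                  signal_window = c(0, 0.4),
                                  baseline_window = cfg$baseline_s,
                                  trials = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  if (is.null(trials)) trials <- seq_len(d[3])
  if (length(trials) < 2) stop("need at least 2 trials")
  sig_idx <- window_idx(ep$times_s, signal_window)
  base_idx <- window_idx(ep$times_s, baseline_window)
  if (!length(sig_idx) || !length(base_idx))
    stop("signal or baseline window outside epoch")

  sub <- ep$data[, , trials, drop = FALSE]
  xm <- matrix(aperm(sub, c(1, 3, 2)), d[1] * length(trials), d[2])
  xm <- sweep(xm, 2, colMeans(xm))
  e <- eigen(crossprod(xm) / nrow(xm), symmetric = TRUE)
  comps <- e$vectors

  avg <- rowMeans(sub, dims = 2) %*% comps     # time x components
  v_sig <- apply(avg[sig_idx, , drop = FALSE], 2, var)
  v_base <- apply(avg[base_idx, , drop = FALSE], 2, var)
  snr <- 10 * log10(v_sig / v_base)
  snr[v_sig == 0 & v_base == 0] <- -Inf
  ord <- order(snr, decreasing = TRUE)
  pass <- ord[snr[ord] >= cfg$snr_cutoff_db]
  if (!length(pass)) {
    warning("no component reached the SNR cutoff; keeping the best one")
    pass <- ord[1]
  }
  list(projection = comps[, pass, drop = FALSE],
       snr_db = snr[ord], n_components = length(pass))
}

#' Cross-validation folds with one trial per design cell
#'
#' Builds test sets holding exactly one randomly chosen trial from each
#' leading-by-trailing design cell, so that category and transition
#' structure are balanced in every test set (with the full 2:1 condition
#' this is leave-8-out: 4 leading x 2 trailing cells). The number of
#' folds is the minimum per-cell trial count (optionally capped by
#' `max_folds`); trials beyond the per-cell minimum appear in training
#' sets only.
#'
#' @param metadata trial metadata with `leading_cat` and `trailing_cat`.
#' @param seed integer seed for the within-cell shuffles.
#' @param max_folds cap on the number of folds.
#' @param cells optional character vector of required `"leading:trailing"`
#'   cells; a required cell with no trials raises an error naming it.
#' @return list with `fold` (integer per trial; `NA` marks training-only
#'   surplus trials), `n_folds` and `cells`.
#' @export
make_cv_folds <- function(metadata, seed = 1L, max_folds = Inf,
                          cells = NULL) {
  stopifnot(all(c("leading_cat", "trailing_cat") %in% names(metadata)))
  rng <- local_rng(seed)
  cell_of <- paste(metadata$leading_cat, metadata$trailing_cat, sep = ":")
  observed <- unique(cell_of)
  if (is.null(cells)) cells <- sort(observed)
  missing_cells <- setdiff(cells, observed)
  if (length(missing_cells))
    stop("design cell(s) with 0 trials: ", paste(missing_cells, collapse = ", "))
  counts <- table(factor(cell_of, levels = cells))
  if (any(counts < 2))
    stop("every design cell needs at least 2 trials")
  n_folds <- min(min(counts), max_folds)
  fold <- rep(NA_integer_, nrow(metadata))
  for (cc in cells) {
    ids <- which(cell_of == cc)
    ids <- ids[sample.int(length(ids))]
    fold[ids[seq_len(n_folds)]] <- seq_len(n_folds)
  }
  list(fold = fold, n_folds = as.integer(n_folds), cells = cells)
}

# majority vote over one-vs-one decision values; ties broken by the
# summed signed decision value per class
vote_from_decision_values <- function(dv, classes) {
  votes <- matrix(0, nrow(dv), length(classes),
                  dimnames = list(NULL, classes))
  score <- votes
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    pos <- dv[, j] > 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
    score[, a] <- score[, a] + dv[, j]
    score[, b] <- score[, b] - dv[, j]
  }
  vapply(seq_len(nrow(dv)), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) best <- best[which.max(score[i, best])]
    classes[best]
  }, character(1))
}

#' Time-resolved linear SVM decoding
#'
#' At every requested time point, a linear support vector machine is
#' trained on the selected component amplitudes of the training trials
#' (features standardized with training-fold statistics) and evaluated
#' on the fold's test trials. Multi-class problems use one-vs-one
#' classifiers with majority voting; ties are broken by the summed
#' decision values. With `cfg$selection = "per_fold"` the PCA/SNR
#' feature selection is refit within each training fold (leakage-safe);
#' `"global"` fits it once on all trials.
#'
#' @param ep an `eeg_epochs` object.
#' @param labels factor (or coercible) of class labels, one per trial.
#' @param folds a [make_cv_folds()] result.
#' @param cfg a [pipeline_config()].
#' @param time_idx indices into `ep$times_s` to decode (default: all).
#' @param signal_window,baseline_window passed to
#'   [select_components_snr()].
#' @param analysis,validity,subject_id bookkeeping labels stored in the
#'   result.
#' @return object of class `"decoding_result"`: `accuracy` (per decoded
#'   time point), `times_s`, `per_trial_correct` (trials x time, `NA`
#'   for untested trials), `metadata`, `chance_level`,
#'   `n_components_used` (mean over folds), `analysis`, `validity`,
#'   `subject_id`.
#' @export
decode_timecourse <- function(ep, labels, folds, cfg = pipeline_config(),
                              time_idx = NULL,
                              signal_window = c(0, 0.4),
                              baseline_window = cfg$baseline_s,
                              analysis = "custom", validity = "all",
                              subject_id = NA) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  labels <- factor(labels)
  stopifnot(length(labels) == d[3])
  if (is.null(time_idx)) time_idx <- seq_len(d[1])
  ntp <- length(time_idx)
  ntr <- d[3]
  classes <- levels(labels)

  usable <- seq_len(ntr)
  if (cfg$surplus == "discard")
    usable <- which(!is.na(folds$fold))

  global_sel <- NULL
  if (cfg$selection == "global")
    global_sel <- select_components_snr(ep, cfg, signal_window,
                                        baseline_window, trials = usable)

  D <- ep$data[time_idx, , , drop = FALSE]
  flat <- matrix(aperm(D, c(1, 3, 2)), ntp * ntr, d[2])
  correct <- matrix(NA, ntr, ntp)
  ncomp <- numeric(folds$n_folds)

  for (k in seq_len(folds$n_folds)) {
    test <- which(folds$fold == k)
    train <- setdiff(usable, test)
    if (length(unique(labels[train])) < 2)
      stop("training fold contains a single class")
    sel <- if (is.null(global_sel)) {
      select_components_snr(ep, cfg, signal_window, baseline_window,
                            trials = train)
    } else global_sel
    ncomp[k] <- sel$n_components
    feats <- flat %*% sel$projection          # (tp*trial) x k
    for (it in seq_len(ntp)) {
      rows <- it + (seq_len(ntr) - 1L) * ntp
      f_t <- feats[rows, , drop = FALSE]
      mu <- colMeans(f_t[train, , drop = FALSE])
      sdv <- col_sds(f_t[train, , drop = FALSE])
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(f_t[train, , drop = FALSE], 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(f_t[test, , drop = FALSE], 2, mu), 2, sdv, "/")
      fit <- e1071::svm(xtr, labels[train], kernel = "linear",
                        cost = cfg$svm_cost, scale = FALSE)
      if (length(classes) > 2) {
        pr <- predict(fit, xte, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        pred <- vote_from_decision_values(dv, fit$levels)
      } else {
        w <- crossprod(fit$coefs, fit$SV)
        dec <- xte %*% t(w) - fit$rho
        pred <- fit$levels[fit$labels[ifelse(dec > 0, 1, 2)]]
      }
      correct[test, it] <- pred == as.character(labels[test])
    }
  }
  structure(list(accuracy = colMeans(correct, na.rm = TRUE),
                 times_s = ep$times_s[time_idx],
                 per_trial_correct = correct,
                 metadata = ep$metadata,
                 chance_level = 1 / length(classes),
                 n_components_used = mean(ncomp),
                 n_folds = folds$n_folds,
                 analysis = analysis, validity = validity,
                 subject_id = subject_id,
                 time_lock = ep$time_lock),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s (%s), %d time points, chance %.2f, mean accuracy %.3f\n",
              x$analysis, x$validity, length(x$accuracy), x$chance_level,
              mean(x$accuracy)))
  invisible(x)
}

#' Run a full decoding analysis split by validity
#'
#' Restricts the epochs to non-catch trials of the 2:1 condition and
#' runs the selected analysis separately for valid and invalid trials
#' (each with its own feature selection, folds and decoders):
#'
#' * `sensory_leading`: leading-onset-locked window, labels = leading
#'   category (4 classes, chance 0.25);
#' * `sensory_trailing`: trailing-onset-locked window, labels = trailing
#'   category (2 classes, chance 0.5);
#' * `memory`: trailing-onset-locked window, labels = leading category
#'   (4 classes, chance 0.25) — decoding the predictive context from the
#'   response to the trailing image;
#' * `prediction`: leading-onset-locked window, labels = trailing
#'   category (the anticipated trailing category decoded before it
#'   appears).
#'
#' The decoded time range is `cfg$decode_window_s` relative to the
#' locking onset, sampled every `cfg$decode_step` epoch samples.
#'
#' @param ep leading-onset-locked `eeg_epochs` from
#'   [preprocess_pipeline()] (the trailing onset is 0.9 s later).
#' @param analysis one of `"sensory_leading"`, `"sensory_trailing"`,
#'   `"memory"`, `"prediction"`.
#' @param cfg a [pipeline_config()].
#' @param seed integer seed (fold construction).
#' @param subject_id bookkeeping label.
#' @return list with elements `valid` and `invalid`, each a
#'   `decoding_result` whose `times_s` are relative to the locking
#'   onset.
#' @export
run_decoding_suite <- function(ep, analysis = c("sensory_trailing",
                                                "sensory_leading",
                                                "memory", "prediction"),
                               cfg = pipeline_config(), seed = 1L,
                               subject_id = NA) {
  analysis <- match.arg(analysis)
  keep <- ep$metadata$condition == "two_to_one" & !ep$metadata$is_catch
  ep <- subset_epochs(ep, keep)

  lock <- if (analysis %in% c("sensory_trailing", "memory")) "trailing" else "leading"
  offset <- if (lock == "trailing") 0.9 else 0
  rel_times <- ep$times_s - offset
  in_win <- window_idx(rel_times, cfg$decode_window_s)
  if (!length(in_win)) stop("decode window outside epoch")
  time_idx <- in_win[seq(1, length(in_win), by = cfg$decode_step)]
  label_col <- if (analysis == "sensory_trailing" || analysis == "prediction")
    "trailing_cat" else "leading_cat"
  sig_win <- cfg$decode_window_s + offset

  out <- lapply(c(valid = "valid", invalid = "invalid"), function(v) {
    sub <- subset_epochs(ep, ep$metadata$validity == v)
    folds <- make_cv_folds(sub$metadata, seed = child_seed(seed, match(v, c("valid", "invalid"))),
                           max_folds = cfg$max_folds)
    res <- decode_timecourse(sub, sub$metadata[[label_col]], folds, cfg,
                             time_idx = time_idx,
                             signal_window = sig_win,
                             baseline_window = cfg$baseline_s,
                             analysis = analysis, validity = v,
                             subject_id = subject_id)
    res$times_s <- rel_times[time_idx]
    res$time_lock <- paste0(lock, "_onset")
    res
  })
  out
}

#' Subset epochs by trial
#'
#' @param ep an `eeg_epochs` object.
#' @param keep logical or integer trial selector.
#' @return the subset `eeg_epochs`.
#' @export
subset_epochs <- function(ep, keep) {
  ep$data <- ep$data[, , keep, drop = FALSE]
  ep$metadata <- ep$metadata[keep, , drop = FALSE]
  rownames(ep$metadata) <- NULL
  ep$rejected_mask <- rep(FALSE, dim(ep$data)[3])
  ep
}
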