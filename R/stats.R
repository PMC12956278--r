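# ---- vectorized t statistics ----------------------------------------------

one_sample_t_series <- function(x, mu = 0) {
  n <- nrow(x)
  d <- x - mu
  m <- colMeans(d)
  s <- col_sds(d)
  t <- m / (s / sqrt(n))
  t[s == 0] <- 0
  t
}

two_sample_t_series <- function(x, y) {
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- col_sds(x)^2; v2 <- col_sds(y)^2
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  t[sp == 0] <- 0
  t
}

# sign-flip null distribution of one-sample t series: n_perm x tp
sign_flip_t <- function(d, n_perm, seed) {
  local_rng(seed)
  n <- nrow(d)
  s <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  m <- (s %*% d) / n
  ss <- matrix(colSums(d^2), n_perm, ncol(d), byrow = TRUE)
  v <- (ss - n * m^2) / (n - 1)
  t <- m / sqrt(v / n)
  t[!is.finite(t)] <- 0
  t
}

# label-shuffle null of two-sample t series: n_perm x tp
shuffle_two_sample_t <- function(x, y, n_perm, seed) {
  local_rng(seed)
  z <- rbind(x, y)
  n1 <- nrow(x); n <- nrow(z)
  g <- matrix(0, n_perm, n)
  for (p in seq_len(n_perm)) g[p, sample.int(n, n1)] <- 1
  z2 <- z^2
  s1 <- g %*% z; s2 <- (1 - g) %*% z
  q1 <- g %*% z2; q2 <- (1 - g) %*% z2
  n2 <- n - n1
  m1 <- s1 / n1; m2 <- s2 / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (q2 - n2 * m2^2) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
  t <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  t[!is.finite(t)] <- 0
  t
}

find_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

cluster_masses <- function(stat, crit, type = "mass") {
  out <- list()
  for (sign in c(1, -1)) {
    runs <- find_runs(sign * stat > crit)
    if (nrow(runs)) {
      runs$sign <- sign
      runs$mass <- vapply(seq_len(nrow(runs)), function(i) {
        if (type == "extent") runs$end[i] - runs$start[i] + 1
        else sum(abs(stat[runs$start[i]:runs$end[i]]))
      }, numeric(1))
      out[[length(out) + 1]] <- runs
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      sign = numeric(0), mass = numeric(0)))
  do.call(rbind, out)
}

#' Cluster-mass permutation correction over time
#'
#' Family-wise error control for a statistic time series: contiguous
#' suprathreshold runs (two-tailed at the forming threshold) are scored
#' by their mass (sum of the statistic, or extent), and each observed
#' cluster's mass is compared against the permutation distribution of
#' the maximum cluster mass, yielding cluster-level
#' `p_fwe = (1 + #{max-null >= mass}) / (n_perm + 1)`.
#'
#' @param stat observed statistic series (finite).
#' @param perm_stat matrix of permuted statistic series (permutations in
#'   rows), at least 100 rows.
#' @param crit forming threshold on the statistic (e.g.
#'   `qt(1 - alpha/2, df)`).
#' @param times time axis of the series (s).
#' @param cluster_stat `"mass"` or `"extent"`.
#' @return object of class `"cluster_result"`: data frame `clusters`
#'   with `start_s`, `end_s`, `sign`, `mass`, `p_fwe` (ordered by onset,
#'   possibly empty), plus `crit`, `n_perm`, `max_null` (the null
#'   distribution) and the input `stat`/`times`.
#' @export
cluster_correct <- function(stat, perm_stat, crit, times = seq_along(stat),
                            cluster_stat = c("mass", "extent")) {
  cluster_stat <- match.arg(cluster_stat)
  stopifnot(all(is.finite(stat)), nrow(perm_stat) >= 100,
            ncol(perm_stat) == length(stat))
  obs <- cluster_masses(stat, crit, cluster_stat)
  max_null <- apply(perm_stat, 1, function(s) {
    cl <- cluster_masses(s, crit, cluster_stat)
    if (nrow(cl)) max(cl$mass) else 0
  })
  n_perm <- nrow(perm_stat)
  clusters <- data.frame(start_s = times[obs$start], end_s = times[obs$end],
                         sign = obs$sign, mass = obs$mass,
                         p_fwe = vapply(obs$mass, function(m)
                           (1 + sum(max_null >= m)) / (n_perm + 1), numeric(1)))
  clusters <- clusters[order(clusters$start_s), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, crit = crit, n_perm = n_perm,
                 max_null = max_null, stat = stat, times = times),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> forming |stat| > %.3f, %d permutations\n",
              x$crit, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}

#' Group-level statistics on decoding accuracy time series
#'
#' Runs, per time point, a one-sample t test of subject accuracies
#' against the chance level (separately for valid and invalid) and a
#' paired t test of valid minus invalid, all corrected over time with
#' cluster-mass permutation using sign-flip nulls (exchangeability of
#' the sign of subject-level effects under the null).
#'
#' @param valid_mat,invalid_mat subjects x time accuracy matrices on a
#'   common time axis.
#' @param times time axis (s).
#' @param chance chance level of the analysis (0.5 or 0.25).
#' @param cfg a [pipeline_config()].
#' @param seed integer seed for the permutations.
#' @return list with `vs_chance` (per validity, `cluster_result`) and
#'   `paired` (`cluster_result` for valid minus invalid; positive sign
#'   means valid > invalid).
#' @export
group_decoding_stats <- function(valid_mat, invalid_mat, times, chance,
                                 cfg = pipeline_config(), seed = 1L) {
  stopifnot(is.matrix(valid_mat), is.matrix(invalid_mat),
            all(dim(valid_mat) == dim(invalid_mat)),
            ncol(valid_mat) == length(times))
  n <- nrow(valid_mat)
  if (n < 2) stop("need at least 2 subjects")
  crit <- qt(1 - cfg$forming_alpha / 2, df = n - 1)

  vs_chance <- lapply(list(valid = valid_mat, invalid = invalid_mat),
                      function(m) {
    d <- m - chance
    cluster_correct(one_sample_t_series(d),
                    sign_flip_t(d, cfg$n_perm, child_seed(seed, 1)),
                    crit, times, cfg$cluster_stat)
  })
  d <- valid_mat - invalid_mat
  paired <- cluster_correct(one_sample_t_series(d),
                            sign_flip_t(d, cfg$n_perm, child_seed(seed, 2)),
                            crit, times, cfg$cluster_stat)
  list(vs_chance = vs_chance, paired = paired)
}

#' Univariate ERP contrast at an occipital region of interest
#'
#' Trial-level (fixed-effects) contrast of the event-related response to
#' valid versus invalid trailing images: amplitudes are averaged over
#' the region-of-interest channels, a two-sample t statistic is computed
#' per time point (valid minus invalid), and clusters over time are
#' corrected by permutation of the condition labels. Also returns the
#' all-channel t map at a requested latency (topography data) and,
#' optionally, an exploratory whole-sensor analysis in which every
#' channel's time series is clustered and compared against the
#' permutation distribution of the maximum cluster mass across all
#' channels.
#'
#' @param ep leading-onset-locked `eeg_epochs` (non-catch trials of both
#'   validities).
#' @param roi_channels channel labels averaged for the ROI test.
#' @param cfg a [pipeline_config()].
#' @param latency_s latency (s, relative to trailing onset) of the
#'   returned per-channel t map.
#' @param time_window analysis window (s, relative to trailing onset).
#' @param whole_sensor also run the exploratory all-channel analysis.
#' @param seed integer seed.
#' @return list with `roi` (`cluster_result`), `t_map` (named per-channel
#'   t values at `latency_s`) and `whole_sensor` (`NULL` or a data frame
#'   of channel clusters with `p_fwe`).
#' @export
erp_contrast <- function(ep, roi_channels = c("Oz", "O1", "O2"),
                         cfg = pipeline_config(), latency_s = 0.15,
                         time_window = c(0, 0.4), whole_sensor = FALSE,
                         seed = 1L) {
  stopifnot(inherits(ep, "eeg_epochs"))
  miss <- setdiff(roi_channels, ep$channel_labels)
  if (length(miss)) stop("missing ROI channel(s): ", paste(miss, collapse = ", "))
  rel_times <- ep$times_s - 0.9   # trailing onset is 0.9 s after leading
  tidx <- window_idx(rel_times, time_window)
  vsel <- ep$metadata$validity == "valid"
  isel <- ep$metadata$validity == "invalid"
  if (sum(vsel) < 2 || sum(isel) < 2)
    stop("both conditions need at least 2 epochs")

  roi_idx <- match(roi_channels, ep$channel_labels)
  roi_amp <- apply(ep$data[tidx, roi_idx, , drop = FALSE], c(1, 3), mean)
  x <- t(roi_amp[, vsel, drop = FALSE])   # trials x time
  y <- t(roi_amp[, isel, drop = FALSE])
  df <- nrow(x) + nrow(y) - 2
  crit <- qt(1 - cfg$forming_alpha / 2, df = df)
  roi <- cluster_correct(two_sample_t_series(x, y),
                         shuffle_two_sample_t(x, y, cfg$n_perm,
                                              child_seed(seed, 1)),
                         crit, rel_times[tidx], cfg$cluster_stat)

  lat_i <- which.min(abs(rel_times - latency_s))
  amp_lat <- ep$data[lat_i, , , drop = TRUE]   # channel x trial
  t_map <- two_sample_t_series(t(amp_lat[, vsel, drop = FALSE]),
                               t(amp_lat[, isel, drop = FALSE]))
  names(t_map) <- ep$channel_labels

  ws <- NULL
  if (whole_sensor) {
    n_ch <- length(ep$channel_labels)
    tser <- matrix(0, n_ch, length(tidx))
    null_max <- rep(0, cfg$n_perm)
    per_ch <- vector("list", n_ch)
    for (ch in seq_len(n_ch)) {
      amp <- ep$data[tidx, ch, , drop = TRUE]   # time x trial
      xv <- t(amp[, vsel, drop = FALSE]); yv <- t(amp[, isel, drop = FALSE])
      tser[ch, ] <- two_sample_t_series(xv, yv)
      perm <- shuffle_two_sample_t(xv, yv, cfg$n_perm, child_seed(seed, 2))
      null_max <- pmax(null_max, apply(perm, 1, function(s) {
        cl <- cluster_masses(s, crit, cfg$cluster_stat)
        if (nrow(cl)) max(cl$mass) else 0
      }))
      per_ch[[ch]] <- cluster_masses(tser[ch, ], crit, cfg$cluster_stat)
      if (nrow(per_ch[[ch]])) per_ch[[ch]]$channel <- ep$channel_labels[ch]
    }
    ws <- do.call(rbind, per_ch[vapply(per_ch, nrow, 1L) > 0])
    if (!is.null(ws) && nrow(ws)) {
      ws$p_fwe <- vapply(ws$mass, function(m)
        (1 + sum(null_max >= m)) / (cfg$n_perm + 1), numeric(1))
      ws$start_s <- rel_times[tidx][ws$start]
      ws$end_s <- rel_times[tidx][ws$end]
    }
  }
  list(roi = roi, t_map = t_map, whole_sensor = ws)
}
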