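# internal helpers

# Seed the RNG for a reproducible operation; NULL leaves the stream alone.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

# Derive a child seed from a base seed and a stream index, kept within
# 32-bit integer range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + 7919 * as.numeric(k)) %% 2147483647
}

# centred moving average with truncated edges
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 0) return(x)
  half <- floor(k / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# indices of a time vector falling inside a closed window
window_idx <- function(times, window) {
  which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
}

# column means/sds ignoring NA, vectorized
col_sds <- function(x) {
  n <- colSums(!is.na(x))
  m <- colMeans(x, na.rm = TRUE)
  sqrt((colSums(x^2, na.rm = TRUE) - n * m^2) / pmax(n - 1, 1))
}

gcd_int <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}
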