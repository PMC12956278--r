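#' Default category labels
#'
#' Five leading and four trailing scene-category labels used by the
#' default design.
#' @name default_labels
#' @return character vectors of category names.
#' @export
default_leading_labels <- function() {
  c("barn", "beach", "library", "restaurant", "cave")
}

#' @rdname default_labels
#' @export
default_trailing_labels <- function() {
  c("church", "conference_room", "castle", "forest")
}

#' Build the transitional-probability matrix of the paired-image design
#'
#' Constructs the design object linking five leading categories to four
#' trailing categories. Four leading categories form the 2:1 condition:
#' each predicts one trailing category with 75% validity (its "valid"
#' pair) and transitions to exactly one other trailing category on the
#' remaining 25% of trials (its "invalid" pair). Two 2:1 trailing
#' categories are used, each serving as the valid outcome of two leading
#' categories. The fifth leading category is the 1:2 control: it leads
#' to the two remaining trailing categories with probability 0.5 each,
#' and its trials are labelled "neutral" downstream.
#'
#' @param leading_labels character vector of exactly 5 distinct names.
#' @param trailing_labels character vector of exactly 4 distinct names.
#' @param assignment_seed integer seed controlling the random assignment
#'   of roles (which leading category is the control, which trailing
#'   pair carries the 2:1 condition, and which valid pair each leading
#'   category receives).
#'
#' @return an object of class `"transition_matrix"`: a list with
#'   `leading_labels`, `trailing_labels`, `pair_role` (5 x 4 character
#'   matrix with entries `"valid"`, `"invalid"` or `"nonexistent"`;
#'   both existing cells of the control row are marked `"valid"` since
#'   neither transition violates an expectation),
#'   `condition_of_leading` (named vector, `"two_to_one"`/`"control"`)
#'   and `p_valid_given_leading` (named numeric, 0.75 or 0.5).
#' @examples
#' tm <- build_transition_matrix(assignment_seed = 1)
#' tm$pair_role
#' @export
build_transition_matrix <- function(leading_labels = default_leading_labels(),
                                    trailing_labels = default_trailing_labels(),
                                    assignment_seed = 1L) {
  if (length(leading_labels) != 5L || anyDuplicated(leading_labels))
    stop("invalid design: need exactly 5 distinct leading labels")
  if (length(trailing_labels) != 4L || anyDuplicated(trailing_labels))
    stop("invalid design: need exactly 4 distinct trailing labels")
  rng <- local_rng(assignment_seed)
  control_leading <- sample(leading_labels, 1L)
  two_to_one <- setdiff(leading_labels, control_leading)
  paired_trailing <- sample(trailing_labels, 2L)   # carry the 2:1 condition
  control_trailing <- setdiff(trailing_labels, paired_trailing)
  # two leading categories converge on each 2:1 trailing category
  valid_of <- setNames(sample(rep(paired_trailing, 2L)), two_to_one)

  pair_role <- matrix("nonexistent", 5L, 4L,
                      dimnames = list(leading_labels, trailing_labels))
  for (ld in two_to_one) {
    pair_role[ld, valid_of[[ld]]] <- "valid"
    pair_role[ld, setdiff(paired_trailing, valid_of[[ld]])] <- "invalid"
  }
  pair_role[control_leading, control_trailing] <- "valid"

  condition <- setNames(ifelse(leading_labels == control_leading,
                               "control", "two_to_one"), leading_labels)
  p_valid <- setNames(ifelse(condition == "control", 0.5, 0.75),
                      leading_labels)
  structure(list(leading_labels = leading_labels,
                 trailing_labels = trailing_labels,
                 pair_role = pair_role,
                 condition_of_leading = condition,
                 p_valid_given_leading = p_valid),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> 5 leading x 4 trailing\n")
  print(x$pair_role)
  invisible(x)
}

#' Session-level design configuration
#'
#' Per-block trial allocation for [generate_session()]. The defaults
#' give 8 blocks of 216 trials: each of the four 2:1 leading categories
#' contributes 33 valid + 11 invalid trials per block (exactly 75%
#' validity) and the control leading category contributes 20 trials per
#' control trailing category (exactly 50/50), for 4 x 44 + 40 = 216.
#'
#' @param n_blocks number of blocks.
#' @param n_valid_per_leading valid trials per 2:1 leading category per
#'   block; must equal `3 * n_invalid_per_leading` for an exact 3:1
#'   valid:invalid ratio.
#' @param n_invalid_per_leading invalid trials per 2:1 leading category
#'   per block.
#' @param n_control_per_trailing control trials per control trailing
#'   category per block.
#' @param catch_fraction fraction of trials flagged as catch trials
#'   (inverted trailing image requiring a response); catch trials are
#'   ordinary trials carrying a flag and are removed before analysis.
#' @param iti_range intertrial interval range in seconds (uniform draw).
#' @return a list of class `"design_config"`.
#' @export
design_config <- function(n_blocks = 8L,
                          n_valid_per_leading = 33L,
                          n_invalid_per_leading = 11L,
                          n_control_per_trailing = 20L,
                          catch_fraction = 0.05,
                          iti_range = c(1.3, 2.2)) {
  if (n_valid_per_leading != 3L * n_invalid_per_leading)
    stop("infeasible allocation: valid:invalid per leading category must be exactly 3:1")
  stopifnot(n_blocks >= 0, n_invalid_per_leading >= 0,
            n_control_per_trailing >= 0,
            catch_fraction >= 0, catch_fraction < 1,
            length(iti_range) == 2, iti_range[1] <= iti_range[2],
            iti_range[1] > 0)
  structure(list(n_blocks = as.integer(n_blocks),
                 n_valid_per_leading = as.integer(n_valid_per_leading),
                 n_invalid_per_leading = as.integer(n_invalid_per_leading),
                 n_control_per_trailing = as.integer(n_control_per_trailing),
                 trials_per_block = 4L * (as.integer(n_valid_per_leading) +
                                          as.integer(n_invalid_per_leading)) +
                                    2L * as.integer(n_control_per_trailing),
                 catch_fraction = catch_fraction,
                 iti_range = iti_range),
            class = "design_config")
}

#' Generate a randomized trial sequence
#'
#' Expands the per-block allocation of a [design_config()] into a full
#' randomized session. Validity ratios are enforced by exact
#' counterbalancing (counts, not Bernoulli draws), so the session-level
#' valid:invalid ratio in the 2:1 condition is exactly 3:1 and the
#' control trailing categories occur exactly 50/50. Trial order is
#' randomized within block. Each trial presents the leading image for
#' 100 ms, an 800 ms interstimulus interval, the trailing image for
#' 100 ms, then a uniform 1.3-2.2 s intertrial interval, so the trailing
#' onset is exactly 0.9 s after the leading onset.
#'
#' @param matrix a [build_transition_matrix()] object.
#' @param config a [design_config()].
#' @param seed integer seed for the within-block shuffles, catch-trial
#'   placement and intertrial intervals.
#' @param t_start_s onset time (s) of the first leading stimulus.
#'
#' @return a `data.frame` of class `"trial_sequence"` with one row per
#'   trial and columns `index` (0-based), `block` (0-based),
#'   `leading_cat`, `trailing_cat`, `validity`
#'   (`valid`/`invalid`/`neutral`), `condition`
#'   (`two_to_one`/`control`), `is_catch`, `leading_onset_s`,
#'   `trailing_onset_s`, `iti_s`.
#' @examples
#' tm <- build_transition_matrix(assignment_seed = 1)
#' seq <- generate_session(tm, design_config(), seed = 1)
#' nrow(seq)  # 1728
#' @export
generate_session <- function(matrix, config = design_config(), seed = 1L,
                             t_start_s = 2) {
  stopifnot(inherits(matrix, "transition_matrix"),
            inherits(config, "design_config"))
  rng <- local_rng(seed)
  if (config$n_blocks == 0L) return(empty_sequence())

  two_to_one <- names(which(matrix$condition_of_leading == "two_to_one"))
  control_leading <- names(which(matrix$condition_of_leading == "control"))
  control_trailing <- colnames(matrix$pair_role)[
    matrix$pair_role[control_leading, ] != "nonexistent"]

  block_rows <- list()
  for (ld in two_to_one) {
    v_tr <- colnames(matrix$pair_role)[matrix$pair_role[ld, ] == "valid"]
    i_tr <- colnames(matrix$pair_role)[matrix$pair_role[ld, ] == "invalid"]
    block_rows[[length(block_rows) + 1L]] <- data.frame(
      leading_cat = ld,
      trailing_cat = c(rep(v_tr, config$n_valid_per_leading),
                       rep(i_tr, config$n_invalid_per_leading)),
      validity = c(rep("valid", config$n_valid_per_leading),
                   rep("invalid", config$n_invalid_per_leading)),
      condition = "two_to_one", stringsAsFactors = FALSE)
  }
  block_rows[[length(block_rows) + 1L]] <- data.frame(
    leading_cat = control_leading,
    trailing_cat = rep(control_trailing, each = config$n_control_per_trailing),
    validity = "neutral", condition = "control", stringsAsFactors = FALSE)
  block_proto <- do.call(rbind, block_rows)
  stopifnot(nrow(block_proto) == config$trials_per_block)

  blocks <- lapply(seq_len(config$n_blocks) - 1L, function(b) {
    bl <- block_proto[sample.int(nrow(block_proto)), , drop = FALSE]
    bl$block <- b
    bl
  })
  trials <- do.call(rbind, blocks)
  rownames(trials) <- NULL
  n <- nrow(trials)
  trials$index <- seq_len(n) - 1L

  n_catch <- round(config$catch_fraction * n)
  trials$is_catch <- FALSE
  if (n_catch > 0)
    trials$is_catch[sample.int(n, n_catch)] <- TRUE

  trials$iti_s <- runif(n, config$iti_range[1], config$iti_range[2])
  # leading -> 100 ms image + 800 ms ISI -> trailing -> 100 ms image -> ITI
  step <- 0.9 + 0.1 + trials$iti_s
  trials$leading_onset_s <- t_start_s + c(0, cumsum(step[-n]))
  trials$trailing_onset_s <- trials$leading_onset_s + 0.9

  trials <- trials[, c("index", "block", "leading_cat", "trailing_cat",
                       "validity", "condition", "is_catch",
                       "leading_onset_s", "trailing_onset_s", "iti_s")]
  class(trials) <- c("trial_sequence", "data.frame")
  trials
}

empty_sequence <- function() {
  out <- data.frame(index = integer(0), block = integer(0),
                    leading_cat = character(0), trailing_cat = character(0),
                    validity = character(0), condition = character(0),
                    is_catch = logical(0), leading_onset_s = numeric(0),
                    trailing_onset_s = numeric(0), iti_s = numeric(0))
  class(out) <- c("trial_sequence", "data.frame")
  out
}

#' Summarize a trial sequence
#'
#' Exact counts and proportions obtained by enumeration over the trial
#' records; invariant to trial order and idempotent.
#'
#' @param seq a [generate_session()] trial sequence.
#' @return a list of class `"design_summary"` with `n_trials`,
#'   `n_blocks`, `trials_per_block`, `cell_counts` (counts per leading x
#'   trailing x validity cell), `proportion_valid_in_2to1`,
#'   `proportion_per_trailing_in_control` and `catch_fraction`.
#' @export
summarize_design <- function(seq) {
  stopifnot(inherits(seq, "data.frame"))
  if (nrow(seq) == 0L) stop("empty trial sequence")
  tt <- seq[seq$condition == "two_to_one", ]
  ctrl <- seq[seq$condition == "control", ]
  prop_valid <- if (nrow(tt)) sum(tt$validity == "valid") / nrow(tt) else NA_real_
  prop_ctrl <- if (nrow(ctrl)) {
    tab <- table(ctrl$trailing_cat)
    as.numeric(tab) / nrow(ctrl)
  } else numeric(0)
  cells <- as.data.frame(table(leading = seq$leading_cat,
                               trailing = seq$trailing_cat,
                               validity = seq$validity),
                         stringsAsFactors = FALSE)
  cells <- cells[cells$Freq > 0, ]
  names(cells)[names(cells) == "Freq"] <- "count"
  rownames(cells) <- NULL
  structure(list(
    n_trials = nrow(seq),
    n_blocks = length(unique(seq$block)),
    trials_per_block = as.integer(nrow(seq) / max(1L, length(unique(seq$block)))),
    cell_counts = cells,
    proportion_valid_in_2to1 = prop_valid,
    proportion_per_trailing_in_control = prop_ctrl,
    catch_fraction = mean(seq$is_catch)
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("<design_summary> %d trials in %d block(s) of %d\n",
              x$n_trials, x$n_blocks, x$trials_per_block))
  cat(sprintf("  valid fraction in 2:1 condition: %.4f\n",
              x$proportion_valid_in_2to1))
  cat(sprintf("  control trailing split: %s\n",
              paste(format(x$proportion_per_trailing_in_control, digits = 3),
                    collapse = " / ")))
  cat(sprintf("  catch fraction: %.4f\n", x$catch_fraction))
  invisible(x)
}

#' Read or write a trial sequence as a tab-separated events table
#'
#' One row per trial with the fixed columns `index`, `block`,
#' `onset_s` (leading onset), `leading`, `trailing`, `validity`,
#' `condition`, `is_catch`.
#'
#' @param seq a trial sequence.
#' @param path file path.
#' @return `write_events_tsv` returns `path` invisibly;
#'   `read_events_tsv` returns a `trial_sequence` data frame (trailing
#'   onsets are reconstructed as `onset_s + 0.9`).
#' @export
write_events_tsv <- function(seq, path) {
  out <- data.frame(index = seq$index, block = seq$block,
                    onset_s = seq$leading_onset_s,
                    leading = seq$leading_cat, trailing = seq$trailing_cat,
                    validity = seq$validity, condition = seq$condition,
                    is_catch = seq$is_catch)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(index = tab$index, block = tab$block,
                    leading_cat = tab$leading, trailing_cat = tab$trailing,
                    validity = tab$validity, condition = tab$condition,
                    is_catch = as.logical(tab$is_catch),
                    leading_onset_s = tab$onset_s,
                    trailing_onset_s = tab$onset_s + 0.9,
                    iti_s = NA_real_)
  n <- nrow(out)
  if (n > 1)
    out$iti_s[-n] <- diff(out$leading_onset_s) - 1.0
  class(out) <- c("trial_sequence", "data.frame")
  out
}
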