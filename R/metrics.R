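# Behavioral exploration / performance indices.
#
# All indices are proportions over "qualifying" trials:
#   performance — trials where the block's target lever was pressed;
#   win-shift   — of trials immediately following a rewarded press of the
#                 target lever, the fraction where the choice changed;
#   lose-shift  — of trials immediately following any unrewarded trial, the
#                 fraction where the choice changed.
# Shifts are only counted within a block: the first trial of a block has no
# predecessor. A group with no qualifying trials yields NA (e.g. a subject
# with no win in a window is excluded rather than scored 0).

# per-trial qualifying indicator and shift/hit value for one ordered
# within-sequence data frame
index_trial_values <- function(h, index) {
  prev_action <- c(NA, h$action[-nrow(h)])
  prev_reward <- c(NA, h$reward[-nrow(h)])
  prev_target <- c(NA, h$target[-nrow(h)])
  same_block <- c(FALSE, h$block[-1] == h$block[-nrow(h)])
  switch(index,
    performance = list(qual = rep(TRUE, nrow(h)),
                       val = as.numeric(h$action == h$target)),
    win_shift = list(
      qual = same_block & prev_reward == 1 & prev_action == prev_target,
      val = as.numeric(h$action != prev_action)),
    lose_shift = list(
      qual = same_block & prev_reward == 0,
      val = as.numeric(h$action != prev_action)),
    stop("unknown index '", index, "'", call. = FALSE))
}

#' Behavioral indices of a trial log
#'
#' Computes performance, win-shift and lose-shift as proportions over
#' qualifying trials, grouped by the given columns (plus, optionally, six
#' within-block bins of four trials).
#'
#' @param trials trial data frame (columns `subject`, `condition`, `block`,
#'   `trial_in_block`, `action`, `reward`, `target`, `risk`; an optional
#'   `rep` column from simulations is honoured in the sequence split).
#' @param indices which indices to compute.
#' @param by grouping columns for the output table.
#' @param bins if `TRUE`, adds a `bin` column (1..6, four trials each);
#'   requires 24-trial blocks.
#' @param trial_range optional restriction to a window of `trial_in_block`
#'   positions (e.g. `19:24` for the last-six-trials asymptote); qualifying
#'   predecessors are still found in the full sequence.
#' @return tidy data frame with columns `by`..., (`bin`,) `index`, `value`
#'   (proportion in \[0, 1\], NA when no trial qualifies), `n` (qualifying
#'   trials).
#' @examples
#' cfg <- task_config(n_sessions = 1)
#' h <- run_agent("fql", c(alpha = .4, alpha2 = .5, beta = 6),
#'                build_schedule(cfg, 1), cfg, seed = 2)
#' behavior_indices(h, by = c("subject", "risk"))
#' @export
behavior_indices <- function(trials,
                             indices = c("performance", "win_shift", "lose_shift"),
                             by = c("subject", "condition", "risk"),
                             bins = FALSE, trial_range = NULL) {
  indices <- match.arg(indices, several.ok = TRUE)
  need <- c("subject", "condition", "block", "trial_in_block",
            "action", "reward", "target")
  miss <- setdiff(c(need, setdiff(by, "bin")), names(trials))
  if (length(miss))
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (bins && max(trials$trial_in_block) != 24L)
    stop("within-block binning expects 24-trial blocks", call. = FALSE)

  seq_cols <- intersect(c("subject", "condition", "rep"), names(trials))
  seq_key <- do.call(paste, c(trials[seq_cols], sep = "|"))
  ord <- order(factor(seq_key, levels = unique(seq_key)), trials$block,
               trials$trial_in_block)
  trials <- trials[ord, ]
  seq_key <- seq_key[ord]

  out <- list()
  for (index in indices) {
    parts <- lapply(split(seq_len(nrow(trials)), factor(seq_key, unique(seq_key))),
                    function(i) index_trial_values(trials[i, ], index))
    qual <- unlist(lapply(parts, `[[`, "qual"), use.names = FALSE)
    val <- unlist(lapply(parts, `[[`, "val"), use.names = FALSE)
    keep <- qual & !is.na(qual)
    if (!is.null(trial_range)) keep <- keep & trials$trial_in_block %in% trial_range
    d <- trials[keep, , drop = FALSE]
    d$value <- val[keep]
    if (bins) d$bin <- ceiling(d$trial_in_block / 4)
    grp_cols <- c(by, if (bins) "bin")
    # groups present in the data but with no qualifying trial -> NA row
    all_grp <- if (bins)
      merge(unique(trials[, setdiff(grp_cols, "bin"), drop = FALSE]),
            data.frame(bin = 1:6))
    else unique(trials[, grp_cols, drop = FALSE])
    if (nrow(d) == 0L) {
      agg <- all_grp
      agg$value <- NA_real_
      agg$n <- 0L
    } else {
      agg <- aggregate(d$value, by = d[grp_cols], FUN = mean)
      names(agg)[ncol(agg)] <- "value"
      agg$n <- aggregate(d$value, by = d[grp_cols], FUN = length)$x
      agg <- merge(all_grp, agg, all.x = TRUE)
      agg$n[is.na(agg$n)] <- 0L
    }
    agg$index <- index
    out[[index]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[do.call(order, res[c(by, if (bins) "bin", "index")]), ,
      drop = FALSE][, c(by, if (bins) "bin", "index", "value", "n")]
}

#' @rdname behavior_indices
#' @export
performance <- function(trials, by = c("subject", "condition", "risk"),
                        bins = FALSE, trial_range = NULL) {
  behavior_indices(trials, "performance", by, bins, trial_range)
}

#' @rdname behavior_indices
#' @export
win_shift <- function(trials, by = c("subject", "condition", "risk"),
                      bins = FALSE, trial_range = NULL) {
  behavior_indices(trials, "win_shift", by, bins, trial_range)
}

#' @rdname behavior_indices
#' @export
lose_shift <- function(trials, by = c("subject", "condition", "risk"),
                       bins = FALSE, trial_range = NULL) {
  behavior_indices(trials, "lose_shift", by, bins, trial_range)
}

#' Within-block index curves (six bins of four trials)
#'
#' The standard within-block learning curves: each 24-trial block is grouped
#' into six bins of four trials and every index is averaged per bin within
#' the given groups.
#'
#' @inheritParams behavior_indices
#' @return tidy data frame as in [behavior_indices()] with a `bin` column.
#' @export
block_curves <- function(trials,
                         indices = c("performance", "win_shift", "lose_shift"),
                         by = c("subject", "condition", "risk")) {
  behavior_indices(trials, indices, by, bins = TRUE)
}

#' Asymptotic (end-of-block) index summaries
#'
#' Indices restricted to the last `last` trials of each block, where
#' performance has typically stabilized — the usual windows are the last six
#' trials (performance and win-shift asymptotes) and the last eight trials
#' (win-shift once the target has been identified).
#'
#' @inheritParams behavior_indices
#' @param last number of end-of-block trials in the window.
#' @return tidy data frame with a `window` label column.
#' @export
asymptote_indices <- function(trials,
                              indices = c("performance", "win_shift", "lose_shift"),
                              by = c("subject", "condition", "risk"),
                              last = 6) {
  block_length <- max(trials$trial_in_block)
  res <- behavior_indices(trials, indices, by,
                          trial_range = (block_length - last + 1):block_length)
  res$window <- sprintf("last_%d", last)
  res
}

#' Friedman rank test across conditions
#'
#' Non-parametric repeated-measures test of a condition effect on a
#' complete subjects x conditions design (each subject measured once per
#' condition), as used when parameter distributions violate normality.
#' Delegates to [stats::friedman.test()].
#'
#' @param values numeric matrix, rows = subjects, columns = conditions; no
#'   missing cells.
#' @return list with `statistic` (chi-squared), `df`, and `p_value`.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 5), b = c(2, 3, 4, 4), c = c(5, 6, 7, 8))
#' friedman_test(m)
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  if (any(is.na(values)))
    stop("friedman_test() requires a complete design (no missing cells)",
         call. = FALSE)
  if (ncol(values) < 2L || nrow(values) < 2L)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  ft <- friedman.test(values)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {
    # every row completely tied (e.g. identical columns): no evidence of a
    # condition effect; the tie-corrected statistic is 0/0
    stat <- 0
    p <- 1
  }
  list(statistic = stat, df = unname(ft$parameter), p_value = p)
}
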