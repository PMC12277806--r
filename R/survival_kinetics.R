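# Longitudinal fluorescent-count analysis: net death, trajectory AUC,
# exponential-decay fits and multi-condition comparisons.

check_series <- function(time_h, count) {
  if (length(time_h) != length(count)) {
    stop("times and counts must have equal length", call. = FALSE)
  }
  if (length(time_h) < 2) {
    stop("insufficient data: a survival series needs at least 2 time points",
         call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(count < 0)) stop("counts must be nonnegative", call. = FALSE)
  invisible(TRUE)
}

#' Net death over a survival series
#'
#' First count minus last count. Negative values (net growth) are permitted;
#' callers can detect them by sign.
#'
#' @param time_h Strictly increasing times in hours.
#' @param count Nonnegative object counts at each time.
#' @return Signed count: `count[first] - count[last]`.
#' @export
net_death <- function(time_h, count) {
  check_series(time_h, count)
  count[1] - count[length(count)]
}

#' Trapezoidal area under a count trajectory
#'
#' @inheritParams net_death
#' @return Area in count-hours.
#' @export
trajectory_auc <- function(time_h, count) {
  check_series(time_h, count)
  sum(diff(time_h) * (utils::head(count, -1) + utils::tail(count, -1)) / 2)
}

#' Fit a constant-hazard exponential decay to a series
#'
#' Log-linear least squares on `log(count) ~ time_h` over the strictly
#' positive counts. For a noiseless exponential series this recovers the
#' hazard to numerical precision.
#'
#' @inheritParams net_death
#' @return List with `n0` (fitted initial count) and `rate` (per-hour
#'   death hazard, positive for decline).
#' @export
fit_decay <- function(time_h, count) {
  check_series(time_h, count)
  keep <- count > 0
  if (sum(keep) < 2) stop("insufficient positive counts for a decay fit", call. = FALSE)
  fit <- stats::lm(log(count[keep]) ~ time_h[keep])
  list(n0 = exp(unname(stats::coef(fit)[1])), rate = -unname(stats::coef(fit)[2]))
}

#' Load a survival table from CSV
#'
#' Expects columns condition, treatment, replicate, time_h, count.
#' @param path CSV path.
#' @export
load_survival_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "treatment", "replicate", "time_h", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("survival table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Rolling-median smoothing of a count series
#'
#' Optional guard against single-frame imaging dropouts: each count is
#' replaced by the median of its `window`-wide neighbourhood (edges keep a
#' truncated window). Off by default everywhere.
#'
#' @param count Numeric count series.
#' @param window Odd window width (default 3).
#' @return Smoothed series, same length.
#' @export
rolling_median <- function(count, window = 3) {
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd number", call. = FALSE)
  h <- (window - 1) / 2
  n <- length(count)
  vapply(seq_len(n), function(i) {
    stats::median(count[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Per-replicate death summary of a survival table
#'
#' @param df Long survival table: condition, treatment, replicate, time_h,
#'   count (one series per condition x treatment x replicate).
#' @param smooth Apply [rolling_median()] (window 3) to each series before
#'   summarising; off by default.
#' @return data.frame with one row per series: condition, treatment,
#'   replicate, net_death, auc, growth flag (net increase).
#' @export
summarize_death <- function(df, smooth = FALSE) {
  keys <- unique(df[, c("condition", "treatment", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- df[df$condition == keys$condition[i] & df$treatment == keys$treatment[i] &
              df$replicate == keys$replicate[i], ]
    s <- s[order(s$time_h), ]
    if (smooth) s$count <- rolling_median(s$count, window = 3)
    nd <- net_death(s$time_h, s$count)
    data.frame(condition = keys$condition[i], treatment = keys$treatment[i],
               replicate = keys$replicate[i], net_death = nd,
               auc = trajectory_auc(s$time_h, s$count),
               growth = nd < 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` over `m` planned pairwise comparisons. Always at
#' least the raw p; equal iff `m = 1`.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param m Number of planned comparisons (default: `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, 1 - (1 - p)^m)
}

# Two-sample test with the degenerate-case convention: zero variance in
# both groups with equal means gives t = 0, p = 1 (with a warning).
two_sample_test <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    stop("insufficient replicates: each group needs >= 2 values", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("zero variance in both groups with equal means; p = 1 by convention")
      return(list(t = 0, p = 1, df = NA_real_))
    }
    # distinct constants: infinitely separated under the model
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = NA_real_))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Pairwise comparisons of net death across groups
#'
#' Groups are condition x treatment cells of a [summarize_death()] table.
#' Each pair is compared with a two-sided two-sample test on replicate-level
#' net death (Welch by default; classic pooled-variance mode available) and
#' the selected multiplicity adjustment over all planned pairs.
#'
#' @param death A [summarize_death()] data.frame.
#' @param adjustment `"sidak"` (default, the planned-comparison convention),
#'   `"bh"` or `"none"`.
#' @param variant `"welch"` (default) or `"student"`.
#' @param alpha Flagging level on the adjusted p (default 0.05).
#' @return data.frame with one row per pair: group_a, group_b, mean_a,
#'   mean_b, t, p, p_adj, significant.
#' @export
compare_death <- function(death, adjustment = c("sidak", "bh", "none"),
                          variant = c("welch", "student"), alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  variant <- match.arg(variant)
  death$group <- paste(death$condition, death$treatment, sep = "/")
  groups <- unique(death$group)
  if (length(groups) < 2) stop("need >= 2 groups to compare", call. = FALSE)
  ns <- table(death$group)
  if (any(ns < 2)) {
    stop("insufficient replicates (< 2) in group(s): ",
         paste(names(ns)[ns < 2], collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    x <- death$net_death[death$group == ga]
    y <- death$net_death[death$group == gb]
    tt <- two_sample_test(x, y, variant)
    data.frame(group_a = ga, group_b = gb, mean_a = mean(x), mean_b = mean(y),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- switch(adjustment,
                      sidak = sidak_adjust(out$p, m = nrow(out)),
                      bh = bh_adjust(out$p),
                      none = out$p)
  out$significant <- out$p_adj < alpha
  out
}
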