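# Differential-abundance statistics for secretome / cytokine tables.

#' log2 fold change between two groups
#'
#' `log2(mean(a) / mean(b))` on raw abundances by default: positive values
#' mean higher abundance in group A. `mode = "log_mean"` instead takes the
#' difference of mean log2 abundances (geometric-mean ratio).
#'
#' @param a,b Nonempty numeric vectors of strictly positive abundances.
#' @param mode `"mean"` (arithmetic group means, default) or `"log_mean"`.
#' @return log2 ratio (positive = higher in A).
#' @export
log2fc <- function(a, b, mode = c("mean", "log_mean")) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty", call. = FALSE)
  if (any(a <= 0) || any(b <= 0)) {
    stop("abundances must be > 0 for log2 fold change", call. = FALSE)
  }
  if (mode == "mean") log2(mean(a) / mean(b)) else mean(log2(a)) - mean(log2(b))
}

#' Unpaired two-sample t-test
#'
#' Two-sided. The `student` variant pools variances; `welch` does not.
#' Zero variance in both groups with equal means returns `p = 1` by
#' convention (with a warning) instead of erroring.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant `"student"` (default, the plain unpaired t-test) or
#'   `"welch"` (recommended under unequal variances).
#' @return List with `t` and two-sided `p`.
#' @export
unpaired_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  tt <- two_sample_test(a, b, variant = variant)
  list(t = tt$t, p = tt$p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up procedure: sort p ascending, `q_(i) = min_{j >= i} p_(j) * m / j`
#' capped at 1, mapped back to the input order. Matches the definition-level
#' brute force exactly; q-values are monotone nondecreasing along sorted p.
#'
#' @param p Numeric p-values in `[0, 1]` (NA passed through).
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  ord <- ok[order(p[ok])]
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q[ord] <- pmin(1, q_sorted)
  q
}

#' Differential-abundance (volcano) table
#'
#' Per row of a wide abundance table: log2 fold change of group A over
#' group B, unpaired t-test p-value, Benjamini-Hochberg q-value computed
#' jointly across all tested rows, and a significance flag
#' `q <= q_cutoff` (inclusive) optionally combined with an absolute
#' log2FC bound. Rows with fewer than 2 complete observations in either
#' group are dropped (their count is recorded in the `n_dropped`
#' attribute).
#'
#' @param abundance data.frame or matrix: one row per protein/analyte, one
#'   column per sample; strictly positive values.
#' @param groups Character/factor of length `ncol(abundance)` with exactly
#'   two levels; the first level (or `ref`) is group A.
#' @param ids Row identifiers (default rownames).
#' @param q_cutoff Significance cutoff on q (inclusive; default 0.05).
#' @param fc_cutoff Optional minimum `|log2FC|`.
#' @param variant t-test variant, see [unpaired_t()].
#' @param fc_mode log2FC mode, see [log2fc()].
#' @return data.frame: id, log2fc, t, p, q, significant; sorted by q then
#'   decreasing `|log2fc|`.
#' @export
volcano_table <- function(abundance, groups, ids = rownames(abundance),
                          q_cutoff = 0.05, fc_cutoff = NULL,
                          variant = c("student", "welch"),
                          fc_mode = c("mean", "log_mean")) {
  variant <- match.arg(variant)
  fc_mode <- match.arg(fc_mode)
  abundance <- as.matrix(abundance)
  if (length(groups) != ncol(abundance)) {
    stop("groups must have one entry per sample column", call. = FALSE)
  }
  lev <- unique(as.character(groups))
  if (length(lev) != 2) stop("exactly two groups are required", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(abundance)))
  if (nrow(abundance) == 0) {
    out <- data.frame(id = character(0), log2fc = numeric(0), t = numeric(0),
                      p = numeric(0), q = numeric(0), significant = logical(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  a_idx <- which(as.character(groups) == lev[1])
  b_idx <- which(as.character(groups) == lev[2])
  rows <- vector("list", nrow(abundance))
  dropped <- 0L
  for (i in seq_len(nrow(abundance))) {
    a <- abundance[i, a_idx]; a <- a[!is.na(a)]
    b <- abundance[i, b_idx]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) { dropped <- dropped + 1L; next }
    tt <- suppressWarnings(unpaired_t(a, b, variant))
    rows[[i]] <- data.frame(id = ids[i], log2fc = log2fc(a, b, fc_mode),
                            t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), log2fc = numeric(0), t = numeric(0),
                      p = numeric(0), q = numeric(0), significant = logical(0))
    attr(out, "n_dropped") <- dropped
    return(out)
  }
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= q_cutoff
  if (!is.null(fc_cutoff)) {
    out$significant <- out$significant & abs(out$log2fc) >= fc_cutoff
  }
  out <- out[order(out$q, -abs(out$log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  attr(out, "group_a") <- lev[1]
  attr(out, "group_b") <- lev[2]
  out
}
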