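# Cell-type proportion quantification over time from classified-object
# tables.

COMPOSITION_MARKERS <- c("MN", "astrocyte", "microglia")

#' Per-sample marker fractions of a composition table
#'
#' Fractions over the classified cells (MN + astrocyte + microglia) by
#' default; `include_unclassified = TRUE` adds an `unclassified` column to
#' the denominator when present. Fractions sum to 1 per sample.
#'
#' @param ct data.frame with columns sample, genotype, timepoint and one
#'   count column per marker class (`MN`, `astrocyte`, `microglia`, and
#'   optionally `unclassified`).
#' @param include_unclassified Include unclassified objects in the
#'   denominator.
#' @return data.frame with the same key columns and marker columns holding
#'   fractions; the `total` column holds the denominator used.
#' @export
proportions <- function(ct, include_unclassified = FALSE) {
  markers <- intersect(COMPOSITION_MARKERS, names(ct))
  if (include_unclassified && "unclassified" %in% names(ct)) {
    markers <- c(markers, "unclassified")
  }
  if (length(markers) == 0) stop("no marker count columns found", call. = FALSE)
  counts <- as.matrix(ct[, markers, drop = FALSE])
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  total <- rowSums(counts)
  zero <- which(total == 0)
  if (length(zero) > 0) {
    stop("zero classified cells in sample(s): ",
         paste(ct$sample[zero], collapse = ", "), call. = FALSE)
  }
  out <- ct
  out[, markers] <- counts / total
  out$total <- total
  out
}

#' Compare marker proportions between two groups per marker and timepoint
#'
#' For every marker x timepoint, a two-sided two-sample test on per-sample
#' fractions between the two levels of `factor` (genotype by default), with
#' a multiplicity adjustment over all pairs tested. Markers absent (all-zero)
#' everywhere are skipped with a warning.
#'
#' @param ct Composition count table (see [proportions()]).
#' @param factor Grouping column name, `"genotype"` or `"treatment"`.
#' @param adjustment `"sidak"` (default), `"bh"` or `"none"`.
#' @param variant `"welch"` (default) or `"student"`.
#' @param include_unclassified Passed to [proportions()].
#' @param alpha Flagging level on the adjusted p.
#' @return data.frame: marker, timepoint, group_a, group_b, mean_a, mean_b,
#'   t, p, p_adj, significant.
#' @export
compare_proportions <- function(ct, factor = "genotype",
                                adjustment = c("sidak", "bh", "none"),
                                variant = c("welch", "student"),
                                include_unclassified = FALSE, alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  variant <- match.arg(variant)
  if (!factor %in% names(ct)) stop("grouping column '", factor, "' not found", call. = FALSE)
  lev <- unique(as.character(ct[[factor]]))
  if (length(lev) != 2) stop("exactly two groups are required in '", factor, "'", call. = FALSE)
  fr <- proportions(ct, include_unclassified = include_unclassified)
  markers <- intersect(COMPOSITION_MARKERS, names(ct))
  if (include_unclassified && "unclassified" %in% names(ct)) {
    markers <- c(markers, "unclassified")
  }
  absent <- markers[vapply(markers, function(m) all(ct[[m]] == 0), logical(1))]
  if (length(absent) > 0) {
    warning("marker(s) absent everywhere, skipped: ", paste(absent, collapse = ", "))
    markers <- setdiff(markers, absent)
  }
  rows <- list()
  for (day in sort(unique(fr$timepoint))) {
    sub <- fr[fr$timepoint == day, ]
    x_idx <- as.character(sub[[factor]]) == lev[1]
    if (sum(x_idx) < 2 || sum(!x_idx) < 2) {
      stop("insufficient replicates at timepoint ", day, " for groups: ",
           paste(lev, collapse = ", "), call. = FALSE)
    }
    for (m in markers) {
      tt <- suppressWarnings(two_sample_test(sub[[m]][x_idx], sub[[m]][!x_idx], variant))
      rows[[length(rows) + 1]] <- data.frame(
        marker = m, timepoint = day, group_a = lev[1], group_b = lev[2],
        mean_a = mean(sub[[m]][x_idx]), mean_b = mean(sub[[m]][!x_idx]),
        t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- switch(adjustment,
                      sidak = sidak_adjust(out$p, m = nrow(out)),
                      bh = bh_adjust(out$p),
                      none = out$p)
  out$significant <- out$p_adj < alpha
  out
}
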