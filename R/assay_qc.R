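# Assay-robustness statistics: control summaries and Z'-factor.

#' Summarise control wells per platform, analyte and role
#'
#' Sample SD uses the n-1 denominator. Log-scale summaries (natural log) are
#' reported only when all values in the group are strictly positive;
#' single-well groups report `NA` SD with a warning entry.
#'
#' @param ds A [screen_dataset()].
#' @param roles Roles to summarise (default: the three control roles).
#' @return data.frame with columns platform, analyte, role, n, mean, sd,
#'   log_mean, log_sd, plus a `warnings` attribute (character vector).
#' @export
control_summary <- function(ds, roles = c("vehicle", "positive", "negative")) {
  stopifnot(inherits(ds, "screen_dataset"))
  warns <- character(0)
  rows <- list()
  for (pf in unique(ds$wells$platform)) {
    for (role in roles) {
      w <- wells_of(ds, role, pf)
      if (nrow(w) == 0) {
        warns <- c(warns, sprintf("role '%s' absent on platform %s", role, pf))
        next
      }
      for (a in ds$analyte_panel) {
        v <- w[[a]]
        v <- v[!is.na(v)]
        if (length(v) == 0) next
        sdv <- if (length(v) >= 2) stats::sd(v) else NA_real_
        if (length(v) == 1) {
          warns <- c(warns, sprintf("single-well group: %s/%s/%s, SD undefined",
                                    pf, a, role))
        }
        if (all(v > 0)) {
          lm <- mean(log(v))
          ls <- if (length(v) >= 2) stats::sd(log(v)) else NA_real_
        } else {
          lm <- NA_real_; ls <- NA_real_
          warns <- c(warns, sprintf("zero value in %s/%s/%s: log-scale summary omitted",
                                    pf, a, role))
        }
        rows[[length(rows) + 1]] <- data.frame(
          platform = pf, analyte = a, role = role, n = length(v),
          mean = mean(v), sd = sdv, log_mean = lm, log_sd = ls,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(platform = character(0), analyte = character(0), role = character(0),
               n = integer(0), mean = numeric(0), sd = numeric(0),
               log_mean = numeric(0), log_sd = numeric(0))
  attr(out, "warnings") <- warns
  out
}

#' Z'-factor between two control groups
#'
#' The screening-window statistic
#' \deqn{Z' = 1 - \frac{3(\mathrm{SD}_p + \mathrm{SD}_v)}{|\bar x_p - \bar x_v|}}
#' quantifying separation between positive and vehicle controls. `Z' <= 1`
#' always; `Z' >= 0.5` is conventionally excellent, `0 <= Z' < 0.5`
#' acceptable, `Z' < 0` a failed window. The statistic is symmetric in its
#' two arguments and strictly decreasing in either SD.
#'
#' @param positive,vehicle Numeric vectors of at least 2 values each.
#' @return Z' score (scalar, at most 1).
#' @export
zprime <- function(positive, vehicle) {
  if (length(positive) < 2 || length(vehicle) < 2) {
    stop("zprime requires >= 2 values in each group (insufficient replicates)",
         call. = FALSE)
  }
  mp <- mean(positive); mv <- mean(vehicle)
  if (mp == mv) stop("zprime undefined: group means are equal", call. = FALSE)
  1 - 3 * (stats::sd(positive) + stats::sd(vehicle)) / abs(mp - mv)
}

zprime_verdict <- function(z) {
  ifelse(z >= 0.5, "excellent", ifelse(z >= 0, "acceptable", "failed"))
}

#' Z'-factor QC report for a screen dataset
#'
#' Computes Z' between positive and vehicle controls per (platform, analyte),
#' on log-transformed signals (default, matching how assay separation is
#' visually assessed on log scale) and on the raw scale.
#'
#' @param ds A [screen_dataset()].
#' @return data.frame: platform, analyte, zprime_log, zprime_raw, verdict
#'   (banded on the log-scale Z').
#' @export
qc_report <- function(ds) {
  stopifnot(inherits(ds, "screen_dataset"))
  rows <- list()
  for (pf in unique(ds$wells$platform)) {
    pos <- wells_of(ds, "positive", pf)
    veh <- wells_of(ds, "vehicle", pf)
    if (nrow(pos) < 2 || nrow(veh) < 2) next
    for (a in ds$analyte_panel) {
      p <- pos[[a]]; v <- veh[[a]]
      zl <- if (all(p > 0) && all(v > 0)) zprime(log(p), log(v)) else NA_real_
      zr <- zprime(p, v)
      rows[[length(rows) + 1]] <- data.frame(
        platform = pf, analyte = a, zprime_log = zl, zprime_raw = zr,
        verdict = zprime_verdict(if (is.na(zl)) zr else zl),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
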