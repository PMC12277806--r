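# Core screen analytics: percent-decrease normalization, viability
# exclusion, control-anchored thresholds, hit classification, ranking and
# cross-platform intersection.

#' Percent decrease against the vehicle control
#'
#' The screen's normalization statistic:
#' `100 * (1 - value / vehicle_mean)`. Negative values mean the compound
#' elevated the analyte; the statistic is bounded above by 100 (a
#' concentration cannot go below zero).
#'
#' @param value Compound-well concentration(s), pg/mL, `>= 0`.
#' @param vehicle_mean Vehicle-control mean concentration, pg/mL, `> 0`.
#' @return Percent decrease (vectorised over `value`).
#' @export
percent_decrease <- function(value, vehicle_mean) {
  if (any(vehicle_mean <= 0)) stop("vehicle_mean must be > 0", call. = FALSE)
  if (any(value < 0, na.rm = TRUE)) stop("value must be >= 0", call. = FALSE)
  100 * (1 - value / vehicle_mean)
}

#' Diameter-based viability filter
#'
#' A compound is excluded on a platform when its microtissue diameter is
#' below `(1 - tolerance)` times the mean reference diameter. The reference
#' is the vehicle wells, the untreated wells, or the pooled mean of both.
#' Compounds with a missing diameter are flagged `unknown` and retained,
#' with a warning recorded.
#'
#' @param ds A [screen_dataset()].
#' @param tolerance Fractional shrink tolerated before exclusion
#'   (default 0.2; always restate this in reports).
#' @param reference `"vehicle"`, `"untreated"` or `"both"`.
#' @return A `viability_result`: data.frame (compound_id, platform,
#'   diameter_um, ref_mean, status in pass/excluded/unknown) with the
#'   settings and any warnings as attributes.
#' @export
viability_filter <- function(ds, tolerance = 0.2,
                             reference = c("vehicle", "untreated", "both")) {
  stopifnot(inherits(ds, "screen_dataset"))
  reference <- match.arg(reference)
  ref_roles <- switch(reference, vehicle = "vehicle", untreated = "untreated",
                      both = c("vehicle", "untreated"))
  warns <- character(0)
  rows <- list()
  for (pf in unique(ds$wells$platform)) {
    refw <- ds$wells[ds$wells$role %in% ref_roles & ds$wells$platform == pf, ]
    ref_d <- refw$diameter_um[!is.na(refw$diameter_um)]
    if (length(ref_d) == 0) {
      stop("no reference diameters (roles: ", paste(ref_roles, collapse = "/"),
           ") on platform ", pf, call. = FALSE)
    }
    ref_mean <- mean(ref_d)
    cw <- wells_of(ds, "compound", pf)
    status <- ifelse(is.na(cw$diameter_um), "unknown",
              ifelse(cw$diameter_um < (1 - tolerance) * ref_mean,
                     "excluded", "pass"))
    if (any(status == "unknown")) {
      warns <- c(warns, sprintf("%d compound wells with missing diameter on %s retained as 'unknown'",
                                sum(status == "unknown"), pf))
    }
    rows[[length(rows) + 1]] <- data.frame(
      compound_id = cw$compound_id, platform = pf,
      diameter_um = cw$diameter_um, ref_mean = ref_mean, status = status,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "tolerance") <- tolerance
  attr(out, "reference") <- reference
  attr(out, "warnings") <- warns
  class(out) <- c("viability_result", class(out))
  out
}

#' Compounds excluded by a viability result
#' @param vr A [viability_filter()] result.
#' @param platform Optional platform to restrict to.
#' @return Character vector of excluded compound ids.
#' @export
excluded_compounds <- function(vr, platform = NULL) {
  d <- vr
  if (!is.null(platform)) d <- d[d$platform == platform, ]
  unique(d$compound_id[d$status == "excluded"])
}

#' Derive hit thresholds from the negative control
#'
#' The threshold for calling a hit on each (platform, analyte) is the percent
#' decrease of the negative-control mean against the vehicle mean, floored at
#' `floor` percent. When the negative control barely moves an analyte (or
#' elevates it), the floor branch applies; the provenance column records
#' which branch set each threshold — always restate it in reports.
#'
#' @param ds A [screen_dataset()].
#' @param floor Minimum threshold in percent-decrease units (default 15).
#' @return data.frame: platform, analyte, threshold, provenance
#'   (`"negative_control"` or `"floor"`).
#' @export
derive_thresholds <- function(ds, floor = 15) {
  stopifnot(inherits(ds, "screen_dataset"))
  if (floor < 0) stop("floor must be >= 0", call. = FALSE)
  rows <- list()
  for (pf in unique(ds$wells$platform)) {
    neg <- wells_of(ds, "negative", pf)
    veh <- wells_of(ds, "vehicle", pf)
    if (nrow(neg) == 0) {
      stop("no negative-control wells on platform ", pf,
           "; supply manual thresholds instead", call. = FALSE)
    }
    if (nrow(veh) == 0) stop("no vehicle wells on platform ", pf, call. = FALSE)
    for (a in ds$analyte_panel) {
      anchor <- percent_decrease(mean(neg[[a]]), mean(veh[[a]]))
      rows[[length(rows) + 1]] <- data.frame(
        platform = pf, analyte = a,
        threshold = max(anchor, floor),
        provenance = if (anchor > floor) "negative_control" else "floor",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Manually specified thresholds
#'
#' Convenience constructor for the same shape [derive_thresholds()] returns,
#' for screens without a usable negative control.
#'
#' @param platform,analyte,threshold Equal-length vectors (recycled).
#' @export
manual_thresholds <- function(platform, analyte, threshold) {
  data.frame(platform = platform, analyte = analyte, threshold = threshold,
             provenance = "manual", stringsAsFactors = FALSE)
}

#' Call hits on a screen dataset
#'
#' For every (compound, platform, analyte): the percent decrease of the
#' compound well against the platform's vehicle mean; a viability status;
#' and a hit flag. A compound is a hit iff its percent decrease is strictly
#' greater than the threshold ("beyond" the threshold) and it is not
#' excluded by viability. Ranks are dense 1..k per (platform, analyte),
#' descending by percent decrease, hits only, ties broken by compound_id.
#'
#' @param ds A [screen_dataset()].
#' @param thresholds Output of [derive_thresholds()] or
#'   [manual_thresholds()]; must cover every (platform, analyte) pair.
#' @param viability Optional [viability_filter()] result; `NULL` means no
#'   exclusion and viability status `unknown`.
#' @param strict Use strict `>` at the threshold (default, documented
#'   tie rule); `FALSE` uses `>=`.
#' @return A `hit_table` data.frame: compound_id, platform, analyte, value,
#'   percent_decrease, viability_status, hit, rank.
#' @export
call_hits <- function(ds, thresholds, viability = NULL, strict = TRUE) {
  stopifnot(inherits(ds, "screen_dataset"))
  rows <- list()
  for (pf in unique(ds$wells$platform)) {
    cw <- wells_of(ds, "compound", pf)
    if (nrow(cw) == 0) next
    veh <- wells_of(ds, "vehicle", pf)
    if (nrow(veh) == 0) stop("no vehicle wells on platform ", pf, call. = FALSE)
    vstat <- stats::setNames(rep("unknown", nrow(cw)), cw$compound_id)
    if (!is.null(viability)) {
      vsub <- viability[viability$platform == pf, ]
      vstat[vsub$compound_id] <- vsub$status
    }
    for (a in ds$analyte_panel) {
      thr <- thresholds$threshold[thresholds$platform == pf & thresholds$analyte == a]
      if (length(thr) != 1) {
        stop("thresholds do not cover platform ", pf, ", analyte ", a, call. = FALSE)
      }
      pd <- percent_decrease(cw[[a]], mean(veh[[a]]))
      beyond <- if (strict) pd > thr else pd >= thr
      hit <- unname(beyond & vstat[cw$compound_id] != "excluded")
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = cw$compound_id, platform = pf, analyte = a,
        value = cw[[a]], percent_decrease = pd,
        viability_status = unname(vstat[cw$compound_id]),
        hit = hit, stringsAsFactors = FALSE)
    }
  }
  ht <- do.call(rbind, rows)
  rownames(ht) <- NULL
  ht$rank <- NA_integer_
  for (key in unique(paste(ht$platform, ht$analyte, sep = "\r"))) {
    sel <- which(paste(ht$platform, ht$analyte, sep = "\r") == key & ht$hit)
    if (length(sel) == 0) next
    ord <- sel[order(-ht$percent_decrease[sel], ht$compound_id[sel])]
    ht$rank[ord] <- seq_along(ord)
  }
  class(ht) <- c("hit_table", class(ht))
  ht
}

#' Top-k hit shortlist per (platform, analyte)
#'
#' @param ht A [call_hits()] table.
#' @param k Shortlist size (default 15, the conventional top-hit cut).
#' @return data.frame of at most `k` hits per (platform, analyte), ordered
#'   by rank.
#' @export
rank_hits <- function(ht, k = 15) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  out <- ht[!is.na(ht$rank) & ht$rank <= k, , drop = FALSE]
  out <- out[order(out$platform, out$analyte, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect hit sets from two platforms
#'
#' @param a,b [call_hits()] tables (e.g. one per platform).
#' @param mode `"any_analyte"`: a compound counts as a hit in a table if it
#'   is a hit for at least one analyte; `"per_analyte"`: intersection
#'   computed separately per analyte (returned as a named list).
#' @return For `any_analyte`: list with `shared`, `exclusive_a`,
#'   `exclusive_b` (sorted character vectors partitioning the union). For
#'   `per_analyte`: a named list of such lists.
#' @export
intersect_hits <- function(a, b, mode = c("any_analyte", "per_analyte")) {
  mode <- match.arg(mode)
  one <- function(ha, hb) {
    shared <- sort(intersect(ha, hb))
    list(shared = shared,
         exclusive_a = sort(setdiff(ha, hb)),
         exclusive_b = sort(setdiff(hb, ha)))
  }
  if (mode == "any_analyte") {
    return(one(unique(a$compound_id[a$hit]), unique(b$compound_id[b$hit])))
  }
  analytes <- union(unique(a$analyte), unique(b$analyte))
  stats::setNames(lapply(analytes, function(an) {
    one(unique(a$compound_id[a$hit & a$analyte == an]),
        unique(b$compound_id[b$hit & b$analyte == an]))
  }), analytes)
}
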