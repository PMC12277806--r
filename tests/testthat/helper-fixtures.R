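# Fixture builders shared across the suite. All data is generated in code.

# Minimal plate table: control triplicates plus optional compound wells.
# compound_values: named list compound_id -> named numeric of analyte values.
toy_wells <- function(platform = "spinal_microtissue",
                      analytes = c("IL-6", "IL-8"),
                      vehicle = c(100, 200), negative = c(98, 140),
                      positive = c(800, 1600),
                      compound_values = list(),
                      compound_diameters = NULL,
                      control_diameter = 350) {
  mk <- function(role, id, vals, diam) {
    row <- data.frame(plate_id = paste0(platform, "_p1"), position = "W000",
                      role = role, compound_id = id, dose_um = 5,
                      platform = platform, diameter_um = diam,
                      stringsAsFactors = FALSE)
    for (j in seq_along(analytes)) row[[analytes[j]]] <- vals[j]
    row
  }
  rows <- list()
  for (i in 1:3) {
    rows[[length(rows) + 1]] <- mk("vehicle", "", vehicle, control_diameter)
    rows[[length(rows) + 1]] <- mk("negative", "", negative, control_diameter)
    rows[[length(rows) + 1]] <- mk("positive", "", positive, control_diameter)
  }
  ids <- names(compound_values)
  for (i in seq_along(ids)) {
    diam <- if (is.null(compound_diameters)) control_diameter else compound_diameters[[i]]
    rows[[length(rows) + 1]] <- mk("compound", ids[i], compound_values[[i]], diam)
  }
  w <- do.call(rbind, rows)
  w$position <- sprintf("W%03d", seq_len(nrow(w)))
  w
}

toy_dataset <- function(...) {
  args <- list(...)
  analytes <- if (!is.null(args$analytes)) args$analytes else c("IL-6", "IL-8")
  screen_dataset(toy_wells(...), analytes)
}

# Independent brute-force re-derivation of the full hit-calling chain
# (viability -> thresholds -> hits) with explicit loops; the oracle for
# call_hits(). Deliberately written without reusing package internals.
brute_force_hits <- function(ds, floor, tolerance, strict = TRUE) {
  w <- ds$wells
  out <- list()
  for (pf in unique(w$platform)) {
    veh <- w[w$role == "vehicle" & w$platform == pf, ]
    neg <- w[w$role == "negative" & w$platform == pf, ]
    ref_mean <- mean(veh$diameter_um[!is.na(veh$diameter_um)])
    cw <- w[w$role == "compound" & w$platform == pf, ]
    for (a in ds$analyte_panel) {
      vm <- mean(veh[[a]])
      thr <- 100 * (1 - mean(neg[[a]]) / vm)
      if (thr < floor) thr <- floor
      for (i in seq_len(nrow(cw))) {
        pd <- 100 * (1 - cw[[a]][i] / vm)
        excl <- !is.na(cw$diameter_um[i]) &&
          cw$diameter_um[i] < (1 - tolerance) * ref_mean
        hit <- if (strict) pd > thr else pd >= thr
        hit <- hit && !excl
        out[[length(out) + 1]] <- data.frame(
          compound_id = cw$compound_id[i], platform = pf, analyte = a,
          percent_decrease = pd, hit = hit, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Definition-level BH brute force: q_i = min over j with p_j >= p_i of
# p_(j) * m / rank_j, computed with explicit loops.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r_i <- which(ord == i)  # rank of p[i]
    cands <- numeric(0)
    for (j in r_i:m) cands <- c(cands, p[ord[j]] * m / j)
    q[i] <- min(1, min(cands))
  }
  q
}
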