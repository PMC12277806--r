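# Synthetic-data generators with known ground truth. Every generator is a
# pure function of its config (including the seed): same config => bit
# identical output.

#' Configuration for the synthetic screen generator
#'
#' Defaults emulate the screen design: 190 compounds in single wells per
#' platform, triplicate LPS (1 ug/mL) positive, tocilizumab (1 uM) negative
#' and DMSO (0.01%) vehicle controls, on a spinal-microtissue and a
#' microglia-spheroid platform, with multiplicative log-normal assay noise.
#'
#' Vehicle baselines (pg/mL) are arbitrary plausible Luminex-scale values —
#' absolute control concentrations are not part of the emulated design — and
#' LPS fold-elevations are chosen so control separation is many noise SDs.
#' The negative control barely moves IL-6 while moderately reducing IL-8,
#' which is what makes a threshold floor necessary downstream.
#'
#' @param n_compounds Number of library compounds (single well each).
#' @param analyte_panel Analyte names; defaults to IL-6 + IL-8, extensible to
#'   [cytokine_panel_14()].
#' @param baseline Named vector of vehicle mean concentrations (pg/mL), one
#'   per analyte; unnamed scalar is recycled.
#' @param noise_sigma_log SD of the log-scale multiplicative noise.
#' @param lps_fold Fold-elevation of the positive control per analyte.
#' @param toci_effect Fractional reduction applied by the negative control
#'   per analyte, in `[0, 1)`.
#' @param control_replicates Wells per control role per platform.
#' @param n_untreated Untreated wells per platform (viability reference).
#' @param diameter_mean,diameter_sd Microtissue diameter distribution (um).
#' @param platforms Platform labels (one simulated plate each).
#' @param dose_um Library compound dose (uM).
#' @param active_fraction Probability a compound truly reduces the analytes.
#' @param effect_range Range of true fractional reductions for active
#'   compounds (drawn uniformly, one draw per compound x analyte).
#' @param n_toxic Number of compounds with a toxic diameter shrink
#'   (`NULL`, the default, means 5 capped at `n_compounds`).
#' @param diameter_shrink Fractional diameter reduction for toxic compounds.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_compounds = 190,
                              analyte_panel = c("IL-6", "IL-8"),
                              baseline = c("IL-6" = 120, "IL-8" = 200),
                              noise_sigma_log = 0.1,
                              lps_fold = 8,
                              toci_effect = c("IL-6" = 0.02, "IL-8" = 0.30),
                              control_replicates = 3,
                              n_untreated = 3,
                              diameter_mean = 350,
                              diameter_sd = 12,
                              platforms = c("spinal_microtissue", "microglia_spheroid"),
                              dose_um = 5,
                              active_fraction = 0.15,
                              effect_range = c(0.2, 0.7),
                              n_toxic = NULL,
                              diameter_shrink = 0.4,
                              seed = 1L) {
  expand <- function(x, default) {
    out <- rep(default, length(analyte_panel))
    names(out) <- analyte_panel
    if (is.null(names(x))) {
      out[] <- x
    } else {
      out[intersect(names(x), analyte_panel)] <- x[intersect(names(x), analyte_panel)]
    }
    out
  }
  cfg <- list(
    n_compounds = as.integer(n_compounds),
    analyte_panel = analyte_panel,
    baseline = expand(baseline, 100),
    noise_sigma_log = noise_sigma_log,
    lps_fold = expand(lps_fold, 8),
    toci_effect = expand(toci_effect, 0),
    control_replicates = as.integer(control_replicates),
    n_untreated = as.integer(n_untreated),
    diameter_mean = diameter_mean,
    diameter_sd = diameter_sd,
    platforms = platforms,
    dose_um = dose_um,
    active_fraction = active_fraction,
    effect_range = effect_range,
    n_toxic = as.integer(if (is.null(n_toxic)) min(5L, n_compounds) else n_toxic),
    diameter_shrink = diameter_shrink,
    seed = as.integer(seed)
  )
  if (any(cfg$baseline <= 0)) stop("baselines must be > 0", call. = FALSE)
  if (any(cfg$toci_effect < 0 | cfg$toci_effect >= 1)) {
    stop("toci_effect must be in [0, 1)", call. = FALSE)
  }
  if (any(cfg$lps_fold <= 1)) stop("lps_fold must be > 1", call. = FALSE)
  if (cfg$noise_sigma_log < 0) stop("noise_sigma_log must be >= 0", call. = FALSE)
  if (cfg$n_compounds < 1) stop("n_compounds must be >= 1", call. = FALSE)
  if (cfg$n_toxic > cfg$n_compounds) stop("n_toxic exceeds n_compounds", call. = FALSE)
  if (cfg$active_fraction < 0 || cfg$active_fraction > 1) {
    stop("active_fraction must be in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "screen_sim_config"
  cfg
}

#' Draw a ground-truth effect specification for a screen config
#'
#' Each compound is active with probability `active_fraction`; active
#' compounds draw an independent fractional reduction per analyte from
#' `effect_range`. The first `n_toxic` compounds (after a seeded shuffle)
#' are flagged toxic with the configured diameter shrink. Nontoxic compounds
#' have zero shrink.
#'
#' @param cfg A [screen_sim_config()].
#' @return An `effect_spec`: list with `effects` (compound x analyte matrix of
#'   true fractional reductions), `toxic` (named logical) and
#'   `diameter_shrink` (named numeric, 0 for nontoxic compounds).
#' @export
draw_effect_spec <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  ids <- sprintf("CMP%03d", seq_len(cfg$n_compounds))
  set.seed(cfg$seed)
  active <- stats::runif(cfg$n_compounds) < cfg$active_fraction
  eff <- matrix(0, nrow = cfg$n_compounds, ncol = length(cfg$analyte_panel),
                dimnames = list(ids, cfg$analyte_panel))
  n_draw <- sum(active) * length(cfg$analyte_panel)
  if (n_draw > 0) {
    eff[active, ] <- stats::runif(n_draw, cfg$effect_range[1], cfg$effect_range[2])
  }
  toxic <- stats::setNames(rep(FALSE, cfg$n_compounds), ids)
  if (cfg$n_toxic > 0) toxic[sample(ids, cfg$n_toxic)] <- TRUE
  shrink <- ifelse(toxic, cfg$diameter_shrink, 0)
  structure(list(effects = eff, toxic = toxic, diameter_shrink = shrink),
            class = "effect_spec")
}

#' Generate a synthetic screen dataset with known ground truth
#'
#' Concentration of analyte `a` in the well of compound `c` is drawn
#' multiplicatively as `baseline_a * (1 - f_{c,a}) * exp(eps)` with
#' `eps ~ Normal(0, noise_sigma_log)`. Vehicle wells use `f = 0`, positive
#' wells multiply the baseline by `lps_fold`, negative wells apply
#' `toci_effect`. Toxic compounds centre their diameter on
#' `(1 - diameter_shrink) * diameter_mean`.
#'
#' @param cfg A [screen_sim_config()].
#' @param effects Optional [draw_effect_spec()] output to impose a specific
#'   ground truth; drawn from `cfg` when `NULL`.
#' @return List with `dataset` (a [screen_dataset()]) and `effects`
#'   (the `effect_spec` used).
#' @export
generate_screen <- function(cfg = screen_sim_config(), effects = NULL) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  if (is.null(effects)) effects <- draw_effect_spec(cfg)
  ids <- rownames(effects$effects)
  set.seed(cfg$seed + 1L)  # separate stream from the effect draw

  make_platform <- function(pf) {
    roles <- c(rep("compound", cfg$n_compounds),
               rep("vehicle", cfg$control_replicates),
               rep("positive", cfg$control_replicates),
               rep("negative", cfg$control_replicates),
               rep("untreated", cfg$n_untreated))
    n <- length(roles)
    w <- data.frame(
      plate_id = paste0(pf, "_plate1"),
      position = sprintf("W%03d", seq_len(n)),
      role = roles,
      compound_id = c(ids, rep("", n - cfg$n_compounds)),
      dose_um = ifelse(roles == "compound", cfg$dose_um,
                ifelse(roles == "negative", 1,
                ifelse(roles == "positive", 1, NA_real_))),
      dose_unit = ifelse(roles == "positive", "ug_per_mL",
                  ifelse(roles %in% c("compound", "negative"), "uM", "")),
      platform = pf,
      stringsAsFactors = FALSE
    )
    # fractional reduction per well x analyte (positive wells use fold > 1)
    mult <- matrix(1, nrow = n, ncol = length(cfg$analyte_panel),
                   dimnames = list(NULL, cfg$analyte_panel))
    mult[roles == "compound", ] <- 1 - effects$effects
    for (a in cfg$analyte_panel) {
      mult[roles == "positive", a] <- cfg$lps_fold[a]
      mult[roles == "negative", a] <- 1 - cfg$toci_effect[a]
    }
    eps <- matrix(stats::rnorm(n * length(cfg$analyte_panel), 0, cfg$noise_sigma_log),
                  nrow = n)
    conc <- sweep(mult * exp(eps), 2, cfg$baseline[cfg$analyte_panel], "*")
    for (j in seq_along(cfg$analyte_panel)) w[[cfg$analyte_panel[j]]] <- conc[, j]
    diam_centre <- rep(cfg$diameter_mean, n)
    diam_centre[roles == "compound"] <-
      cfg$diameter_mean * (1 - effects$diameter_shrink)
    w$diameter_um <- pmax(1, stats::rnorm(n, diam_centre, cfg$diameter_sd))
    w
  }

  wells <- do.call(rbind, lapply(cfg$platforms, make_platform))
  ds <- screen_dataset(wells, cfg$analyte_panel,
                       metadata = list(generator = "generate_screen", seed = cfg$seed))
  list(dataset = ds, effects = effects)
}

#' Write a ground-truth effect spec as a long CSV
#'
#' Columns: compound_id, analyte, true_effect, toxic.
#' @param effects An `effect_spec`.
#' @param path Output CSV path.
#' @export
write_effect_spec <- function(effects, path) {
  stopifnot(inherits(effects, "effect_spec"))
  ids <- rownames(effects$effects)
  long <- data.frame(
    compound_id = rep(ids, times = ncol(effects$effects)),
    analyte = rep(colnames(effects$effects), each = length(ids)),
    true_effect = as.vector(effects$effects),
    toxic = rep(unname(effects$toxic), times = ncol(effects$effects)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Configuration for the synthetic survival generator
#'
#' Emulates longitudinal fluorescent-object (Td-Tomato nuclear tag) counting:
#' one reading every `interval` hours for `duration` hours. Decline follows a
#' constant-hazard exponential, `E[count at t] = n0 * exp(-death_rate * t)`.
#' Default conditions mirror a monoculture/co-culture/triculture design in
#' which disease microglia raise the motor-neuron death rate and drug
#' treatment restores it to near control levels.
#'
#' @param interval Imaging cadence in hours.
#' @param duration Total imaging span in hours (must be a multiple of
#'   `interval`).
#' @param n0 Initial object count per well.
#' @param conditions data.frame with columns condition, treatment, death_rate
#'   (per-hour hazard). Defaults cover MN alone, MN + control or disease
#'   microglia, and control/disease tricultures under vehicle and drug.
#' @param count_noise Draw Poisson counts around the expectation; when off,
#'   counts are the rounded expectation.
#' @param n_replicates Wells per condition x treatment.
#' @param seed Integer seed.
#' @return A `survival_sim_config` list.
#' @export
survival_sim_config <- function(interval = 4, duration = 336, n0 = 500,
                                conditions = NULL, count_noise = TRUE,
                                n_replicates = 3, seed = 1L) {
  if (duration %% interval != 0) {
    stop("duration must be an integer multiple of interval", call. = FALSE)
  }
  if (n0 <= 0) stop("n0 must be > 0", call. = FALSE)
  if (is.null(conditions)) {
    conditions <- data.frame(
      condition = rep(c("MN_alone", "MN_ctrl_microglia", "MN_c9_microglia",
                        "ctrl_triculture", "c9_triculture"), each = 2),
      treatment = rep(c("vehicle", "telmisartan"), times = 5),
      death_rate = c(0.0010, 0.0010,   # MN alone: drug has no effect
                     0.0012, 0.0012,   # control microglia: no effect
                     0.0040, 0.0015,   # disease microglia: drug rescues
                     0.0012, 0.0012,   # control triculture
                     0.0040, 0.0015),  # disease triculture: drug rescues
      stringsAsFactors = FALSE
    )
  }
  if (any(conditions$death_rate < 0)) stop("death_rate must be >= 0", call. = FALSE)
  structure(list(interval = interval, duration = duration, n0 = n0,
                 conditions = conditions, count_noise = isTRUE(count_noise),
                 n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Generate synthetic survival series
#'
#' @param cfg A [survival_sim_config()].
#' @return Long data.frame: condition, treatment, replicate, time_h, count.
#'   Counts are nonnegative integers.
#' @export
generate_survival <- function(cfg = survival_sim_config()) {
  stopifnot(inherits(cfg, "survival_sim_config"))
  set.seed(cfg$seed)
  times <- seq(0, cfg$duration, by = cfg$interval)
  out <- list()
  for (i in seq_len(nrow(cfg$conditions))) {
    lam <- cfg$conditions$death_rate[i]
    expect <- cfg$n0 * exp(-lam * times)
    for (r in seq_len(cfg$n_replicates)) {
      counts <- if (cfg$count_noise) stats::rpois(length(times), expect) else round(expect)
      out[[length(out) + 1]] <- data.frame(
        condition = cfg$conditions$condition[i],
        treatment = cfg$conditions$treatment[i],
        replicate = r,
        time_h = times,
        count = as.integer(counts),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Configuration for the synthetic composition generator
#'
#' Emulates microtissue cell composition: 7,500 cells at a 1:3:1
#' astrocyte:MN:microglia ratio (4,500 MNs, 1,500 astrocytes, 1,500
#' microglia), assessed on days 5, 7 and 14. The disease genotype loses a
#' fixed fraction of its motor neurons per day, compounded from day 0; the
#' control genotype keeps the seeded ratio.
#'
#' @param total_cells Cells per microtissue.
#' @param ratio Integer parts astrocyte:MN:microglia.
#' @param mn_decline_rate Per-day fractional MN loss in the disease genotype.
#' @param timepoints Assessment days.
#' @param sampling `"exact"` (deterministic rounded counts) or
#'   `"multinomial"` (sample `total_cells` classified objects per microtissue).
#' @param n_samples Microtissues per genotype per timepoint.
#' @param seed Integer seed (used by multinomial sampling).
#' @return A `composition_sim_config` list.
#' @export
composition_sim_config <- function(total_cells = 7500, ratio = c(astrocyte = 1, MN = 3, microglia = 1),
                                   mn_decline_rate = 0.05, timepoints = c(5, 7, 14),
                                   sampling = c("exact", "multinomial"),
                                   n_samples = 6, seed = 1L) {
  sampling <- match.arg(sampling)
  if (any(ratio <= 0) || any(ratio != round(ratio))) {
    stop("ratio parts must be positive integers", call. = FALSE)
  }
  if (sampling == "exact" && total_cells %% sum(ratio) != 0) {
    stop("total_cells must be divisible by the ratio part sum in exact mode",
         call. = FALSE)
  }
  if (mn_decline_rate < 0 || mn_decline_rate >= 1) {
    stop("mn_decline_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(total_cells = as.integer(total_cells), ratio = ratio,
                 mn_decline_rate = mn_decline_rate, timepoints = timepoints,
                 sampling = sampling, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "composition_sim_config")
}

#' Generate synthetic cell-type composition tables
#'
#' Expected MN count in the disease genotype at day `t` is
#' `MN0 * (1 - mn_decline_rate)^t`; the other classes keep their seeded
#' counts (lost MNs simply leave the denominator). Exact mode rounds the
#' expectation; multinomial mode samples `total_cells` objects per
#' microtissue from the expected class proportions.
#'
#' @param cfg A [composition_sim_config()].
#' @return Long data.frame: sample, genotype, timepoint, marker columns
#'   MN / astrocyte / microglia (counts).
#' @export
generate_composition <- function(cfg = composition_sim_config()) {
  stopifnot(inherits(cfg, "composition_sim_config"))
  set.seed(cfg$seed)
  base <- cfg$total_cells * cfg$ratio / sum(cfg$ratio)
  out <- list()
  for (day in cfg$timepoints) {
    for (gt in c("CTRL", "C9")) {
      counts <- base
      if (gt == "C9") counts["MN"] <- base["MN"] * (1 - cfg$mn_decline_rate)^day
      for (s in seq_len(cfg$n_samples)) {
        if (cfg$sampling == "exact") {
          obs <- round(counts)
        } else {
          obs <- stats::setNames(
            as.numeric(stats::rmultinom(1, cfg$total_cells, counts / sum(counts))),
            names(counts))
        }
        out[[length(out) + 1]] <- data.frame(
          sample = sprintf("%s_D%g_S%02d", gt, day, s),
          genotype = gt, timepoint = day,
          MN = obs[["MN"]], astrocyte = obs[["astrocyte"]],
          microglia = obs[["microglia"]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}
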