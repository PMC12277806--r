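test_that("generate_screen honours the configured layout", {
  cfg <- screen_sim_config(n_compounds = 190, seed = 11)
  sim <- generate_screen(cfg)
  w <- sim$dataset$wells
  for (pf in cfg$platforms) {
    expect_equal(sum(w$role == "compound" & w$platform == pf), 190)
    for (role in c("vehicle", "positive", "negative")) {
      expect_equal(sum(w$role == role & w$platform == pf), 3)
    }
  }
  expect_equal(dim(sim$effects$effects), c(190, 2))
  expect_equal(sum(sim$effects$toxic), cfg$n_toxic)
  expect_true(all(sim$effects$diameter_shrink[!sim$effects$toxic] == 0))
})

test_that("zero-noise screens propagate effects exactly", {
  cfg <- screen_sim_config(n_compounds = 4, noise_sigma_log = 0, seed = 5,
                           active_fraction = 1, effect_range = c(0.65, 0.65),
                           n_toxic = 0)
  sim <- generate_screen(cfg)
  w <- sim$dataset$wells
  cw <- w[w$role == "compound" & w$platform == "spinal_microtissue", ]
  expect_equal(cw[["IL-8"]], rep(0.35 * cfg$baseline[["IL-8"]], 4), tolerance = 1e-12)
  veh <- w[w$role == "vehicle", ]
  expect_equal(veh[["IL-6"]], rep(cfg$baseline[["IL-6"]], 6), tolerance = 1e-12)
  pos <- w[w$role == "positive", ]
  expect_equal(pos[["IL-6"]], rep(8 * cfg$baseline[["IL-6"]], 6), tolerance = 1e-12)
})

test_that("generators are pure functions of their seed", {
  a <- generate_screen(screen_sim_config(n_compounds = 20, seed = 7))
  b <- generate_screen(screen_sim_config(n_compounds = 20, seed = 7))
  c <- generate_screen(screen_sim_config(n_compounds = 20, seed = 8))
  expect_identical(a$dataset$wells, b$dataset$wells)
  expect_identical(a$effects, b$effects)
  expect_false(identical(a$dataset$wells[["IL-6"]], c$dataset$wells[["IL-6"]]))

  s1 <- generate_survival(survival_sim_config(seed = 3))
  s2 <- generate_survival(survival_sim_config(seed = 3))
  expect_identical(s1, s2)

  c1 <- generate_composition(composition_sim_config(sampling = "multinomial", seed = 9))
  c2 <- generate_composition(composition_sim_config(sampling = "multinomial", seed = 9))
  expect_identical(c1, c2)
})

test_that("config invariants are enforced", {
  expect_error(screen_sim_config(baseline = c("IL-6" = -1)), "baseline")
  expect_error(screen_sim_config(toci_effect = 1.2), "toci_effect")
  expect_error(screen_sim_config(lps_fold = 0.5), "lps_fold")
  expect_error(survival_sim_config(interval = 5, duration = 336), "multiple")
  expect_error(composition_sim_config(total_cells = 7003, ratio = c(1, 3, 1),
                                      sampling = "exact"), "divisible")
  expect_error(composition_sim_config(ratio = c(0.5, 3, 1)), "positive integers")
})

test_that("survival series follow the stated grid and decay", {
  cfg <- survival_sim_config(interval = 4, duration = 336, n0 = 1000,
                             count_noise = FALSE, n_replicates = 1, seed = 1,
                             conditions = data.frame(condition = "A",
                                                     treatment = "vehicle",
                                                     death_rate = 0))
  s <- generate_survival(cfg)
  expect_equal(nrow(s), 85)
  expect_equal(max(s$time_h), 336)
  expect_true(all(diff(s$time_h) == 4))
  expect_true(all(s$count == 1000))  # zero-hazard limit

  lam <- -log(600 / 1000) / 336
  cfg2 <- survival_sim_config(n0 = 1000, count_noise = FALSE, n_replicates = 1,
                              conditions = data.frame(condition = "B",
                                                      treatment = "vehicle",
                                                      death_rate = lam))
  s2 <- generate_survival(cfg2)
  expect_equal(s2$count[s2$time_h == 336], 600)
})

test_that("composition generator reproduces the seeded ratio and decline", {
  cfg <- composition_sim_config(timepoints = 0, sampling = "exact", n_samples = 1)
  ct <- generate_composition(cfg)
  d0 <- ct[ct$genotype == "CTRL", ]
  expect_equal(d0$MN, 4500)
  expect_equal(d0$astrocyte, 1500)
  expect_equal(d0$microglia, 1500)

  flat <- generate_composition(composition_sim_config(mn_decline_rate = 0,
                                                      sampling = "exact",
                                                      n_samples = 1))
  expect_equal(length(unique(flat$MN)), 1)  # identical counts at all timepoints

  dec <- generate_composition(composition_sim_config(mn_decline_rate = 0.05,
                                                     sampling = "exact",
                                                     n_samples = 1))
  c9_d14 <- dec[dec$genotype == "C9" & dec$timepoint == 14, "MN"][1]
  expect_equal(c9_d14, round(4500 * 0.95^14))
})

test_that("multinomial composition proportions fall within 3 SE of truth", {
  cfg <- composition_sim_config(sampling = "multinomial", mn_decline_rate = 0,
                                n_samples = 1, timepoints = 5, seed = 21)
  ct <- generate_composition(cfg)
  n <- cfg$total_cells
  for (i in seq_len(nrow(ct))) {
    for (m in c("MN", "astrocyte", "microglia")) {
      p <- if (m == "MN") 0.6 else 0.2
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(ct[[m]][i] / n - p), 3 * se)
    }
  }
})

test_that("vehicle log-concentrations are consistent with log-normal noise", {
  # pool vehicle wells from many seeded small screens to n = 1000
  vals <- unlist(lapply(1:167, function(s) {
    sim <- generate_screen(screen_sim_config(n_compounds = 1, seed = s,
                                             platforms = "spinal_microtissue"))
    w <- sim$dataset$wells
    w[["IL-6"]][w$role == "vehicle"]
  }))
  vals <- vals[1:1000]
  p <- shapiro.test(log(vals))$p.value
  expect_gt(p, 0.01)
})
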