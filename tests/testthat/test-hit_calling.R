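test_that("percent_decrease is the vehicle-normalized statistic", {
  expect_equal(percent_decrease(35, 100), 65)
  expect_equal(percent_decrease(100, 100), 0)
  expect_equal(percent_decrease(120, 100), -20)
  expect_equal(percent_decrease(0, 100), 100)  # upper bound
  expect_error(percent_decrease(10, 0), "vehicle_mean")
  expect_error(percent_decrease(-1, 100), "value")
})

test_that("viability_filter applies the diameter rule with missing-data handling", {
  w <- toy_wells(compound_values = list(A = c(50, 60), B = c(50, 60), C = c(50, 60)),
                 compound_diameters = c(70, 85, NA), control_diameter = 100)
  ds <- screen_dataset(w, c("IL-6", "IL-8"))
  vr <- viability_filter(ds, tolerance = 0.2, reference = "vehicle")
  st <- setNames(vr$status, vr$compound_id)
  expect_equal(st[["A"]], "excluded")   # 70 < 80
  expect_equal(st[["B"]], "pass")       # 85 >= 80
  expect_equal(st[["C"]], "unknown")    # missing diameter retained
  expect_true(any(grepl("missing diameter", attr(vr, "warnings"))))
  expect_equal(excluded_compounds(vr), "A")

  # no reference diameters -> configuration error
  w2 <- w
  w2$diameter_um[w2$role == "vehicle"] <- NA
  ds2 <- screen_dataset(w2, c("IL-6", "IL-8"))
  expect_error(viability_filter(ds2, reference = "vehicle"), "reference diameters")
})

test_that("derive_thresholds anchors on the negative control with a floor", {
  mk <- function(neg6) {
    screen_dataset(toy_wells(vehicle = c(100, 100), negative = c(neg6, 80)),
                   c("IL-6", "IL-8"))
  }
  thr <- derive_thresholds(mk(80), floor = 0)
  expect_equal(thr$threshold[thr$analyte == "IL-6"], 20)
  expect_equal(thr$provenance[thr$analyte == "IL-6"], "negative_control")

  thr2 <- derive_thresholds(mk(99), floor = 15)
  expect_equal(thr2$threshold[thr2$analyte == "IL-6"], 15)
  expect_equal(thr2$provenance[thr2$analyte == "IL-6"], "floor")

  thr3 <- derive_thresholds(mk(120), floor = 10)  # negative control elevates
  expect_equal(thr3$threshold[thr3$analyte == "IL-6"], 10)
  expect_equal(thr3$provenance[thr3$analyte == "IL-6"], "floor")

  w <- toy_wells()
  w <- w[w$role != "negative", ]
  expect_error(derive_thresholds(screen_dataset(w, c("IL-6", "IL-8"))),
               "manual thresholds")
})

test_that("call_hits applies strict threshold and exclusion precedence", {
  w <- toy_wells(vehicle = c(100, 100),
                 compound_values = list(A = c(75, 100), B = c(85, 100),
                                        C = c(120, 100), D = c(50, 100),
                                        E = c(80, 100)),
                 compound_diameters = c(350, 350, 350, 100, 350))
  ds <- screen_dataset(w, c("IL-6", "IL-8"))
  thr <- manual_thresholds(rep("spinal_microtissue", 2), c("IL-6", "IL-8"), c(20, 20))
  vr <- viability_filter(ds, tolerance = 0.2)
  ht <- call_hits(ds, thr, viability = vr)
  il6 <- ht[ht$analyte == "IL-6", ]
  hits <- il6$compound_id[il6$hit]
  expect_setequal(hits, "A")             # 25% > 20; B 15%, C -20%
  expect_false(il6$hit[il6$compound_id == "D"])  # 50% but excluded by viability
  expect_equal(il6$viability_status[il6$compound_id == "D"], "excluded")
  # exact tie at the threshold: not a hit under strict ">", a hit under ">="
  # (threshold 25 and value 75 keep 100*(1 - 75/100) exactly representable)
  thr25 <- manual_thresholds(rep("spinal_microtissue", 2), c("IL-6", "IL-8"), c(25, 25))
  hA <- call_hits(ds, thr25, viability = vr)
  expect_false(hA$hit[hA$analyte == "IL-6" & hA$compound_id == "A"])  # exactly 25%
  hA2 <- call_hits(ds, thr25, viability = vr, strict = FALSE)
  expect_true(hA2$hit[hA2$analyte == "IL-6" & hA2$compound_id == "A"])
})

test_that("hit ranks are dense, descending, tie-broken by compound_id", {
  vals <- list(A = c(30, 100), B = c(70, 100), C = c(70, 100), D = c(10, 100))
  w <- toy_wells(vehicle = c(100, 100), compound_values = vals)
  ds <- screen_dataset(w, c("IL-6", "IL-8"))
  thr <- manual_thresholds(rep("spinal_microtissue", 2), c("IL-6", "IL-8"), c(20, 20))
  ht <- call_hits(ds, thr)
  il6 <- ht[ht$analyte == "IL-6", ]
  # hits: A (70%), B (30%), C (30%), D (90%) -> D, A, then B/C tie by id
  expect_equal(il6$rank[match(c("D", "A", "B", "C"), il6$compound_id)], 1:4)
  short <- rank_hits(ht, k = 2)
  expect_equal(short$compound_id[short$analyte == "IL-6"], c("D", "A"))
  short15 <- rank_hits(ht, k = 15)  # truncation to available hits
  expect_equal(sum(short15$analyte == "IL-6"), 4)
  expect_error(rank_hits(ht, k = 0), "k")
})

test_that("intersect_hits partitions the union", {
  mk_ht <- function(ids) {
    data.frame(compound_id = ids, platform = rep("x", length(ids)),
               analyte = rep("IL-6", length(ids)),
               hit = rep(TRUE, length(ids)), stringsAsFactors = FALSE)
  }
  res <- intersect_hits(mk_ht(c("tel", "val", "azi", "flu")),
                        mk_ht(c("tel", "val", "azi", "del")))
  expect_equal(res$shared, c("azi", "tel", "val"))
  expect_equal(res$exclusive_a, "flu")
  expect_equal(res$exclusive_b, "del")

  res2 <- intersect_hits(mk_ht(c("a", "b")), mk_ht(c("c")))
  expect_length(res2$shared, 0)

  res3 <- intersect_hits(mk_ht(c("a", "b")), mk_ht(c("a", "b")))
  expect_equal(res3$shared, c("a", "b"))
  expect_length(res3$exclusive_a, 0)

  # partition property on random sets
  set.seed(1)
  for (i in 1:20) {
    ha <- sample(letters, sample(0:10, 1))
    hb <- sample(letters, sample(0:10, 1))
    r <- intersect_hits(mk_ht(ha), mk_ht(hb))
    expect_setequal(c(r$shared, r$exclusive_a, r$exclusive_b), union(ha, hb))
    expect_length(intersect(r$shared, r$exclusive_a), 0)
    expect_length(intersect(r$shared, r$exclusive_b), 0)
    expect_length(intersect(r$exclusive_a, r$exclusive_b), 0)
  }
})

test_that("per-analyte intersection is computed separately", {
  mk <- function(ids6, ids8) {
    rbind(data.frame(compound_id = ids6, platform = "x", analyte = "IL-6",
                     hit = TRUE, stringsAsFactors = FALSE),
          data.frame(compound_id = ids8, platform = "x", analyte = "IL-8",
                     hit = TRUE, stringsAsFactors = FALSE))
  }
  res <- intersect_hits(mk("a", c("a", "b")), mk(c("a", "c"), "b"),
                        mode = "per_analyte")
  expect_equal(res[["IL-6"]]$shared, "a")
  expect_equal(res[["IL-8"]]$shared, "b")
})

test_that("call_hits matches the brute-force oracle on small random screens", {
  for (s in 1:25) {
    set.seed(1000 + s)
    cfg <- screen_sim_config(n_compounds = sample(1:10, 1),
                             noise_sigma_log = runif(1, 0, 0.3),
                             active_fraction = runif(1),
                             n_toxic = sample(0:1, 1),
                             seed = s)
    sim <- generate_screen(cfg)
    floor <- sample(c(0, 10, 20), 1)
    tol <- runif(1, 0.1, 0.3)
    vr <- viability_filter(sim$dataset, tolerance = tol, reference = "vehicle")
    thr <- derive_thresholds(sim$dataset, floor = floor)
    ht <- call_hits(sim$dataset, thr, viability = vr)
    oracle <- brute_force_hits(sim$dataset, floor = floor, tolerance = tol)
    key <- function(d) paste(d$compound_id, d$platform, d$analyte)
    ht <- ht[order(key(ht)), ]
    oracle <- oracle[order(key(oracle)), ]
    expect_equal(ht$percent_decrease, oracle$percent_decrease, tolerance = 1e-12)
    expect_equal(ht$hit, oracle$hit)
  }
})
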