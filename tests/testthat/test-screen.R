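test_that("normalization is per plate and treatment, not pooled", {
  w1 <- make_wells("mirA", "vehicle", 800, ctrl_signal = 1000,
                   plate_id = "P1_vehicle")
  w2 <- make_wells("mirA", "vehicle", 800, ctrl_signal = 2000,
                   plate_id = "P2_vehicle")
  rec1 <- normalize_to_control(w1)
  rec2 <- normalize_to_control(w2)
  expect_equal(rec1$viability_pct[rec1$perturbation_id == "mirA"], 80)
  expect_equal(rec2$viability_pct[rec2$perturbation_id == "mirA"], 40)
  # identity and half-control cases
  w3 <- make_wells(c("mirB", "mirC"), "vehicle", c(1000, 500))
  rec3 <- normalize_to_control(w3)
  expect_equal(rec3$viability_pct[rec3$perturbation_id == "mirB"], 100)
  expect_equal(rec3$viability_pct[rec3$perturbation_id == "mirC"], 50)
  expect_equal(rec3$viability_pct[rec3$perturbation_id == "NTC"], 100)
})

test_that("normalization errors name a stratum without controls", {
  w <- make_wells("mirA", "vehicle", 800)
  w <- w[w$perturbation_class != "non_targeting", ]
  expect_error(normalize_to_control(w), "P1_vehicle")
  wz <- make_wells("mirA", "vehicle", 800, ctrl_signal = 0)
  expect_error(normalize_to_control(wz), "control mean")
})

test_that("normalization is invariant to rescaling a plate's raw signals", {
  cfg <- screen_sim_config(seed = 3, n_perturbations = 40, noise_cv = 0.05)
  sim <- simulate_screen(cfg)
  rec <- normalize_to_control(sim$wells)
  scaled <- sim$wells
  p1 <- scaled$plate_id == scaled$plate_id[1]
  scaled$signal[p1] <- scaled$signal[p1] * 7.3
  rec2 <- normalize_to_control(scaled)
  expect_equal(rec2$viability_pct, rec$viability_pct)
  calls <- call_sensitisers(rec, "docetaxel")
  calls2 <- call_sensitisers(rec2, "docetaxel")
  expect_identical(calls$category, calls2$category)
})

test_that("blacklist exclusion removes listed ids and warns on absent ones", {
  rec <- make_records(sprintf("mir%02d", 1:10), rep(100, 10), rep(90, 10))
  out <- exclude_blacklist(rec, sprintf("mir%02d", 1:3))
  expect_equal(length(unique(out$perturbation_id)), 7)
  expect_equal(attr(out, "n_removed"), 6L)  # 3 ids x 2 treatments
  expect_identical(exclude_blacklist(rec, character(0)), {
    r <- rec; attr(r, "n_removed") <- 0L; r
  })
  expect_warning(exclude_blacklist(rec, "mirXX"), "not present")
})

test_that("dual-threshold calling applies the printed rule with strict boundaries", {
  rec <- make_records(
    c("a", "b", "c", "d", "e", "f"),
    vehicle_pct = c(95, 95, 100, 80, 30, 30),
    drug_pct = c(70, 45, 80, 70, 28, 15))
  calls <- call_sensitisers(rec, "docetaxel")
  got <- setNames(calls$category, calls$perturbation_id)
  expect_equal(got[["a"]], "sensitiser")
  expect_false(calls$strong[calls$perturbation_id == "a"])
  expect_equal(got[["b"]], "sensitiser")
  expect_true(calls$strong[calls$perturbation_id == "b"])
  expect_equal(got[["c"]], "none")      # drug exactly 80: strict "<80"
  expect_equal(got[["d"]], "toxic")     # vehicle exactly 80 fails ">80"
  expect_equal(got[["e"]], "toxic")     # no extra drug effect
  expect_equal(got[["f"]], "toxic_sensitiser")
})

test_that("calling errors when a treatment record is missing", {
  rec <- make_records("a", 95, 70)
  rec <- rec[rec$treatment != "vehicle", ]
  expect_error(call_sensitisers(rec, "docetaxel"), "a")
})

test_that("hit calling agrees with the one-line oracle and partitions input", {
  set.seed(42)
  n <- 2000
  veh <- c(runif(n - 4, 0, 130), 80, 80, 100, 100)
  drg <- c(runif(n - 4, 0, 130), 80, 50, 80, 50)
  ids <- sprintf("p%04d", seq_len(n))
  calls <- call_sensitisers(make_records(ids, veh, drg), "docetaxel")
  expected <- mapply(oracle_category,
                     calls$viability_vehicle_pct, calls$viability_drug_pct)
  expect_identical(calls$category, unname(expected))
  expect_identical(calls$strong, calls$viability_drug_pct < 50)
  expect_equal(nrow(calls), n)  # exactly one category per perturbation
  expect_true(all(calls$category %in%
    c("none", "sensitiser", "toxic", "toxic_sensitiser")))
})

test_that("sensitisers are recovered from a simulated screen", {
  cfg <- screen_sim_config(seed = 101, n_perturbations = 500,
                           fraction_sensitiser = 0.2,
                           fraction_toxic = 0.05, fraction_both = 0.05,
                           noise_cv = 0.05)
  sim <- simulate_screen(cfg)
  calls <- call_sensitisers(normalize_to_control(sim$wells), cfg$drug)
  truth <- sim$truth$true_class[match(calls$perturbation_id,
                                      sim$truth$perturbation_id)]
  sens <- mean(calls$category[truth == "sensitiser"] == "sensitiser")
  spec <- mean(calls$category[truth != "sensitiser"] != "sensitiser")
  expect_gte(sens, 0.90)
  expect_gte(spec, 0.95)
})

test_that("siRNA classification reproduces the toxic / sensitiser / both bands", {
  rec <- make_records(
    c("tox", "sens", "both", "none"),
    vehicle_pct = c(30, 90, 30, 95),
    drug_pct = c(30, 85, 15, 95))
  calls <- classify_sirna(rec, "docetaxel",
                          gene = c(tox = "GENE1", sens = "GENE2",
                                   both = "GENE3", none = "GENE4"))
  got <- setNames(calls$category, calls$perturbation_id)
  expect_equal(got[["tox"]], "toxic")        # 20-40 band, no further drop
  expect_equal(got[["sens"]], "sensitiser")  # 15-point deficit vs drug control
  expect_equal(got[["both"]], "toxic_sensitiser")
  expect_equal(got[["none"]], "none")
  expect_true(calls$in_toxic_band[calls$perturbation_id == "tox"])
  s <- summarize_hits(calls)
  expect_equal(s$n_hit_genes, 3)
})

test_that("positive-control QC reports normalized lethality", {
  cfg <- screen_sim_config(seed = 6, n_perturbations = 20, noise_cv = 0.02)
  rec <- normalize_to_control(simulate_screen(cfg)$wells)
  qc <- positive_control_qc(rec)
  expect_true(qc$pass)
  expect_true(all(qc$viability_pct < 25))
})
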