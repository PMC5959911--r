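test_that("invalid simulation configs are rejected", {
  expect_error(screen_sim_config(fraction_sensitiser = 0.6,
                                 fraction_toxic = 0.3, fraction_both = 0.2),
               "sum to at most 1")
  expect_error(screen_sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(screen_sim_config(n_replicates = 0), "n_replicates")
  expect_error(simulate_confluency(-1, 0:10), "doubling time")
  expect_error(simulate_dose_response(5, doses = numeric(0)), "nonempty")
  expect_error(simulate_expression(n_control = 1), ">= 2 samples")
  expect_error(simulate_tumor_matrix(n_normal = 1), ">= 2 samples")
  expect_error(simulate_tumor_matrix(missing_rate = 1), "missing_rate")
})

test_that("noise-free screen signals reproduce the IC20 contract", {
  cfg <- screen_sim_config(seed = 7, n_perturbations = 4,
                           fraction_sensitiser = 0.5, fraction_toxic = 0,
                           fraction_both = 0, noise_cv = 0,
                           n_replicates = 1, plate_size = 16,
                           plate_effect_sd = 0,
                           effect_ranges = list(
                             sensitiser = list(vehicle = c(1, 1),
                                               drug_extra = c(0.5, 0.5)),
                             toxic = list(vehicle = c(0.3, 0.3),
                                          drug_extra = c(1, 1)),
                             toxic_sensitiser = list(vehicle = c(0.3, 0.3),
                                                     drug_extra = c(0.5, 0.5))))
  sim <- simulate_screen(cfg)
  w <- sim$wells
  base <- w$signal[w$perturbation_class == "non_targeting" &
                     w$treatment == "vehicle"][1]
  # drug reduces every unperturbed signal to 80% of vehicle (IC20 dose)
  expect_equal(
    w$signal[w$perturbation_class == "non_targeting" &
               w$treatment != "vehicle"][1],
    0.8 * base)
  for (id in sim$truth$perturbation_id) {
    cls <- sim$truth$true_class[sim$truth$perturbation_id == id]
    veh <- w$signal[w$perturbation_id == id & w$treatment == "vehicle"]
    drg <- w$signal[w$perturbation_id == id & w$treatment != "vehicle"]
    if (cls == "null") {
      expect_equal(veh, base)
      expect_equal(drg, 0.8 * base)  # raw drug/vehicle ratio is the IC20 80%
    } else {
      expect_equal(veh, base)
      expect_equal(drg, 0.8 * 0.5 * base)  # sensitiser: extra 0.5 under drug
    }
  }
})

test_that("simulators are byte-identical under a fixed seed", {
  cfg <- screen_sim_config(seed = 1, n_perturbations = 50, noise_cv = 0.05)
  expect_identical(simulate_screen(cfg), simulate_screen(cfg))
  expect_identical(
    simulate_dose_response(5, doses = c(1, 2, 4, 8), seed = 3),
    simulate_dose_response(5, doses = c(1, 2, 4, 8), seed = 3))
  expect_identical(simulate_expression(seed = 9), simulate_expression(seed = 9))
  expect_identical(simulate_tumor_matrix(seed = 9),
                   simulate_tumor_matrix(seed = 9))
})

test_that("truth table covers every perturbation once with unit null factors", {
  sim <- simulate_screen(screen_sim_config(seed = 2, n_perturbations = 120,
                                           fraction_sensitiser = 0.2,
                                           fraction_toxic = 0.1,
                                           fraction_both = 0.1))
  tr <- sim$truth
  expect_equal(sort(unique(sim$wells$perturbation_id[
    sim$wells$perturbation_class == "mimic"])), sort(tr$perturbation_id))
  expect_equal(anyDuplicated(tr$perturbation_id), 0L)
  nulls <- tr[tr$true_class == "null", ]
  expect_true(all(nulls$true_vehicle_factor == 1))
  expect_true(all(nulls$true_drug_extra_factor == 1))
  # each perturbation appears n_replicates times per treatment
  cnt <- table(sim$wells$perturbation_id[sim$wells$perturbation_class == "mimic"],
               sim$wells$treatment[sim$wells$perturbation_class == "mimic"])
  expect_true(all(cnt == 2))
})

test_that("empirical replicate CV converges to the configured noise CV", {
  cfg <- screen_sim_config(seed = 11, n_perturbations = 30, noise_cv = 0.1,
                           n_replicates = 40, plate_effect_sd = 0)
  sim <- simulate_screen(cfg)
  w <- sim$wells[sim$wells$perturbation_class == "mimic" &
                   sim$wells$treatment == "vehicle", ]
  cvs <- tapply(w$signal, w$perturbation_id,
                function(x) stats::sd(x) / mean(x))
  expect_lt(abs(mean(cvs) - 0.1) / 0.1, 0.2)
})

test_that("confluency curves honour start, doubling time and monotonicity", {
  c24 <- simulate_confluency(24, seq(0, 72, 2), start_confluency = 1)
  expect_equal(c24$confluency_pct[1], 1)
  # exponential limit: one doubling over 24 h within 1% relative
  expect_lt(abs(c24$confluency_pct[c24$time_h == 24] - 2) / 2, 0.01)
  c12 <- simulate_confluency(12, seq(0, 72, 2), start_confluency = 1)
  t5_24 <- min(c24$time_h[c24$confluency_pct >= 5])
  t5_12 <- min(c12$time_h[c12$confluency_pct >= 5])
  expect_lt(t5_12, t5_24)
})

test_that("dose-response generator hits the curve exactly without noise", {
  dr <- simulate_dose_response(ic50 = 5, hill = 1, lower = 0, upper = 100,
                               doses = c(0, 1, 5, 25), n_replicates = 1,
                               noise_cv = 0, seed = 1)
  expect_equal(dr$viability_pct[dr$dose_nM == 5], 50)
  expect_equal(dr$viability_pct[dr$dose_nM == 0], 100)  # vehicle anchor
  means <- dr$viability_pct[order(dr$dose_nM)]
  expect_true(all(diff(means) <= 0))
})

test_that("expression generator plants exact fold effects without noise", {
  sim <- simulate_expression(n_genes = 50, n_planted_down = 5,
                             fold_range_down = c(0.5, 0.5), noise_cv = 0,
                             frac_low_signal = 0, seed = 4)
  m <- sim$matrix
  ctrl <- rowMeans(m[, sim$groups == "control"])
  mim <- rowMeans(m[, sim$groups == "mimic"])
  expect_equal(mim[sim$planted], 0.5 * ctrl[sim$planted])
  others <- setdiff(rownames(m), sim$planted)
  expect_equal(mim[others], ctrl[others])
})

test_that("tumor generator plants fold and forced high-missingness genes", {
  sim <- simulate_tumor_matrix(n_genes = 100, n_normal = 5, n_tumor = 5,
                               n_planted_up = 10, fold = 2,
                               missing_rate = 0, n_high_missing = 3,
                               noise_cv = 0.01, seed = 5)
  m <- sim$matrix$values
  norm_idx <- sim$groups == "normal"
  ratio <- rowMeans(m[sim$planted, !norm_idx]) /
    rowMeans(m[sim$planted, norm_idx])
  expect_true(all(abs(ratio - 2) < 0.05))
  frac <- rowMeans(is.na(m[sim$high_missing, norm_idx, drop = FALSE]))
  expect_true(all(frac > 0.5))  # flagged for removal downstream
  cleaned <- clean_matrix(sim$matrix)
  expect_false(any(sim$high_missing %in% rownames(cleaned$values)))
})
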