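test_that("the generator is seed-deterministic and validates its config", {
  sp <- model_spec(3, 3, 10, 10, 5)
  expect_error(synth_config(sp, 100), "seed")
  expect_error(synth_config(sp, 100, seed = 1, intensity_cv = 1.5), "cv")
  expect_error(synth_config(sp, 100, seed = 1, binucleate_fraction = 2),
               "fractions")
  cfg <- synth_config(sp, n_cells = 120, seed = 77)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$truth, p2$truth)
  r1 <- render_spot_table(p1)
  r2 <- render_spot_table(p2)
  expect_identical(r1$spots, r2$spots)
})

test_that("noise-free rendering reconciles exactly with the ground truth", {
  sp <- model_spec(2, 2, 8, 8, 4)
  cfg <- synth_config(sp, n_cells = 150, seed = 5, intensity_cv = 0,
                      gain_cv = 0, mask_error_rate = 0,
                      binucleate_fraction = 0)
  pop <- generate_population(cfg)
  rend <- render_spot_table(pop)
  # all single-molecule spots have intensity exactly 1
  single <- rend$spots$true_molecules == 1
  expect_true(all(rend$spots$intensity_amplitude[single] == 1))
  # the merged TS spot intensity equals its nascent count
  ts_spots <- rend$spots[!single, ]
  expect_equal(ts_spots$intensity_amplitude, ts_spots$true_molecules)
  # per-cell spot-level molecule sums match the truth table
  tot <- rend$spots |>
    dplyr::group_by(cell_id, compartment) |>
    dplyr::summarise(n = sum(true_molecules), .groups = "drop")
  truth <- pop$truth
  cyt <- tot$n[tot$compartment == "cytoplasmic"][
    match(truth$cell_id, tot$cell_id[tot$compartment == "cytoplasmic"])]
  cyt[is.na(cyt)] <- 0
  expect_equal(cyt, truth$true_cytoplasmic)
  nuc <- tot$n[tot$compartment == "nuclear"][
    match(truth$cell_id, tot$cell_id[tot$compartment == "nuclear"])]
  nuc[is.na(nuc)] <- 0
  expect_equal(nuc, truth$true_nuclear + truth$true_nascent)
})

test_that("rendered intensities hit the configured CV and stay unimodal", {
  sp <- model_spec(1, 1, 1, 8, 2, k_D = 1, time_unit = "absolute")
  cfg <- synth_config(sp, n_cells = 2500, seed = 6, intensity_cv = 0.3,
                      binucleate_fraction = 0)
  rend <- render_spot_table(generate_population(cfg))
  spots <- normalize_intensities(rend$spots)
  cyt <- spots$normalized_intensity[spots$compartment == "cytoplasmic" &
                                      spots$true_molecules == 1]
  expect_gt(length(cyt), 1e4)
  cv <- sd(cyt) / mean(cyt)
  expect_gt(cv, 0.27); expect_lt(cv, 0.33)
  # unimodal single-molecule intensity distribution
  expect_equal(subpoisson:::kde_modes(log(cyt)), 1L)
})

test_that("size scaling produces a positive count-size slope but a
           calibrated size-corrected Fano", {
  sp <- model_spec(1, 1, 1, 10, 2, k_D = 1, time_unit = "absolute")
  cfg_on <- synth_config(sp, n_cells = 1200, seed = 7, size_scaling = TRUE,
                         binucleate_fraction = 0)
  pop_on <- generate_population(cfg_on)
  sl_on <- coef(lm(pop_on$truth$true_cytoplasmic ~
                     pop_on$cells$length))[[2]]
  expect_gt(sl_on, 0.2)
  fe <- size_corrected_fano(pop_on$truth$true_cytoplasmic,
                            pop_on$cells$length, n_boot = 500, seed = 1)
  expect_lt(abs(fe$fano - 1), 3 * fe$se)  # Poisson model stays Poisson
  cfg_off <- synth_config(sp, n_cells = 1200, seed = 7,
                          size_scaling = FALSE, binucleate_fraction = 0)
  pop_off <- generate_population(cfg_off)
  sl_off <- coef(lm(pop_off$truth$true_cytoplasmic ~
                      pop_off$cells$length))[[2]]
  expect_lt(abs(sl_off), 3 * abs(sl_on) / 10)
})

test_that("binucleate handling follows the configured fraction and dosage", {
  sp <- model_spec(2, 2, 8, 8, 4)
  cfg0 <- synth_config(sp, n_cells = 300, seed = 8,
                       binucleate_fraction = 0)
  expect_true(all(generate_population(cfg0)$cells$n_nuclei == 1))
  cfg <- synth_config(sp, n_cells = 3000, seed = 9,
                      binucleate_fraction = 0.3,
                      binucleate_multiplier = 2)
  pop <- generate_population(cfg)
  frac <- mean(pop$cells$n_nuclei == 2)
  expect_gt(frac, 0.25); expect_lt(frac, 0.35)
  m1 <- mean(pop$truth$true_cytoplasmic[pop$cells$n_nuclei == 1])
  m2 <- mean(pop$truth$true_cytoplasmic[pop$cells$n_nuclei == 2])
  expect_equal(m2 / m1, 2, tolerance = 0.15)
})

test_that("round trip: spot counts undercount multi-mRNA TS spots,
           hybrid does not, intensity counting inflates the Fano", {
  sp <- model_spec(3, 3, 10, 10, 5)
  cfg <- synth_config(sp, n_cells = 800, seed = 13, nascent_mean = 2)
  rep <- roundtrip_check(cfg, n_boot = 400)
  cb <- rep$count_bias
  nuc_spot <- cb$rel_bias[cb$method == "spot" & cb$compartment == "nuclear"]
  nuc_hyb <- cb$rel_bias[cb$method == "hybrid" & cb$compartment == "nuclear"]
  expect_lt(nuc_spot, -0.1)       # merged TS spots undercounted
  expect_gt(nuc_hyb, -0.05)       # hybrid recovers the multi-mRNA spots
  # spot counts in the cytoplasm (all singleton spots) are near-exact
  cyt_spot <- cb$rel_bias[cb$method == "spot" &
                            cb$compartment == "cytoplasmic"]
  expect_lt(abs(cyt_spot), 0.02)
  # technical intensity noise inflates the intensity-count Fano
  f <- rep$fano
  expect_gte(f$fano_corrected[f$method == "intensity"],
             f$fano_corrected[f$method == "hybrid"])
})
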