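test_that("simulators are deterministic under a fixed seed", {
  expect_identical(simulate_dilution(Ka = 1.71, seed = 5),
                   simulate_dilution(Ka = 1.71, seed = 5))
  expect_identical(simulate_titration(Ka = 5, seed = 5),
                   simulate_titration(Ka = 5, seed = 5))
  expect_identical(simulate_dosy(Ka = 2, rel_noise = 0.02, seed = 5),
                   simulate_dosy(Ka = 2, rel_noise = 0.02, seed = 5))
  expect_identical(simulate_decay(seed = 5), simulate_decay(seed = 5))
  # different seeds give different noise
  expect_false(identical(simulate_decay(seed = 5), simulate_decay(seed = 6)))
})

test_that("zero noise reproduces the forward models exactly", {
  d <- simulate_dilution(Ka = 1.71, noise_sd = 0, seed = 1)
  panel <- dilution_proton_panel()
  row <- d[d$proton == "H12", ]
  i <- which(panel$proton == "H12")
  expect_equal(row$shift_ppm,
               panel$delta_mon[i] -
                 predict_dilution_shift(1.71, row$conc_mM, panel$delta_max[i]))

  t0 <- simulate_titration(Ka = 5, noise_sd = 0, seed = 1)
  tp <- titration_proton_panel()
  rt <- t0[t0$proton == "H11", ]
  j <- which(tp$proton == "H11")
  expect_equal(rt$shift_ppm,
               tp$delta_L[j] + predict_titration_shift(5, rt$C_DNA_mM, rt$C_L_mM,
                                                       tp$delta_complex[j]))

  dec <- simulate_decay(t_half = 50, noise_sd = 0, seed = 1)
  expect_equal(dec$intact_fraction,
               predict_remaining_fraction(log(2) / 50, dec$time_days))
  expect_equal(dec$intact_fraction[1], 1)
})

test_that("default dilution grid spans 0.003 to 1.2 mM in 12 log-spaced points", {
  d <- simulate_dilution(Ka = 1, noise_sd = 0, seed = 1)
  cc <- sort(unique(d$conc_mM))
  expect_length(cc, 12)
  expect_equal(min(cc), 0.003)
  expect_equal(max(cc), 1.2)
  expect_equal(diff(log(cc)), rep(diff(log(c(0.003, 1.2))) / 11, 11))
  expect_equal(length(unique(d$proton)), 6)
})

test_that("default titration design reaches a 1:3 ligand:duplex ratio and brackets half-saturation", {
  t0 <- simulate_titration(Ka = 5, noise_sd = 0, seed = 1)
  expect_equal(max(t0$C_DNA_mM), 3 * max(t0$C_L_mM))
  expect_equal(min(t0$C_DNA_mM), 0)
  expect_equal(length(unique(t0$C_DNA_mM)), 8)

  # the analytic half-saturation duplex level (Ka*[DNA] = 1) lies inside the
  # titrated range: solve C_DNA s.t. free [DNA] = 1/Ka at fixed C_L
  Ka <- 5; C_L <- unique(t0$C_L_mM)
  dna_half <- 1 / Ka
  C_DNA_half <- dna_half + C_L * Ka * dna_half / (1 + Ka * dna_half)
  expect_true(C_DNA_half > min(t0$C_DNA_mM) && C_DNA_half < max(t0$C_DNA_mM))
  dd_half <- predict_titration_shift(Ka, C_DNA_half, C_L, 1)
  expect_equal(dd_half, 0.5, tolerance = 1e-10)
})

test_that("dosy simulator honours the no-binding limit and relative-noise contract", {
  r0 <- simulate_dosy(Ka = 0, C_L = 0.1, C_DNA = 0.3)
  expect_equal(r0$D_obs_L, r0$D_L_free)
  rn <- simulate_dosy(Ka = 2, rel_noise = 0.02, seed = 8)
  r_clean <- simulate_dosy(Ka = 2, rel_noise = 0)
  expect_false(identical(rn$D_obs_L, r_clean$D_obs_L))
  expect_lt(abs(rn$D_obs_L / r_clean$D_obs_L - 1), 0.1)
})

test_that("decay simulator truncates noisy fractions to [0, 1]", {
  d <- simulate_decay(t_half = 5, times = seq(0, 100, 5), noise_sd = 0.2, seed = 21)
  expect_true(all(d$intact_fraction >= 0 & d$intact_fraction <= 1))
  raw <- simulate_decay(t_half = 5, times = seq(0, 100, 5), noise_sd = 0.2,
                        truncate = FALSE, seed = 21)
  expect_true(any(raw$intact_fraction < 0 | raw$intact_fraction > 1))
})
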