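test_that("monomer concentration matches the mass balance and its limits", {
  expect_identical(monomer_concentration(0, 2), 2)
  expect_equal(monomer_concentration(1, 2), 0.5, tolerance = 1e-12)

  # closed form agrees with brute-force root solving over a log grid
  for (Ka in c(0.01, 0.1, 1, 10, 100)) {
    for (L0 in c(0.003, 0.05, 1.2, 10)) {
      L <- monomer_concentration(Ka, L0)
      expect_equal(L, oracle_monomer(Ka, L0), tolerance = 1e-10)
      expect_equal(L / (1 - Ka * L)^2, L0, tolerance = 1e-10)
      expect_true(L > 0 && L <= L0)
    }
  }

  # saturation: [L] decreases monotonically in Ka
  Ls <- monomer_concentration(10^seq(-2, 4, length.out = 30), 2)
  expect_true(all(diff(Ls) < 0))

  expect_error(monomer_concentration(-1, 1), class = "nmrbind_domain_error")
  expect_error(monomer_concentration(1, 0), class = "nmrbind_domain_error")
  expect_error(monomer_concentration(NaN, 1), class = "nmrbind_domain_error")
})

test_that("oligomer distribution is the isodesmic geometric ladder and conserves mass", {
  expect_equal(oligomer_distribution(1, 2, 3), c(0.5, 0.25, 0.125), tolerance = 1e-12)
  expect_equal(oligomer_distribution(0, 1, 5), c(1, 0, 0, 0, 0))

  for (Ka in c(0.1, 1, 5)) {
    for (L0 in c(0.1, 1, 2)) {
      if (Ka * L0 > 10) next
      conc <- oligomer_distribution(Ka, L0, 200)
      expect_lt(abs(L0 - sum(seq_along(conc) * conc)), 1e-6)
    }
  }
})

test_that("the dilution shift factor equals Ka*[L] and behaves at both limits", {
  expect_identical(predict_dilution_shift(0, 5, 1), 0)
  expect_equal(predict_dilution_shift(1, 2, 1), 0.5, tolerance = 1e-12)

  grid <- expand.grid(Ka = 10^seq(-2, 3, length.out = 12),
                      L0 = 10^seq(-3, 1, length.out = 12))
  factor_form <- predict_dilution_shift(grid$Ka, grid$L0, 1)
  identity_form <- grid$Ka * monomer_concentration(grid$Ka, grid$L0)
  expect_equal(factor_form, identity_form, tolerance = 1e-12)

  # monotone increasing in L0 and Ka; saturates at delta_max
  L0s <- 10^seq(-3, 2, length.out = 50)
  expect_true(all(diff(predict_dilution_shift(1, L0s, 0.4)) > 0))
  Kas <- 10^seq(-2, 4, length.out = 50)
  expect_true(all(diff(predict_dilution_shift(Kas, 1, 0.4)) > 0))
  expect_equal(predict_dilution_shift(1e8, 1, 0.4), 0.4, tolerance = 1e-3)
  expect_true(all(predict_dilution_shift(Kas, 1, 0.4) <= 0.4))
})

test_that("noiseless dilution fits recover the generating parameters exactly", {
  d <- simulate_dilution(Ka = 1.71, noise_sd = 0, seed = 1)
  fit <- fit_isodesmic(d)
  expect_lt(abs(fit$Ka_mean - 1.71) / 1.71, 1e-6)
  pp <- dplyr::arrange(tidy(fit), proton)
  panel <- dplyr::arrange(dilution_proton_panel(), proton)
  expect_equal(pp$delta_mon, panel$delta_mon, tolerance = 1e-6)
  expect_equal(pp$delta_max, panel$delta_max, tolerance = 1e-4)
  expect_true(all(pp$Ka >= 0))

  # global mode: one shared Ka, same recovery on noiseless data
  gfit <- fit_isodesmic(d, mode = "global")
  expect_lt(abs(gfit$Ka_mean - 1.71) / 1.71, 1e-6)
  expect_equal(length(unique(tidy(gfit)$Ka)), 1L)
})

test_that("per-proton pooling is the arithmetic mean and SD of per-proton Ka", {
  d <- simulate_dilution(Ka = 1.2, noise_sd = 0.002, seed = 7)
  fit <- fit_isodesmic(d)
  used <- fit$per_proton[!fit$per_proton$excluded, ]
  expect_equal(fit$Ka_mean, mean(used$Ka))
  expect_equal(fit$Ka_sd, sd(used$Ka))
})

test_that("flat series are flagged and excluded from the pooled mean", {
  panel <- dilution_proton_panel()
  panel$delta_max[1] <- 1e-4  # essentially unresponsive proton
  d <- simulate_dilution(Ka = 1.71, protons = panel, noise_sd = 0.0005, seed = 3)
  fit <- fit_isodesmic(d, noise_floor = 0.002)
  expect_true(fit$per_proton$excluded[fit$per_proton$proton == panel$proton[1]])
  used <- fit$per_proton[!fit$per_proton$excluded, ]
  expect_equal(fit$Ka_mean, mean(used$Ka))
})

test_that("dilution fit validates its input contract", {
  d <- simulate_dilution(Ka = 1, noise_sd = 0, seed = 1)
  expect_error(fit_isodesmic(d[, c("proton", "conc_mM")]),
               class = "nmrbind_schema_error")
  short <- d[d$conc_mM > 0.4, ]  # 3 concentrations per proton
  expect_error(fit_isodesmic(short), class = "nmrbind_schema_error")
  bad <- d; bad$conc_mM[1] <- -1
  expect_error(fit_isodesmic(bad), class = "nmrbind_schema_error")
  narrow <- simulate_dilution(Ka = 1, conc = seq(0.5, 1.2, length.out = 6),
                              noise_sd = 0, seed = 1)
  w <- capture_warnings(fit_isodesmic(narrow))  # one warning per proton
  expect_true(all(grepl("decade", w)) && length(w) == 6)
})

test_that("Ka_mean is recovered with small bias over replicate noisy datasets", {
  reps <- 200
  est <- vapply(seq_len(reps), function(s) {
    d <- simulate_dilution(Ka = 1.71, noise_sd = 0.002, seed = 5000 + s)
    suppressWarnings(fit_isodesmic(d))$Ka_mean
  }, numeric(1))
  bias <- mean(est) - 1.71
  expect_lt(abs(bias), 0.05 * 1.71)
})
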