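test_that("free duplex concentration is the physical root of the 1:1 quadratic", {
  expect_equal(free_dna_concentration(0, 1, 1), 1)
  expect_equal(free_dna_concentration(1, 1, 1), (sqrt(5) - 1) / 2, tolerance = 1e-12)
  expect_equal(free_dna_concentration(7, 0.5, 0), 0.5)

  # mass action and both mass balances hold on back-substitution
  set.seed(42)
  for (i in 1:40) {
    Ka <- 10^runif(1, -2, 2)
    C_DNA <- 10^runif(1, -2, 1)
    C_L <- 10^runif(1, -2, 1)
    dna <- free_dna_concentration(Ka, C_DNA, C_L)
    expect_equal(dna, oracle_free_dna(Ka, C_DNA, C_L), tolerance = 1e-10)
    cx <- C_DNA - dna
    L <- C_L - cx
    expect_equal(dna + cx, C_DNA, tolerance = 1e-10)
    expect_equal(L + cx, C_L, tolerance = 1e-10)
    expect_equal(cx / (dna * L), Ka, tolerance = 1e-10)
    expect_true(dna >= max(0, C_DNA - C_L) - 1e-12 && dna <= C_DNA + 1e-12)
  }
  expect_error(free_dna_concentration(-1, 1, 1), class = "nmrbind_domain_error")
})

test_that("titration shift model is the bounded 1:1 isotherm in both conventions", {
  # half-saturation: Ka*[DNA] = 1 gives half the limiting shift
  expect_equal(predict_titration_shift(2, 0.5, 1e-9, 1, "total_approx"), 0.5,
               tolerance = 1e-9)
  expect_equal(predict_titration_shift(1, 1, 1, 1, "free_exact"),
               ((sqrt(5) - 1) / 2) / (1 + (sqrt(5) - 1) / 2), tolerance = 1e-12)
  expect_equal(predict_titration_shift(1, 1, 1, 1, "free_exact"), 0.382,
               tolerance = 1e-3)
  # saturation limit
  expect_equal(predict_titration_shift(1, 1e7, 1, 0.4, "free_exact"), 0.4,
               tolerance = 1e-5)

  # conventions agree under large duplex excess and mild binding
  dd_free <- predict_titration_shift(0.5, 2.0, 0.05, 1, "free_exact")
  dd_tot <- predict_titration_shift(0.5, 2.0, 0.05, 1, "total_approx")
  expect_lt(abs(dd_free - dd_tot) / abs(dd_free), 0.01)

  # bound fraction monotone in C_DNA and Ka, confined to [0, 1)
  cds <- seq(0.01, 5, length.out = 60)
  bf <- predict_titration_shift(2, cds, 0.3, 1, "free_exact")
  expect_true(all(diff(bf) > 0) && all(bf >= 0 & bf < 1))
  kas <- 10^seq(-2, 3, length.out = 60)
  bfk <- predict_titration_shift(kas, 0.9, 0.3, 1, "free_exact")
  expect_true(all(diff(bfk) > 0) && all(bfk >= 0 & bfk < 1))
})

test_that("noiseless titration fits recover the generating parameters exactly", {
  t0 <- simulate_titration(Ka = 5, noise_sd = 0, seed = 1)
  fit <- fit_binding_titration(t0)
  expect_lt(abs(fit$Ka_mean - 5) / 5, 1e-6)
  pp <- dplyr::arrange(tidy(fit), proton)
  panel <- dplyr::arrange(titration_proton_panel(), proton)
  expect_equal(pp$delta_complex, panel$delta_complex, tolerance = 1e-5)

  # total_approx round trip under its own convention
  t1 <- simulate_titration(Ka = 3.76, noise_sd = 0, dna_mode = "total_approx", seed = 2)
  fit1 <- fit_binding_titration(t1, dna_mode = "total_approx")
  expect_lt(abs(fit1$Ka_mean - 3.76) / 3.76, 1e-6)
})

test_that("free and total duplex conventions give compatible Ka under duplex excess", {
  panel <- titration_proton_panel()
  t0 <- simulate_titration(Ka = 0.5, protons = panel, C_L = 0.02,
                           C_DNA = seq(0, 2, length.out = 9),
                           noise_sd = 0, seed = 3)
  ka_free <- fit_binding_titration(t0, dna_mode = "free_exact")$Ka_mean
  ka_tot <- fit_binding_titration(t0, dna_mode = "total_approx")$Ka_mean
  expect_lt(abs(ka_free - ka_tot) / ka_free, 0.05)
})

test_that("weak saturation triggers the poorly-constrained warning", {
  t0 <- simulate_titration(Ka = 0.05, C_L = 0.05,
                           C_DNA = seq(0, 0.15, length.out = 8),
                           noise_sd = 0, seed = 4)
  w <- capture_warnings(fit_binding_titration(t0))  # one warning per proton
  expect_true(all(grepl("poorly constrained", w)) && length(w) == 6)
})

test_that("self-association baseline drift biases fixed-baseline fits and the correction reduces it", {
  sa <- data.frame(proton = titration_proton_panel()$proton,
                   Ka_self = 1.71,
                   delta_mon = titration_proton_panel()$delta_L,
                   delta_max = c(0.25, 0.32, 0.40, 0.35, 0.12, -0.06))
  true_Ka <- 5
  td <- simulate_titration(Ka = true_Ka, C_L = 0.6, noise_sd = 0,
                           self_assoc = sa, seed = 5)
  fit_fixed <- suppressWarnings(fit_binding_titration(td))
  fit_corr <- suppressWarnings(
    fit_binding_titration(td, baseline_mode = "self_assoc", self_assoc = sa))
  err_fixed <- abs(fit_fixed$Ka_mean - true_Ka)
  err_corr <- abs(fit_corr$Ka_mean - true_Ka)
  expect_gt(err_fixed, err_corr)
  expect_lt(err_corr / true_Ka, 1e-4)
})

test_that("titration and diffusion routes agree on data generated at the same Ka", {
  true_Ka <- 5
  td <- simulate_titration(Ka = true_Ka, noise_sd = 0.003, seed = 6)
  ka_tit <- fit_binding_titration(td)
  rec <- simulate_dosy(Ka = true_Ka, C_L = 0.1, C_DNA = 0.3)
  ka_dosy <- ka_from_diffusion(rec)$Ka_mM_inv
  expect_lt(abs(ka_tit$Ka_mean - ka_dosy), 2 * max(ka_tit$Ka_sd, 0.1))
})

test_that("titration fit validates its input contract", {
  t0 <- simulate_titration(Ka = 5, noise_sd = 0, seed = 1)
  expect_error(fit_binding_titration(t0[, 1:3]), class = "nmrbind_schema_error")
  no_base <- t0[t0$C_DNA_mM > 0, ]
  expect_error(fit_binding_titration(no_base), class = "nmrbind_schema_error")
  base <- dplyr::distinct(t0[t0$C_DNA_mM == 0, c("proton")])
  base$delta_L_ppm <- titration_proton_panel()$delta_L[
    match(base$proton, titration_proton_panel()$proton)]
  fit <- fit_binding_titration(no_base, baseline = base)
  expect_lt(abs(fit$Ka_mean - 5) / 5, 1e-6)
})
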