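#' Default proton panel for the dilution simulator
#'
#' Six aromatic/aliphatic protons of a camptothecin-like stacking ligand with
#' heterogeneous limiting shift changes, including one sign-reversed proton
#' (a ring-current edge case seen in real stacking systems).  `delta_mon` is
#' the infinite-dilution shift, `delta_max` the monomer-to-oligomer limit,
#' both in ppm.
#'
#' @return A tibble with columns `proton`, `delta_mon`, `delta_max`.
#' @export
dilution_proton_panel <- function() {
  tibble::tibble(
    proton = c("H5", "H11", "H12", "H14", "H19", "H23"),
    delta_mon = c(5.45, 7.62, 7.98, 7.35, 1.38, 8.10),
    delta_max = c(0.25, 0.32, 0.40, 0.35, 0.12, -0.06)
  )
}

#' Default proton panel for the titration simulator
#'
#' Limiting complexation shift changes `delta_complex` (ppm, mostly negative:
#' upfield shifts from mutual ring-current shielding on stacking with the
#' terminal G-C base pair, with one sign-reversed proton) and free-ligand
#' baseline shifts `delta_L` (ppm).
#'
#' @return A tibble with columns `proton`, `delta_L`, `delta_complex`.
#' @export
titration_proton_panel <- function() {
  tibble::tibble(
    proton = c("H5", "H11", "H12", "H14", "H19", "H23"),
    delta_L = c(5.40, 7.55, 7.90, 7.28, 1.36, 8.11),
    delta_complex = c(-0.45, -0.35, -0.52, -0.30, 0.08, -0.12)
  )
}

#' Simulate a dilution chemical-shift experiment
#'
#' Generates per-proton observed shifts over a concentration grid from the
#' isodesmic forward model, `shift = delta_mon -
#' predict_dilution_shift(Ka, conc, delta_max) + N(0, noise_sd)`.  The default
#' grid is 12 log-spaced concentrations from 0.003 to 1.2 mM, the span over
#' which stacking of a millimolar-Ka ligand is resolvable by NMR dilution.
#'
#' @param Ka True self-association constant, 1/mM.
#' @param protons Data frame `proton`, `delta_mon`, `delta_max`; default
#'   [dilution_proton_panel()].
#' @param conc Concentration grid, mM; default
#'   `exp(seq(log(0.003), log(1.2), length.out = 12))`.
#' @param noise_sd Gaussian shift noise, ppm; default 0.002 (a typical
#'   shift-reading error).
#' @param seed Optional integer seed; identical seed gives identical data.
#'
#' @return A tibble `proton`, `conc_mM`, `shift_ppm`, ready for
#'   [fit_isodesmic()].
#'
#' @examples
#' d <- simulate_dilution(Ka = 1.71, seed = 42)
#' @export
simulate_dilution <- function(Ka,
                              protons = dilution_proton_panel(),
                              conc = exp(seq(log(0.003), log(1.2), length.out = 12)),
                              noise_sd = 0.002,
                              seed = NULL) {
  check_nonneg(Ka, "Ka")
  check_positive(conc, "conc")
  check_nonneg(noise_sd, "noise_sd")
  check_columns(protons, c("proton", "delta_mon", "delta_max"),
                numeric_cols = c("delta_mon", "delta_max"), what = "protons")
  if (length(conc) < 2) stop_domain("concentration grid needs at least 2 points")
  conc <- sort(conc)
  with_optional_seed(seed, {
    out <- tidyr::expand_grid(protons, conc_mM = conc)
    out$shift_ppm <- out$delta_mon -
      predict_dilution_shift(Ka, out$conc_mM, out$delta_max) +
      rnorm(nrow(out), 0, noise_sd)
    dplyr::select(out, "proton", "conc_mM", "shift_ppm")
  })
}

#' Simulate a DNA-ligand chemical-shift titration
#'
#' Generates observed ligand shifts while duplex is titrated into a fixed
#' ligand concentration, from the 1:1 binding forward model
#' ([predict_titration_shift()]).  The default design holds `C_L` fixed and
#' steps `C_DNA` from 0 to `3 * C_L` in 8 points, reaching a 1:3
#' ligand:duplex ratio.  Optionally the free-ligand baseline is made to drift
#' with its own self-association (via `self_assoc`): as duplex withdraws
#' monomer into the complex, the residual ligand de-stacks and its reference
#' shift moves — the realistic confound for protons dominated by
#' self-stacking.
#'
#' @param Ka True binding constant, 1/mM.
#' @param protons Data frame `proton`, `delta_L`, `delta_complex`; default
#'   [titration_proton_panel()].
#' @param C_L Total ligand concentration, mM.
#' @param C_DNA Duplex grid, mM; default `seq(0, 3 * C_L, length.out = 8)`.
#' @param noise_sd Gaussian shift noise, ppm; default 0.003.
#' @param dna_mode Forward-model convention, `"free_exact"` (default) or
#'   `"total_approx"`.
#' @param self_assoc Optional data frame `proton`, `Ka_self`, `delta_mon`,
#'   `delta_max`; when given, `delta_L` is replaced by the isodesmic shift at
#'   the residual free-ligand concentration (see Details).
#' @param seed Optional integer seed.
#'
#' @return A tibble `proton`, `C_L_mM`, `C_DNA_mM`, `shift_ppm` (the
#'   `C_DNA_mM = 0` rows carry the baseline), ready for
#'   [fit_binding_titration()].
#'
#' @examples
#' t <- simulate_titration(Ka = 5, seed = 7)
#' @export
simulate_titration <- function(Ka,
                               protons = titration_proton_panel(),
                               C_L = 0.3,
                               C_DNA = seq(0, 3 * C_L, length.out = 8),
                               noise_sd = 0.003,
                               dna_mode = c("free_exact", "total_approx"),
                               self_assoc = NULL,
                               seed = NULL) {
  dna_mode <- match.arg(dna_mode)
  check_nonneg(Ka, "Ka")
  check_positive(C_L, "C_L")
  check_nonneg(C_DNA, "C_DNA")
  check_nonneg(noise_sd, "noise_sd")
  check_columns(protons, c("proton", "delta_L", "delta_complex"),
                numeric_cols = c("delta_L", "delta_complex"), what = "protons")
  if (length(C_DNA) < 2) stop_domain("duplex grid needs at least 2 points")
  C_DNA <- sort(C_DNA)
  if (!is.null(self_assoc)) {
    check_columns(self_assoc, c("proton", "Ka_self", "delta_mon", "delta_max"),
                  numeric_cols = c("Ka_self", "delta_mon", "delta_max"),
                  what = "self_assoc")
  }
  with_optional_seed(seed, {
    out <- tidyr::expand_grid(protons, C_DNA_mM = C_DNA)
    out$C_L_mM <- C_L
    if (is.null(self_assoc)) {
      base <- out$delta_L
    } else {
      sa <- dplyr::left_join(out["proton"], self_assoc, by = "proton")
      cx <- complex_concentration(Ka, out$C_DNA_mM, out$C_L_mM)
      free_L <- pmax(out$C_L_mM - cx, 1e-9)
      base <- sa$delta_mon -
        predict_dilution_shift(sa$Ka_self, free_L, sa$delta_max)
    }
    dd <- predict_titration_shift(Ka, out$C_DNA_mM, out$C_L_mM,
                                  out$delta_complex, dna_mode)
    out$shift_ppm <- base + dd + rnorm(nrow(out), 0, noise_sd)
    dplyr::select(out, "proton", "C_L_mM", "C_DNA_mM", "shift_ppm")
  })
}

#' Simulate fast-exchange diffusion (DOSY) records
#'
#' Generates mixture diffusion records from the population-weighted averaging
#' forward model ([predict_observed_diffusion()]), optionally with relative
#' Gaussian noise on every measured coefficient.  Default free coefficients
#' are typical of a camptothecin-sized ligand (4.0e-10 m^2/s) and an 8-mer
#' DNA duplex (1.3e-10 m^2/s) in water near ambient temperature.
#'
#' @param Ka True binding constant, 1/mM.
#' @param C_L,C_DNA Total concentrations, mM (vectorised in parallel; one
#'   record per element).
#' @param D_L_free,D_DNA_free Free-species diffusion coefficients, m^2/s.
#' @param rel_noise Relative Gaussian noise applied to `D_obs_L`, `D_obs_DNA`
#'   and the reported `D_L_free`; default 0 (noiseless).
#' @param seed Optional integer seed.
#'
#' @return A tibble of diffusion records with the columns expected by
#'   [ka_from_diffusion()].
#'
#' @examples
#' simulate_dosy(Ka = 5.9, C_L = 0.1, C_DNA = 0.3)
#' @export
simulate_dosy <- function(Ka,
                          C_L = 0.3,
                          C_DNA = 0.9,
                          D_L_free = 4.0e-10,
                          D_DNA_free = 1.3e-10,
                          rel_noise = 0,
                          seed = NULL) {
  check_nonneg(rel_noise, "rel_noise")
  pred <- predict_observed_diffusion(Ka, C_L, C_DNA, D_L_free, D_DNA_free)
  n <- nrow(pred)
  with_optional_seed(seed, {
    noise <- function(x) x * (1 + rnorm(n, 0, rel_noise))
    tibble::tibble(
      sample_id = sprintf("mix%02d", seq_len(n)),
      C_L_mM = pred$C_L_mM, C_DNA_mM = pred$C_DNA_mM,
      D_obs_L = noise(pred$D_obs_L),
      D_obs_DNA = noise(pred$D_obs_DNA),
      D_L_free = noise(rep_len(D_L_free, n)),
      D_DNA_free = rep_len(D_DNA_free, n)
    )
  })
}

#' Simulate a degradation time course
#'
#' First-order (or zero-order) decay of the intact fraction with additive
#' Gaussian noise.  Noisy values are truncated to `[0, 1]` when
#' `truncate = TRUE` (fractions outside that range are unphysical); the
#' truncation slightly biases points near the boundaries and is therefore
#' optional.
#'
#' @param t_half True half-life, days; default 50.
#' @param times Sampling times, days; default 11 points over 0-100 d.
#' @param noise_sd Gaussian noise on the fraction; default 0.02.
#' @param order Kinetic order, 1 (default) or 0.
#' @param truncate Truncate noisy fractions to `[0, 1]`; default TRUE.
#' @param seed Optional integer seed.
#'
#' @return A tibble `time_days`, `intact_fraction`, ready for [fit_decay()].
#'
#' @examples
#' simulate_decay(t_half = 50, seed = 3)
#' @export
simulate_decay <- function(t_half = 50,
                           times = seq(0, 100, length.out = 11),
                           noise_sd = 0.02,
                           order = 1,
                           truncate = TRUE,
                           seed = NULL) {
  check_positive(t_half, "t_half")
  check_nonneg(times, "times")
  check_nonneg(noise_sd, "noise_sd")
  times <- sort(times)
  k <- if (order == 1) log(2) / t_half else 1 / (2 * t_half)
  with_optional_seed(seed, {
    f <- predict_remaining_fraction(k, times, A0 = 1, order = order) +
      rnorm(length(times), 0, noise_sd)
    if (truncate) f <- pmin(pmax(f, 0), 1)
    tibble::tibble(time_days = times, intact_fraction = f)
  })
}
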