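#' Mole fraction of free ligand from an averaged diffusion coefficient
#'
#' Under fast exchange the observed ligand diffusion coefficient is the
#' population-weighted average of the free and complexed species,
#' `D_obs = MF * D_free + (1 - MF) * D_complex`, so
#' `MF = (D_obs - D_complex) / (D_free - D_complex)`.
#'
#' Values slightly outside `[0, 1]` (up to `tol`) arise from measurement noise
#' and are clipped with a warning; larger excursions are an error because they
#' signal an inconsistent record.
#'
#' @param D_obs_L Observed ligand diffusion coefficient, m^2/s.
#' @param D_L_free Free-ligand diffusion coefficient at matched concentration.
#' @param D_complex Diffusion coefficient of the complex.
#' @param tol Absolute clipping tolerance outside `[0, 1]`; default 0.02.
#'
#' @return Mole fraction of free ligand in `[0, 1]`, vectorised.
#'
#' @examples
#' mole_fraction_free(2.75e-10, 4.0e-10, 1.5e-10)  # 0.5
#' @export
mole_fraction_free <- function(D_obs_L, D_L_free, D_complex, tol = 0.02) {
  check_positive(D_obs_L, "D_obs_L")
  check_positive(D_L_free, "D_L_free")
  check_positive(D_complex, "D_complex")
  denom <- D_L_free - D_complex
  if (any(abs(denom) < 1e-3 * pmax(D_L_free, D_complex))) {
    stop_domain("free and complexed diffusion indistinguishable (degenerate denominator)")
  }
  mf <- (D_obs_L - D_complex) / denom
  out_lo <- mf < -tol
  out_hi <- mf > 1 + tol
  if (any(out_lo | out_hi)) {
    stop_domain("mole fraction %.3f outside [0, 1] beyond tolerance %.3g: observed diffusion inconsistent with the free/complex references",
                mf[which(out_lo | out_hi)[1]], tol)
  }
  if (any(mf < 0 | mf > 1)) {
    warn("mole fraction slightly outside [0, 1]; clipped (measurement noise)")
  }
  pmin(pmax(mf, 0), 1)
}

#' Binding constant from fast-exchange diffusion measurements
#'
#' Closed-form 1:1 binding constant from a set of diffusion (DOSY) records.
#' Because the duplex is much larger than the ligand, the complex diffuses
#' like the duplex, so the observed duplex coefficient stands in for the
#' complex: `D_complex ~= D_obs_DNA`.  Then per record:
#' mole fraction of free ligand `MF_L` from [mole_fraction_free()];
#' complex concentration `[DNA.L] = (1 - MF_L) * C_L`; and
#' `Ka = [DNA.L] / ((C_DNA - [DNA.L]) * (C_L - [DNA.L]))`.
#' This is the exact algebraic inverse of [predict_observed_diffusion()].
#'
#' @param data Data frame of diffusion records with columns `sample_id`,
#'   `C_L_mM`, `C_DNA_mM`, `D_obs_L`, `D_obs_DNA`, `D_L_free`, `D_DNA_free`
#'   (D in m^2/s; `D_L_free` measured on ligand alone at matched
#'   concentration, `C_DNA_mM` counted in duplexes).
#' @param tol Mole-fraction clipping tolerance, see [mole_fraction_free()].
#'
#' @return A tibble, one row per record: `sample_id`, `mf_L_free`,
#'   `complex_mM`, `Ka_mM_inv`, and `assumption_flag` recording the
#'   `D_complex ~= D_obs_DNA` convention.
#'
#' @examples
#' rec <- data.frame(sample_id = "s1", C_L_mM = 0.3, C_DNA_mM = 0.9,
#'                   D_obs_L = 2.75e-10, D_obs_DNA = 1.5e-10,
#'                   D_L_free = 4.0e-10, D_DNA_free = 1.5e-10)
#' ka_from_diffusion(rec)  # Ka = 4/3
#' @export
ka_from_diffusion <- function(data, tol = 0.02) {
  check_columns(data,
                c("sample_id", "C_L_mM", "C_DNA_mM", "D_obs_L", "D_obs_DNA",
                  "D_L_free", "D_DNA_free"),
                numeric_cols = c("C_L_mM", "C_DNA_mM", "D_obs_L", "D_obs_DNA",
                                 "D_L_free", "D_DNA_free"),
                what = "diffusion records")
  if (any(data$C_L_mM <= 0) || any(data$C_DNA_mM <= 0)) {
    stop_schema("diffusion records need C_L_mM > 0 and C_DNA_mM > 0")
  }
  if (any(data$D_DNA_free >= data$D_L_free)) {
    stop_schema("expected D_DNA_free < D_L_free (the duplex is the larger species)")
  }
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    r <- data[i, ]
    mf <- mole_fraction_free(r$D_obs_L, r$D_L_free, r$D_obs_DNA, tol = tol)
    cx <- (1 - mf) * r$C_L_mM
    if (cx >= r$C_DNA_mM - 1e-12 || cx >= r$C_L_mM - 1e-12) {
      if (mf == 0) stop_domain("sample %s: saturated - Ka unbounded", r$sample_id)
      stop_domain("sample %s: complex concentration %.4g mM exhausts a total concentration - Ka unbounded",
                  r$sample_id, cx)
    }
    tibble::tibble(
      sample_id = r$sample_id, mf_L_free = mf, complex_mM = cx,
      Ka_mM_inv = cx / ((r$C_DNA_mM - cx) * (r$C_L_mM - cx)),
      assumption_flag = "D_complex = D_obs_DNA"
    )
  })
}

#' Forward model for fast-exchange-averaged diffusion coefficients
#'
#' Given a binding constant and total concentrations, computes the complex
#' concentration from the 1:1 quadratic (shared with the titration module),
#' the free mole fractions of ligand and duplex, and the observed averaged
#' diffusion coefficients, taking the complex to diffuse like the free duplex
#' (`D_complex = D_DNA_free`; the observed duplex coefficient is then equal
#' to `D_DNA_free` whatever the populations).
#'
#' @inheritParams free_dna_concentration
#' @param C_L Total ligand concentration, mM (> 0).
#' @param C_DNA Total duplex concentration, mM (> 0).
#' @param D_L_free Free-ligand diffusion coefficient, m^2/s.
#' @param D_DNA_free Free-duplex diffusion coefficient, m^2/s
#'   (< `D_L_free`).
#'
#' @return A tibble with `C_L_mM`, `C_DNA_mM`, `D_obs_L`, `D_obs_DNA`,
#'   `mf_L_free`, `mf_DNA_free`, `complex_mM`, vectorised over the inputs.
#'
#' @examples
#' predict_observed_diffusion(Ka = 5.9, C_L = 0.1, C_DNA = 0.3,
#'                            D_L_free = 4.0e-10, D_DNA_free = 1.3e-10)
#' @export
predict_observed_diffusion <- function(Ka, C_L, C_DNA, D_L_free, D_DNA_free) {
  check_nonneg(Ka, "Ka")
  check_positive(C_L, "C_L")
  check_positive(C_DNA, "C_DNA")
  check_positive(D_L_free, "D_L_free")
  check_positive(D_DNA_free, "D_DNA_free")
  if (any(D_DNA_free >= D_L_free)) {
    stop_domain("expected D_DNA_free < D_L_free (the duplex is the larger species)")
  }
  cx <- complex_concentration(Ka, C_DNA, C_L)
  mf_L <- (C_L - cx) / C_L
  mf_DNA <- (C_DNA - cx) / C_DNA
  tibble::tibble(
    C_L_mM = rep_len(C_L, length(cx)), C_DNA_mM = rep_len(C_DNA, length(cx)),
    D_obs_L = mf_L * D_L_free + (1 - mf_L) * D_DNA_free,
    D_obs_DNA = mf_DNA * D_DNA_free + (1 - mf_DNA) * D_DNA_free,
    mf_L_free = mf_L, mf_DNA_free = mf_DNA, complex_mM = cx
  )
}

#' Monte-Carlo error propagation for diffusion-derived binding constants
#'
#' Perturbs every measured diffusion coefficient of each record with relative
#' Gaussian noise and recomputes `Ka`, summarising the resulting distribution.
#' Draws that land in a saturated or inconsistent region are dropped (and
#' counted), mirroring how such measurements would be rejected in practice.
#'
#' @param data Diffusion records as in [ka_from_diffusion()].
#' @param rel_sd Relative standard deviation applied to `D_obs_L`,
#'   `D_obs_DNA` and `D_L_free`; default 0.02 (2 %).
#' @param n Number of Monte-Carlo draws per record.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A tibble per record: `sample_id`, `Ka_mM_inv` (point estimate),
#'   `Ka_median`, `Ka_q025`, `Ka_q975`, `n_valid`.
#' @export
dosy_mc_error <- function(data, rel_sd = 0.02, n = 1000, seed = NULL) {
  check_nonneg(rel_sd, "rel_sd")
  point <- ka_from_diffusion(data)
  with_optional_seed(seed, {
    purrr::map_dfr(seq_len(nrow(data)), function(i) {
      r <- data[i, ]
      draws <- purrr::map_dbl(seq_len(n), function(j) {
        pert <- r
        pert$D_obs_L <- r$D_obs_L * (1 + rnorm(1, 0, rel_sd))
        pert$D_obs_DNA <- r$D_obs_DNA * (1 + rnorm(1, 0, rel_sd))
        pert$D_L_free <- r$D_L_free * (1 + rnorm(1, 0, rel_sd))
        tryCatch(suppressWarnings(ka_from_diffusion(pert)$Ka_mM_inv),
                 error = function(e) NA_real_)
      })
      ok <- draws[!is.na(draws)]
      tibble::tibble(
        sample_id = r$sample_id,
        Ka_mM_inv = point$Ka_mM_inv[i],
        Ka_median = median(ok), Ka_q025 = quantile(ok, 0.025),
        Ka_q975 = quantile(ok, 0.975), n_valid = length(ok)
      )
    })
  })
}
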