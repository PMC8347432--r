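#' Equilibrium free-duplex concentration for 1:1 binding
#'
#' For the 1:1 equilibrium `DNA + L <-> DNA.L` with constant
#' `Ka = [DNA.L]/([DNA][L])`, the free duplex concentration is the unique
#' non-negative root of
#' `Ka*[DNA]^2 + (1 + Ka*C_L - Ka*C_DNA)*[DNA] - C_DNA = 0`,
#' where `C_DNA` and `C_L` are total (analytical) duplex and ligand
#' concentrations.
#'
#' @param Ka Binding constant, 1/mM. Non-negative.
#' @param C_DNA Total duplex concentration, mM (duplexes, not strands).
#' @param C_L Total ligand concentration, mM.
#'
#' @return Free duplex concentration in mM, in
#'   `[max(0, C_DNA - C_L), C_DNA]`. Vectorised.
#'
#' @examples
#' free_dna_concentration(Ka = 1, C_DNA = 1, C_L = 1)  # (sqrt(5) - 1)/2
#' @export
free_dna_concentration <- function(Ka, C_DNA, C_L) {
  check_nonneg(Ka, "Ka")
  check_nonneg(C_DNA, "C_DNA")
  check_nonneg(C_L, "C_L")
  n <- max(length(Ka), length(C_DNA), length(C_L))
  Ka <- rep_len(Ka, n); C_DNA <- rep_len(C_DNA, n); C_L <- rep_len(C_L, n)
  out <- numeric(n)
  zero <- Ka == 0
  out[zero] <- C_DNA[zero]
  if (any(!zero)) {
    k <- Ka[!zero]; cd <- C_DNA[!zero]; cl <- C_L[!zero]
    b <- 1 + k * (cl - cd)
    # root via the numerically stable branch of the quadratic formula
    disc <- sqrt(b^2 + 4 * k * cd)
    out[!zero] <- ifelse(b >= 0, 2 * cd / (b + disc), (disc - b) / (2 * k))
  }
  pmin(pmax(out, 0), C_DNA)
}

#' Complex concentration for 1:1 binding
#'
#' Convenience companion of [free_dna_concentration()]:
#' `[DNA.L] = C_DNA - [DNA]`.
#'
#' @inheritParams free_dna_concentration
#' @return Complex concentration in mM, vectorised.
#' @export
complex_concentration <- function(Ka, C_DNA, C_L) {
  C_DNA - free_dna_concentration(Ka, C_DNA, C_L)
}

#' Predicted titration shift change for 1:1 binding
#'
#' Forward model for the fast-exchange-averaged shift change of a ligand
#' proton during titration with a DNA duplex:
#' `dd = delta_complex * Ka*[DNA] / (1 + Ka*[DNA])`,
#' with `dd = delta_obs - delta_L` and `delta_complex` the limiting shift
#' change of the fully complexed ligand.  `[DNA]` is the equilibrium free
#' duplex (`dna_mode = "free_exact"`, via the 1:1 quadratic) or the total
#' duplex `C_DNA` (`"total_approx"`, the common excess-titrant shortcut;
#' accurate when `C_DNA >> C_L` and saturation is mild).
#'
#' @inheritParams free_dna_concentration
#' @param delta_complex Limiting shift change of the bound ligand, ppm
#'   (negative for upfield/low-frequency shifts on stacking).
#' @param dna_mode `"free_exact"` (default) or `"total_approx"`.
#'
#' @return Predicted shift change `delta_obs - delta_L` in ppm, vectorised.
#'
#' @examples
#' predict_titration_shift(Ka = 1, C_DNA = 1, C_L = 1, delta_complex = 1)
#' @export
predict_titration_shift <- function(Ka, C_DNA, C_L, delta_complex,
                                    dna_mode = c("free_exact", "total_approx")) {
  dna_mode <- match.arg(dna_mode)
  check_finite_one(delta_complex, "delta_complex")
  dna <- if (dna_mode == "free_exact") {
    free_dna_concentration(Ka, C_DNA, C_L)
  } else {
    check_nonneg(Ka, "Ka"); check_nonneg(C_DNA, "C_DNA")
    C_DNA
  }
  delta_complex * Ka * dna / (1 + Ka * dna)
}

#' Fit a 1:1 binding constant to a chemical-shift titration
#'
#' Per-proton nonlinear least squares of the 1:1 binding isotherm
#' (see [predict_titration_shift()]) over `(Ka, delta_complex)`, pooled as
#' mean and SD of the per-proton `Ka`.  The unbound-ligand reference shift
#' `delta_L` is taken from the `C_DNA = 0` rows (or supplied via `baseline`).
#'
#' Because the ligand also self-associates, withdrawing monomer into the DNA
#' complex shifts the residual free-ligand resonance during the titration:
#' protons whose shifts are dominated by self-stacking then show distorted
#' isotherms when `delta_L` is held fixed.  With
#' `baseline_mode = "self_assoc"` and a `self_assoc` parameter table the fit
#' re-evaluates `delta_L` at each titration point from the isodesmic model at
#' the residual free-ligand concentration `C_L - [DNA.L]`.
#'
#' @param data Data frame with columns `proton`, `C_L_mM`, `C_DNA_mM`,
#'   `shift_ppm`; the `C_DNA_mM = 0` rows define the baseline shift.
#' @param dna_mode Passed to [predict_titration_shift()].
#' @param baseline Optional data frame `proton`, `delta_L_ppm`, used when the
#'   titration has no `C_DNA = 0` point.
#' @param baseline_mode `"fixed"` (default) or `"self_assoc"`; see Details.
#' @param self_assoc Data frame `proton`, `Ka_self`, `delta_mon`, `delta_max`
#'   (or an `isodesmic_fit`), required for `baseline_mode = "self_assoc"`.
#' @param noise_floor Shift noise scale (ppm); protons with fitted
#'   `|delta_complex| < 3 * noise_floor` are flagged and excluded from the
#'   pooled mean.
#' @param Ka_start,Ka_upper Start and upper bound for `Ka` (1/mM).
#'
#' @return An object of class `binding_fit`: `per_proton` tibble (proton, Ka,
#'   delta_complex, rss, max_saturation, excluded), `Ka_mean`, `Ka_sd`,
#'   `dna_mode`, `baseline_mode` and the input data.  Supports [tidy()],
#'   [glance()], [autoplot()], `print()`.
#'
#' @examples
#' t <- simulate_titration(Ka = 5, noise_sd = 0, seed = 1)
#' glance(fit_binding_titration(t))
#' @export
fit_binding_titration <- function(data,
                                  dna_mode = c("free_exact", "total_approx"),
                                  baseline = NULL,
                                  baseline_mode = c("fixed", "self_assoc"),
                                  self_assoc = NULL,
                                  noise_floor = 0.002,
                                  Ka_start = 1,
                                  Ka_upper = 1000) {
  dna_mode <- match.arg(dna_mode)
  baseline_mode <- match.arg(baseline_mode)
  check_columns(data, c("proton", "C_L_mM", "C_DNA_mM", "shift_ppm"),
                numeric_cols = c("C_L_mM", "C_DNA_mM", "shift_ppm"),
                what = "titration data")
  if (any(data$C_DNA_mM < 0) || any(data$C_L_mM <= 0)) {
    stop_schema("titration data needs C_L_mM > 0 and C_DNA_mM >= 0")
  }
  if (baseline_mode == "self_assoc") {
    self_assoc <- as_self_assoc_table(self_assoc)
  }

  data <- dplyr::arrange(tibble::as_tibble(data), .data$proton, .data$C_DNA_mM)
  groups <- split(data, data$proton)

  per <- purrr::map_dfr(groups, function(g) {
    pts <- g[g$C_DNA_mM > 0, ]
    if (nrow(pts) < 4) stop_schema("proton %s has fewer than 4 titration points", g$proton[1])
    dL <- baseline_shift_for(g, baseline)
    sa <- if (baseline_mode == "self_assoc") {
      row <- self_assoc[self_assoc$proton == g$proton[1], ]
      if (nrow(row) != 1) {
        stop_schema("self_assoc table has no unique row for proton %s", g$proton[1])
      }
      row
    } else NULL
    fit <- fit_one_titration(pts, dL, dna_mode, sa, Ka_start, Ka_upper)
    sat <- max(bound_fraction(fit$Ka, pts$C_DNA_mM, pts$C_L_mM, dna_mode))
    if (sat < 0.2) {
      warn(sprintf("proton %s: Ka poorly constrained (max saturation %.0f%% < 20%%)",
                   g$proton[1], 100 * sat))
    }
    tibble::tibble(
      proton = g$proton[1], Ka = fit$Ka, delta_complex = fit$delta_complex,
      rss = fit$rss, max_saturation = sat,
      excluded = abs(fit$delta_complex) < 3 * noise_floor
    )
  })

  used <- per$Ka[!per$excluded]
  if (length(used) == 0) stop_fit("all protons excluded: no shift response above the noise floor")

  structure(
    list(per_proton = per, Ka_mean = mean(used),
         Ka_sd = if (length(used) > 1) sd(used) else NA_real_,
         dna_mode = dna_mode, baseline_mode = baseline_mode, data = data),
    class = "binding_fit"
  )
}

# Fraction of ligand-facing sites occupied: Ka*[DNA]/(1 + Ka*[DNA]).
bound_fraction <- function(Ka, C_DNA, C_L, dna_mode = "free_exact") {
  dna <- if (dna_mode == "free_exact") free_dna_concentration(Ka, C_DNA, C_L) else C_DNA
  Ka * dna / (1 + Ka * dna)
}

baseline_shift_for <- function(g, baseline) {
  z <- g$shift_ppm[g$C_DNA_mM == 0]
  if (length(z) > 0) return(mean(z))
  if (is.null(baseline)) {
    stop_schema("proton %s has no C_DNA = 0 point and no `baseline` was supplied",
                g$proton[1])
  }
  check_columns(baseline, c("proton", "delta_L_ppm"), numeric_cols = "delta_L_ppm",
                what = "baseline")
  row <- baseline$delta_L_ppm[baseline$proton == g$proton[1]]
  if (length(row) != 1) stop_schema("baseline has no unique delta_L for proton %s", g$proton[1])
  row
}

as_self_assoc_table <- function(self_assoc) {
  if (is.null(self_assoc)) {
    stop_schema("baseline_mode = \"self_assoc\" requires `self_assoc` parameters")
  }
  if (inherits(self_assoc, "isodesmic_fit")) {
    pp <- self_assoc$per_proton
    return(tibble::tibble(proton = pp$proton, Ka_self = pp$Ka,
                          delta_mon = pp$delta_mon, delta_max = pp$delta_max))
  }
  check_columns(self_assoc, c("proton", "Ka_self", "delta_mon", "delta_max"),
                numeric_cols = c("Ka_self", "delta_mon", "delta_max"),
                what = "self_assoc")
  tibble::as_tibble(self_assoc)
}

# Observed-shift forward model for one proton at candidate parameters.
# With self-association correction the baseline is re-evaluated at the
# residual free-ligand concentration C_L - [DNA.L].
predict_titration_obs <- function(Ka, delta_complex, dL, pts, dna_mode, sa) {
  base <- if (is.null(sa)) {
    dL
  } else {
    cx <- complex_concentration(Ka, pts$C_DNA_mM, pts$C_L_mM)
    free_L <- pmax(pts$C_L_mM - cx, 1e-9)
    sa$delta_mon - predict_dilution_shift(sa$Ka_self, free_L, sa$delta_max)
  }
  base + predict_titration_shift(Ka, pts$C_DNA_mM, pts$C_L_mM, delta_complex, dna_mode)
}

fit_one_titration <- function(pts, dL, dna_mode, sa, Ka_start, Ka_upper) {
  dd_end <- pts$shift_ppm[which.max(pts$C_DNA_mM)] - dL
  dc0 <- if (abs(dd_end) > 1e-6) dd_end * 1.5 else 0.01

  resid_fn <- function(par) {
    pts$shift_ppm - predict_titration_obs(par[1], par[2], dL, pts, dna_mode, sa)
  }
  starts <- list(c(Ka_start, dc0), c(Ka_start * 0.1, dc0 * 2),
                 c(Ka_start * 10, dc0 * 0.5), c(Ka_start * 30, dc0))
  for (st in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = c(0, -Inf), upper = c(Ka_upper, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (!is.null(out) && !(out$info %in% c(0, 9))) {
      return(list(Ka = out$par[1], delta_complex = out$par[2], rss = out$deviance))
    }
  }
  stop_fit("titration fit failed to converge for proton %s", pts$proton[1])
}
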